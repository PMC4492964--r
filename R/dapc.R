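#' Number of principal components to retain for DAPC
#'
#' The stability rule of thumb: retain at most one-third of the number of
#' lineages, i.e. `floor(n_mll * fraction)` with a floor of 1.
#'
#' @param n_mll number of multilocus lineages (>= 3)
#' @param fraction retained fraction (default 1/3)
#' @return integer PC count
#' @export
retain_pcs <- function(n_mll, fraction = 1 / 3) {
  if (n_mll < 3L) stop("need at least 3 MLLs to retain a PC")
  max(1L, as.integer(floor(n_mll * fraction)))
}

#' Allele-dosage design matrix
#'
#' One column per (locus, allele); entries are the sample's dosage of that
#' allele over the diploid genotype (0, 0.5 or 1). Missing genotypes are
#' imputed by the column mean, so an untyped locus is neutral in the
#' ordination.
#'
#' @param x a [genotype_matrix()]
#' @return numeric matrix, samples x allele columns
#' @export
allele_dosage <- function(x) {
  cols <- list()
  for (j in seq_len(n_loci(x))) {
    g <- genotypes_at(x, j)
    alleles <- sort(unique(as.vector(g[g != 0])))
    for (a in alleles) {
      d <- (g[, 1L] == a) / 2 + (g[, 2L] == a) / 2
      d[g[, 1L] == 0] <- NA
      cols[[paste0(locus_ids(x)[j], ".", a)]] <- d
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- sample_ids(x)
  for (jj in seq_len(ncol(m))) {
    v <- m[, jj]
    v[is.na(v)] <- mean(v, na.rm = TRUE)
    m[, jj] <- v
  }
  m
}

# PCA + linear discriminants on a numeric design matrix; returns enough
# to project new rows (center, combined loading matrix).
dapc_core <- function(X, groups, n_pcs) {
  groups <- droplevels(factor(groups))
  g <- nlevels(groups)
  if (g < 2L) stop("DAPC needs at least two groups")
  center <- colMeans(X)
  Xc <- sweep(X, 2L, center)
  sv <- svd(Xc)
  pos <- sv$d > max(sv$d) * 1e-9
  n_pcs <- min(n_pcs, sum(pos))
  V <- sv$v[, seq_len(n_pcs), drop = FALSE]
  scores <- Xc %*% V
  pc_eig <- (sv$d^2 / nrow(X))[seq_len(n_pcs)]

  mu <- colMeans(scores)
  W <- matrix(0, n_pcs, n_pcs)
  B <- matrix(0, n_pcs, n_pcs)
  for (lev in levels(groups)) {
    rows <- which(groups == lev)
    cg <- colMeans(scores[rows, , drop = FALSE])
    dev <- sweep(scores[rows, , drop = FALSE], 2L, cg)
    W <- W + crossprod(dev)
    B <- B + length(rows) * tcrossprod(cg - mu)
  }
  ridge <- 0
  if (rcond_sym(W) < 1e-10) {
    ridge <- 1e-6 * mean(diag(W) + 1e-12)
    warning("singular within-group scatter; ridge-regularized")
  }
  ei <- eigen(solve(W + diag(ridge, n_pcs), B))
  n_axes <- min(g - 1L, n_pcs)
  vec <- Re(ei$vectors[, seq_len(n_axes), drop = FALSE])
  proj <- V %*% vec                     # dosage space -> discriminant space
  coords <- Xc %*% proj
  rownames(coords) <- rownames(X)
  colnames(coords) <- paste0("LD", seq_len(n_axes))
  centroids <- matrix(apply(coords, 2, function(cc) tapply(cc, groups, mean)),
                      nrow = g,
                      dimnames = list(levels(groups), colnames(coords)))
  list(coords = coords, centroids = centroids, n_pcs = n_pcs,
       eigenvalues = Re(ei$values[seq_len(n_axes)]),
       pc_eigenvalues = pc_eig, groups = groups,
       center = center, proj = proj)
}

#' Discriminant analysis of principal components (DAPC)
#'
#' Projects MLL allele-dosage profiles onto principal components
#' (eigendecomposition of the column-centered dosage covariance), then
#' finds the linear discriminant axes separating predefined groups in the
#' retained PC space. Model-free: no Hardy-Weinberg or linkage
#' assumptions. With g groups at most `min(g - 1, n_pcs)` discriminant
#' axes exist (one axis for the two-type case). A singular within-group
#' scatter is ridge-regularized with a warning.
#'
#' @param x a [genotype_matrix()], MLL-collapsed
#' @param groups per-sample group labels; defaults to the mito types
#' @param n_pcs retained PCs; `"auto"` applies [retain_pcs()] to the
#'   sample count
#' @return list of class `dapc_fit`: `coords` (samples x axes),
#'   `centroids`, `n_pcs`, `eigenvalues`, `pc_eigenvalues`, `groups`,
#'   plus the projection (`center`, `proj`) for placing new samples
#' @export
dapc_fit <- function(x, groups = x$mito_type, n_pcs = "auto") {
  stopifnot(inherits(x, "genotype_matrix"))
  if (is.null(groups)) stop("group labels required")
  n <- n_samples(x)
  if (identical(n_pcs, "auto")) n_pcs <- retain_pcs(n)
  n_pcs <- as.integer(n_pcs)
  if (n_pcs < 1L || n_pcs >= n) stop("n_pcs must be in [1, n_samples)")
  fit <- dapc_core(allele_dosage(x), groups, n_pcs)
  class(fit) <- "dapc_fit"
  fit
}

rcond_sym <- function(m) {
  e <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (max(abs(e)) == 0) return(0)
  min(abs(e)) / max(abs(e))
}

#' @export
print.dapc_fit <- function(x, ...) {
  cat("dapc_fit:", nrow(x$coords), "samples,", x$n_pcs, "PCs,",
      ncol(x$coords), "discriminant axis/axes\n")
  invisible(x)
}

#' Leave-one-out reassignment accuracy of a DAPC grouping
#'
#' Refits the analysis without each sample in turn, projects the held-out
#' sample into the training discriminant space, and assigns it to the
#' nearest group centroid; the fraction correctly reassigned calibrates
#' how separable the groups are (about chance level for undifferentiated
#' groups).
#'
#' @inheritParams dapc_fit
#' @return fraction of samples reassigned to their own group
#' @export
dapc_loo <- function(x, groups = x$mito_type, n_pcs = "auto") {
  groups <- factor(groups)
  X <- allele_dosage(x)
  n <- nrow(X)
  if (identical(n_pcs, "auto")) n_pcs <- retain_pcs(n - 1L)
  correct <- 0L
  for (i in seq_len(n)) {
    fit <- suppressWarnings(
      dapc_core(X[-i, , drop = FALSE], groups[-i], n_pcs))
    co <- (X[i, ] - fit$center) %*% fit$proj
    cent <- fit$centroids
    d2 <- rowSums((cent - matrix(co, nrow(cent), ncol(cent), byrow = TRUE))^2)
    if (rownames(cent)[which.min(d2)] == as.character(groups[i]))
      correct <- correct + 1L
  }
  correct / n
}
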