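# F_ST between groups, with a label-permutation significance test.

# Per-locus Weir-Cockerham variance components (a, b, c) summed over
# alleles, plus Nei-style H_S / H_T bookkeeping for reporting.
fst_components <- function(x, labels) {
  groups <- unique(labels)
  r <- length(groups)
  L <- n_loci(x)
  comp <- data.frame(locus_id = locus_ids(x), a = NA_real_, b = NA_real_,
                     c = NA_real_, h_s = NA_real_, h_t = NA_real_)
  for (j in seq_len(L)) {
    g <- genotypes_at(x, j)
    typed <- g[, 1L] != 0
    alleles <- sort(unique(as.vector(g[typed, , drop = FALSE])))
    k <- length(alleles)
    if (k < 2L) next
    n_i <- numeric(r)
    p <- matrix(0, r, k)   # sample allele freqs per group
    h <- matrix(0, r, k)   # observed heterozygote freq involving allele a
    for (gi in seq_len(r)) {
      rows <- typed & labels == groups[gi]
      n_i[gi] <- sum(rows)
      if (n_i[gi] == 0) next
      gg <- g[rows, , drop = FALSE]
      cnt <- (tabulate(match(gg[, 1L], alleles), k) +
              tabulate(match(gg[, 2L], alleles), k))
      p[gi, ] <- cnt / (2 * n_i[gi])
      het <- gg[, 1L] != gg[, 2L]
      for (a in seq_len(k))
        h[gi, a] <- mean(het & (gg[, 1L] == alleles[a] | gg[, 2L] == alleles[a]))
    }
    if (any(n_i < 2)) next  # a group without >= 2 typed members is uninformative
    nbar <- mean(n_i)
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    pbar <- colSums(n_i * p) / (r * nbar)
    s2 <- colSums(n_i * (p - rep(pbar, each = r))^2) / ((r - 1) * nbar)
    hbar <- colSums(n_i * h) / (r * nbar)
    av <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
    bv <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cv <- hbar / 2
    comp$a[j] <- sum(av); comp$b[j] <- sum(bv); comp$c[j] <- sum(cv)
    comp$h_s[j] <- mean(1 - rowSums(p^2))        # unweighted mean within-group H_E
    pm <- colMeans(p)
    comp$h_t[j] <- 1 - sum(pm^2)                 # H_E of pooled mean frequencies
  }
  comp
}

fst_value <- function(comp, estimator) {
  ok <- !is.na(comp$a)
  if (!any(ok)) stop("F_ST undefined: every locus is monomorphic")
  if (estimator == "wc") {
    sum(comp$a[ok]) / sum(comp$a[ok] + comp$b[ok] + comp$c[ok])
  } else {
    (mean(comp$h_t[ok]) - mean(comp$h_s[ok])) / mean(comp$h_t[ok])
  }
}

#' F_ST between groups of MLL-collapsed genotypes
#'
#' Multiallelic, multilocus differentiation index between two (or more)
#' groups, combined across loci as a ratio of summed components so that
#' low-information loci do not dominate. Two estimators are offered:
#'
#' * `"wc"` (default): the Weir-Cockerham analysis-of-variance estimator
#'   theta, which corrects both for finite sample sizes and for the finite
#'   number of groups, so its expectation under an island-type divergence
#'   model equals the model's F parameter.
#' * `"nei"`: the heterozygosity-based index
#'   \eqn{(H_T - H_S)/H_T}, with \eqn{H_S} the unweighted mean within-group
#'   expected heterozygosity and \eqn{H_T} the expected heterozygosity of
#'   the pooled (unweighted mean) allele frequencies, averaged
#'   ratio-of-means across loci. With two groups this index is bounded
#'   well below 1 and under-states the divergence parameter.
#'
#' Small negative estimates (finite-sample noise around zero) are clamped
#' to 0 with a warning.
#'
#' @param x a [genotype_matrix()], clonal replicates already collapsed
#' @param labels per-sample group labels; defaults to the mito types
#' @param estimator `"wc"` or `"nei"`
#' @return numeric F_ST, with the per-locus component table in
#'   `attr(, "per_locus")`
#' @export
fst <- function(x, labels = x$mito_type, estimator = c("wc", "nei")) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(x, "genotype_matrix"))
  if (is.null(labels)) stop("group labels required (none stored on matrix)")
  labels <- as.character(labels)
  stopifnot(length(labels) == n_samples(x))
  if (length(unique(labels)) < 2L) stop("F_ST needs at least two groups")
  if (min(table(labels)) < 2L) stop("every group needs >= 2 members")
  comp <- fst_components(x, labels)
  est <- fst_value(comp, estimator)
  if (est < 0) {
    warning("negative F_ST estimate (", signif(est, 3), ") clamped to 0")
    est <- 0
  }
  attr(est, "per_locus") <- comp
  est
}

#' Permutation test for F_ST
#'
#' Permutes group labels across (MLL-collapsed) individuals and recomputes
#' F_ST; \eqn{p = (1 + \#\{F^*_{ST} \ge F_{ST}\}) / (n_{perm} + 1)}, whose
#' attainable floor at the default 999 permutations is 0.001. Raw
#' (unclamped) estimates are compared, so ties at zero are handled fairly.
#'
#' @inheritParams fst
#' @param n_perm number of label permutations (default 999)
#' @param seed optional RNG seed
#' @return list of class `fst_result`: `fst`, `p_value`, `n_perm`,
#'   `estimator`, `per_locus`
#' @export
fst_perm_test <- function(x, labels = x$mito_type, n_perm = 999L,
                          seed = NULL, estimator = c("wc", "nei")) {
  estimator <- match.arg(estimator)
  if (!is.null(seed)) set.seed(seed)
  labels <- as.character(labels)
  comp <- fst_components(x, labels)
  obs <- fst_value(comp, estimator)
  n_ge <- 0L
  for (r in seq_len(n_perm)) {
    perm <- fst_value(fst_components(x, sample(labels)), estimator)
    if (perm >= obs - 1e-12) n_ge <- n_ge + 1L
  }
  est <- max(obs, 0)
  structure(list(fst = est, p_value = (1 + n_ge) / (n_perm + 1),
                 n_perm = n_perm, estimator = estimator, per_locus = comp),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("F_ST = %.3f (%s estimator), P = %.4g (%d permutations)\n",
              x$fst, x$estimator, x$p_value, x$n_perm))
  invisible(x)
}
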