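#' Multilocus diploid microsatellite genotypes
#'
#' A `genotype_matrix` holds codominant diploid genotypes for a set of
#' colonies (samples) at a set of microsatellite loci. Alleles are coded as
#' PCR fragment sizes in base pairs (bp); the reported size includes any
#' universal fluorescent-tail extension, so sizes are comparable only within
#' a locus. The value 0 denotes a missing allele; a genotype is either fully
#' typed (two nonzero calls) or fully missing `(0, 0)` -- half-calls are
#' rejected. Genotypes are unordered pairs and are stored canonically in
#' ascending order, since gametic phase is meaningless for fragment-length
#' data.
#'
#' @param tab numeric matrix with one row per sample and two columns per
#'   locus (allele 1, allele 2), row names giving sample ids.
#' @param loci data frame describing loci, with at least `locus_id`;
#'   optional columns `motif`, `unit_length`, `cross_type`, `accession`.
#'   A character vector of ids is also accepted.
#' @param mito_type character vector of per-sample mitochondrial-type
#'   labels (e.g. `"mt-L"`, `"mt-S"`), or `NULL`.
#' @param population character vector of per-sample population labels, or
#'   `NULL` (defaults to the mito type when available, else `"pop1"`).
#'
#' @return an object of class `genotype_matrix` with components `tab`,
#'   `loci`, `mito_type`, `population`.
#' @export
#' @examples
#' tab <- rbind(s1 = c(100, 104, 200, 200),
#'              s2 = c(104, 104, 0, 0))
#' gm <- genotype_matrix(tab, c("L1", "L2"), mito_type = c("mt-L", "mt-L"))
#' n_samples(gm)
#' genotypes_at(gm, "L2")
genotype_matrix <- function(tab, loci, mito_type = NULL, population = NULL) {
  if (is.character(loci)) loci <- data.frame(locus_id = loci)
  stopifnot(is.data.frame(loci), "locus_id" %in% names(loci))
  loci$locus_id <- as.character(loci$locus_id)
  tab <- as.matrix(tab)
  storage.mode(tab) <- "double"
  n_loc <- nrow(loci)
  if (n_loc < 1L) stop("a genotype_matrix needs at least one locus")
  if (ncol(tab) != 2L * n_loc)
    stop("tab must have 2 columns per locus (", 2L * n_loc,
         " expected, ", ncol(tab), " found)")
  if (is.null(rownames(tab)))
    rownames(tab) <- paste0("s", seq_len(nrow(tab)))
  if (anyDuplicated(rownames(tab))) stop("duplicate sample ids")
  if (anyDuplicated(loci$locus_id)) stop("duplicate locus ids")
  colnames(tab) <- paste0(rep(loci$locus_id, each = 2L), c(".1", ".2"))

  if (anyNA(tab) || any(tab < 0))
    stop("allele calls must be non-negative numbers (0 = missing)")
  # canonicalize unordered pairs ascending; reject half-missing calls
  a1 <- tab[, seq(1L, ncol(tab), by = 2L), drop = FALSE]
  a2 <- tab[, seq(2L, ncol(tab), by = 2L), drop = FALSE]
  half <- xor(a1 == 0, a2 == 0)
  if (any(half)) {
    bad <- which(half, arr.ind = TRUE)[1L, ]
    stop("half-missing genotype at sample '", rownames(tab)[bad[1L]],
         "', locus '", loci$locus_id[bad[2L]],
         "': a genotype is (0,0) or two nonzero calls")
  }
  lo <- pmin(a1, a2); hi <- pmax(a1, a2)
  tab[, seq(1L, ncol(tab), by = 2L)] <- lo
  tab[, seq(2L, ncol(tab), by = 2L)] <- hi

  n <- nrow(tab)
  if (!is.null(mito_type)) {
    mito_type <- as.character(mito_type)
    if (length(mito_type) != n) stop("mito_type must have one entry per sample")
  }
  if (is.null(population)) {
    population <- if (!is.null(mito_type) && !anyNA(mito_type)) mito_type
                  else rep("pop1", n)
  }
  population <- as.character(population)
  if (length(population) != n) stop("population must have one entry per sample")

  structure(list(tab = tab, loci = loci, mito_type = mito_type,
                 population = population),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix: ", n_samples(x), " samples x ", n_loci(x),
      " loci\n", sep = "")
  if (!is.null(x$mito_type)) {
    tt <- table(x$mito_type, useNA = "ifany")
    cat("  mito types: ",
        paste(names(tt), tt, sep = "=", collapse = ", "), "\n", sep = "")
  }
  miss <- mean(x$tab[, seq(1L, ncol(x$tab), by = 2L)] == 0)
  cat("  missing genotypes: ", sprintf("%.1f%%", 100 * miss), "\n", sep = "")
  invisible(x)
}

#' @rdname genotype_matrix
#' @param x a `genotype_matrix`
#' @export
n_samples <- function(x) nrow(x$tab)

#' @rdname genotype_matrix
#' @export
n_loci <- function(x) nrow(x$loci)

#' @rdname genotype_matrix
#' @export
sample_ids <- function(x) rownames(x$tab)

#' @rdname genotype_matrix
#' @export
locus_ids <- function(x) x$loci$locus_id

#' Extract the two-column allele block for one locus
#'
#' @param x a `genotype_matrix`
#' @param locus a locus id or index
#' @return numeric matrix, samples x 2, canonically ordered alleles
#' @export
genotypes_at <- function(x, locus) {
  j <- locus_index(x, locus)
  x$tab[, c(2L * j - 1L, 2L * j), drop = FALSE]
}

locus_index <- function(x, locus) {
  if (is.numeric(locus)) {
    j <- as.integer(locus)
    if (any(j < 1L | j > n_loci(x))) stop("locus index out of range")
  } else {
    j <- match(locus, locus_ids(x))
    if (anyNA(j)) stop("unknown locus: ", paste(locus[is.na(j)], collapse = ", "))
  }
  j
}

#' Integer genotype keys per locus
#'
#' Encodes each sample's unordered genotype at each locus as a small
#' integer (equal keys iff equal genotypes), with NA for missing. Used by
#' the clonality and linkage machinery.
#'
#' @param x a `genotype_matrix`
#' @return integer matrix, samples x loci
#' @keywords internal
genotype_keys <- function(x) {
  L <- n_loci(x)
  out <- matrix(NA_integer_, n_samples(x), L,
                dimnames = list(sample_ids(x), locus_ids(x)))
  for (j in seq_len(L)) {
    g <- genotypes_at(x, j)
    key <- paste(g[, 1L], g[, 2L])
    key[g[, 1L] == 0] <- NA
    out[, j] <- match(key, unique(key[!is.na(key)]))
  }
  out
}

#' Subset a genotype matrix by mitochondrial type and/or loci
#'
#' Restricts a genotype matrix to the samples of a given mitochondrial type
#' and/or a set of loci, preserving input order. An empty result is an
#' error, so downstream statistics cannot silently divide by zero.
#'
#' @param x a `genotype_matrix`
#' @param mito_type optional type label(s) to keep (e.g. `"mt-L"`)
#' @param locus_ids optional locus ids (or indices) to keep; the string
#'   `"cross_type"` keeps the loci flagged `cross_type` in `x$loci`
#' @param sample_ids optional sample ids to keep
#' @param ... ignored
#' @return a `genotype_matrix`
#' @export
subset.genotype_matrix <- function(x, mito_type = NULL, locus_ids = NULL,
                                   sample_ids = NULL, ...) {
  keep_s <- seq_len(n_samples(x))
  if (!is.null(mito_type)) {
    if (is.null(x$mito_type)) stop("matrix carries no mito_type labels")
    keep_s <- keep_s[x$mito_type %in% mito_type]
    if (length(keep_s) == 0L)
      stop("no samples of mito type ", paste(mito_type, collapse = "/"))
  }
  if (!is.null(sample_ids)) {
    idx <- match(sample_ids, rownames(x$tab))
    if (anyNA(idx)) stop("unknown sample id(s)")
    keep_s <- intersect(keep_s, idx)
    if (length(keep_s) == 0L) stop("empty sample subset")
  }
  keep_l <- seq_len(n_loci(x))
  if (!is.null(locus_ids)) {
    if (identical(locus_ids, "cross_type")) {
      if (is.null(x$loci$cross_type)) stop("loci carry no cross_type flag")
      keep_l <- which(as.logical(x$loci$cross_type))
    } else {
      keep_l <- locus_index(x, locus_ids)
    }
    if (length(keep_l) == 0L) stop("empty locus subset")
  }
  cols <- as.vector(rbind(2L * keep_l - 1L, 2L * keep_l))
  genotype_matrix(x$tab[keep_s, cols, drop = FALSE],
                  x$loci[keep_l, , drop = FALSE],
                  mito_type = x$mito_type[keep_s],
                  population = x$population[keep_s])
}

#' Equality of two genotype matrices
#'
#' @param a,b `genotype_matrix` objects
#' @param check_labels also compare mito-type labels
#' @return logical
#' @export
gm_equal <- function(a, b, check_labels = TRUE) {
  ok <- identical(dim(a$tab), dim(b$tab)) &&
    identical(rownames(a$tab), rownames(b$tab)) &&
    identical(locus_ids(a), locus_ids(b)) &&
    isTRUE(all.equal(unname(a$tab), unname(b$tab), tolerance = 1e-9))
  if (ok && check_labels)
    ok <- identical(a$mito_type, b$mito_type)
  ok
}
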