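#' Pairwise genotype mismatch between two samples
#'
#' Compares two colonies locus by locus over a stated locus set. Loci
#' missing in either sample are excluded from the comparison; equality is
#' unordered-pair equality of the two allele sizes. Clone-mates separated
#' by a single somatic mutation or scoring error differ at exactly one
#' locus, which is the basis of the one-mismatch lineage rule.
#'
#' @param x a [genotype_matrix()]
#' @param a,b sample ids or indices
#' @param loci optional locus ids/indices (default: all loci)
#' @return list with `n_compared` and `n_mismatch`
#' @export
genotype_mismatch <- function(x, a, b, loci = NULL) {
  keys <- genotype_keys(x)
  if (!is.null(loci)) keys <- keys[, locus_index(x, loci), drop = FALSE]
  ia <- if (is.numeric(a)) a else match(a, sample_ids(x))
  ib <- if (is.numeric(b)) b else match(b, sample_ids(x))
  if (is.na(ia) || is.na(ib)) stop("unknown sample id")
  ka <- keys[ia, ]; kb <- keys[ib, ]
  both <- !is.na(ka) & !is.na(kb)
  if (!any(both))
    stop("incomparable pair: no locus typed in both '",
         sample_ids(x)[ia], "' and '", sample_ids(x)[ib], "'")
  list(n_compared = sum(both), n_mismatch = sum(ka[both] != kb[both]))
}

# samples x samples mismatch and comparability counts, vectorized per locus
pairwise_mismatch <- function(keys) {
  n <- nrow(keys)
  mism <- matrix(0L, n, n)
  comp <- matrix(0L, n, n)
  for (j in seq_len(ncol(keys))) {
    k <- keys[, j]
    typed <- !is.na(k)
    both <- outer(typed, typed, "&")
    comp <- comp + both
    k0 <- k; k0[is.na(k0)] <- -1L
    mism <- mism + (outer(k0, k0, "!=") & both)
  }
  list(mismatch = mism, compared = comp)
}

#' Assign multilocus lineages (MLLs) under the one-mismatch rule
#'
#' Two colonies are deemed clone-mates (same genet) when their multilocus
#' genotypes differ at no more than `max_mismatch` loci among the loci
#' typed in both; the lone divergent locus, when present, is attributed to
#' a somatic mutation or a scoring error. Because the rule is pairwise,
#' lineages are taken as the transitive (single-linkage) closure of the
#' clone-mate relation, so an MLL is an equivalence class. Lineage ids are
#' deterministic: MLLs are numbered by the input order of their first
#' member.
#'
#' @param x a [genotype_matrix()]
#' @param max_mismatch maximum number of divergent loci for clone-mates
#'   (default 1)
#' @param min_compared minimum loci typed in both members of every pair;
#'   pairs below this floor are an error rather than a silent vacuous match
#' @return an object of class `mll_partition`: list with `assignment`
#'   (named integer vector colony -> MLL id), `n_mll`, `n`
#' @export
assign_mlls <- function(x, max_mismatch = 1L, min_compared = 5L) {
  stopifnot(inherits(x, "genotype_matrix"), n_samples(x) >= 1L)
  keys <- genotype_keys(x)
  n <- nrow(keys)
  pw <- pairwise_mismatch(keys)
  if (n > 1L) {
    cmp <- pw$compared; diag(cmp) <- NA
    bad <- which(cmp < min_compared, arr.ind = TRUE)
    if (nrow(bad))
      stop("incomparable pair (fewer than ", min_compared,
           " shared typed loci): ", sample_ids(x)[bad[1L, 1L]], " / ",
           sample_ids(x)[bad[1L, 2L]])
  }
  adj <- pw$mismatch <= max_mismatch
  # union-find over the clone-mate graph = single-linkage closure
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) if (adj[i, j]) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  ids <- match(roots, unique(roots))  # numbered by first member's order
  names(ids) <- sample_ids(x)
  structure(list(assignment = ids, n_mll = length(unique(ids)), n = n),
            class = "mll_partition")
}

#' @export
print.mll_partition <- function(x, ...) {
  cat("mll_partition: N_MLL =", x$n_mll, ", N =", x$n,
      sprintf(", N_MLL/N = %.3f\n", clonality_index(x)))
  invisible(x)
}

#' Clonality index N_MLL / N
#'
#' Ratio of distinct multilocus lineages to sampled colonies; 1 means no
#' clonality, small values mean extensive clonal (fragmentation) spread.
#'
#' @param partition an `mll_partition` from [assign_mlls()]
#' @return numeric scalar in (0, 1]
#' @export
clonality_index <- function(partition) {
  stopifnot(inherits(partition, "mll_partition"), partition$n >= 1L)
  partition$n_mll / partition$n
}

#' Flag single-locus variants inside clonal lineages
#'
#' Within each MLL, any pair of members differing at exactly one locus
#' points at a somatic mutation or a scoring error at that locus. During
#' marker characterization on the reference type the whole locus is
#' dropped (`mode = "drop_locus"`); on the secondary type only the
#' deviant call is blanked (`mode = "zero_allele"`). The deviant sample at
#' a locus is the carrier of the minority genotype within the MLL; when
#' the split is even, the genotype of the first-encountered member is
#' taken as the lineage reference and later members are flagged.
#'
#' @param x a [genotype_matrix()]
#' @param partition an `mll_partition` computed from `x`
#' @param mode QC action to emit: `"drop_locus"` or `"zero_allele"`
#' @return list of [qc_flag()] objects (possibly empty)
#' @export
flag_single_locus_variants <- function(x, partition,
                                       mode = c("drop_locus", "zero_allele")) {
  mode <- match.arg(mode)
  stopifnot(inherits(partition, "mll_partition"),
            identical(names(partition$assignment), sample_ids(x)))
  keys <- genotype_keys(x)
  flags <- list()
  for (m in unique(partition$assignment)) {
    members <- which(partition$assignment == m)
    if (length(members) < 2L) next
    sub <- keys[members, , drop = FALSE]
    for (j in seq_len(ncol(sub))) {
      k <- sub[, j]
      k <- k[!is.na(k)]
      if (length(unique(k)) < 2L) next
      # a variable locus inside an MLL: confirm it is a 1-locus difference
      # for at least one pair (it is, by construction of the partition)
      counts <- table(k)
      ref <- if (any(counts > min(counts))) {
        as.integer(names(counts)[which.max(counts)])
      } else {
        sub[which(!is.na(sub[, j]))[1L], j]  # even split: first member rules
      }
      deviants <- members[!is.na(sub[, j]) & sub[, j] != ref]
      if (mode == "drop_locus") {
        flags[[length(flags) + 1L]] <-
          qc_flag(locus_ids(x)[j], "single_locus_variant", "drop_locus")
      } else {
        for (d in deviants)
          flags[[length(flags) + 1L]] <-
            qc_flag(locus_ids(x)[j], "single_locus_variant", "zero_allele",
                    sample_id = sample_ids(x)[d])
      }
    }
  }
  # drop duplicate drop_locus flags for the same locus
  if (mode == "drop_locus" && length(flags)) {
    flags <- flags[!duplicated(vapply(flags, `[[`, "", "locus_id"))]
  }
  flags
}

#' Collapse clonal replicates to one representative per MLL
#'
#' Diversity and structure statistics are computed on distinct lineages,
#' not on ramet counts; this keeps the first-encountered colony of each
#' MLL and drops the rest.
#'
#' @param x a [genotype_matrix()]
#' @param partition an `mll_partition` computed from `x`
#' @return a `genotype_matrix` with one sample per MLL
#' @export
collapse_mlls <- function(x, partition) {
  stopifnot(identical(names(partition$assignment), sample_ids(x)))
  keep <- !duplicated(partition$assignment)
  subset(x, sample_ids = sample_ids(x)[keep])
}
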