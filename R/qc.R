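#' Locus quality-control flags
#'
#' A QC flag records one problem found at a locus and the remedy to apply.
#' The two remedies mirror common practice when a single-locus variant
#' (somatic mutation or scoring error) turns up inside a clonal lineage:
#' during marker characterization the whole locus is discarded
#' (`drop_locus`); once a locus set is frozen, only the offending call is
#' blanked to missing (`zero_allele`).
#'
#' @param locus_id locus the flag refers to
#' @param issue one of `"single_locus_variant"`, `"non_amplifying"`,
#'   `"low_polymorphism"`
#' @param action one of `"drop_locus"`, `"zero_allele"`, `"none"`;
#'   `zero_allele` requires a `sample_id`, `drop_locus` forbids one
#' @param sample_id sample carrying the offending call (for `zero_allele`)
#' @return an object of class `qc_flag`
#' @export
qc_flag <- function(locus_id,
                    issue = c("single_locus_variant", "non_amplifying",
                              "low_polymorphism"),
                    action = c("drop_locus", "zero_allele", "none"),
                    sample_id = NULL) {
  issue <- match.arg(issue)
  action <- match.arg(action)
  if (action == "drop_locus" && !is.null(sample_id))
    stop("drop_locus flags apply to the whole locus; sample_id must be NULL")
  if (action == "zero_allele" && is.null(sample_id))
    stop("zero_allele flags must name the sample to blank")
  structure(list(locus_id = as.character(locus_id), issue = issue,
                 action = action,
                 sample_id = if (is.null(sample_id)) NA_character_
                             else as.character(sample_id)),
            class = "qc_flag")
}

#' @export
print.qc_flag <- function(x, ...) {
  cat("qc_flag:", x$issue, "at", x$locus_id,
      if (!is.na(x$sample_id)) paste0("(sample ", x$sample_id, ")"),
      "->", x$action, "\n")
  invisible(x)
}

#' Apply locus QC actions to a genotype matrix
#'
#' `drop_locus` removes the locus column for all samples; `zero_allele`
#' sets the flagged sample's genotype at that locus to `(0, 0)`; `none`
#' leaves data untouched. Applying the same flags twice is a no-op, and
#' flags on distinct loci/samples commute.
#'
#' @param x a [genotype_matrix()]
#' @param flags a list of [qc_flag()] objects
#' @return a `genotype_matrix` with the actions applied
#' @export
apply_locus_qc <- function(x, flags) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (inherits(flags, "qc_flag")) flags <- list(flags)
  drop <- character(0)
  for (f in flags) {
    stopifnot(inherits(f, "qc_flag"))
    j <- match(f$locus_id, locus_ids(x))
    if (is.na(j)) stop("flag references unknown locus '", f$locus_id, "'")
    if (f$action == "drop_locus") {
      drop <- union(drop, f$locus_id)
    } else if (f$action == "zero_allele") {
      i <- match(f$sample_id, sample_ids(x))
      if (is.na(i)) stop("flag references unknown sample '", f$sample_id, "'")
      x$tab[i, c(2L * j - 1L, 2L * j)] <- 0
    }
  }
  if (length(drop)) {
    keep <- setdiff(locus_ids(x), drop)
    if (length(keep) == 0L) stop("QC would drop every locus")
    x <- subset(x, locus_ids = keep)
  }
  x
}
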