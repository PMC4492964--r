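#' Run the full genotype-to-inference analysis
#'
#' End-to-end orchestration in the standard order for a two-type, partly
#' clonal dataset: multilocus-lineage assignment per type, clonal
#' collapse, per-locus diversity and Hardy-Weinberg tables, all-pairs
#' linkage disequilibrium with FDR control, F_ST between types with a
#' permutation test, admixture-model clustering across a K range with
#' replicate runs, Evanno delta-K model choice, replicate-run merging,
#' and DAPC. The reference (first) type is analyzed on the full locus
#' set; the second type and every between-type analysis use the
#' cross-type loci only (all loci when no `cross_type` flag is present).
#' One master seed expands deterministically into per-stage seeds, so a
#' rerun with the same config reproduces every artifact.
#'
#' @param x a [genotype_matrix()] with mito-type labels, or a file path
#' @param dialect input dialect when `x` is a path
#' @param out_dir optional directory for per-stage TSV/JSON artifacts
#' @param types the two type labels, reference first
#' @param max_mismatch clone-mate mismatch tolerance (default 1)
#' @param n_perm_ld,n_perm_fst permutation counts
#' @param q_fdr FDR level for the LD scan
#' @param k_range,n_iter,burn_in,n_reps clustering controls
#' @param n_pcs DAPC PC count or `"auto"` (one-third rule)
#' @param seed master seed
#' @return list of class `pipeline_result` with components `mll`,
#'   `stats`, `ld`, `fst`, `cluster`, `dapc`, `log`
#' @export
run_pipeline <- function(x, dialect = "genalex", out_dir = NULL,
                         types = NULL, max_mismatch = 1L,
                         n_perm_ld = 1000L, n_perm_fst = 999L, q_fdr = 0.05,
                         k_range = 1:6, n_iter = 10L, burn_in = 5000L,
                         n_reps = 20000L, n_pcs = "auto", seed = 1L) {
  t0 <- Sys.time()
  log <- list()
  note <- function(stage, msg) {
    entry <- list(stage = stage, time = format(Sys.time()), msg = msg)
    log[[length(log) + 1L]] <<- entry
  }
  stage_seed <- function(i) (seed * 48271 + i * 65537) %% 2147483629

  if (is.character(x)) x <- read_genotype_table(x, dialect)
  if (is.null(types)) {
    if (is.null(x$mito_type)) stop("matrix carries no mito-type labels")
    types <- unique(x$mito_type)
  }
  if (length(types) != 2L) stop("pipeline expects exactly two types")
  cross <- if (!is.null(x$loci$cross_type) &&
               any(!as.logical(x$loci$cross_type)))
    locus_ids(x)[as.logical(x$loci$cross_type)] else locus_ids(x)

  # --- MLL assignment per type ---
  mll <- list(); collapsed <- list()
  for (ti in seq_along(types)) {
    ty <- types[ti]
    loci_ty <- if (ti == 1L) locus_ids(x) else cross
    xt <- subset(x, mito_type = ty, locus_ids = loci_ty)
    part <- assign_mlls(xt, max_mismatch = max_mismatch)
    mll[[ty]] <- list(partition = part,
                      clonality = clonality_index(part),
                      flags = flag_single_locus_variants(
                        xt, part,
                        mode = if (ti == 1L) "drop_locus" else "zero_allele"))
    collapsed[[ty]] <- collapse_mlls(xt, part)
    note("mll", sprintf("%s: N_MLL = %d, N = %d, N_MLL/N = %.3f", ty,
                        part$n_mll, part$n, clonality_index(part)))
  }

  # --- diversity tables ---
  stats_tabs <- lapply(types, function(ty)
    locus_stats_table(collapsed[[ty]], group = ty))
  names(stats_tabs) <- types
  note("stats", "per-locus N_A / H_E / H_O / F_IS / HWE tables computed")

  # --- linkage disequilibrium ---
  ld <- lapply(seq_along(types), function(ti) {
    ld_scan(collapsed[[types[ti]]], n_perm = n_perm_ld, q = q_fdr,
            seed = stage_seed(10L + ti))
  })
  names(ld) <- types
  note("ld", sprintf("LD scans done (%d permutations, FDR q = %g)",
                     n_perm_ld, q_fdr))

  # --- between-type data: cross-type loci, MLL-collapsed, pooled ---
  pooled <- pool_collapsed(collapsed, types, cross)
  fst_res <- fst_perm_test(pooled, n_perm = n_perm_fst,
                           seed = stage_seed(20L))
  note("fst", sprintf("F_ST = %.3f, P = %.4g", fst_res$fst, fst_res$p_value))

  scan <- cluster_k_scan(pooled, k_range = k_range, n_iter = n_iter,
                         burn_in = burn_in, n_reps = n_reps,
                         seed = stage_seed(30L))
  note("cluster", sprintf("K scan %s, best K by delta-K = %s",
                          paste(range(k_range), collapse = "-"),
                          scan$evanno$best_k))

  dapc <- dapc_fit(pooled, n_pcs = n_pcs)
  note("dapc", sprintf("DAPC with %d PCs", dapc$n_pcs))

  out <- structure(list(mll = mll, stats = stats_tabs, ld = ld,
                        fst = fst_res, cluster = scan, dapc = dapc,
                        types = types, seed = seed, log = log,
                        elapsed = as.numeric(difftime(Sys.time(), t0,
                                                      units = "secs"))),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_artifacts(out, pooled, out_dir)
  out
}

# stack the per-type collapsed matrices on the shared cross-type loci
pool_collapsed <- function(collapsed, types, cross) {
  parts <- lapply(types, function(ty)
    subset(collapsed[[ty]], locus_ids = intersect(cross,
                                                  locus_ids(collapsed[[ty]]))))
  tab <- do.call(rbind, lapply(parts, `[[`, "tab"))
  genotype_matrix(tab, parts[[1L]]$loci,
                  mito_type = unlist(lapply(parts, `[[`, "mito_type")))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result (", sprintf("%.1f", x$elapsed), " s)\n", sep = "")
  for (ty in x$types)
    cat(sprintf("  %s: N_MLL = %d / N = %d (N_MLL/N = %.3f)\n", ty,
                x$mll[[ty]]$partition$n_mll, x$mll[[ty]]$partition$n,
                x$mll[[ty]]$clonality))
  cat(sprintf("  F_ST = %.3f (P = %.4g)\n", x$fst$fst, x$fst$p_value))
  cat("  best K by delta-K:", x$cluster$evanno$best_k, "\n")
  invisible(x)
}

write_pipeline_artifacts <- function(res, pooled, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wtsv <- function(d, f) utils::write.table(
    d, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  for (ty in res$types) {
    part <- res$mll[[ty]]$partition
    wtsv(data.frame(colony_id = names(part$assignment),
                    mll_id = part$assignment),
         paste0("mll_", gsub("[^A-Za-z0-9]", "_", ty), ".tsv"))
    wtsv(res$stats[[ty]],
         paste0("stats_", gsub("[^A-Za-z0-9]", "_", ty), ".tsv"))
    wtsv(res$ld[[ty]],
         paste0("ld_", gsub("[^A-Za-z0-9]", "_", ty), ".tsv"))
  }
  jsonlite::write_json(
    list(fst = res$fst$fst, p_value = res$fst$p_value,
         n_perm = res$fst$n_perm, estimator = res$fst$estimator),
    file.path(out_dir, "fst.json"), auto_unbox = TRUE, digits = NA)
  wtsv(res$cluster$evanno$table, "evanno.tsv")
  for (k in names(res$cluster$merged_q)) {
    q <- res$cluster$merged_q[[k]]
    wtsv(data.frame(sample_id = rownames(q), q, check.names = FALSE),
         paste0("merged_q_K", k, ".tsv"))
  }
  co <- res$dapc$coords
  wtsv(data.frame(sample_id = rownames(co), group = res$dapc$groups, co,
                  check.names = FALSE), "dapc.tsv")
  jsonlite::write_json(res$log, file.path(out_dir, "log.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}
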