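#' MCMC configuration for admixture clustering
#'
#' Hyperparameter defaults follow the reference Bayesian-clustering
#' toolchain: a symmetric allele-frequency prior with concentration
#' `lambda = 1` (uniform over the simplex), a single admixture
#' concentration `alpha` shared by all clusters, initialized at 1 with a
#' uniform prior on `(0, alpha_max = 10)` and a random-walk Metropolis
#' proposal of sd 0.025. Production analyses of real data typically use a
#' burn-in of 100,000 followed by 1,000,000 replications; the defaults
#' here are scaled down for the small MLL-level datasets this package
#' targets, and tests scale further.
#'
#' @param k assumed number of clusters K (>= 1)
#' @param burn_in burn-in iterations
#' @param n_reps post-burn-in iterations
#' @param lambda Dirichlet concentration of the allele-frequency prior
#' @param alpha_init,alpha_max,alpha_proposal_sd admixture hyperparameter
#'   controls
#' @param thin store every `thin`-th post-burn-in sample for the posterior
#'   mean Q (the likelihood trace keeps every iteration)
#' @param seed optional RNG seed
#' @return list of class `mcmc_config`
#' @export
mcmc_config <- function(k, burn_in = 5000L, n_reps = 20000L, lambda = 1,
                        alpha_init = 1, alpha_max = 10,
                        alpha_proposal_sd = 0.025, thin = 10L, seed = NULL) {
  stopifnot(k >= 1L, burn_in > 0L, n_reps > 0L, lambda > 0,
            alpha_init > 0, alpha_max > 0, thin >= 1L)
  structure(list(k = as.integer(k), burn_in = as.integer(burn_in),
                 n_reps = as.integer(n_reps), lambda = lambda,
                 alpha_init = alpha_init, alpha_max = alpha_max,
                 alpha_proposal_sd = alpha_proposal_sd,
                 thin = as.integer(thin), seed = seed),
            class = "mcmc_config")
}

# recode a genotype_matrix to 0-based allele indices per locus (-1 missing)
geno_codes <- function(x) {
  L <- n_loci(x)
  codes <- matrix(-1L, n_samples(x), 2L * L)
  n_alleles <- integer(L)
  for (j in seq_len(L)) {
    g <- genotypes_at(x, j)
    alleles <- sort(unique(as.vector(g[g != 0])))
    n_alleles[j] <- max(length(alleles), 1L)
    for (c2 in 1:2) {
      v <- g[, c2]
      codes[, 2L * j - 2L + c2] <-
        ifelse(v == 0, -1L, match(v, alleles) - 1L)
    }
  }
  list(codes = codes, n_alleles = n_alleles)
}

#' Run one admixture-model Gibbs chain
#'
#' Bayesian clustering of MLL-collapsed diploid genotypes under the
#' admixture model with independent allele frequencies between clusters.
#' Each individual owns a membership vector Q over K clusters; each allele
#' copy is assigned a cluster of origin Z given Q and the cluster allele
#' frequencies P; P and Q are Gibbs-updated from their Dirichlet full
#' conditionals, and the shared admixture parameter alpha follows a
#' random-walk Metropolis step. Missing allele copies are skipped in every
#' update. Returns the posterior-mean membership matrix and the model
#' log-probability Ln P(D) computed from the post-burn-in likelihood
#' trace (see [ln_pd()]).
#'
#' Convergence of alpha is reported, not enforced: when the post-burn-in
#' range of alpha exceeds `alpha_max / 2`, the run is tagged with a
#' warning flag, mirroring the practice of checking the mean and range of
#' alpha for each K.
#'
#' @param x a [genotype_matrix()] (MLL-collapsed)
#' @param config an [mcmc_config()]
#' @param store_state keep per-sample P and Q snapshots (tiny runs only;
#'   used for likelihood verification)
#' @return list of class `run_result`: `q` (samples x K, rows sum to 1),
#'   `ln_pd`, `ln_l_mean`, `ln_l_var`, `lnl_trace`, `alpha_mean`,
#'   `alpha_range`, `k`, `warnings`
#' @export
run_admixture <- function(x, config, store_state = FALSE) {
  stopifnot(inherits(x, "genotype_matrix"), inherits(config, "mcmc_config"))
  if (n_samples(x) < 1L) stop("empty genotype matrix")
  if (!is.null(config$seed)) set.seed(config$seed)
  gc <- geno_codes(x)
  res <- .admixture_gibbs(gc$codes, gc$n_alleles, config$k, config$burn_in,
                          config$n_reps, config$lambda, config$alpha_init,
                          config$alpha_max, config$alpha_proposal_sd,
                          config$thin, store_state)
  rownames(res$q) <- sample_ids(x)
  colnames(res$q) <- paste0("K", seq_len(config$k))
  tr <- res$lnl_trace
  warnings <- character(0)
  if (config$k > 1L && diff(res$alpha_range) > config$alpha_max / 2)
    warnings <- c(warnings, sprintf(
      "alpha range %.2f-%.2f exceeds alpha_max/2: possible non-convergence",
      res$alpha_range[1L], res$alpha_range[2L]))
  out <- list(q = res$q, ln_pd = ln_pd(tr), ln_l_mean = mean(tr),
              ln_l_var = pop_var(tr), lnl_trace = tr,
              alpha_mean = res$alpha_mean, alpha_range = res$alpha_range,
              k = config$k, warnings = warnings)
  if (store_state) {
    out$state_q <- res$state_q; out$state_p <- res$state_p
    out$state_lnl <- unlist(res$state_lnl)
  }
  for (w in warnings) warning(w, call. = FALSE)
  class(out) <- "run_result"
  out
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("admixture run: K = %d, Ln P(D) = %.2f, mean lnL = %.2f, alpha = %.3f [%.3f, %.3f]\n",
              x$k, x$ln_pd, x$ln_l_mean, x$alpha_mean,
              x$alpha_range[1L], x$alpha_range[2L]))
  invisible(x)
}

pop_var <- function(v) mean((v - mean(v))^2)  # denominator n

#' Model log-probability Ln P(D) from a likelihood trace
#'
#' The harmonic-approximation estimator used for model choice across K:
#' mean of the post-burn-in log-likelihood trace minus half its variance
#' (population variance, denominator n). A constant trace returns its
#' mean. Always `<=` the trace mean.
#'
#' @param ln_l_trace numeric vector of post-burn-in log-likelihoods
#'   (length >= 2; a length-1 trace is returned as is)
#' @return numeric scalar
#' @export
ln_pd <- function(ln_l_trace) {
  stopifnot(length(ln_l_trace) >= 1L)
  mean(ln_l_trace) - pop_var(ln_l_trace) / 2
}

#' Evanno delta-K model choice across K
#'
#' Second-order rate of change of Ln P(D) (here: of the replicate-mean
#' model log-probability L(K)) scaled by the between-replicate standard
#' deviation: \eqn{L'(K) = L(K) - L(K-1)},
#' \eqn{|L''(K)| = |L'(K+1) - L'(K)|}, \eqn{\Delta K = |L''(K)| / sd(K)}.
#' Delta-K exists only for interior K with positive sd; the argmax over
#' those is the suggested cluster count. Delta-K cannot, by construction,
#' evaluate the smallest and largest K tried.
#'
#' @param summary_by_k data.frame with columns `k`, `mean_l`, `sd_l` for
#'   consecutive K values (typically from [cluster_k_scan()])
#' @return list of class `evanno_summary`: the input table augmented with
#'   `l_prime`, `abs_l_double_prime`, `delta_k`, plus `best_k`
#' @export
evanno <- function(summary_by_k) {
  d <- as.data.frame(summary_by_k)
  stopifnot(all(c("k", "mean_l", "sd_l") %in% names(d)))
  d <- d[order(d$k), , drop = FALSE]
  if (any(diff(d$k) != 1L)) stop("K values must be consecutive")
  nk <- nrow(d)
  d$l_prime <- c(NA, diff(d$mean_l))
  d$abs_l_double_prime <- c(NA, abs(diff(d$l_prime[-1L])), NA)
  d$delta_k <- ifelse(!is.na(d$abs_l_double_prime) & d$sd_l > 0,
                      d$abs_l_double_prime / d$sd_l, NA_real_)
  best_k <- if (all(is.na(d$delta_k))) NA_integer_
            else d$k[which.max(d$delta_k)]
  structure(list(table = d, best_k = best_k), class = "evanno_summary")
}

#' @export
print.evanno_summary <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat("best K by delta-K:", x$best_k, "\n")
  invisible(x)
}

#' Replicate admixture runs across a range of K
#'
#' Runs `n_iter` independent chains for every K in `k_range`, collects
#' Ln P(D) summaries for [evanno()], and merges each K's replicate
#' membership matrices with [align_and_merge()].
#'
#' @param x a [genotype_matrix()] (MLL-collapsed)
#' @param k_range integer vector of K values (consecutive, e.g. `1:6`)
#' @param n_iter replicate chains per K (default 10)
#' @param burn_in,n_reps chain lengths per run
#' @param seed master seed; per-run seeds are derived deterministically
#' @param ... further arguments to [mcmc_config()]
#' @return list: `runs` (list of lists of `run_result`), `summary`
#'   (data.frame k, mean_l, sd_l over the replicate Ln P(D) values),
#'   `evanno`, `merged_q` (list of merged Q matrices per K)
#' @export
cluster_k_scan <- function(x, k_range = 1:6, n_iter = 10L, burn_in = 5000L,
                           n_reps = 20000L, seed = NULL, ...) {
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  runs <- list(); summ <- list(); merged <- list()
  for (k in k_range) {
    rk <- vector("list", n_iter)
    for (it in seq_len(n_iter)) {
      run_seed <- (seed + 10007L * match(k, k_range) + 97L * it) %% 2147483647L
      cfg <- mcmc_config(k, burn_in = burn_in, n_reps = n_reps,
                         seed = run_seed, ...)
      rk[[it]] <- suppressWarnings(run_admixture(x, cfg))
    }
    runs[[as.character(k)]] <- rk
    lp <- vapply(rk, `[[`, 0, "ln_pd")
    summ[[as.character(k)]] <- data.frame(k = k, mean_l = mean(lp),
                                          sd_l = stats::sd(lp))
    merged[[as.character(k)]] <- align_and_merge(lapply(rk, `[[`, "q"))
  }
  summary <- do.call(rbind, summ)
  list(runs = runs, summary = summary, evanno = evanno(summary),
       merged_q = merged)
}

#' Align replicate membership matrices and average them
#'
#' Cluster labels are arbitrary within each MCMC run (label switching).
#' Runs are aligned greedily: the first run fixes the reference; each
#' subsequent run is permuted by the column permutation maximizing the
#' sum of elementwise products with the incrementally built mean, which
#' is exhaustive over permutations for the K <= 6 regime this package
#' targets. The aligned matrices are averaged elementwise and rows
#' renormalized to sum to 1.
#'
#' @param qs list of membership matrices sharing dimensions and row order
#' @return merged membership matrix
#' @export
align_and_merge <- function(qs) {
  stopifnot(length(qs) >= 1L)
  k <- ncol(qs[[1L]])
  if (!all(vapply(qs, ncol, 0L) == k)) stop("runs disagree on K")
  if (!all(vapply(qs, nrow, 0L) == nrow(qs[[1L]])))
    stop("runs disagree on sample count")
  perms <- all_permutations(k)
  ref <- qs[[1L]]
  acc <- ref
  for (r in seq_along(qs)[-1L]) {
    q <- qs[[r]]
    best <- NULL; best_score <- -Inf
    for (p in perms) {
      score <- sum(acc / (r - 1) * q[, p, drop = FALSE])
      if (score > best_score) { best_score <- score; best <- p }
    }
    acc <- acc + q[, best, drop = FALSE]
  }
  merged <- acc / length(qs)
  merged / rowSums(merged)
}

all_permutations <- function(k) {
  if (k == 1L) return(list(1L))
  sub <- all_permutations(k - 1L)
  out <- list()
  for (p in sub) for (pos in seq_len(k)) out[[length(out) + 1L]] <-
    append(p, k, after = pos - 1L)
  out
}
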