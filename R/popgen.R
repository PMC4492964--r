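#' Allele frequencies at one locus
#'
#' Frequencies over nonzero allele calls; missing genotypes are excluded
#' from the denominator.
#'
#' @param x a [genotype_matrix()] (normally MLL-collapsed)
#' @param locus locus id or index
#' @return named numeric vector of frequencies summing to 1, names = allele
#'   sizes (bp)
#' @export
allele_freqs <- function(x, locus) {
  g <- genotypes_at(x, locus)
  calls <- as.vector(g)
  calls <- calls[calls != 0]
  if (length(calls) == 0L)
    stop("locus '", if (is.numeric(locus)) locus_ids(x)[locus] else locus,
         "' has no typed genotype")
  tt <- table(calls)
  f <- as.numeric(tt) / sum(tt)
  names(f) <- names(tt)
  f
}

#' Per-locus diversity summary
#'
#' Computes, for one locus in one (already subset, MLL-collapsed) group:
#' the number of alleles N_A, expected heterozygosity
#' \eqn{H_E = 1 - \sum_i p_i^2} (uncorrected, the convention of the
#' standard spreadsheet toolchain), observed heterozygosity H_O (fraction
#' of typed genotypes that are heterozygous), the deviation index
#' \eqn{F_{IS} = (H_E - H_O)/H_E} (NA when \eqn{H_E = 0}: a monomorphic
#' locus carries no information about Hardy-Weinberg deviation), and the
#' chi-square Hardy-Weinberg probability from [hwe_test()].
#'
#' @param x a [genotype_matrix()], MLL-collapsed
#' @param locus locus id or index
#' @param group label stored in the output (e.g. `"mt-L"`)
#' @param hwe also run the Hardy-Weinberg test (needs >= 2 alleles)
#' @return one-row data.frame: locus_id, group, n, n_a, h_e, h_o, f_is, hwe_p
#' @export
summarize_locus <- function(x, locus, group = NA_character_, hwe = TRUE) {
  g <- genotypes_at(x, locus)
  typed <- g[g[, 1L] != 0, , drop = FALSE]
  p <- allele_freqs(x, locus)
  h_e <- 1 - sum(p^2)
  h_o <- mean(typed[, 1L] != typed[, 2L])
  f_is <- deviation_index(h_e, h_o)
  hwe_p <- NA_real_
  if (hwe && length(p) >= 2L) hwe_p <- hwe_test(x, locus)$p_value
  data.frame(locus_id = if (is.numeric(locus)) locus_ids(x)[locus] else locus,
             group = group, n = nrow(typed), n_a = length(p),
             h_e = h_e, h_o = h_o, f_is = f_is, hwe_p = hwe_p,
             stringsAsFactors = FALSE)
}

#' Deviation index F_IS from expected and observed heterozygosity
#'
#' \eqn{F_{IS} = (H_E - H_O)/H_E}: positive values mean a heterozygote
#' deficit relative to Hardy-Weinberg proportions, negative an excess.
#' Undefined (NA) for a monomorphic locus (\eqn{H_E = 0}).
#'
#' @param h_e expected heterozygosity in `[0, 1)`
#' @param h_o observed heterozygosity in `[0, 1]`
#' @return numeric F_IS, or NA when `h_e` is 0
#' @export
deviation_index <- function(h_e, h_o) {
  stopifnot(h_e >= 0, h_e < 1, h_o >= 0, h_o <= 1)
  if (h_e > 0) (h_e - h_o) / h_e else NA_real_
}

#' Chi-square test of Hardy-Weinberg proportions at one locus
#'
#' Goodness-of-fit of observed genotype counts against the proportions
#' implied by random mating at the sample allele frequencies:
#' \eqn{n p_i^2} for homozygotes and \eqn{2 n p_i p_j} for heterozygotes,
#' on \eqn{k(k-1)/2} degrees of freedom for \eqn{k} alleles. Expected
#' counts below 1 (or mostly below 5) make the chi-square approximation
#' unreliable; the result then carries `low_count = TRUE` rather than
#' being suppressed.
#'
#' @param x a [genotype_matrix()], MLL-collapsed
#' @param locus locus id or index
#' @return list: `statistic`, `df`, `p_value`, `low_count`
#' @export
hwe_test <- function(x, locus) {
  g <- genotypes_at(x, locus)
  typed <- g[g[, 1L] != 0, , drop = FALSE]
  n <- nrow(typed)
  if (n < 1L) stop("no typed genotype at this locus")
  alleles <- sort(unique(as.vector(typed)))
  k <- length(alleles)
  if (k < 2L) stop("Hardy-Weinberg test needs a polymorphic locus")
  p <- allele_freqs(x, locus)
  p <- p[as.character(alleles)]
  obs <- matrix(0, k, k)  # upper triangle incl. diagonal
  i1 <- match(typed[, 1L], alleles); i2 <- match(typed[, 2L], alleles)
  for (r in seq_len(n)) {
    a <- min(i1[r], i2[r]); b <- max(i1[r], i2[r])
    obs[a, b] <- obs[a, b] + 1
  }
  exp_ <- matrix(0, k, k)
  for (a in seq_len(k)) for (b in a:k)
    exp_[a, b] <- if (a == b) n * p[a]^2 else 2 * n * p[a] * p[b]
  o <- obs[upper.tri(obs, diag = TRUE)]
  e <- exp_[upper.tri(exp_, diag = TRUE)]
  stat <- sum((o - e)^2 / e)
  df <- k * (k - 1) / 2
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       low_count = any(e < 1) || mean(e < 5) > 0.2)
}

# G statistic (log-likelihood-ratio) for a two-way contingency table of
# integer category codes; cells with zero observed count contribute 0.
g_statistic <- function(a, b) {
  ka <- max(a); kb <- max(b)
  tab <- tabulate(a + ka * (b - 1L), ka * kb)
  n <- length(a)
  e <- as.vector(outer(tabulate(a, ka), tabulate(b, kb))) / n
  nz <- tab > 0L
  2 * sum(tab[nz] * log(tab[nz] / e[nz]))
}

#' Permutation G-test of linkage disequilibrium between two loci
#'
#' Tests non-random association of the (unordered) genotypes at two loci
#' with a log-likelihood-ratio G statistic on the two-locus genotype
#' contingency table, comparing the observed G with its permutation null:
#' one locus's genotypes are shuffled across individuals `n_perm` times and
#' \eqn{p = (1 + \#\{G^* \ge G\}) / (n_{perm} + 1)}. Exact-test engines
#' reach the same null hypothesis by Markov chain instead; the permutation
#' version is used here because it is seedable and calibratable.
#'
#' @param x a [genotype_matrix()], MLL-collapsed
#' @param locus_a,locus_b locus ids or indices
#' @param n_perm number of permutations (default 1000)
#' @param seed optional RNG seed for reproducibility
#' @param min_shared minimum individuals typed at both loci
#' @return list: `locus_pair`, `g_statistic`, `p_value`, `n`
#' @export
ld_test <- function(x, locus_a, locus_b, n_perm = 1000L, seed = NULL,
                    min_shared = 5L) {
  keys <- genotype_keys(x)
  ja <- locus_index(x, locus_a); jb <- locus_index(x, locus_b)
  ka <- keys[, ja]; kb <- keys[, jb]
  both <- !is.na(ka) & !is.na(kb)
  if (sum(both) < min_shared)
    stop("fewer than ", min_shared, " individuals typed at both loci")
  ka <- ka[both]; kb <- kb[both]
  if (!is.null(seed)) set.seed(seed)
  g_obs <- g_statistic(ka, kb)
  n_ge <- 0L
  for (r in seq_len(n_perm))
    if (g_statistic(ka, sample(kb)) >= g_obs - 1e-12) n_ge <- n_ge + 1L
  list(locus_pair = c(locus_ids(x)[ja], locus_ids(x)[jb]),
       g_statistic = g_obs,
       p_value = (1 + n_ge) / (n_perm + 1),
       n = length(ka))
}

#' All-pairs linkage disequilibrium scan with FDR control
#'
#' Runs [ld_test()] on every locus pair and flags significance after
#' Benjamini-Hochberg adjustment at level `q`.
#'
#' @param x a [genotype_matrix()], MLL-collapsed
#' @param n_perm permutations per pair
#' @param q FDR level (default 0.05, i.e. 95% confidence)
#' @param seed optional RNG seed
#' @return data.frame: locus_a, locus_b, g_statistic, p_value,
#'   significant_after_fdr
#' @export
ld_scan <- function(x, n_perm = 1000L, q = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- n_loci(x)
  pairs <- utils::combn(L, 2)
  res <- apply(pairs, 2, function(pr)
    ld_test(x, pr[1L], pr[2L], n_perm = n_perm))
  out <- data.frame(
    locus_a = vapply(res, function(r) r$locus_pair[1L], ""),
    locus_b = vapply(res, function(r) r$locus_pair[2L], ""),
    g_statistic = vapply(res, `[[`, 0, "g_statistic"),
    p_value = vapply(res, `[[`, 0, "p_value"))
  out$significant_after_fdr <- fdr_adjust(out$p_value, q = q)
  out
}

#' Benjamini-Hochberg significance flags
#'
#' Step-up false-discovery-rate procedure: sort the m p-values ascending,
#' find the largest i with \eqn{p_{(i)} \le q\, i/m}, and flag all tests
#' with p-values up to that threshold.
#'
#' @param p_values numeric vector in `[0, 1]`
#' @param q FDR level
#' @return logical vector of per-test flags (empty input gives empty output)
#' @export
fdr_adjust <- function(p_values, q = 0.05) {
  m <- length(p_values)
  if (m == 0L) return(logical(0))
  stopifnot(all(p_values >= 0 & p_values <= 1))
  o <- order(p_values)
  ps <- p_values[o]
  ok <- which(ps <= q * seq_len(m) / m)
  flags <- logical(m)
  if (length(ok)) flags[o[seq_len(max(ok))]] <- TRUE
  flags
}

#' Count alleles shared between two groups
#'
#' Across a set of loci, counts distinct alleles observed in either group
#' (`n_total`) and alleles observed in both (`n_shared`). Shared fragment
#' sizes can arise by descent or by size homoplasy; this operation only
#' counts them.
#'
#' @param x a [genotype_matrix()] with mito-type labels
#' @param type_a,type_b the two group labels
#' @param loci optional locus subset (ids/indices)
#' @return list with `n_shared`, `n_total`
#' @export
shared_allele_count <- function(x, type_a, type_b, loci = NULL) {
  if (is.null(loci)) loci <- locus_ids(x)
  xa <- subset(x, mito_type = type_a, locus_ids = loci)
  xb <- subset(x, mito_type = type_b, locus_ids = loci)
  n_shared <- 0L; n_total <- 0L
  for (j in seq_along(locus_index(x, loci))) {
    aa <- setdiff(unique(as.vector(genotypes_at(xa, j))), 0)
    ab <- setdiff(unique(as.vector(genotypes_at(xb, j))), 0)
    n_shared <- n_shared + length(intersect(aa, ab))
    n_total <- n_total + length(union(aa, ab))
  }
  list(n_shared = n_shared, n_total = n_total)
}

#' Diversity table for a group of samples
#'
#' Convenience wrapper building the per-locus table (N_A, H_E, H_O, F_IS,
#' HWE p) for every locus of an MLL-collapsed matrix.
#'
#' @param x a [genotype_matrix()], MLL-collapsed
#' @param group label stored in the table
#' @return data.frame, one row per locus
#' @export
locus_stats_table <- function(x, group = NA_character_) {
  do.call(rbind, lapply(seq_len(n_loci(x)), function(j) {
    s <- try(summarize_locus(x, j, group = group), silent = TRUE)
    if (inherits(s, "try-error"))
      data.frame(locus_id = locus_ids(x)[j], group = group, n = 0L,
                 n_a = NA_integer_, h_e = NA_real_, h_o = NA_real_,
                 f_is = NA_real_, hwe_p = NA_real_)
    else s
  }))
}
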