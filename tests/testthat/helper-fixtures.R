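# Shared builders and independent oracles for the test suite.

# genotype_matrix from a list of per-sample allele vectors
gm_build <- function(rows, loci = NULL, mito_type = NULL) {
  tab <- do.call(rbind, rows)
  if (is.null(loci)) loci <- paste0("L", seq_len(ncol(tab) / 2))
  if (is.null(rownames(tab))) rownames(tab) <- names(rows)
  genotype_matrix(tab, loci, mito_type = mito_type)
}

# random valid genotype matrix (allele sizes on a 3-bp ladder)
gm_random <- function(n = 6, L = 4, n_alleles = 5, p_missing = 0.1,
                      mito_type = NULL) {
  tab <- matrix(0, n, 2 * L)
  for (j in seq_len(L)) {
    sizes <- 100 + 20 * j + 3 * seq_len(n_alleles)
    g <- matrix(sample(sizes, 2 * n, replace = TRUE), n, 2)
    mis <- runif(n) < p_missing
    g[mis, ] <- 0
    tab[, 2 * j - 1] <- pmin(g[, 1], g[, 2])
    tab[, 2 * j] <- pmax(g[, 1], g[, 2])
  }
  rownames(tab) <- sprintf("s%02d", seq_len(n))
  genotype_matrix(tab, paste0("L", seq_len(L)), mito_type = mito_type)
}

# Oracle: pairwise mismatch counts by direct per-pair comparison
oracle_pair_diff <- function(x, i, j) {
  n_comp <- 0L; n_mis <- 0L
  for (l in seq_len(n_loci(x))) {
    ga <- genotypes_at(x, l)[i, ]; gb <- genotypes_at(x, l)[j, ]
    if (ga[1] == 0 || gb[1] == 0) next
    n_comp <- n_comp + 1L
    if (!identical(unname(ga), unname(gb))) n_mis <- n_mis + 1L
  }
  c(n_comp, n_mis)
}

# Oracle: transitive closure of the <=max_mismatch graph by boolean
# matrix powering (independent of the union-find implementation)
oracle_mll_closure <- function(x, max_mismatch = 1) {
  n <- n_samples(x)
  adj <- diag(TRUE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
    d <- oracle_pair_diff(x, i, j)
    if (d[2] <= max_mismatch) adj[i, j] <- TRUE
  }
  reach <- adj
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comp <- integer(n)
  next_id <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      next_id <- next_id + 1L
      comp[reach[i, ]] <- next_id
    }
  }
  comp
}

# two partitions describe the same grouping
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(tapply(seq_along(a), a, function(ix) length(unique(b[ix])) == 1)) &&
    length(unique(a)) == length(unique(b))
}

# Oracle: brute-force scan for every perfect tandem run of a given motif
oracle_has_run <- function(s, motif, k) {
  grepl(strrep(motif, k), s, fixed = TRUE)
}
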