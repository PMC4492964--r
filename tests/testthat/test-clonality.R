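test_that("genotype_mismatch counts loci and excludes missing", {
  sim <- simulate_dataset(sim_config(n_loci = 27, colonies_per_pop = c(10, 7),
                                     p_somatic = 0, p_error = 0,
                                     p_missing = 0), seed = 1)
  x <- sim$matrix
  tab <- x$tab
  tab <- rbind(tab, copy = tab[1, ], onediff = tab[1, ], holey = tab[1, ])
  tab["onediff", 1:2] <- tab["onediff", 1:2] + 3
  tab["holey", 1:6] <- 0
  x2 <- genotype_matrix(tab, x$loci)
  expect_equal(genotype_mismatch(x2, "c001", "copy"),
               list(n_compared = 27, n_mismatch = 0))
  expect_equal(genotype_mismatch(x2, "c001", "onediff"),
               list(n_compared = 27, n_mismatch = 1))
  expect_equal(genotype_mismatch(x2, "c001", "holey")$n_compared, 24)
  # unordered-pair equality, not allele-sharing distance
  y <- gm_build(list(a = c(100, 104), b = c(104, 100), c = c(100, 106)))
  expect_equal(genotype_mismatch(y, "a", "b")$n_mismatch, 0)
  expect_equal(genotype_mismatch(y, "a", "c")$n_mismatch, 1)
  # incomparable pair
  z <- gm_build(list(a = c(100, 104, 0, 0), b = c(0, 0, 200, 200)))
  expect_error(genotype_mismatch(z, "a", "b"), "incomparable")
})

test_that("assign_mlls equals the brute-force closure oracle on random instances", {
  set.seed(99)
  for (rep in 1:40) {
    x <- gm_random(n = 12, L = 5, n_alleles = 3, p_missing = 0)
    part <- assign_mlls(x, min_compared = 1)
    oracle <- oracle_mll_closure(x, max_mismatch = 1)
    expect_true(same_partition(part$assignment, oracle),
                label = paste("closure oracle rep", rep))
    expect_equal(part$n_mll, length(unique(oracle)))
  }
})

test_that("assign_mlls is order-invariant and monotone in max_mismatch", {
  set.seed(4)
  x <- gm_random(n = 10, L = 6, n_alleles = 4, p_missing = 0)
  part <- assign_mlls(x, min_compared = 1)
  perm <- sample(n_samples(x))
  xp <- subset(x, sample_ids = sample_ids(x)[perm])
  partp <- assign_mlls(xp, min_compared = 1)
  expect_true(same_partition(part$assignment[sample_ids(xp)],
                             partp$assignment))
  exact <- assign_mlls(x, max_mismatch = 0, min_compared = 1)
  expect_lte(part$n_mll, exact$n_mll)
  # all-distinct data: N_MLL = N under the exact rule
  sim <- simulate_dataset(sim_config(colonies_per_pop = c(10, 7),
                                     p_somatic = 0, p_error = 0,
                                     p_missing = 0), seed = 2)
  xs <- subset(sim$matrix, mito_type = "mt-S")
  expect_equal(assign_mlls(xs)$n_mll, n_samples(xs))
})

test_that("min_compared floor raises on sparsely shared pairs", {
  z <- gm_build(list(a = c(100, 104, 200, 200, 0, 0),
                     b = c(100, 104, 0, 0, 300, 300)))
  expect_error(assign_mlls(z, min_compared = 2), "incomparable")
  expect_silent(assign_mlls(z, min_compared = 1))
})

test_that("clonality_index returns N_MLL / N", {
  p <- structure(list(assignment = c(a = 1L, b = 1L, c = 2L), n_mll = 2L,
                      n = 3L), class = "mll_partition")
  expect_equal(clonality_index(p), 2 / 3)
  sim <- simulate_dataset(sim_config(colonies_per_pop = c(10, 7),
                                     p_somatic = 0, p_error = 0,
                                     p_missing = 0), seed = 8)
  part <- assign_mlls(subset(sim$matrix, mito_type = "mt-L"))
  expect_equal(clonality_index(part), 1)
})

test_that("flag_single_locus_variants pinpoints the deviant sample and locus", {
  base <- c(100, 104, 200, 206, 300, 300, 412, 415, 500, 503,
            150, 156, 250, 250)
  rows <- list(r1 = base, r2 = base, r3 = base)
  rows$r3[13:14] <- c(253, 253)          # locus L7 deviates in r3
  x <- gm_build(rows)
  part <- assign_mlls(x)
  expect_equal(part$n_mll, 1)
  fl <- flag_single_locus_variants(x, part, mode = "zero_allele")
  expect_length(fl, 1)
  expect_equal(fl[[1]]$locus_id, "L7")
  expect_equal(fl[[1]]$sample_id, "r3")
  fl2 <- flag_single_locus_variants(x, part, mode = "drop_locus")
  expect_length(fl2, 1)
  expect_true(is.na(fl2[[1]]$sample_id))
  expect_equal(n_loci(apply_locus_qc(x, fl2)), 6)
  # clean clonal data -> no flags
  xc <- gm_build(list(r1 = base, r2 = base))
  expect_length(flag_single_locus_variants(xc, assign_mlls(xc)), 0)
})

test_that("planted-genet recovery is exact on clean simulations", {
  set.seed(31)
  ok <- 0
  for (r in 1:50) {
    sim <- simulate_dataset(sim_config(n_loci = 11, alleles_per_locus = 6,
                                       p_somatic = 0, p_error = 0,
                                       p_missing = 0), seed = 3000 + r)
    x <- subset(sim$matrix, mito_type = "mt-L")
    part <- assign_mlls(x)
    if (same_partition(part$assignment,
                       sim$truth$genet[sample_ids(x)])) ok <- ok + 1
  }
  expect_gte(ok / 50, 0.98)
})

test_that("collapse_mlls keeps the first colony of each lineage", {
  base <- c(100, 104, 200, 206, 300, 303, 418, 421, 500, 506)
  rows <- list(r1 = base, r2 = base + rep(c(3, 3), 5), r3 = base)
  x <- gm_build(rows)
  part <- assign_mlls(x, max_mismatch = 0)
  col <- collapse_mlls(x, part)
  expect_equal(sample_ids(col), c("r1", "r2"))
})
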