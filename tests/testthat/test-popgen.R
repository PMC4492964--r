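test_that("allele_freqs tallies nonzero calls only", {
  x <- gm_build(list(a = c(100, 100), b = c(100, 104), c = c(0, 0)))
  f <- allele_freqs(x, "L1")
  expect_equal(unname(f[c("100", "104")]), c(0.75, 0.25))
  mono <- gm_build(list(a = c(100, 100), b = c(100, 100)))
  expect_equal(unname(allele_freqs(mono, "L1")), 1)
  allmiss <- gm_build(list(a = c(0, 0, 100, 100)))
  expect_error(allele_freqs(allmiss, "L1"), "no typed genotype")
  # counting oracle on random fixtures
  set.seed(12)
  for (r in 1:20) {
    x <- gm_random(n = 15, L = 1, n_alleles = 4, p_missing = 0.2)
    calls <- as.vector(genotypes_at(x, 1))
    calls <- calls[calls != 0]
    if (length(calls) == 0) next
    expected <- table(calls) / length(calls)
    got <- allele_freqs(x, 1)
    expect_equal(unname(got[names(expected)]), unname(as.numeric(expected)))
    expect_equal(sum(got), 1)
  }
})

test_that("summarize_locus computes H_E, H_O, F_IS on the GenAlEx convention", {
  # 4 samples: freqs p(100)=5/8, p(104)=3/8; H_E = 1 - (25+9)/64; H_O = 3/4
  x <- gm_build(list(a = c(100, 104), b = c(100, 104), c = c(100, 104),
                     d = c(100, 100)))
  s <- summarize_locus(x, "L1", hwe = FALSE)
  expect_equal(s$n_a, 2)
  expect_equal(s$h_e, 1 - (25 + 9) / 64)
  expect_equal(s$h_o, 0.75)
  expect_equal(s$f_is, (s$h_e - s$h_o) / s$h_e)
  # H_E = H_O -> F_IS = 0
  expect_equal(deviation_index(0.5, 0.5), 0)
  # monomorphic locus: F_IS undefined, not 0
  mono <- gm_build(list(a = c(100, 100), b = c(100, 100)))
  expect_true(is.na(summarize_locus(mono, "L1", hwe = FALSE)$f_is))
  # H_E invariant under allele relabeling; maximal at uniform frequencies
  set.seed(3)
  for (k in 2:6) {
    counts <- c(3, rep(1, k - 1))
    uniform <- rep(2, k)
    he <- function(cnt) 1 - sum((cnt / sum(cnt))^2)
    expect_lt(he(counts), he(uniform))
  }
  y1 <- gm_build(list(a = c(100, 104), b = c(104, 104)))
  y2 <- gm_build(list(a = c(301, 355), b = c(355, 355)))
  expect_equal(summarize_locus(y1, "L1", hwe = FALSE)$h_e,
               summarize_locus(y2, "L1", hwe = FALSE)$h_e)
})

test_that("hwe_test matches the hand-computed chi-square", {
  # perfectly HWE-proportioned counts: 4 AA, 4 BB, 8 AB at p = 0.5
  rows <- c(rep(list(c(100, 100)), 4), rep(list(c(103, 103)), 4),
            rep(list(c(100, 103)), 8))
  names(rows) <- sprintf("s%02d", seq_along(rows))
  h <- hwe_test(gm_build(rows), "L1")
  expect_equal(h$statistic, 0)
  expect_equal(h$p_value, 1)
  # all-homozygote two-allele sample at n = 20:
  # observed (10, 0, 10) vs expected (5, 10, 5) -> X2 = 20, df = 1
  rows <- c(rep(list(c(100, 100)), 10), rep(list(c(103, 103)), 10))
  names(rows) <- sprintf("s%02d", seq_along(rows))
  h <- hwe_test(gm_build(rows), "L1")
  expect_equal(h$statistic, 20)
  expect_equal(h$df, 1)
  expect_lt(h$p_value, 0.05)
  expect_equal(h$p_value, pchisq(20, 1, lower.tail = FALSE))
  # df = k(k-1)/2
  set.seed(8)
  x <- gm_random(n = 30, L = 1, n_alleles = 4, p_missing = 0)
  k <- length(allele_freqs(x, 1))
  expect_equal(hwe_test(x, 1)$df, k * (k - 1) / 2)
  mono <- gm_build(list(a = c(100, 100), b = c(100, 100)))
  expect_error(hwe_test(mono, "L1"), "polymorphic")
})

test_that("ld_test recovers maximal dependence and the hand-computed G", {
  # locus B an exact copy of locus A -> permutation floor
  set.seed(21)
  g <- matrix(sample(c(100, 103, 106), 60, TRUE), ncol = 2)
  x <- genotype_matrix(cbind(pmin(g[, 1], g[, 2]), pmax(g[, 1], g[, 2]),
                             pmin(g[, 1], g[, 2]) + 100,
                             pmax(g[, 1], g[, 2]) + 100),
                       c("A", "B"))
  r <- ld_test(x, "A", "B", n_perm = 199, seed = 1)
  expect_equal(r$p_value, 1 / 200)
  # hand-computed G on a printed 2x2 genotype table: counts 10, 5, 5, 10
  rows <- c(rep(list(c(100, 100, 200, 200)), 10),
            rep(list(c(100, 100, 200, 203)), 5),
            rep(list(c(100, 103, 200, 200)), 5),
            rep(list(c(100, 103, 200, 203)), 10))
  names(rows) <- sprintf("s%02d", seq_along(rows))
  x2 <- gm_build(rows, loci = c("A", "B"))
  obs <- c(10, 5, 5, 10); e <- c(7.5, 7.5, 7.5, 7.5)
  g_hand <- 2 * sum(obs * log(obs / e))
  r2 <- ld_test(x2, "A", "B", n_perm = 99, seed = 2)
  expect_equal(r2$g_statistic, g_hand)
  expect_error(ld_test(gm_build(list(a = c(1, 1, 2, 2) * 100)), 1, 1),
               "fewer than")
})

test_that("fdr_adjust reproduces the step-up oracle and is monotone", {
  expect_equal(fdr_adjust(rep(1, 5)), rep(FALSE, 5))
  # hand enumeration at q = 0.05, m = 4: thresholds 0.0125, 0.025, 0.0375,
  # 0.05; the largest i with p_(i) <= q i/m is 3, so the first three flag
  expect_equal(fdr_adjust(c(0.001, 0.02, 0.03, 0.9)),
               c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(fdr_adjust(0.04), TRUE)
  expect_equal(fdr_adjust(numeric(0)), logical(0))
  set.seed(5)
  for (r in 1:30) {
    p <- runif(sample(3:12, 1))
    expect_equal(fdr_adjust(p, 0.05), p.adjust(p, "BH") <= 0.05)
    # lowering any p never removes a flag elsewhere
    i <- sample(length(p), 1)
    p2 <- p; p2[i] <- p2[i] / 2
    before <- fdr_adjust(p, 0.05); after <- fdr_adjust(p2, 0.05)
    expect_true(all(after[-i] | !before[-i]))
  }
})

test_that("shared_allele_count equals the set-intersection oracle", {
  x <- gm_build(list(a = c(100, 104, 200, 200), b = c(100, 100, 206, 206),
                     c = c(130, 136, 200, 206), d = c(130, 130, 200, 200)),
                mito_type = c("mt-L", "mt-L", "mt-S", "mt-S"))
  # locus 1: L has {100,104}, S has {130,136} -> disjoint
  # locus 2: L has {200,206}, S has {200,206} -> both shared
  r <- shared_allele_count(x, "mt-L", "mt-S")
  expect_equal(r$n_shared, 2)
  expect_equal(r$n_total, 6)
  set.seed(77)
  for (rep in 1:10) {
    y <- gm_random(12, 4, n_alleles = 5, p_missing = 0.1,
                   mito_type = rep(c("mt-L", "mt-S"), each = 6))
    got <- shared_allele_count(y, "mt-L", "mt-S")
    ns <- 0; nt <- 0
    for (j in 1:4) {
      al <- setdiff(unique(as.vector(genotypes_at(subset(y, mito_type = "mt-L"), j))), 0)
      as_ <- setdiff(unique(as.vector(genotypes_at(subset(y, mito_type = "mt-S"), j))), 0)
      ns <- ns + length(intersect(al, as_)); nt <- nt + length(union(al, as_))
    }
    expect_equal(got, list(n_shared = ns, n_total = nt))
  }
})
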