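test_that("constructor canonicalizes pairs and rejects half-missing calls", {
  gm <- gm_build(list(s1 = c(104, 100, 200, 200), s2 = c(100, 100, 0, 0)))
  expect_equal(unname(genotypes_at(gm, "L1")[1, ]), c(100, 104))
  expect_equal(unname(genotypes_at(gm, "L2")[2, ]), c(0, 0))
  expect_error(gm_build(list(s1 = c(100, 0, 200, 200))), "half-missing")
  expect_error(genotype_matrix(matrix(100, 2, 3), c("L1", "L2")),
               "2 columns per locus")
  expect_error(gm_build(list(s1 = c(100, 100), s1 = c(100, 100))),
               "duplicate sample")
})

test_that("round-trip identity holds for every dialect on simulated data", {
  for (seed in 1:3) {
    sim <- simulate_dataset(sim_config(n_loci = 5), seed = seed)
    for (dialect in c("genalex", "structure", "genepop")) {
      f <- tempfile(fileext = ".txt")
      write_genotype_table(sim$matrix, f, dialect)
      back <- read_genotype_table(f, dialect)
      expect_true(gm_equal(sim$matrix, back),
                  label = paste("round trip", dialect, "seed", seed))
    }
  }
})

test_that("genalex -> structure -> genalex preserves genotypes via the dictionary", {
  sim <- simulate_dataset(sim_config(n_loci = 4), seed = 11)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".str")
  f3 <- tempfile(fileext = ".csv")
  write_genotype_table(sim$matrix, f1, "genalex")
  x1 <- read_genotype_table(f1, "genalex")
  write_genotype_table(x1, f2, "structure")
  expect_true(file.exists(paste0(f2, ".alleles.tsv")))
  x2 <- read_genotype_table(f2, "structure")
  write_genotype_table(x2, f3, "genalex")
  expect_true(gm_equal(x1, read_genotype_table(f3, "genalex")))
  # without the dictionary, integer codes survive but bp sizes are gone
  file.remove(paste0(f2, ".alleles.tsv"))
  x3 <- read_genotype_table(f2, "structure")
  expect_equal(dim(x3$tab), dim(x1$tab))
  expect_true(all(x3$tab[x3$tab != 0] <= 20))
})

test_that("parse errors name the offending line", {
  f <- tempfile()
  writeLines(c("2,2,1,2", "t,,,p1", "Sample,Pop,L1,,L2,",
               "s1,p1,100,104,200,200", "s2,p1,100,104,200"), f)
  expect_error(read_genotype_table(f, "genalex"), "line 5")
  writeLines(c("L1 L2", "s1 1 1 2 3 4", "s2 1 1 2 3"), f)
  expect_error(read_genotype_table(f, "structure"), "line 3")
  writeLines(c("title", "L1", "Pop", "s1 , 100x04"), f)
  expect_error(read_genotype_table(f, "genepop"), "line 4")
  expect_error(read_genotype_table(f, "csv"), "arg")
  expect_error(read_genotype_table(tempfile(), "genalex"), "not found")
})

test_that("genalex writer emits one data row per sample", {
  sim <- simulate_dataset(sim_config(), seed = 3)   # 97 samples, 11 loci
  f <- tempfile()
  write_genotype_table(sim$matrix, f, "genalex")
  raw <- readLines(f)
  expect_length(raw, 3 + 97)
  expect_match(raw[1], "^11,97,2,53,44$")
})

test_that("apply_locus_qc drops loci, zeroes calls, and is idempotent", {
  gm <- gm_random(5, 4, p_missing = 0, mito_type = rep("mt-L", 5))
  dropped <- apply_locus_qc(gm, list(qc_flag("L2", action = "drop_locus")))
  expect_equal(locus_ids(dropped), c("L1", "L3", "L4"))
  z <- apply_locus_qc(gm, list(qc_flag("L2", action = "zero_allele",
                                       sample_id = "s03")))
  expect_equal(unname(genotypes_at(z, "L2")[3, ]), c(0, 0))
  expect_true(gm_equal(subset(z, sample_ids = sample_ids(z)[-3]),
                       subset(gm, sample_ids = sample_ids(gm)[-3])))
  # idempotent and commuting across independent flags
  fl <- list(qc_flag("L1", action = "drop_locus"),
             qc_flag("L3", action = "zero_allele", sample_id = "s01"))
  once <- apply_locus_qc(gm, fl)
  expect_true(gm_equal(apply_locus_qc(once, fl[2]), once))
  expect_true(gm_equal(apply_locus_qc(apply_locus_qc(gm, fl[1]), fl[2]),
                       apply_locus_qc(apply_locus_qc(gm, fl[2]), fl[1])))
  expect_error(apply_locus_qc(gm, list(qc_flag("L9", action = "drop_locus"))),
               "unknown locus")
  expect_error(qc_flag("L1", action = "zero_allele"), "name the sample")
  expect_error(qc_flag("L1", action = "drop_locus", sample_id = "s1"),
               "sample_id must be NULL")
})

test_that("subset partitions samples by type and restricts loci", {
  sim <- simulate_dataset(sim_config(), seed = 5)
  x <- sim$matrix
  xl <- subset(x, mito_type = "mt-L")
  xs <- subset(x, mito_type = "mt-S")
  expect_equal(n_samples(xl), 53)
  expect_equal(n_samples(xs), 44)
  expect_setequal(c(sample_ids(xl), sample_ids(xs)), sample_ids(x))
  expect_error(subset(x, mito_type = "mt-X"), "no samples")
  # cross-type restriction: 11 of 27 loci
  loci27 <- data.frame(locus_id = paste0("G", 1:27),
                       cross_type = rep(c(TRUE, FALSE), c(11, 16)))
  tab <- matrix(rep(c(100, 100), 27), nrow = 2, ncol = 54, byrow = TRUE)
  gm27 <- genotype_matrix(tab, loci27)
  expect_equal(n_loci(subset(gm27, locus_ids = "cross_type")), 11)
  expect_error(subset(gm27, locus_ids = character(0)), "locus")
})
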