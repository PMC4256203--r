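test_that("generators are byte-identical under a fixed seed", {
  cfg <- sim_config(n_cds = 40, seed = 1, reads_per_library = 200)
  a <- simulate_cds(cfg)
  b <- simulate_cds(cfg)
  expect_identical(a, b)
  fa1 <- withr::local_tempfile(fileext = ".fasta")
  fa2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(setNames(a$cds$sequence, a$cds$id), fa1)
  write_fasta(setNames(b$cds$sequence, b$cds$id), fa2)
  expect_identical(unname(tools::md5sum(fa1)), unname(tools::md5sum(fa2)))

  ra <- simulate_reads(a$cds, a$truth, cfg)
  rb <- simulate_reads(b$cds, b$truth, cfg)
  expect_identical(ra, rb)
  fq1 <- withr::local_tempfile(fileext = ".fastq")
  fq2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(ra[[3]], fq1)
  write_fastq(rb[[3]], fq2)
  expect_identical(unname(tools::md5sum(fq1)), unname(tools::md5sum(fq2)))

  expect_identical(simulate_snps(a$cds, cfg), simulate_snps(b$cds, cfg))
})

test_that("class proportions drive the simulated composition", {
  cfg <- sim_config(n_cds = 50, seed = 2,
                    class_proportions = c(Secreted = 1, Housekeeping = 0,
                                          `Transposable element` = 0,
                                          Viral = 0, Unknown = 0))
  sim <- simulate_cds(cfg)
  expect_true(all(sim$cds$class_label == "Secreted"))
  expect_true(all(sim$cds$has_signal_peptide))
  expect_error(sim_config(class_proportions = c(Secreted = 0.5)), "sum")
})

test_that("simulated CDS are well-formed ORFs with realistic lengths", {
  cfg <- sim_config(n_cds = 5000, seed = 4, reads_per_library = 100)
  sim <- simulate_cds(cfg)
  s <- sim$cds$sequence
  expect_true(all(substr(s, 1, 3) == "ATG"))
  stops <- c("TAA", "TAG", "TGA")
  expect_true(all(substring(s, nchar(s) - 2L) %in% stops))
  # no internal in-frame stop
  set.seed(1)
  for (i in sample(length(s), 50)) {
    starts <- seq(1, nchar(s[i]) - 3L, by = 3L)
    codons <- substring(s[i], starts, starts + 2L)
    expect_false(any(codons %in% stops))
  }
  # mean deduced protein length within 10% of the 398-aa target
  aa <- nchar(s) / 3 - 1
  expect_lt(abs(mean(aa) - 398) / 398, 0.10)
})

test_that("error-free reads are exact substrings of their source CDS", {
  cfg <- sim_config(n_cds = 1, seed = 6, reads_per_library = 1000,
                    error_rate = 0, bad_read_fraction = 0,
                    low_tail_fraction = 0,
                    class_proportions = c(Secreted = 1, Housekeeping = 0,
                                          `Transposable element` = 0,
                                          Viral = 0, Unknown = 0),
                    fold_overexpressed_fraction = 0)
  sim <- simulate_cds(cfg)
  reads <- simulate_reads(sim$cds, sim$truth, cfg)
  lib <- reads[[1]]
  cds_seq <- sim$cds$sequence[1]
  ok <- vapply(lib$sequence, function(r)
    grepl(r, cds_seq, fixed = TRUE) ||
      grepl(oracle_revcomp(r), cds_seq, fixed = TRUE), logical(1))
  expect_true(all(ok))
})

test_that("a planted 10x stage effect shows in the truth counts", {
  cfg <- sim_config(n_cds = 50, seed = 8, reads_per_library = 50000,
                    library_noise_sdlog = 0, fold_overexpressed_fraction = 0)
  sim <- simulate_cds(cfg)
  # plant one exact 10x adult effect by hand for a clean binomial check
  i <- which.max(sim$truth$baseline_expr)
  sim$truth$effect_target[i] <- "stage:adult"
  sim$truth$effect_fold[i] <- 10
  reads <- simulate_reads(sim$cds, sim$truth, cfg)
  tc <- attr(reads, "truth_counts")
  adult <- cfg$design$library_id[cfg$design$stage == "adult"]
  nymph <- cfg$design$library_id[cfg$design$stage == "nymph"]
  r_ad <- sum(tc[i, adult]); r_ny <- sum(tc[i, nymph])
  R_ad <- sum(tc[, adult]); R_ny <- sum(tc[, nymph])
  ratio <- (r_ad / R_ad) / (r_ny / R_ny)
  # expected share ratio: boosting one CDS renormalizes the library weights
  w <- sim$truth$baseline_expr * sim$cds$length_nt
  expected <- 10 * sum(w) / (sum(w) + 9 * w[i])
  se <- sqrt(1 / r_ad + 1 / r_ny)  # log-scale binomial sampling error
  expect_lt(abs(log(ratio) - log(expected)), 3 * se)
})

test_that("planted SNP effects are verified against the genetic code", {
  cfg <- sim_config(n_cds = 80, seed = 10, reads_per_library = 100)
  sim <- simulate_cds(cfg)
  snps <- simulate_snps(sim$cds, cfg)
  out <- classify_snps(snps, sim$cds)
  expect_identical(out$effect, out$effect_truth)
  # ref column matches the CDS base at every planted position
  ci <- match(out$cds_id, sim$cds$id)
  expect_identical(substring(sim$cds$sequence[ci], out$pos_1based,
                             out$pos_1based), out$ref)
})

test_that("planted rates are recovered within Poisson sampling error", {
  rates_s <- c(Secreted = 1, Housekeeping = 1, `Transposable element` = 1,
               Viral = 1, Unknown = 1)
  cfg <- sim_config(n_cds = 40, seed = 12, reads_per_library = 100,
                    snp_rate_s = rates_s, snp_rate_ns = 2 * rates_s,
                    snp_low_conf_fraction = 0)
  sim <- simulate_cds(cfg)
  snps <- classify_snps(simulate_snps(sim$cds, cfg), sim$cds)
  per <- rates_per_cds(snps, sim$cds, polymorphic_only = FALSE)
  n_codons <- sum(per$n_codons)
  expect_gt(n_codons, 5000)
  s_rate <- 100 * sum(per$s_count) / n_codons
  ns_rate <- 100 * sum(per$ns_count) / n_codons
  se_s <- 100 * sqrt(sum(per$s_count)) / n_codons
  se_ns <- 100 * sqrt(sum(per$ns_count)) / n_codons
  expect_lt(abs(s_rate - 1), 3 * se_s)
  expect_lt(abs(ns_rate - 2), 3 * se_ns)
})

test_that("sub-threshold depth or quality removes SNPs downstream", {
  cfg <- sim_config(n_cds = 30, seed = 14, reads_per_library = 100,
                    snp_low_conf_fraction = 1)
  sim <- simulate_cds(cfg)
  snps <- simulate_snps(sim$cds, cfg)
  expect_gt(nrow(snps), 0)
  expect_equal(nrow(filter_snps(snps)), 0L)
  # and the truth flags agree with the filter outcome generally
  cfg2 <- sim_config(n_cds = 30, seed = 15, reads_per_library = 100)
  snps2 <- simulate_snps(sim$cds, cfg2)
  kept <- filter_snps(snps2)
  expect_true(all(kept$pass_filter))
  expect_equal(nrow(kept), sum(snps2$pass_filter))
})

test_that("paralog duplication creates tied reads", {
  cfg <- sim_config(n_cds = 10, seed = 16, reads_per_library = 500,
                    paralog_families = 3L, error_rate = 0,
                    bad_read_fraction = 0, low_tail_fraction = 0)
  sim <- simulate_cds(cfg)
  expect_equal(nrow(sim$cds), 13L)
  idx <- build_index(sim$cds)
  reads <- simulate_reads(sim$cds, sim$truth, cfg)
  lc <- count_library(reads[[1]], idx)
  # at 97% identity many reads match both family members
  expect_gt(lc$total_mapped, lc$distinct_mapped)
})

test_that("configuration files round-trip through YAML", {
  skip_if_not_installed("yaml")
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_cds: 25", "seed: 99", "reads_per_library: 123",
               "error_rate: 0.01"), yml)
  cfg <- read_sim_config(yml)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$n_cds, 25)
  expect_equal(cfg$seed, 99)
  expect_equal(cfg$reads_per_library, 123)
  expect_equal(cfg$error_rate, 0.01)
})
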