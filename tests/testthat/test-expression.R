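test_that("rpkm implements reads*1e9/(length*total)", {
  expect_equal(rpkm(0, 1000, 1e6), 0)
  expect_equal(rpkm(100, 1000, 1e6), 100)
  expect_equal(rpkm(100, 1000, 2e6), 50)  # doubling total halves RPKM
  expect_error(rpkm(1, 1000, 0), "total_mapped")
})

test_that("pooled RPKM sums counts and totals before the formula", {
  counts <- cbind(l1 = c(a = 10, b = 0), l2 = c(a = 30, b = 5))
  lens <- c(a = 1000, b = 2000)
  expect_equal(pooled_rpkm(counts, lens, totals = c(1e6, 3e6)),
               c(a = 40 * 1e9 / (1000 * 4e6), b = 5 * 1e9 / (2000 * 4e6)))
})

test_that("normalized ratio matches the pseudocount formula", {
  nr <- normalized_ratio(10, 1000, 0, 1000)
  expect_equal(nr$ratio_1over2, 10)
  nr <- normalized_ratio(0, 1000, 0, 1000)
  expect_equal(nr$ratio_1over2, 0)
  expect_equal(nr$ratio_2over1, 0)
  nr <- normalized_ratio(50, 2000, 5, 1000)
  expect_equal(nr$ratio_1over2, 50 * 1000 / (2000 * 6))  # 4.1667
  expect_equal(round(nr$ratio_1over2, 4), 4.1667)
})

test_that("normalized ratio is anti-symmetric under group swap", {
  set.seed(3)
  for (i in 1:50) {
    R1 <- sample(1000:5000, 1); R2 <- sample(1000:5000, 1)
    r1 <- sample(0:R1, 1); r2 <- sample(0:R2, 1)
    a <- normalized_ratio(r1, R1, r2, R2)
    b <- normalized_ratio(r2, R2, r1, R1)
    expect_equal(a$ratio_1over2, b$ratio_2over1)
    expect_equal(a$ratio_2over1, b$ratio_1over2)
  }
})

test_that("chi-squared matches the closed-form 2x2 oracle on random tables", {
  set.seed(5)
  R1 <- sample(50:10000, 1000, replace = TRUE)
  R2 <- sample(50:10000, 1000, replace = TRUE)
  r1 <- vapply(R1, function(R) sample(0:R, 1), numeric(1))
  r2 <- vapply(R2, function(R) sample(0:R, 1), numeric(1))
  got <- chi2_test(r1, R1, r2, R2)
  want <- oracle_chi2_2x2(r1, R1, r2, R2)
  ok <- r1 + r2 > 0 & (r1 + r2) < (R1 + R2)
  expect_lt(max(abs(got$chi2[ok] - want[ok])), 1e-9)
  expect_true(all(got$chi2[!ok] == 0) && all(got$p[!ok] == 1))
})

test_that("chi-squared agrees with stats::chisq.test", {
  cases <- list(c(30, 1000, 10, 1000), c(5, 200, 9, 350),
                c(120, 4000, 80, 2500))
  for (cs in cases) {
    got <- chi2_test(cs[1], cs[2], cs[3], cs[4])
    ref <- suppressWarnings(chisq.test(
      matrix(c(cs[1], cs[2] - cs[1], cs[3], cs[4] - cs[3]), 2, byrow = TRUE),
      correct = FALSE))
    expect_equal(got$chi2, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p, unname(ref$p.value), tolerance = 1e-12)
  }
})

test_that("degenerate and symmetric tables behave", {
  ct <- chi2_test(25, 1000, 25, 1000)
  expect_equal(ct$chi2, 0)
  expect_equal(ct$p, 1)
  # larger proportion gap at fixed totals gives larger chi2
  gaps <- vapply(c(5, 10, 20, 40), function(d)
    chi2_test(50 + d, 1000, 50 - d, 1000)$chi2, numeric(1))
  expect_true(all(diff(gaps) > 0))
})

test_that("overexpression calls require both fold and significance", {
  cmp <- compare_groups(c(a = 500, b = 99, c = 2, d = 0),
                        c(a = 1, b = 10, c = 1, d = 0),
                        R1 = 10000, R2 = 10000)
  called <- call_overexpression(cmp, fold = 10, alpha = 0.05, mtc = "none")
  expect_identical(as.character(called$call),
                   c("over_in_1", "ns", "ns", "ns"))
  # high ratio but weak evidence stays ns; strong evidence below fold stays ns
  weak <- compare_groups(c(x = 3), c(x = 0), R1 = 1e6, R2 = 1e6)
  expect_identical(as.character(
    call_overexpression(weak, fold = 10, alpha = 1e-4,
                        mtc = "none")$call), "ns")
  strong <- compare_groups(c(x = 900), c(x = 100), R1 = 1e5, R2 = 1e5)
  expect_lt(strong$p, 1e-10)
  expect_identical(as.character(
    call_overexpression(strong, fold = 10, mtc = "none")$call), "ns")
})

test_that("fold=1, alpha=1 uncorrected calls every one-sided CDS", {
  # the +1 pseudocount keeps balanced low-count CDS below ratio 1, so the
  # permissive limit is exercised on CDS expressed in a single group, where
  # the ratio is >= 1 and the table is always unbalanced (p < 1)
  set.seed(8)
  c1 <- setNames(c(sample(1:50, 15, replace = TRUE), rep(0, 15)),
                 paste0("c", 1:30))
  c2 <- setNames(c(rep(0, 15), sample(1:50, 15, replace = TRUE)),
                 paste0("c", 1:30))
  cmp <- compare_groups(c1, c2, R1 = 5000, R2 = 5000)
  called <- call_overexpression(cmp, fold = 1, alpha = 1, mtc = "none")
  expect_true(all(called$call != "ns"))
  expect_identical(as.character(called$call),
                   rep(c("over_in_1", "over_in_2"), each = 15))
})

test_that("contrasts pool counts and totals over the design", {
  cfg <- sim_config(n_cds = 10, seed = 21, reads_per_library = 200)
  sim <- simulate_cds(cfg)
  reads <- simulate_reads(sim$cds, sim$truth, cfg)
  idx <- build_index(sim$cds)
  libs <- lapply(names(reads), function(l)
    count_library(reads[[l]], idx, library_id = l))
  cons <- build_contrasts(libs, cfg$design)
  expect_named(cons, c("stage", paste0("region:", unique(cfg$design$region))))

  grand <- sum(vapply(libs, function(x) x$total_mapped, numeric(1)))
  st <- cons$stage
  expect_equal(st$R1[1] + st$R2[1], grand)
  for (reg in unique(cfg$design$region)) {
    rc <- cons[[paste0("region:", reg)]]
    expect_equal(rc$R1[1] + rc$R2[1], grand)
    expect_equal(rc$r1 + rc$r2, st$r1 + st$r2)
  }

  # one library per group reduces to the raw comparison
  two <- libs[c(1, 4)]  # Arg-N (nymph) vs BolCol-A (adult)
  des <- cfg$design[c(1, 4), ]
  cc <- build_contrasts(two, des)
  expect_equal(cc$stage$r1, unname(two[[1]]$counts))
  expect_equal(cc$stage$r2, unname(two[[2]]$counts))
  expect_equal(cc[["region:Arg"]]$r1, unname(two[[1]]$counts))
  # a region holding every library leaves its complement empty
  expect_error(build_contrasts(libs, transform(cfg$design, region = "one")),
               "zero libraries")
})

test_that("class summaries compute mean and SE per class", {
  called <- data.frame(cds_id = c("a", "b", "c"),
                       call = factor(c("over_in_1", "over_in_1", "over_in_1"),
                                     levels = c("over_in_1", "over_in_2", "ns")),
                       stringsAsFactors = FALSE)
  rpkm1 <- c(a = 10, b = 20, c = 7)
  rpkm2 <- c(a = 1, b = 1, c = 3)
  classes <- c(a = "Lipocalin", b = "Lipocalin", c = "Protease")
  out <- class_summary(called, rpkm1, rpkm2, classes)
  lip <- out[out$class == "Lipocalin", ]
  expect_equal(lip$mean_rpkm_1, 15)
  expect_equal(lip$se_1, sd(c(10, 20)) / sqrt(2))
  expect_equal(lip$n_cds, 2L)
  # single-CDS class: SE undefined
  expect_true(is.na(out$se_1[out$class == "Protease"]))
  # two CDS with identical values: SE 0
  called2 <- called
  called2$call[called2$cds_id == "c"] <- "ns"
  out2 <- class_summary(called2, c(a = 5, b = 5, c = 1), rpkm2,
                        c(a = "K", b = "K", c = "K"))
  expect_equal(out2$se_1, 0)
})

test_that("row-average normalization filters then scales rows to mean 1", {
  m <- rbind(a = c(10, 10, 10), b = c(0, 0, 30), c = c(5, 5, 5),
             d = c(0, 0, 0))
  norm <- row_average_normalize(m, min_overall_rpkm = 0)
  expect_equal(unname(norm["a", ]), c(1, 1, 1))
  expect_equal(unname(norm["b", ]), c(0, 0, 3))
  expect_false("d" %in% rownames(norm))  # all-zero row dropped
  expect_true(all(abs(rowMeans(norm) - 1) < 1e-12))
  # overall filter drops weakly expressed rows before normalization
  norm20 <- row_average_normalize(m, min_overall_rpkm = 20,
                                  overall = c(100, 10, 30, 0))
  expect_identical(rownames(norm20), c("a", "c"))
  # z-score option
  z <- row_average_normalize(m, min_overall_rpkm = 0, method = "zscore")
  expect_true(all(abs(rowMeans(z)) < 1e-12))
})
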