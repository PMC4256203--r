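test_that("end trimming and mean-quality rejection follow the QC rule", {
  # terminal bases below Q10 are clipped, interior kept
  r <- trim_and_filter("ACGTGA", c(5L, 5L, 30L, 30L, 30L, 5L), min_len = 1L)
  expect_true(r$kept)
  expect_identical(r$sequence, "GTG")
  expect_identical(r$qualities, c(30L, 30L, 30L))

  # mean below 20 after trimming is rejected (boundary: 19 < 20)
  r <- trim_and_filter(strrep("A", 30), rep(19L, 30), min_len = 1L)
  expect_false(r$kept)
  expect_identical(r$reason, "low_mean_quality")
  r <- trim_and_filter(strrep("A", 30), rep(20L, 30), min_len = 1L)
  expect_true(r$kept)

  # low-quality head is trimmed away and the remainder mean (40) passes
  r <- trim_and_filter(strrep("A", 40), c(rep(9L, 10), rep(40L, 30)))
  expect_true(r$kept)
  expect_equal(nchar(r$sequence), 30L)
  expect_equal(mean(r$qualities), 40)

  # too short after trimming
  r <- trim_and_filter(strrep("A", 30), c(rep(5L, 20), rep(40L, 10)))
  expect_false(r$kept)
  expect_identical(r$reason, "too_short")
})

test_that("seed index covers both strands and duplicate CDS", {
  one <- c(x = rand_dna(25))
  idx <- build_index(one)
  expect_equal(index_n_entries(idx), 2)  # forward + reverse complement

  dup <- c(a = one[["x"]], b = one[["x"]])
  idx2 <- build_index(dup)
  hits <- index_lookup(idx2, one[["x"]])
  expect_setequal(hits$cds_id[hits$strand == "+"], c("a", "b"))
})

test_that("index membership agrees with a brute-force scan", {
  set.seed(23)
  cds <- setNames(vapply(rep(120, 30), rand_dna, character(1)),
                  sprintf("c%02d", 1:30))
  idx <- build_index(cds)
  # present k-mers from random CDS/strands plus random absent ones
  queries <- c(
    vapply(1:80, function(i) {
      s <- sample(cds, 1)
      if (runif(1) < 0.5) s <- oracle_revcomp(s)
      p <- sample.int(nchar(s) - 24L, 1)
      substr(s, p, p + 24L)
    }, character(1)),
    vapply(1:40, function(i) rand_dna(25), character(1)))
  for (q in queries) {
    hit_ids <- sort(unique(index_lookup(idx, q)$cds_id))
    brute <- sort(names(cds)[vapply(cds, function(s)
      grepl(q, s, fixed = TRUE) || grepl(q, oracle_revcomp(s), fixed = TRUE),
      logical(1))])
    expect_identical(hit_ids, brute)
  }
})

test_that("map_read applies identity threshold and tie rules", {
  set.seed(31)
  cds <- setNames(vapply(rep(400, 5), rand_dna, character(1)),
                  paste0("c", 1:5))
  idx <- build_index(cds)

  # exact substring maps to its unique source
  read <- substr(cds[["c3"]], 101, 150)
  expect_identical(as.character(map_read(read, idx)), "c3")
  # reverse-complement reads map to the same CDS
  expect_identical(as.character(map_read(oracle_revcomp(read), idx)), "c3")

  # 3 mismatches in 50 bases = 94% identity: below 96%, discarded
  bad <- read
  for (p in c(10, 25, 40)) {
    substr(bad, p, p) <- setdiff(c("A", "C", "G", "T"),
                                 substr(bad, p, p))[1]
  }
  expect_length(map_read(bad, idx), 0L)

  # identical paralogs: tied read increments both
  par <- c(cds, p1 = cds[["c1"]])
  idxp <- build_index(par)
  expect_identical(as.character(map_read(substr(cds[["c1"]], 51, 120), idxp)),
                   c("c1", "p1"))

  # beyond max_ties the read is discarded and flagged
  many <- setNames(rep(cds[["c1"]], 7), paste0("m", 1:7))
  idxm <- build_index(many)
  hit <- map_read(substr(cds[["c1"]], 51, 120), idxm)
  expect_length(hit, 0L)
  expect_true(attr(hit, "tie_overflow"))
  hit5 <- map_read(substr(cds[["c1"]], 51, 120), idxm, max_ties = 7)
  expect_length(hit5, 7L)
})

test_that("map_read agrees with the exhaustive alignment oracle", {
  set.seed(47)
  cds <- setNames(vapply(rep(200, 6), rand_dna, character(1)),
                  paste0("c", 1:6))
  idx <- build_index(cds)
  mutate <- function(s, n) {
    for (p in sample.int(nchar(s), n)) {
      substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(s, p, p)), 1)
    }
    s
  }
  reads <- lapply(1:30, function(i) {
    src <- sample(names(cds), 1)
    p <- sample.int(nchar(cds[[src]]) - 79L, 1)
    r <- substr(cds[[src]], p, p + 79L)
    kind <- sample(c("exact", "mismatch", "del", "ins"), 1)
    r <- switch(kind,
      exact = r,
      mismatch = mutate(r, sample(1:2, 1)),
      del = {  # drop g internal bases (gap in read vs CDS)
        g <- sample(1:3, 1); at <- sample(30:50, 1)
        paste0(substr(r, 1, at), substr(r, at + g + 1, 80))
      },
      ins = {  # insert g random bases (gap in CDS)
        g <- sample(1:3, 1); at <- sample(30:50, 1)
        paste0(substr(r, 1, at), rand_dna(g), substr(r, at + 1, 80))
      })
    if (runif(1) < 0.5) r <- oracle_revcomp(r)
    r
  })
  for (r in reads) {
    got <- as.character(map_read(r, idx, max_gap_len = 4L))
    want <- oracle_map_read(r, cds, max_gap_len = 4)
    expect_identical(got, want)
  }
})

test_that("count_library conserves reads and matches synthetic truth", {
  cfg <- sim_config(n_cds = 25, seed = 9, reads_per_library = 400,
                    error_rate = 0, bad_read_fraction = 0,
                    low_tail_fraction = 0)
  sim <- simulate_cds(cfg)
  reads <- simulate_reads(sim$cds, sim$truth, cfg)
  idx <- build_index(sim$cds)
  lc <- count_library(reads[[1]], idx, library_id = names(reads)[1])
  truth <- attr(reads, "truth_counts")[, 1]
  # error-free reads on unique CDS: counts equal truth exactly
  expect_equal(unname(lc$counts), unname(truth))
  expect_equal(lc$total_mapped, sum(lc$counts))
  expect_equal(lc$reads_in,
               lc$reads_rejected_qc + lc$reads_unmapped + lc$distinct_mapped)

  # empty library
  empty <- data.frame(id = character(), sequence = character(),
                      quality = character(), stringsAsFactors = FALSE)
  lc0 <- count_library(empty, idx)
  expect_equal(lc0$reads_in + lc0$total_mapped + lc0$reads_rejected_qc, 0)
})

test_that("QC rejection and tallies stay conserved with noisy reads", {
  cfg <- sim_config(n_cds = 20, seed = 13, reads_per_library = 600)
  sim <- simulate_cds(cfg)
  reads <- simulate_reads(sim$cds, sim$truth, cfg)
  idx <- build_index(sim$cds)
  lc <- count_library(reads[[2]], idx)
  expect_equal(lc$reads_in,
               lc$reads_rejected_qc + lc$reads_unmapped + lc$distinct_mapped)
  # bad_read_fraction = 5%: rejection tally in a sane band
  expect_gt(lc$reads_rejected_qc, 5)
  expect_lt(lc$reads_rejected_qc, 80)
})

test_that("raising min_identity never increases the mapped count", {
  cfg <- sim_config(n_cds = 15, seed = 17, reads_per_library = 300,
                    error_rate = 0.01)
  sim <- simulate_cds(cfg)
  reads <- simulate_reads(sim$cds, sim$truth, cfg)
  idx <- build_index(sim$cds)
  mapped <- vapply(c(0.8, 0.9, 0.96, 0.99, 1.0), function(mi)
    count_library(reads[[1]], idx, min_identity = mi)$distinct_mapped,
    numeric(1))
  expect_true(all(diff(mapped) <= 0))
})

test_that("fractional tie mode splits tied reads", {
  base <- rand_dna(300)
  cds <- c(a = base, b = base)
  idx <- build_index(cds)
  reads <- data.frame(id = "r1", sequence = substr(base, 10, 100),
                      quality = strrep("I", 91), stringsAsFactors = FALSE)
  each <- count_library(reads, idx, tie_mode = "each")
  frac <- count_library(reads, idx, tie_mode = "fractional")
  expect_equal(unname(each$counts), c(1, 1))
  expect_equal(each$total_mapped, 2)
  expect_equal(each$distinct_mapped, 1)
  expect_equal(unname(frac$counts), c(0.5, 0.5))
  expect_equal(frac$total_mapped, 1)
})

test_that("per-library averages derive from residue and sequence totals", {
  libs <- data.frame(library_id = c("l1", "l2"),
                     n_sequences = c(1000, 2000),
                     n_residues = c(272900, 575800),
                     stringsAsFactors = FALSE)
  st <- library_read_stats(libs)
  expect_equal(st$per_library$average_length, c(272.9, 287.9))
  expect_equal(st$total_sequences, 3000)
  expect_equal(st$total_residues, 848700)
})
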