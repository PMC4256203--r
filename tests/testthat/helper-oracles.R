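# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's own code paths.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

oracle_revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

# Exhaustive all-diagonal banded-alignment oracle for read mapping: scores
# every diagonal of every CDS strand with at most one gap of length
# 1..max_gap_len (+1/-2 match/mismatch, -3/-1 gap open/extend), discards
# alignments below the identity threshold, and returns the set of CDS tied
# at the maximum score (empty beyond max_ties).
oracle_map_read <- function(read, cds, min_identity = 0.96, max_gap_len = 4,
                            max_ties = 5) {
  rb <- utf8ToInt(read)
  L <- length(rb)
  best_by_cds <- rep(-Inf, length(cds))
  names(best_by_cds) <- names(cds)
  for (ci in seq_along(cds)) {
    for (tgt in c(cds[[ci]], oracle_revcomp(cds[[ci]]))) {
      tb <- utf8ToInt(tgt)
      Tn <- length(tb)
      diags <- (-(L - 1) - max_gap_len):((Tn - 1) + max_gap_len)
      # P[[as.character(d)]][i + 1] = matches in read[1..i] at diagonal d
      P <- list()
      for (d in diags) {
        idx <- seq_len(L) + d
        ok <- idx >= 1 & idx <= Tn
        m <- integer(L)
        m[ok] <- as.integer(rb[ok] == tb[idx[ok]])
        P[[as.character(d)]] <- c(0L, cumsum(m))
      }
      score_of <- function(matches, alen, gap_cost) {
        if (alen <= 0) return(-Inf)
        if (matches / alen < min_identity - 1e-9) return(-Inf)
        matches - 2 * (alen - matches) - gap_cost
      }
      for (d in (-(L - 1)):(Tn - 1)) {
        Pd <- P[[as.character(d)]]
        best_by_cds[ci] <- max(best_by_cds[ci], score_of(Pd[L + 1], L, 0))
        for (g in seq_len(max_gap_len)) {
          gc <- 3 + (g - 1) * 1
          Pr <- P[[as.character(d - g)]]  # gap in read
          i <- 0:(L - g)
          m <- max(Pd[i + 1] + (Pr[L + 1] - Pr[i + g + 1]))
          best_by_cds[ci] <- max(best_by_cds[ci], score_of(m, L - g, gc))
          Pt <- P[[as.character(d + g)]]  # gap in target
          i <- 0:L
          m <- max(Pd[i + 1] + (Pt[L + 1] - Pt[i + 1]))
          best_by_cds[ci] <- max(best_by_cds[ci], score_of(m, L, gc))
        }
      }
    }
  }
  if (all(!is.finite(best_by_cds))) return(character())
  top <- names(best_by_cds)[best_by_cds == max(best_by_cds)]
  if (length(top) > max_ties) character() else sort(top)
}

# brute-force six-frame ORF scan: every ATG to its first in-frame stop
oracle_find_orfs <- function(sequence) {
  s <- toupper(sequence)
  L <- nchar(s)
  stops <- c("TAA", "TAG", "TGA")
  res <- NULL
  for (strand in c("+", "-")) {
    t <- if (strand == "+") s else oracle_revcomp(s)
    for (f in 0:2) {
      i <- f + 1L
      while (i + 2L <= L) {
        if (substr(t, i, i + 2L) == "ATG") {
          j <- i
          while (j + 2L <= L) {
            if (substr(t, j, j + 2L) %in% stops) {
              st <- i; en <- j + 2L
              if (strand == "-") { tmp <- L - en + 1L; en <- L - st + 1L; st <- tmp }
              res <- rbind(res, data.frame(start = st, end = en,
                                           frame = f + 1L, strand = strand,
                                           stringsAsFactors = FALSE))
              break
            }
            j <- j + 3L
          }
        }
        i <- i + 3L
      }
    }
  }
  res
}

# per-column alignment tally oracle
oracle_column_classify <- function(aln) {
  m <- do.call(rbind, strsplit(unname(aln), "", fixed = TRUE))
  vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    col <- col[col %in% c("A", "C", "G", "T", "-")]
    u <- unique(col)
    if (length(u) <= 1) return("invariant")
    if (any(col == "-")) return("gapped")
    tab <- table(col)
    if (sum(tab >= 2) >= 2) "parsimony_informative" else "singleton"
  }, character(1))
}

# closed-form 2x2 Pearson chi-squared
oracle_chi2_2x2 <- function(r1, R1, r2, R2) {
  a <- r1; b <- R1 - r1; c <- r2; d <- R2 - r2
  N <- R1 + R2
  N * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# minimal aligned fixture: n_cols invariant columns with planted states
make_alignment <- function(n_seq, n_cols, pinfo = integer(), singleton = integer(),
                           gapped = integer()) {
  stopifnot(n_seq >= 4)
  m <- matrix("A", n_seq, n_cols)
  for (j in pinfo) m[, j] <- rep(c("A", "T"), length.out = n_seq)
  for (j in singleton) m[, j] <- c("T", rep("A", n_seq - 1))
  for (j in gapped) m[, j] <- c("-", rep("A", n_seq - 1))
  setNames(apply(m, 1, paste, collapse = ""), paste0("s", seq_len(n_seq)))
}
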