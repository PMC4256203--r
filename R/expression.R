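#' Reads per kilobase per million mapped reads (RPKM)
#'
#' `count * 1e9 / (cds_length_nt * total_mapped)`. For multi-library RPKM
#' pool the counts and the totals first (see [pooled_rpkm()]).
#'
#' @param count Mapped read count(s) for the CDS.
#' @param cds_length_nt CDS length(s) in nucleotides (>= 3).
#' @param total_mapped Total reads mapped to all CDS in the library (R).
#' @return Numeric RPKM value(s); 0 exactly when `count` is 0.
#' @examples
#' rpkm(100, 1000, 1e6)  # 100
#' @export
rpkm <- function(count, cds_length_nt, total_mapped) {
  stopifnot(all(cds_length_nt >= 3), all(count >= 0))
  if (any(total_mapped < 1)) stop("total_mapped must be >= 1")
  count * 1e9 / (cds_length_nt * total_mapped)
}

#' RPKM over pooled libraries
#'
#' Sums per-library counts and per-library totals before applying the RPKM
#' formula, the pooling used for "overall" expression across libraries.
#'
#' @param counts Matrix of counts (rows CDS, columns libraries) or a list of
#'   `library_counts`.
#' @param cds_length_nt CDS lengths, in row order.
#' @param totals Per-library totals R; taken from the objects when `counts`
#'   is a list of `library_counts`.
#' @return Numeric vector of pooled RPKM, one per CDS.
#' @export
pooled_rpkm <- function(counts, cds_length_nt, totals = NULL) {
  if (is.list(counts) && !is.data.frame(counts) && !is.matrix(counts)) {
    totals <- vapply(counts, function(x) x$total_mapped, numeric(1))
    counts <- do.call(cbind, lapply(counts, function(x) x$counts))
  }
  stopifnot(!is.null(totals), ncol(counts) == length(totals))
  rpkm(rowSums(counts), cds_length_nt, sum(totals))
}

#' Per-CDS RPKM matrix over libraries
#'
#' @param libraries List of `library_counts` (all over the same CDS set).
#' @param cds_length_nt Named or ordered CDS lengths matching the count rows.
#' @return Numeric matrix (rows CDS, columns libraries) of RPKM values, with
#'   attribute `cds_length_nt`.
#' @export
rpkm_matrix <- function(libraries, cds_length_nt) {
  counts <- do.call(cbind, lapply(libraries, function(x) x$counts))
  colnames(counts) <- vapply(libraries, function(x) x$library_id, character(1))
  totals <- vapply(libraries, function(x) x$total_mapped, numeric(1))
  m <- sweep(counts, 2, totals, function(c, R) c * 1e9 / R) / cds_length_nt
  attr(m, "cds_length_nt") <- cds_length_nt
  m
}

#' Normalized fold-change ratio between two read groups
#'
#' The library-size-normalized fold statistic `r1*R2 / [R1*(r2+1)]` and its
#' mirror `r2*R1 / [R2*(r1+1)]`, where r are per-CDS reads and R the group
#' totals mapped to all CDS; the +1 pseudocount in the denominator avoids
#' division by zero.
#'
#' @param r1,r2 Per-CDS read counts in group 1 / group 2 (vectorized).
#' @param R1,R2 Total reads mapped to all CDS in group 1 / group 2.
#' @return List with numeric vectors `ratio_1over2` and `ratio_2over1`.
#' @examples
#' normalized_ratio(10, 1000, 0, 1000)  # ratio_1over2 = 10
#' @export
normalized_ratio <- function(r1, R1, r2, R2) {
  stopifnot(all(R1 >= 1), all(R2 >= 1), all(r1 >= 0), all(r2 >= 0),
            all(r1 <= R1), all(r2 <= R2))
  list(ratio_1over2 = r1 * R2 / (R1 * (r2 + 1)),
       ratio_2over1 = r2 * R1 / (R2 * (r1 + 1)))
}

#' Per-CDS chi-squared test on a 2x2 read table
#'
#' Pearson chi-squared with 1 df, no continuity correction, on the table
#' `[[r1, R1-r1], [r2, R2-r2]]`; p from the chi-squared(1) survival
#' function. Degenerate tables (any zero expected cell, i.e. r1 = r2 = 0 or
#' r = R in both groups) return chi2 = 0, p = 1. Vectorized over CDS.
#'
#' @inheritParams normalized_ratio
#' @return List with numeric vectors `chi2` and `p`.
#' @export
chi2_test <- function(r1, R1, r2, R2) {
  stopifnot(all(R1 >= 1), all(R2 >= 1), all(r1 >= 0), all(r2 >= 0),
            all(r1 <= R1), all(r2 <= R2))
  n <- pmax(length(r1), length(r2))
  r1 <- rep_len(as.numeric(r1), n); r2 <- rep_len(as.numeric(r2), n)
  R1 <- rep_len(as.numeric(R1), n); R2 <- rep_len(as.numeric(R2), n)
  N <- R1 + R2
  ptot <- (r1 + r2) / N
  # expected cells: row totals R1, R2; column totals (r1+r2), (N - r1 - r2)
  e11 <- R1 * ptot; e12 <- R1 * (1 - ptot)
  e21 <- R2 * ptot; e22 <- R2 * (1 - ptot)
  chi2 <- numeric(n)
  ok <- e11 > 0 & e12 > 0 & e21 > 0 & e22 > 0
  chi2[ok] <- (r1[ok] - e11[ok])^2 / e11[ok] +
    ((R1[ok] - r1[ok]) - e12[ok])^2 / e12[ok] +
    (r2[ok] - e21[ok])^2 / e21[ok] +
    ((R2[ok] - r2[ok]) - e22[ok])^2 / e22[ok]
  p <- rep(1, n)
  p[ok] <- pchisq(chi2[ok], df = 1, lower.tail = FALSE)
  list(chi2 = chi2, p = p)
}

#' Pairwise differential-expression comparison of two read groups
#'
#' Builds the per-CDS comparison table: counts, normalized ratios in both
#' directions, chi-squared statistic and p-value.
#'
#' @param counts1,counts2 Named per-CDS count vectors for the two groups
#'   (same CDS universe).
#' @param R1,R2 Group totals; default the sum of the supplied counts.
#' @return data.frame of class `de_comparison` with columns `cds_id`, `r1`,
#'   `r2`, `R1`, `R2`, `ratio_1over2`, `ratio_2over1`, `chi2`, `p`.
#' @export
compare_groups <- function(counts1, counts2, R1 = sum(counts1),
                           R2 = sum(counts2)) {
  stopifnot(identical(names(counts1), names(counts2)))
  nr <- normalized_ratio(counts1, R1, counts2, R2)
  ct <- chi2_test(counts1, R1, counts2, R2)
  out <- data.frame(cds_id = names(counts1), r1 = unname(counts1),
                    r2 = unname(counts2), R1 = R1, R2 = R2,
                    ratio_1over2 = unname(nr$ratio_1over2),
                    ratio_2over1 = unname(nr$ratio_2over1),
                    chi2 = ct$chi2, p = ct$p,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("de_comparison", "data.frame")
  out
}

#' Call >= fold overexpression with chi-squared significance
#'
#' A CDS is called `over_in_1` when its normalized ratio group1/group2 is at
#' least `fold` and its (optionally multiplicity-adjusted) p-value is below
#' `alpha`; symmetric for `over_in_2`; otherwise `ns`.
#'
#' @param comparison A `de_comparison` from [compare_groups()].
#' @param fold Fold threshold on the normalized ratio (default 10).
#' @param alpha Significance threshold (default 0.05).
#' @param mtc Multiple-testing correction over the CDS tested: `"bonferroni"`
#'   (default) or `"none"`.
#' @return The comparison with added columns `p_adj` and `call` (factor with
#'   levels `over_in_1`, `over_in_2`, `ns`).
#' @export
call_overexpression <- function(comparison, fold = 10, alpha = 0.05,
                                mtc = c("bonferroni", "none")) {
  mtc <- match.arg(mtc)
  p_adj <- if (mtc == "none") comparison$p else
    stats::p.adjust(comparison$p, method = "bonferroni")
  sig <- p_adj < alpha
  call <- ifelse(sig & comparison$ratio_1over2 >= fold, "over_in_1",
                 ifelse(sig & comparison$ratio_2over1 >= fold, "over_in_2",
                        "ns"))
  comparison$p_adj <- p_adj
  comparison$call <- factor(call, levels = c("over_in_1", "over_in_2", "ns"))
  comparison
}

#' Build stage and region contrasts from a library design
#'
#' The stage contrast pools all nymphal against all adult libraries; each
#' region contrast pools that region's libraries against all the others.
#' Counts and totals are summed within each pool.
#'
#' @param libraries List of `library_counts`.
#' @param design data.frame with columns `library_id`, `stage` (values
#'   `nymph`/`adult`) and `region`.
#' @return Named list of `de_comparison` objects: one `"stage"` contrast
#'   (group 1 = nymph) and one `"region:<name>"` per region (group 1 = that
#'   region).
#' @export
build_contrasts <- function(libraries, design) {
  stopifnot(all(c("library_id", "stage", "region") %in% names(design)))
  ids <- vapply(libraries, function(x) x$library_id, character(1))
  stopifnot(setequal(ids, design$library_id))
  des <- design[match(ids, design$library_id), ]
  stopifnot(all(des$stage %in% c("nymph", "adult")))
  counts <- do.call(cbind, lapply(libraries, function(x) x$counts))
  totals <- vapply(libraries, function(x) x$total_mapped, numeric(1))
  pool <- function(sel) {
    if (!any(sel)) stop("contrast group with zero libraries")
    list(counts = rowSums(counts[, sel, drop = FALSE]),
         R = sum(totals[sel]))
  }
  out <- list()
  g1 <- pool(des$stage == "nymph")
  g2 <- pool(des$stage == "adult")
  out[["stage"]] <- compare_groups(g1$counts, g2$counts, g1$R, g2$R)
  for (reg in unique(des$region)) {
    g1 <- pool(des$region == reg)
    g2 <- pool(des$region != reg)
    out[[paste0("region:", reg)]] <-
      compare_groups(g1$counts, g2$counts, g1$R, g2$R)
  }
  out
}

#' Per-class summary of called CDS
#'
#' For each functional class among the CDS called overexpressed in one group:
#' arithmetic mean and standard error (sd/sqrt(n)) of the per-CDS group-mean
#' RPKM in each group, and the number of CDS. SE is `NA` for single-CDS
#' classes.
#'
#' @param called A `de_comparison` with a `call` column (see
#'   [call_overexpression()]).
#' @param rpkm1,rpkm2 Named per-CDS RPKM vectors for group 1 and group 2
#'   (each the mean over that group's libraries, or the pooled group RPKM).
#' @param classes Named character vector mapping cds_id to class label.
#' @param which_call Which call to summarize (default `"over_in_1"`).
#' @return data.frame with columns `class`, `mean_rpkm_1`, `se_1`,
#'   `mean_rpkm_2`, `se_2`, `n_cds`.
#' @export
class_summary <- function(called, rpkm1, rpkm2, classes,
                          which_call = "over_in_1") {
  sel <- called$cds_id[called$call == which_call]
  if (length(sel) == 0L) {
    return(data.frame(class = character(), mean_rpkm_1 = numeric(),
                      se_1 = numeric(), mean_rpkm_2 = numeric(),
                      se_2 = numeric(), n_cds = integer(),
                      stringsAsFactors = FALSE))
  }
  cls <- unname(classes[sel])
  se <- function(x) if (length(x) > 1L) sd(x) / sqrt(length(x)) else NA_real_
  agg <- lapply(split(sel, cls), function(idx) {
    data.frame(mean_rpkm_1 = mean(rpkm1[idx]), se_1 = se(rpkm1[idx]),
               mean_rpkm_2 = mean(rpkm2[idx]), se_2 = se(rpkm2[idx]),
               n_cds = length(idx))
  })
  out <- cbind(data.frame(class = names(agg), stringsAsFactors = FALSE),
               do.call(rbind, agg))
  rownames(out) <- NULL
  out
}

#' Row-average normalization of an expression matrix
#'
#' Drops rows whose overall RPKM is below `min_overall_rpkm`, then divides
#' each surviving row by its own mean so every row averages 1 (the
#' normalization used for expression heat maps). All-zero rows cannot be
#' normalized and are dropped.
#'
#' @param mat Numeric matrix (rows CDS, columns libraries).
#' @param min_overall_rpkm Overall-expression filter (default 20).
#' @param overall Per-row overall RPKM used for the filter; defaults to the
#'   row mean. Supply the pooled-count RPKM when library totals differ.
#' @param method `"row_average"` (default) or `"zscore"`
#'   (`(x - mean) / sd` per row).
#' @return The filtered, normalized matrix.
#' @export
row_average_normalize <- function(mat, min_overall_rpkm = 20,
                                  overall = rowMeans(mat),
                                  method = c("row_average", "zscore")) {
  method <- match.arg(method)
  stopifnot(is.matrix(mat), ncol(mat) >= 1L, length(overall) == nrow(mat))
  keep <- overall >= min_overall_rpkm & rowMeans(mat) > 0
  m <- mat[keep, , drop = FALSE]
  if (method == "row_average") {
    m / rowMeans(m)
  } else {
    sds <- apply(m, 1, sd)
    sds[sds == 0] <- 1
    (m - rowMeans(m)) / sds
  }
}

#' Write a differential-expression table as TSV
#'
#' @param called A `de_comparison` with calls.
#' @param path Output path.
#' @param classes Optional named class-label vector added as a `class` column.
#' @return `path`, invisibly.
#' @export
write_de_tsv <- function(called, path, classes = NULL) {
  out <- as.data.frame(called)
  if (!is.null(classes)) {
    out$class <- unname(classes[out$cds_id])
    out <- out[, c("cds_id", "class", setdiff(names(out), c("cds_id", "class")))]
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
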