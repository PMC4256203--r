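# Standard genetic code (translation table 1); '*' marks stop codons.
# Hand-coded here because the S/NS classifier is the package's own core.
CODON_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

#' Translate a codon under the standard genetic code
#'
#' @param codon Character vector of 3-base codons (upper case).
#' @return Amino acid letters (`*` for stop); `NA` for codons containing a
#'   base outside A/C/G/T.
#' @export
translate_codon <- function(codon) {
  unname(CODON_TABLE[codon])
}

#' Filter SNP calls on depth and quality
#'
#' Keeps a call iff its coverage depth is at least `min_depth` and its
#' quality at least `min_qual`; both boundaries inclusive.
#'
#' @param snps `snp_calls` data.frame (see [read_vcf_snps()]).
#' @param min_depth Minimum coverage depth (default 20).
#' @param min_qual Minimum site quality (default 13).
#' @return The filtered `snp_calls`.
#' @export
filter_snps <- function(snps, min_depth = 20, min_qual = 13) {
  keep <- !is.na(snps$depth) & snps$depth >= min_depth &
    !is.na(snps$quality) & snps$quality >= min_qual
  out <- snps[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(snps)
  out
}

#' Classify SNPs as synonymous or non-synonymous
#'
#' Each SNP is evaluated independently against the reference codon of its
#' CDS (frame 0 from base 1): the change is synonymous iff the standard
#' genetic code translates the reference and alternate codons to the same
#' amino acid; stop-to-sense (and sense-to-stop) changes are non-synonymous.
#' Codons containing `N` are classified `"unset"` and excluded from rate
#' denominators. CDS whose length is not divisible by 3 are rejected.
#'
#' @param snps `snp_calls` data.frame.
#' @param cds A `cds_set`.
#' @return The calls with the `effect` column set to `"synonymous"`,
#'   `"nonsynonymous"` or `"unset"`.
#' @export
classify_snps <- function(snps, cds) {
  stopifnot(inherits(cds, "cds_set"))
  if (nrow(snps) == 0L) return(snps)
  ci <- match(snps$cds_id, cds$id)
  if (anyNA(ci)) {
    stop("SNP cds_id(s) not in CDS set: ",
         paste(unique(snps$cds_id[is.na(ci)]), collapse = ", "))
  }
  len <- cds$length_nt[ci]
  if (any(len %% 3L != 0L)) {
    stop("CDS length not divisible by 3: ",
         paste(unique(snps$cds_id[len %% 3L != 0L]), collapse = ", "))
  }
  if (any(snps$pos_1based < 1L | snps$pos_1based > len)) {
    stop("SNP position beyond CDS length")
  }
  codon_idx <- (snps$pos_1based - 1L) %/% 3L        # 0-based codon index
  codon_start <- codon_idx * 3L + 1L
  within <- snps$pos_1based - codon_start + 1L      # 1, 2 or 3
  ref_codon <- substring(cds$sequence[ci], codon_start, codon_start + 2L)
  alt_codon <- ref_codon
  substr(alt_codon, within, within) <- snps$alt
  aa_ref <- translate_codon(ref_codon)
  aa_alt <- translate_codon(alt_codon)
  snps$effect <- ifelse(is.na(aa_ref) | is.na(aa_alt), "unset",
                        ifelse(aa_ref == aa_alt, "synonymous",
                               "nonsynonymous"))
  snps
}

#' Classify a single base change against a reference codon
#'
#' Convenience scalar form of [classify_snps()] for one codon.
#'
#' @param ref_codon Reference codon (3 bases).
#' @param pos_in_codon Position of the change within the codon (1-3).
#' @param alt Alternate base.
#' @return `"synonymous"`, `"nonsynonymous"` or `"unset"`.
#' @examples
#' classify_effect("GAA", 3, "G")  # synonymous (Glu -> Glu)
#' classify_effect("GAA", 2, "T")  # nonsynonymous (Glu -> Val)
#' @export
classify_effect <- function(ref_codon, pos_in_codon, alt) {
  stopifnot(nchar(ref_codon) == 3L, pos_in_codon %in% 1:3, nchar(alt) == 1L)
  alt_codon <- ref_codon
  substr(alt_codon, pos_in_codon, pos_in_codon) <- alt
  aa_ref <- translate_codon(ref_codon)
  aa_alt <- translate_codon(alt_codon)
  if (is.na(aa_ref) || is.na(aa_alt)) return("unset")
  if (aa_ref == aa_alt) "synonymous" else "nonsynonymous"
}

n_codons_no_n <- function(sequence) {
  len <- nchar(sequence)
  stopifnot(len %% 3L == 0L)
  starts <- seq.int(1L, len, by = 3L)
  codons <- substring(sequence, starts, starts + 2L)
  sum(!grepl("N", codons, fixed = TRUE))
}

#' Per-CDS polymorphism rates per 100 codons
#'
#' Counts classified synonymous and non-synonymous SNPs per CDS and scales
#' them to rates per 100 codons; codons containing `N` are excluded from the
#' codon denominator, and `"unset"` calls from the counts.
#'
#' @param snps Classified `snp_calls` (see [classify_snps()]), already
#'   filtered as desired.
#' @param cds A `cds_set`.
#' @param polymorphic_only Keep only CDS with at least one classified SNP
#'   (default TRUE, the convention for per-class polymorphism tables).
#' @return data.frame with columns `cds_id`, `class_label`, `n_codons`,
#'   `s_count`, `ns_count`, `unset_count`, `s_per_100`, `ns_per_100`.
#' @export
rates_per_cds <- function(snps, cds, polymorphic_only = TRUE) {
  stopifnot(inherits(cds, "cds_set"))
  n_codons <- vapply(cds$sequence, n_codons_no_n, integer(1), USE.NAMES = FALSE)
  if (any(n_codons == 0L)) stop("CDS with zero N-free codons")
  tab <- function(eff) {
    v <- table(factor(snps$cds_id[snps$effect == eff], levels = cds$id))
    as.integer(v)
  }
  out <- data.frame(cds_id = cds$id, class_label = cds$class_label,
                    n_codons = n_codons, s_count = tab("synonymous"),
                    ns_count = tab("nonsynonymous"),
                    unset_count = tab("unset"),
                    row.names = NULL, stringsAsFactors = FALSE)
  out$s_per_100 <- 100 * out$s_count / out$n_codons
  out$ns_per_100 <- 100 * out$ns_count / out$n_codons
  if (polymorphic_only) {
    out <- out[out$s_count + out$ns_count > 0L, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' NS/S ratio from class mean rates
#'
#' The class-level NS/S ratio is the ratio of the class mean NS and S rates
#' (not the mean of per-CDS ratios).
#'
#' @param mean_ns,mean_s Class mean rates per 100 codons.
#' @return `mean_ns / mean_s`; `NA` when `mean_s` is 0.
#' @export
ns_over_s <- function(mean_ns, mean_s) {
  ifelse(mean_s > 0, mean_ns / mean_s, NA_real_)
}

#' Per-class polymorphism summary
#'
#' For each functional class, over its polymorphic CDS: mean synonymous and
#' non-synonymous rates per 100 codons with standard errors (sd/sqrt(n); NA
#' for single-CDS classes), the NS/S ratio of the class means, and the
#' number of polymorphic CDS.
#'
#' @param per_cds Output of [rates_per_cds()] (polymorphic CDS only).
#' @param classes Optional named class-label vector overriding the
#'   `class_label` column.
#' @return data.frame with columns `class`, `mean_s`, `se_s`, `mean_ns`,
#'   `se_ns`, `ns_over_s`, `n_cds`, ordered by increasing `ns_over_s`.
#' @export
rates_per_class <- function(per_cds, classes = NULL) {
  cls <- if (is.null(classes)) per_cds$class_label
         else unname(classes[per_cds$cds_id])
  se <- function(x) if (length(x) > 1L) sd(x) / sqrt(length(x)) else NA_real_
  agg <- lapply(split(seq_len(nrow(per_cds)), cls), function(i) {
    s <- per_cds$s_per_100[i]; ns <- per_cds$ns_per_100[i]
    data.frame(mean_s = mean(s), se_s = se(s), mean_ns = mean(ns),
               se_ns = se(ns), ns_over_s = ns_over_s(mean(ns), mean(s)),
               n_cds = length(i))
  })
  out <- cbind(data.frame(class = names(agg), stringsAsFactors = FALSE),
               do.call(rbind, agg))
  out <- out[order(out$ns_over_s), ]
  rownames(out) <- NULL
  out
}

#' Per-library polymorphism comparison
#'
#' Computes, for each library's SNP calls, the mean and SE of per-CDS
#' synonymous and non-synonymous rates restricted to the shared polymorphic
#' CDS set (the union of CDS polymorphic in any library), so bars are
#' comparable across libraries.
#'
#' @param snps_by_library Named list of classified, filtered `snp_calls`,
#'   one per library.
#' @param cds A `cds_set` (the same universe for every library).
#' @return data.frame with columns `library_id`, `mean_s`, `se_s`,
#'   `mean_ns`, `se_ns`, `n_cds` (the shared set size).
#' @export
per_library_polymorphism <- function(snps_by_library, cds) {
  stopifnot(inherits(cds, "cds_set"), length(snps_by_library) >= 1L)
  per_lib <- lapply(snps_by_library, rates_per_cds, cds = cds,
                    polymorphic_only = FALSE)
  poly <- sort(unique(unlist(lapply(per_lib, function(x)
    x$cds_id[x$s_count + x$ns_count > 0L]))))
  se <- function(x) if (length(x) > 1L) sd(x) / sqrt(length(x)) else NA_real_
  rows <- lapply(names(per_lib), function(lib) {
    x <- per_lib[[lib]]
    x <- x[match(poly, x$cds_id), , drop = FALSE]
    data.frame(library_id = lib, mean_s = mean(x$s_per_100),
               se_s = se(x$s_per_100), mean_ns = mean(x$ns_per_100),
               se_ns = se(x$ns_per_100), n_cds = length(poly),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
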