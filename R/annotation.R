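STOP_CODONS <- c("TAA", "TAG", "TGA")

revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(x, function(s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""),
    character(1), USE.NAMES = FALSE))
}

#' Find open reading frames in all six frames
#'
#' An ORF runs from an ATG to the first in-frame stop codon (stop included);
#' every ATG opens its own ORF, so nested ORFs sharing a stop are all
#' reported. Coordinates are 1-based inclusive on the input sequence; minus
#' strand ORFs are located on the reverse complement but reported in input
#' coordinates (`start < end` always).
#'
#' @param sequence DNA sequence (single string).
#' @return data.frame with columns `start`, `end`, `frame` (1-3 on the
#'   strand), `strand` (`+`/`-`), `length_nt` (including the stop codon),
#'   sorted longest-first. Zero rows when no ORF exists.
#' @examples
#' find_orfs("ATGAAATGA")
#' @export
find_orfs <- function(sequence) {
  stopifnot(length(sequence) == 1L)
  s <- toupper(sequence)
  L <- nchar(s)
  out <- list()
  for (strand in c("+", "-")) {
    t <- if (strand == "+") s else revcomp(s)
    for (f in 0:2) {
      starts <- seq.int(f + 1L, L, by = 3L)
      starts <- starts[starts + 2L <= L]
      if (length(starts) == 0L) next
      codons <- substring(t, starts, starts + 2L)
      atg <- which(codons == "ATG")
      stp <- which(codons %in% STOP_CODONS)
      if (length(atg) == 0L || length(stp) == 0L) next
      # first stop at or after each ATG
      j <- findInterval(atg - 1L, stp) + 1L
      ok <- j <= length(stp)
      if (!any(ok)) next
      a <- atg[ok]; e <- stp[j[ok]]
      st <- starts[a]; en <- starts[e] + 2L
      if (strand == "-") {
        tmp <- L - en + 1L
        en <- L - st + 1L
        st <- tmp
      }
      out[[length(out) + 1L]] <-
        data.frame(start = st, end = en, frame = f + 1L, strand = strand,
                   length_nt = en - st + 1L, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(), end = integer(), frame = integer(),
                      strand = character(), length_nt = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(-res$length_nt, res$start, res$strand), ]
  rownames(res) <- NULL
  res
}

#' Default keyword vocabulary for functional classification
#'
#' An ordered keyword list (first match wins) mapping annotation-description
#' substrings to the five functional classes (Secreted, Housekeeping,
#' Transposable element, Viral, Unknown) plus a finer subfamily tag used for
#' subclass tables. Shipped as a TSV under `extdata/`; users may edit or
#' extend it and pass their own table.
#'
#' @return data.frame with columns `keyword`, `class`, `subfamily`.
#' @export
default_vocabulary <- function() {
  path <- system.file("extdata", "vocabulary.tsv", package = "sialoseq",
                      mustWork = TRUE)
  voc <- read.delim(path, stringsAsFactors = FALSE)
  validate_vocabulary(voc)
  voc
}

validate_vocabulary <- function(vocabulary) {
  stopifnot(all(c("keyword", "class", "subfamily") %in% names(vocabulary)),
            all(nzchar(vocabulary$keyword)),
            all(vocabulary$class %in% VALID_CLASSES))
  invisible(vocabulary)
}

#' Classify one CDS from its annotation description
#'
#' The first vocabulary keyword found as a case-insensitive substring of the
#' description decides class and subfamily. Transposable-element keywords
#' only fire when `te_evidence` is TRUE (the supplied proxy for a
#' significant repeat-database hit); without it, scanning continues.
#' When no keyword matches, the fallback is Secreted (subfamily
#' `"Other secreted"`) if the CDS carries a signal peptide, else Unknown.
#'
#' @param description Annotation description text (may be empty).
#' @param has_signal_peptide Logical signal-peptide flag (supplied, not
#'   predicted).
#' @param vocabulary Vocabulary data.frame (default [default_vocabulary()]).
#' @param te_evidence Logical transposable-element evidence flag.
#' @return List with `class_label` and `subfamily`.
#' @examples
#' classify_cds("salivary lipocalin precursor", FALSE)
#' @export
classify_cds <- function(description, has_signal_peptide,
                         vocabulary = default_vocabulary(),
                         te_evidence = FALSE) {
  desc <- tolower(description)
  for (i in seq_len(nrow(vocabulary))) {
    if (vocabulary$class[i] == "Transposable element" && !isTRUE(te_evidence)) {
      next
    }
    if (grepl(tolower(vocabulary$keyword[i]), desc, fixed = TRUE)) {
      return(list(class_label = vocabulary$class[i],
                  subfamily = vocabulary$subfamily[i]))
    }
  }
  if (isTRUE(has_signal_peptide)) {
    list(class_label = "Secreted", subfamily = "Other secreted")
  } else {
    list(class_label = "Unknown", subfamily = "Unknown")
  }
}

#' Classify every CDS of a set
#'
#' @param cds A `cds_set` whose `description`, `has_signal_peptide` and
#'   `te_evidence` columns are filled.
#' @param vocabulary Vocabulary data.frame.
#' @return The `cds_set` with `class_label` set and a `subfamily` column
#'   added.
#' @export
classify_cds_set <- function(cds, vocabulary = default_vocabulary()) {
  stopifnot(inherits(cds, "cds_set"))
  validate_vocabulary(vocabulary)
  res <- mapply(function(d, sp, te)
    classify_cds(d, sp, vocabulary, te),
    cds$description, cds$has_signal_peptide, cds$te_evidence,
    SIMPLIFY = FALSE, USE.NAMES = FALSE)
  cds$class_label <- vapply(res, `[[`, character(1), "class_label")
  cds$subfamily <- vapply(res, `[[`, character(1), "subfamily")
  cds
}

#' Per-class assembly metrics
#'
#' Summarizes a classified CDS set against total mapped reads: per class the
#' number of CDS, total reads, reads per CDS (rounded to integer), percent
#' of total CDS and percent of total reads (2 decimals), plus a Total row.
#'
#' @param classes Named character vector mapping cds_id to class label.
#' @param reads Named numeric vector of total mapped reads per CDS (pooled
#'   over libraries).
#' @return data.frame with columns `class`, `n_cds`, `n_reads`,
#'   `reads_per_cds`, `pct_cds`, `pct_reads`.
#' @export
class_metrics <- function(classes, reads) {
  stopifnot(!is.null(names(classes)), !is.null(names(reads)))
  reads <- reads[names(classes)]
  f <- if (is.factor(classes)) classes else factor(unname(classes))
  n_reads <- vapply(levels(f), function(l) sum(reads[f == l]), numeric(1))
  totals <- data.frame(class = levels(f),
                       n_cds = as.integer(table(f)),
                       n_reads = unname(n_reads),
                       stringsAsFactors = FALSE)
  class_metrics_from_totals(totals)
}

#' Per-class metrics from pre-aggregated totals
#'
#' The arithmetic core of [class_metrics()]: derives reads/CDS and the
#' percentage columns from per-class CDS and read totals.
#'
#' @param totals data.frame with columns `class`, `n_cds`, `n_reads`.
#' @return data.frame with derived columns `reads_per_cds` (rounded
#'   integer), `pct_cds` and `pct_reads` (2 decimals), plus a `Total` row.
#' @export
class_metrics_from_totals <- function(totals) {
  stopifnot(all(c("class", "n_cds", "n_reads") %in% names(totals)))
  tot_cds <- sum(totals$n_cds)
  tot_reads <- sum(totals$n_reads)
  out <- totals
  out$reads_per_cds <- ifelse(out$n_cds > 0, round(out$n_reads / out$n_cds),
                              0)
  out$pct_cds <- round(100 * out$n_cds / tot_cds, 2)
  out$pct_reads <- if (tot_reads > 0) round(100 * out$n_reads / tot_reads, 2)
                   else 0
  total_row <- data.frame(class = "Total", n_cds = tot_cds,
                          n_reads = tot_reads, reads_per_cds = NA_real_,
                          pct_cds = 100, pct_reads = if (tot_reads > 0) 100 else 0,
                          stringsAsFactors = FALSE)
  out <- rbind(out, total_row)
  rownames(out) <- NULL
  out
}
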