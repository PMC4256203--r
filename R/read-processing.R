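#' Quality-trim and filter a read
#'
#' Bases are removed from the 5' and 3' ends while their quality is below
#' `end_q`; the read is rejected when the mean quality of the remainder is
#' below `mean_q` or the remainder is shorter than `min_len` (the seed word
#' size, so that every kept read can be mapped).
#'
#' @param sequence Read sequence (single string).
#' @param qualities Integer Phred scores, one per base (see [phred_scores()]).
#' @param end_q End-trimming threshold: terminal bases with quality `< end_q`
#'   are removed (default 10).
#' @param mean_q Minimum mean quality of the trimmed read (default 20).
#' @param min_len Minimum length of the trimmed read (default 25).
#' @return A list with elements `kept` (logical), and when kept, `sequence`
#'   and `qualities` of the trimmed read plus `from`/`to` (1-based bounds on
#'   the input read).
#' @examples
#' trim_and_filter("ACGTGA", c(5L, 5L, 30L, 30L, 30L, 5L))
#' @export
trim_and_filter <- function(sequence, qualities, end_q = 10L, mean_q = 20L,
                            min_len = 25L) {
  stopifnot(length(sequence) == 1L, nchar(sequence) == length(qualities))
  b <- .trim_bounds_cpp(phred_encode(qualities), as.integer(end_q))
  from <- b[1L]; to <- b[2L]
  len <- to - from + 1L
  if (len < min_len) {
    return(list(kept = FALSE, reason = "too_short"))
  }
  q <- qualities[from:to]
  if (mean(q) < mean_q) {
    return(list(kept = FALSE, reason = "low_mean_quality"))
  }
  list(kept = TRUE, sequence = substring(sequence, from, to), qualities = q,
       from = from, to = to)
}

#' Build an exact k-mer seed index over a CDS set
#'
#' Indexes every k-mer of both strands (sense and reverse complement) of each
#' CDS; k-mers containing `N` are skipped. The index drives [map_read()] and
#' [count_library()].
#'
#' @param cds A `cds_set` or a named character vector of CDS sequences.
#' @param k Seed word size (default 25).
#' @return An object of class `cds_index`.
#' @export
build_index <- function(cds, k = 25L) {
  if (inherits(cds, "cds_set")) {
    ids <- cds$id; seqs <- cds$sequence
  } else {
    stopifnot(!is.null(names(cds)))
    ids <- names(cds); seqs <- unname(cds)
  }
  if (length(ids) == 0L) stop("empty CDS set")
  ptr <- .build_index_cpp(ids, seqs, as.integer(k))
  structure(list(ptr = ptr, ids = ids, k = as.integer(k)),
            class = "cds_index")
}

#' @export
print.cds_index <- function(x, ...) {
  s <- .index_stats_cpp(x$ptr)
  cat("cds_index:", s$n_cds, "CDS, k =", s$k, ",",
      format(s$n_entries, big.mark = ","), "seed entries\n")
  invisible(x)
}

#' Number of seed entries stored in an index
#'
#' @param index A `cds_index`.
#' @return Numeric count of (k-mer, cds, strand, offset) entries.
#' @export
index_n_entries <- function(index) {
  .index_stats_cpp(index$ptr)$n_entries
}

#' Look up one k-mer in a seed index
#'
#' @param index A `cds_index`.
#' @param kmer A string of length `k` (A/C/G/T).
#' @return data.frame with columns `cds_id`, `strand` (`+` sense, `-` reverse
#'   complement) and `pos` (1-based offset on the strand-oriented sequence).
#' @export
index_lookup <- function(index, kmer) {
  .index_lookup_cpp(index$ptr, kmer)
}

default_scoring <- function() {
  list(match = 1L, mismatch = 2L, gap_open = 3L, gap_ext = 1L)
}

#' Map one read to a CDS set
#'
#' Candidate CDS are found by exact k-mer seed hits; each candidate diagonal
#' is extended with at most `max_gaps` (0 or 1) gap openings, scored +1 per
#' match, -2 per mismatch, -3 per gap opening and -1 per gap extension.
#' Alignments with identity (matches / aligned read length) below
#' `min_identity` are discarded; all CDS achieving the maximum remaining
#' score are returned. If more than `max_ties` CDS tie at the maximum the
#' read is discarded (empty result with attribute `tie_overflow = TRUE`).
#'
#' @param read Trimmed read sequence (single string).
#' @param index A `cds_index` from [build_index()].
#' @param min_identity Minimum identity (default 0.96).
#' @param max_gaps Maximum gap openings per alignment (default 1).
#' @param max_ties Maximum number of tied best CDS counted per read
#'   (default 5).
#' @param max_gap_len Maximum gap length searched (default 10).
#' @param scoring List with `match`, `mismatch`, `gap_open`, `gap_ext`
#'   penalty magnitudes.
#' @return Character vector of CDS ids (lexicographically sorted), possibly
#'   empty; attribute `tie_overflow` marks reads discarded for exceeding
#'   `max_ties`.
#' @export
map_read <- function(read, index, min_identity = 0.96, max_gaps = 1L,
                     max_ties = 5L, max_gap_len = 10L,
                     scoring = default_scoring()) {
  stopifnot(inherits(index, "cds_index"), length(read) == 1L)
  r <- .map_read_cpp(index$ptr, toupper(read), min_identity,
                     as.integer(max_gaps), as.integer(max_gap_len),
                     as.integer(max_ties), scoring$match, scoring$mismatch,
                     scoring$gap_open, scoring$gap_ext)
  structure(sort(r$cds_id), tie_overflow = r$tie_overflow)
}

#' Count a read library onto a CDS set
#'
#' Applies [trim_and_filter()] then [map_read()] to every read and
#' accumulates per-CDS counts. With `tie_mode = "each"` (default) a read tied
#' across k <= `max_ties` CDS adds 1 to each tied CDS, so the count total R
#' can exceed the number of distinct mapped reads; `"fractional"` adds 1/k
#' instead. Deterministic given its inputs.
#'
#' @param reads A data.frame from [read_fastq()] (columns `sequence`,
#'   `quality`) or a path to a FASTQ file.
#' @param index A `cds_index`.
#' @param library_id Library label stored with the counts.
#' @param end_q,mean_q Quality-trimming thresholds (see [trim_and_filter()]).
#' @param min_identity,max_gaps,max_ties,max_gap_len,scoring Mapping
#'   parameters (see [map_read()]).
#' @param tie_mode `"each"` or `"fractional"` accrual for tied reads.
#' @return An object of class `library_counts`: list with `library_id`,
#'   `counts` (named numeric vector, one entry per CDS), `total_mapped`
#'   (R = sum of counts), `reads_in`, `reads_rejected_qc`, `reads_unmapped`,
#'   `distinct_mapped`, `ties_discarded`.
#' @export
count_library <- function(reads, index, library_id = "lib",
                          end_q = 10L, mean_q = 20L,
                          min_identity = 0.96, max_gaps = 1L, max_ties = 5L,
                          max_gap_len = 10L, scoring = default_scoring(),
                          tie_mode = c("each", "fractional")) {
  stopifnot(inherits(index, "cds_index"))
  tie_mode <- match.arg(tie_mode)
  if (is.character(reads) && length(reads) == 1L) {
    reads <- read_fastq(reads)
  }
  stopifnot(all(c("sequence", "quality") %in% names(reads)),
            all(nchar(reads$sequence) == nchar(reads$quality)))
  r <- .count_library_cpp(index$ptr, reads$sequence, reads$quality,
                          as.integer(end_q), as.integer(mean_q), index$k,
                          min_identity, as.integer(max_gaps),
                          as.integer(max_gap_len), as.integer(max_ties),
                          scoring$match, scoring$mismatch, scoring$gap_open,
                          scoring$gap_ext, tie_mode == "fractional")
  structure(list(library_id = library_id, counts = r$counts,
                 total_mapped = sum(r$counts), reads_in = r$reads_in,
                 reads_rejected_qc = r$reads_rejected_qc,
                 reads_unmapped = r$reads_unmapped,
                 distinct_mapped = r$distinct_mapped,
                 ties_discarded = r$ties_discarded, tie_mode = tie_mode),
            class = "library_counts")
}

#' @export
print.library_counts <- function(x, ...) {
  cat("library_counts '", x$library_id, "': ", format(x$reads_in, big.mark = ","),
      " reads in, ", format(x$distinct_mapped, big.mark = ","), " mapped (R = ",
      format(x$total_mapped, big.mark = ","), "), ",
      format(x$reads_rejected_qc, big.mark = ","), " rejected, ",
      format(x$reads_unmapped, big.mark = ","), " unmapped\n", sep = "")
  invisible(x)
}

#' Write per-CDS counts as TSV
#'
#' One row per CDS (`cds_id`, `count`) followed by `#summary` comment lines
#' with R (total mapped), rejected and unmapped tallies.
#'
#' @param lc A `library_counts` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(lc, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#library\t%s", lc$library_id), con)
  writeLines(sprintf("#total_mapped\t%s\t#rejected\t%s\t#unmapped\t%s",
                     format(lc$total_mapped, scientific = FALSE),
                     format(lc$reads_rejected_qc, scientific = FALSE),
                     format(lc$reads_unmapped, scientific = FALSE)), con)
  writeLines("cds_id\tcount", con)
  writeLines(sprintf("%s\t%s", names(lc$counts),
                     format(lc$counts, trim = TRUE, scientific = FALSE)), con)
  invisible(path)
}

#' Per-library read-length summary
#'
#' Computes the average read length (total residues / total sequences) per
#' library and grand totals, the summary printed for sequencing runs after
#' quality clipping.
#'
#' @param libraries data.frame with columns `library_id`, `n_sequences`,
#'   `n_residues`.
#' @param digits Decimals for the average length (default 1).
#' @return List with `per_library` (input plus `average_length`) and
#'   `total_sequences`, `total_residues`.
#' @export
library_read_stats <- function(libraries, digits = 1L) {
  stopifnot(all(c("library_id", "n_sequences", "n_residues")
                %in% names(libraries)))
  out <- libraries
  out$average_length <- round(out$n_residues / out$n_sequences, digits)
  list(per_library = out,
       total_sequences = sum(libraries$n_sequences),
       total_residues = sum(libraries$n_residues))
}
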