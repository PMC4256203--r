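#' @useDynLib sialoseq, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rbinom rlnorm rmultinom rpois runif sd setNames pchisq
#' @importFrom utils read.delim write.table
NULL

# On-disk positions are 1-based inclusive (VCF/FASTA convention); any 0-based
# half-open arithmetic is internal and converted only in this file.

VALID_CLASSES <- c("Secreted", "Housekeeping", "Transposable element",
                   "Viral", "Unknown")

#' Read a FASTA file
#'
#' Reads plain or gzipped FASTA into a named character vector of upper-cased
#' sequences. By default only unambiguous DNA plus `N` is accepted; alignment
#' gaps (`-`) are allowed when `aligned = TRUE`.
#'
#' @param path Path to a FASTA file (optionally gzip-compressed).
#' @param aligned Logical; allow `-` gap characters (aligned FASTA).
#' @return Named character vector; names are record ids (first whitespace
#'   token of each header), values are upper-case sequences.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "acg", "t"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, aligned = FALSE) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (length(lines) == 0L || !hdr[1L]) {
    stop("FASTA format error at line 1 of '", path, "': expected '>' header")
  }
  blank <- !nzchar(trimws(lines))
  if (any(blank & !hdr)) lines[blank] <- ""
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  if (any(!nzchar(ids))) {
    stop("FASTA format error at line ", which(hdr & lines == ">")[1L],
         " of '", path, "': empty header")
  }
  rec <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], rec[!hdr]),
                 function(x) toupper(paste(x, collapse = "")), character(1))
  out <- setNames(character(length(ids)), ids)
  out[as.integer(names(seqs))] <- seqs
  if (any(!nzchar(out))) {
    bad <- which(hdr)[which(!nzchar(out))[1L]]
    stop("FASTA format error at line ", bad, " of '", path,
         "': record with empty sequence")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  alphabet <- if (aligned) "ACGTN-" else "ACGTN"
  bad <- grepl(sprintf("[^%s]", alphabet), out)
  if (any(bad)) {
    stop("FASTA record '", ids[which(bad)[1L]],
         "' contains characters outside [", alphabet, "]")
  }
  out
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    starts <- seq.int(1L, nchar(s), by = width)
    writeLines(c(paste0(">", names(seqs)[i]),
                 substring(s, starts, pmin(starts + width - 1L, nchar(s)))),
               con)
  }
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#'
#' @param path Path to a FASTQ file (optionally gzip-compressed).
#' @return A data.frame with columns `id`, `sequence` and `quality` (the raw
#'   Phred+33 quality string). Decode scores with [phred_scores()].
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r", "AC", "+", "II"), fq)
#' phred_scores(read_fastq(fq)$quality)
#' @export
read_fastq <- function(path) {
  stopifnot(file.exists(path))
  # structural validation first: the C-level reader is not safe on
  # truncated records (4-line records assumed, as in the C reader itself)
  lines <- readLines(path)
  bad <- function(line, why) {
    stop("FASTQ format error at line ", line, " of '", path, "': ", why,
         call. = FALSE)
  }
  if (length(lines) %% 4L != 0L) {
    bad(length(lines), "truncated record (line count not a multiple of 4)")
  }
  n <- length(lines) %/% 4L
  if (n > 0L) {
    at <- function(k) lines[seq.int(k, by = 4L, length.out = n)]
    if (any(!startsWith(at(1L), "@"))) {
      bad(4L * (which(!startsWith(at(1L), "@"))[1L] - 1L) + 1L,
          "expected '@' header")
    }
    if (any(!startsWith(at(3L), "+"))) {
      bad(4L * (which(!startsWith(at(3L), "+"))[1L] - 1L) + 3L,
          "expected '+' separator")
    }
    mism <- nchar(at(2L)) != nchar(at(4L))
    if (any(mism)) {
      bad(4L * (which(mism)[1L] - 1L) + 4L,
          "sequence/quality length mismatch")
    }
  }
  # Biostrings warns about dropping its own metadata columns here
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.frame(id = sub("\\s.*$", "", names(x)),
             sequence = as.character(x),
             quality = as.character(Biostrings::quality(x)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Decode Phred+33 quality strings to integer scores
#'
#' @param quality Character vector of Phred+33 quality strings.
#' @return List of integer vectors (one per string); a single integer vector
#'   when `quality` has length one.
#' @export
phred_scores <- function(quality) {
  out <- lapply(quality, function(q) utf8ToInt(q) - 33L)
  if (length(out) == 1L) out[[1L]] else out
}

#' Encode integer Phred scores as a Phred+33 string
#'
#' @param scores Integer vector of Phred scores (0-60).
#' @return Single quality string.
#' @export
phred_encode <- function(scores) {
  stopifnot(all(scores >= 0L), all(scores <= 60L))
  intToUtf8(as.integer(scores) + 33L)
}

#' Write reads as FASTQ (Phred+33)
#'
#' @param reads data.frame with columns `id`, `sequence`, `quality` as
#'   returned by [read_fastq()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "sequence", "quality") %in% names(reads)),
            all(nchar(reads$sequence) == nchar(reads$quality)))
  out <- character(4L * nrow(reads))
  out[c(TRUE, FALSE, FALSE, FALSE)] <- paste0("@", reads$id)
  out[c(FALSE, TRUE, FALSE, FALSE)] <- reads$sequence
  out[c(FALSE, FALSE, TRUE, FALSE)] <- "+"
  out[c(FALSE, FALSE, FALSE, TRUE)] <- reads$quality
  writeLines(out, path)
  invisible(path)
}

#' Assemble a validated CDS set
#'
#' A CDS set is the package's central container: one row per coding sequence
#' with its sequence, functional class and annotation metadata.
#'
#' @param seqs Named character vector of CDS sequences (A/C/G/T/N).
#' @param annotation Optional data.frame with columns `cds_id`, `description`,
#'   `has_signal_peptide` (see [read_annotation_tsv()]); may also carry
#'   `class_label` and `te_evidence` columns.
#' @return data.frame of class `cds_set` with columns `id`, `sequence`,
#'   `length_nt`, `description`, `class_label`, `has_signal_peptide`,
#'   `te_evidence`.
#' @export
cds_set <- function(seqs, annotation = NULL) {
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  if (any(grepl("[^ACGTN]", seqs))) {
    stop("CDS sequences restricted to A/C/G/T/N")
  }
  if (any(nchar(seqs) < 3L)) stop("CDS shorter than one codon")
  df <- data.frame(id = names(seqs), sequence = unname(seqs),
                   length_nt = nchar(seqs), description = "",
                   class_label = NA_character_, has_signal_peptide = FALSE,
                   te_evidence = FALSE, row.names = NULL,
                   stringsAsFactors = FALSE)
  if (!is.null(annotation)) {
    stopifnot(all(c("cds_id", "description", "has_signal_peptide")
                  %in% names(annotation)))
    i <- match(df$id, annotation$cds_id)
    hit <- !is.na(i)
    df$description[hit] <- annotation$description[i[hit]]
    df$has_signal_peptide[hit] <-
      as.logical(annotation$has_signal_peptide[i[hit]])
    if ("class_label" %in% names(annotation)) {
      df$class_label[hit] <- annotation$class_label[i[hit]]
    }
    if ("te_evidence" %in% names(annotation)) {
      df$te_evidence[hit] <- as.logical(annotation$te_evidence[i[hit]])
    }
  }
  class(df) <- c("cds_set", "data.frame")
  df
}

#' Read a CDS annotation table
#'
#' Tab-separated annotation with columns `cds_id`, `description`,
#' `has_signal_peptide` (0/1 or TRUE/FALSE) and optionally `class_label`,
#' `te_evidence`.
#'
#' @param path Path to the TSV file.
#' @return data.frame.
#' @export
read_annotation_tsv <- function(path) {
  ann <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("cds_id", "description", "has_signal_peptide")
                %in% names(ann)))
  ann$has_signal_peptide <- as.logical(ann$has_signal_peptide)
  if ("te_evidence" %in% names(ann)) {
    ann$te_evidence <- as.logical(ann$te_evidence)
  }
  ann
}

#' Write a CDS annotation table
#'
#' @param annotation data.frame as read by [read_annotation_tsv()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_tsv <- function(annotation, path) {
  write.table(annotation, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read SNP calls from a VCF file
#'
#' Reads the SNP subset of a VCF whose CHROM values are CDS ids: single-base
#' REF/ALT records only; indel and multi-base lines are skipped and counted.
#' Multi-allelic ALT fields are expanded to one call per alternate base.
#' Depth is taken from the INFO `DP` key and quality from QUAL.
#'
#' @param path Path to a VCF 4.x file.
#' @param cds A `cds_set` (see [cds_set()]); every CHROM must be a CDS id and
#'   every REF base must match the CDS base at POS.
#' @return data.frame of class `snp_calls` with columns `cds_id`,
#'   `pos_1based`, `ref`, `alt`, `depth`, `quality`, `effect` (initially
#'   `"unset"`); attribute `n_skipped` counts non-SNP lines.
#' @export
read_vcf_snps <- function(path, cds) {
  stopifnot(file.exists(path), inherits(cds, "cds_set"))
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    return(empty_snp_calls(n_skipped = 0L))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 8L)) {
    stop("VCF format error: line with fewer than 8 fields")
  }
  m <- matrix(unlist(lapply(f, `[`, 1:8)), ncol = 8L, byrow = TRUE)
  chrom <- m[, 1L]; pos <- as.integer(m[, 2L]); ref <- m[, 4L]
  alt <- m[, 5L]; qual <- as.numeric(m[, 6L]); info <- m[, 8L]
  alt_list <- strsplit(alt, ",", fixed = TRUE)
  is_snp <- nchar(ref) == 1L & ref %in% c("A", "C", "G", "T") &
    vapply(alt_list, function(a) any(nchar(a) == 1L & a %in% c("A", "C", "G", "T")),
           logical(1))
  n_skipped <- sum(!is_snp)
  if (n_skipped > 0L) {
    message("read_vcf_snps: skipped ", n_skipped, " non-SNP line(s)")
  }
  keep <- which(is_snp)
  if (length(keep) == 0L) {
    return(empty_snp_calls(n_skipped = n_skipped))
  }
  dp <- rep(NA_integer_, length(chrom))
  has_dp <- grepl("(^|;)DP=", info)
  dp[has_dp] <- as.integer(sub(".*(^|;)DP=([0-9]+).*", "\\2", info[has_dp]))
  alts <- lapply(alt_list[keep], function(a)
    a[nchar(a) == 1L & a %in% c("A", "C", "G", "T")])
  n_alt <- lengths(alts)
  idx <- rep(keep, n_alt)
  out <- data.frame(cds_id = chrom[idx], pos_1based = pos[idx],
                    ref = ref[idx], alt = unlist(alts),
                    depth = dp[idx], quality = qual[idx],
                    effect = "unset", row.names = NULL,
                    stringsAsFactors = FALSE)
  miss <- setdiff(unique(out$cds_id), cds$id)
  if (length(miss) > 0L) {
    stop("VCF CHROM value(s) not in CDS set: ", paste(miss, collapse = ", "))
  }
  ci <- match(out$cds_id, cds$id)
  if (any(out$pos_1based < 1L | out$pos_1based > cds$length_nt[ci])) {
    stop("VCF POS outside CDS bounds")
  }
  at <- substring(cds$sequence[ci], out$pos_1based, out$pos_1based)
  if (any(at != out$ref)) {
    bad <- which(at != out$ref)[1L]
    stop("VCF REF mismatch: '", out$cds_id[bad], "' position ",
         out$pos_1based[bad], " has CDS base ", at[bad], " but REF ",
         out$ref[bad])
  }
  if (any(out$ref == out$alt)) stop("VCF record with REF == ALT")
  attr(out, "n_skipped") <- n_skipped
  class(out) <- c("snp_calls", "data.frame")
  out
}

empty_snp_calls <- function(n_skipped = 0L) {
  out <- data.frame(cds_id = character(), pos_1based = integer(),
                    ref = character(), alt = character(), depth = integer(),
                    quality = numeric(), effect = character(),
                    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- n_skipped
  class(out) <- c("snp_calls", "data.frame")
  out
}

#' Write SNP calls as a minimal VCF
#'
#' @param snps `snp_calls` data.frame (columns `cds_id`, `pos_1based`, `ref`,
#'   `alt`, `depth`, `quality`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf_snps <- function(snps, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Raw read depth\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t%s\t.\tDP=%d",
                  snps$cds_id, snps$pos_1based, snps$ref, snps$alt,
                  format(snps$quality, trim = TRUE, scientific = FALSE),
                  snps$depth)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an aligned FASTA (equal-length rows)
#'
#' @param path Path to an aligned FASTA file.
#' @return Named character vector of equal-length sequences (gaps `-`).
#' @export
read_aligned_fasta <- function(path) {
  aln <- read_fasta(path, aligned = TRUE)
  if (length(unique(nchar(aln))) > 1L) {
    stop("aligned FASTA rows have unequal lengths")
  }
  aln
}
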