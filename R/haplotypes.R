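aln_matrix <- function(aln) {
  stopifnot(!is.null(names(aln)), length(aln) >= 1L)
  if (length(unique(nchar(aln))) > 1L) {
    stop("aligned sequences have unequal lengths")
  }
  m <- do.call(rbind, strsplit(toupper(aln), "", fixed = TRUE))
  rownames(m) <- names(aln)
  m
}

#' Collapse aligned sequences into haplotypes
#'
#' Identical sequences are grouped; labels are assigned in order of first
#' appearance, numeric (`1, 2, ...`, the rDNA ITS-2 convention) or
#' alphabetic capital letters (`A, B, ...`, the ITS-1 convention). When
#' per-specimen categories (e.g. origin or ecotope) are supplied, counts are
#' cross-tabulated per haplotype.
#'
#' @param aln Named character vector of equal-length aligned sequences.
#' @param categories Optional character vector (named by sequence id, or in
#'   `aln` order) of specimen categories.
#' @param label_style `"numeric"` or `"alpha"`.
#' @param prefix Prepended to every label (e.g. `"CH"`), default none.
#' @return List with `labels` (per input id), `haplotypes` (data.frame:
#'   `haplotype`, `sequence`, `n_members`), `members` (list of id vectors)
#'   and, when categories are given, `by_category` (haplotype x category
#'   count table).
#' @export
collapse_haplotypes <- function(aln, categories = NULL,
                                label_style = c("numeric", "alpha"),
                                prefix = "") {
  label_style <- match.arg(label_style)
  aln_matrix(aln)  # validates equal lengths and names
  first <- !duplicated(unname(aln))
  reps <- unname(aln)[first]
  idx <- match(unname(aln), reps)
  lab <- if (label_style == "numeric") as.character(seq_along(reps))
         else make.unique(rep(LETTERS, length.out = length(reps)), sep = "")
  lab <- paste0(prefix, lab)
  labels <- setNames(lab[idx], names(aln))
  members <- split(names(aln), lab[idx])[lab]
  haps <- data.frame(haplotype = lab, sequence = reps,
                     n_members = as.integer(lengths(members)),
                     stringsAsFactors = FALSE)
  out <- list(labels = labels, haplotypes = haps, members = members)
  if (!is.null(categories)) {
    if (!is.null(names(categories))) categories <- categories[names(aln)]
    stopifnot(length(categories) == length(aln))
    out$by_category <- table(haplotype = factor(lab[idx], levels = lab),
                             category = categories)
  }
  out
}

#' Composite haplotype labels
#'
#' Joins per-specimen ITS-2 (numeric) and ITS-1 (alphabetic) haplotype
#' labels into composite-haplotype names such as `CH1A`.
#'
#' @param its2_labels,its1_labels Equal-length label vectors (same specimen
#'   order or named identically).
#' @param prefix Label prefix (default `"CH"`).
#' @return Character vector of composite labels.
#' @export
composite_haplotypes <- function(its2_labels, its1_labels, prefix = "CH") {
  if (!is.null(names(its2_labels)) && !is.null(names(its1_labels))) {
    its1_labels <- its1_labels[names(its2_labels)]
  }
  stopifnot(length(its2_labels) == length(its1_labels))
  setNames(paste0(prefix, its2_labels, its1_labels), names(its2_labels))
}

#' Classify alignment columns
#'
#' Per-column states over an alignment of two or more sequences: a column is
#' *variable* iff it holds more than one distinct symbol (bases and gap;
#' ambiguity codes such as `N` are treated as missing and ignored); a
#' variable column containing a gap is *gapped*; a gap-free variable column
#' with >= 2 distinct bases is a *substitution*, which is
#' *parsimony-informative* when at least two distinct bases each occur in at
#' least two sequences, and a *singleton* otherwise. Percentages are
#' 100 * count / n_columns, rounded to 2 decimals.
#'
#' @param aln Named character vector of equal-length aligned sequences
#'   (>= 2).
#' @return List of class `alignment_summary`: counts (`n_columns`,
#'   `n_variable`, `n_substitution`, `n_parsimony_informative`,
#'   `n_singleton`, `n_gapped`), matching `pct_*` percentages, and
#'   `column_state` (per column: `invariant`, `gapped`,
#'   `parsimony_informative` or `singleton`).
#' @export
column_classify <- function(aln) {
  m <- aln_matrix(aln)
  if (nrow(m) < 2L) stop("alignment must contain at least 2 sequences")
  bases <- c("A", "C", "G", "T")
  state <- character(ncol(m))
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    col <- col[col %in% c(bases, "-")]  # ambiguity codes treated as missing
    symbols <- unique(col)
    if (length(symbols) <= 1L) {
      state[j] <- "invariant"
    } else if ("-" %in% col) {
      state[j] <- "gapped"
    } else {
      counts <- table(col)
      state[j] <- if (sum(counts >= 2L) >= 2L) "parsimony_informative"
                  else "singleton"
    }
  }
  n <- ncol(m)
  cnt <- function(s) sum(state %in% s)
  out <- list(
    n_columns = n,
    n_variable = cnt(c("gapped", "parsimony_informative", "singleton")),
    n_substitution = cnt(c("parsimony_informative", "singleton")),
    n_parsimony_informative = cnt("parsimony_informative"),
    n_singleton = cnt("singleton"),
    n_gapped = cnt("gapped"),
    column_state = state)
  stopifnot(out$n_variable == out$n_substitution + out$n_gapped,
            out$n_substitution ==
              out$n_parsimony_informative + out$n_singleton)
  for (f in c("variable", "substitution", "parsimony_informative",
              "singleton", "gapped")) {
    out[[paste0("pct_", f)]] <- site_percent(out[[paste0("n_", f)]], n)
  }
  class(out) <- "alignment_summary"
  out
}

#' Percentage of alignment columns, 2 decimals
#'
#' @param count Number of columns in the category.
#' @param n_columns Alignment length.
#' @return `round(100 * count / n_columns, 2)`.
#' @examples
#' site_percent(13, 481)  # 2.7
#' @export
site_percent <- function(count, n_columns) {
  stopifnot(n_columns >= 1)
  round(100 * count / n_columns, 2)
}

#' @export
print.alignment_summary <- function(x, ...) {
  cat(sprintf(
    "alignment_summary: %d columns; %d variable (%.2f%%) = %d substitutions (%.2f%%) [%d P-info + %d singleton] + %d gapped (%.2f%%)\n",
    x$n_columns, x$n_variable, x$pct_variable, x$n_substitution,
    x$pct_substitution, x$n_parsimony_informative, x$n_singleton,
    x$n_gapped, x$pct_gapped))
  invisible(x)
}

#' Length and base composition of a sequence
#'
#' Gaps are stripped before computing; AT% is over unambiguous bases only.
#'
#' @param sequence DNA sequence, possibly with `-` gaps.
#' @return List with `length_bp` (non-gap characters), `at_pct` and
#'   `gc_pct` (2 decimals each).
#' @examples
#' composition_stats("ACGT")  # AT 50.00
#' @export
composition_stats <- function(sequence) {
  s <- gsub("-", "", toupper(sequence), fixed = TRUE)
  if (nchar(s) == 0L) stop("zero-length sequence after gap stripping")
  n <- table(factor(strsplit(s, "", fixed = TRUE)[[1L]],
                    levels = c("A", "C", "G", "T")))
  acgt <- sum(n)
  if (acgt == 0L) stop("sequence contains no unambiguous bases")
  at <- round(100 * (n[["A"]] + n[["T"]]) / acgt, 2)
  list(length_bp = nchar(s), at_pct = at, gc_pct = round(100 - at, 2))
}

#' Polymorphic-site table relative to a reference haplotype
#'
#' Rows are haplotypes, columns the variable alignment positions (1-based);
#' a cell is `.` when identical to the reference, the base when substituted
#' and `-` for a gap.
#'
#' @param aln Named character vector of equal-length aligned sequences.
#' @param ref_id Name of the reference sequence (must be present).
#' @return List with `positions` (integer vector) and `matrix` (character
#'   matrix, rows named by haplotype, columns by position).
#' @export
polymorphic_site_table <- function(aln, ref_id) {
  m <- aln_matrix(aln)
  stopifnot(ref_id %in% rownames(m))
  cc <- column_classify(aln)
  pos <- which(cc$column_state != "invariant")
  sub <- m[, pos, drop = FALSE]
  ref <- sub[ref_id, ]
  out <- sub
  for (i in seq_len(nrow(sub))) {
    same <- sub[i, ] == ref
    out[i, same] <- "."
  }
  colnames(out) <- pos
  list(positions = pos, matrix = out, ref_id = ref_id)
}
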