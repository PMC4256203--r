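# Published summary tables of the Triatoma infestans salivary-gland
# transcriptome study, shipped as plain TSV under extdata/.  They are inputs
# for arithmetic-reproduction checks and for configuring realistic
# simulations; none of them is recomputed from raw reads here.

ref_table <- function(name) {
  read.delim(system.file("extdata", name, package = "sialoseq",
                         mustWork = TRUE), stringsAsFactors = FALSE)
}

#' Published per-library sequencing metadata
#'
#' The 10 salivary-gland libraries (nymph/adult x 5 populations) with their
#' post-clipping sequence and residue totals. Feed to
#' [library_read_stats()] to derive average read lengths and grand totals.
#'
#' @return data.frame with columns `library_id`, `stage`, `region`,
#'   `n_sequences`, `n_residues`, `median_size`, `sra_accession`.
#' @export
tinf_library_metadata <- function() {
  ref_table("tinf_library_metadata.tsv")
}

#' Published per-class CDS and read totals
#'
#' Per-class counts of assembled CDS and of reads mapped to them for the
#' T. infestans sialotranscriptome. Feed to [class_metrics_from_totals()]
#' to derive reads/CDS and the percentage columns.
#'
#' @return data.frame with columns `class`, `n_cds`, `n_reads`.
#' @export
tinf_class_totals <- function() {
  ref_table("tinf_class_totals.tsv")
}

#' Published per-class polymorphism means
#'
#' Mean synonymous and non-synonymous polymorphism rates per 100 codons
#' (with SE and the number of polymorphic CDS) by functional class. The
#' NS/S column is deliberately absent: derive it with [ns_over_s()].
#'
#' @return data.frame with columns `class`, `mean_s`, `se_s`, `mean_ns`,
#'   `se_ns`, `n_cds`.
#' @export
tinf_polymorphism_class_means <- function() {
  ref_table("tinf_polymorphism_class_means.tsv")
}
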