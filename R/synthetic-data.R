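# Synthetic sialotranscriptome designs with known ground truth: a CDS
# population with class structure, stage/region-structured read libraries,
# and planted SNPs with class-dependent S/NS rates.  Everything is
# deterministic under a fixed seed.

#' Default 2-stage x 5-region library design
#'
#' Ten libraries: nymph and adult pools for each of five geographic
#' populations, mirroring the triatomine salivary-gland study design.
#'
#' @return data.frame with columns `library_id`, `stage`, `region`.
#' @export
default_design <- function() {
  regions <- c("Arg", "BolCol", "BolNat", "Chile", "Peru")
  data.frame(
    library_id = paste0(rep(regions, each = 2L), c("-N", "-A")),
    stage = rep(c("nymph", "adult"), times = 5L),
    region = rep(regions, each = 2L),
    stringsAsFactors = FALSE)
}

default_class_proportions <- function() {
  c(Secreted = 0.20, Housekeeping = 0.65, `Transposable element` = 0.05,
    Viral = 0.004, Unknown = 0.096)
}

default_snp_rates <- function() {
  # per-100-codon rates by class: secreted-like classes NS-rich,
  # housekeeping-like classes S-rich
  list(
    s = c(Secreted = 0.938, Housekeeping = 0.555,
          `Transposable element` = 1.385, Viral = 1.66, Unknown = 1.223),
    ns = c(Secreted = 1.942, Housekeeping = 0.406,
           `Transposable element` = 2.206, Viral = 2.044, Unknown = 2.229))
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators with the defaults
#' that emulate the 10-library salivary-gland study: class proportions at
#' the published assembly's composition, a 2-stage x 5-region design,
#' 300-base reads, a small minority of CDS overexpressed >= 10-fold in one
#' stage or region, and class-dependent S/NS polymorphism rates.
#'
#' @param n_cds Number of CDS to simulate.
#' @param seed Integer seed; fixed seed implies byte-identical outputs.
#' @param class_proportions Named fractions over the five classes
#'   (must sum to 1).
#' @param design Library design data.frame (`library_id`, `stage`,
#'   `region`).
#' @param reads_per_library Reads simulated per library (default 50000).
#' @param read_length Read length in bases (default 300).
#' @param mean_protein_aa Mean protein length in amino acids for the
#'   log-normal CDS length model (default 398).
#' @param length_sdlog Log-sd of the protein-length distribution.
#' @param min_codons Minimum CDS size in codons (keeps every CDS longer
#'   than a read).
#' @param expr_sdlog Log-sd of baseline expression across CDS.
#' @param library_noise_sdlog Log-sd of per-library expression noise.
#' @param fold_overexpressed_fraction Fraction of CDS planted with a
#'   >= 10-fold stage or region effect (default 0.03).
#' @param fold_range Planted folds are drawn log-uniformly from this range.
#' @param error_rate Per-base sequencing error rate.
#' @param bad_read_fraction Fraction of reads drawn with mean quality below
#'   20 (rejected by the QC filter).
#' @param low_tail_fraction Fraction of good reads given a low-quality
#'   (<10) 3' tail that end-trimming must remove.
#' @param snp_rate_s,snp_rate_ns Named per-class synonymous /
#'   non-synonymous rates per 100 codons.
#' @param snp_low_conf_fraction Fraction of planted SNPs written with depth
#'   or quality below the 20/13 acceptance thresholds.
#' @param paralog_families Number of CDS duplicated at ~97% identity to
#'   exercise the tied-match rule (default 0).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_cds = 2000L, seed = 1L,
                       class_proportions = default_class_proportions(),
                       design = default_design(),
                       reads_per_library = 50000L, read_length = 300L,
                       mean_protein_aa = 398, length_sdlog = 0.45,
                       min_codons = 104L, expr_sdlog = 1.0,
                       library_noise_sdlog = 0.25,
                       fold_overexpressed_fraction = 0.03,
                       fold_range = c(10, 1000), error_rate = 0.002,
                       bad_read_fraction = 0.05, low_tail_fraction = 0.3,
                       snp_rate_s = default_snp_rates()$s,
                       snp_rate_ns = default_snp_rates()$ns,
                       snp_low_conf_fraction = 0.1,
                       paralog_families = 0L) {
  stopifnot(n_cds >= 1L, abs(sum(class_proportions) - 1) < 1e-9,
            all(class_proportions >= 0), all(snp_rate_s >= 0),
            all(snp_rate_ns >= 0), error_rate >= 0, error_rate < 1,
            fold_overexpressed_fraction >= 0,
            fold_overexpressed_fraction <= 1,
            length(fold_range) == 2L, fold_range[1] >= 1,
            min_codons * 3L >= read_length + 3L)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' Read a simulation configuration from a YAML file
#'
#' Keys mirror the arguments of [sim_config()]; missing keys keep their
#' defaults.
#'
#' @param path Path to a YAML key:value file.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read configuration files")
  }
  vals <- yaml::read_yaml(path)
  keep <- intersect(names(vals), names(formals(sim_config)))
  do.call(sim_config, vals[keep])
}

# draw vocabulary-backed descriptions for class members so that the
# annotation module can recover the truth labels exactly
sample_descriptions <- function(class_label, n, vocabulary) {
  if (class_label == "Unknown") {
    return(list(description = rep("", n),
                subfamily = rep("Unknown", n)))
  }
  rows <- which(vocabulary$class == class_label)
  stopifnot(length(rows) > 0L)
  pick <- rows[sample.int(length(rows), n, replace = TRUE)]
  list(description = paste0("putative ", vocabulary$keyword[pick],
                            ", full length"),
       subfamily = vocabulary$subfamily[pick])
}

#' Simulate a CDS population with known truth
#'
#' CDS lengths follow a log-normal protein-length model (default mean 398
#' aa); every CDS starts with ATG, ends with a stop codon and has no
#' internal in-frame stop. Class labels follow the configured proportions
#' and descriptions are drawn from the bundled vocabulary so the annotation
#' module can recover them. The truth table records class, planted
#' expression effect (stage or region and fold) and baseline expression.
#'
#' @param config A [sim_config()].
#' @return List with `cds` (a classified-truth `cds_set`), `truth`
#'   (data.frame) and `annotation` (the TSV-shaped annotation table).
#' @export
simulate_cds <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  vocab <- default_vocabulary()
  n <- config$n_cds
  classes <- names(config$class_proportions)
  n_by_class <- as.integer(rmultinom(1, n, config$class_proportions))
  class_label <- rep(classes, n_by_class)
  # protein length (aa, incl. start Met) log-normal, clamped below
  aa <- round(rlnorm(n, log(config$mean_protein_aa) -
                       config$length_sdlog^2 / 2, config$length_sdlog))
  aa <- pmax(aa, config$min_codons - 1L)
  codons61 <- setdiff(names(CODON_TABLE), STOP_CODONS)
  internal <- sample(codons61, sum(aa - 1L), replace = TRUE)
  grp <- rep.int(seq_len(n), aa - 1L)
  body <- vapply(split(internal, grp), paste, character(1), collapse = "")
  seqs <- paste0("ATG", body, sample(STOP_CODONS, n, replace = TRUE))
  ids <- sprintf("cds%05d", seq_len(n))
  names(seqs) <- ids
  if (config$paralog_families > 0L) {
    seqs <- add_paralogs(seqs, class_label, config)
    class_label <- attr(seqs, "class_label")
    ids <- names(seqs)
    n <- length(seqs)
  }
  desc <- character(n); subfam <- character(n)
  for (cl in unique(class_label)) {
    i <- which(class_label == cl)
    d <- sample_descriptions(cl, length(i), vocab)
    desc[i] <- d$description
    subfam[i] <- d$subfamily
  }
  has_sp <- class_label == "Secreted"
  te_ev <- class_label == "Transposable element"
  # planted expression effects: stage or region, folds log-uniform
  baseline <- rlnorm(n, 0, config$expr_sdlog)
  n_over <- round(config$fold_overexpressed_fraction * n)
  over_idx <- if (n_over > 0L) sample.int(n, n_over) else integer()
  regions <- unique(config$design$region)
  targets <- c("stage:nymph", "stage:adult", paste0("region:", regions))
  effect_target <- rep(NA_character_, n)
  effect_fold <- rep(1, n)
  if (n_over > 0L) {
    effect_target[over_idx] <- sample(targets, n_over, replace = TRUE)
    lf <- log(config$fold_range)
    effect_fold[over_idx] <- exp(runif(n_over, lf[1], lf[2]))
  }
  annotation <- data.frame(cds_id = ids, description = desc,
                           has_signal_peptide = has_sp,
                           class_label = class_label, te_evidence = te_ev,
                           stringsAsFactors = FALSE)
  cds <- cds_set(seqs, annotation)
  truth <- data.frame(cds_id = ids, class_label = class_label,
                      subfamily = subfam, length_nt = nchar(seqs),
                      baseline_expr = baseline,
                      effect_target = effect_target,
                      effect_fold = effect_fold,
                      stringsAsFactors = FALSE)
  list(cds = cds, truth = truth, annotation = annotation)
}

add_paralogs <- function(seqs, class_label, config) {
  # duplicate the first paralog_families CDS at ~97% identity, with the
  # divergence concentrated in one window (as in tandem gene families), so
  # reads from the conserved stretches exercise the tied-match rule
  nfam <- min(config$paralog_families, length(seqs))
  extra <- character(nfam)
  for (i in seq_len(nfam)) {
    s <- strsplit(seqs[[i]], "", fixed = TRUE)[[1L]]
    nmut <- max(1L, round(0.03 * length(s)))
    from <- sample.int(length(s) - 3L - nmut, 1L) + 3L  # spare ATG and stop
    for (p in seq.int(from, from + nmut - 1L)) {
      s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1L)
    }
    extra[i] <- paste(s, collapse = "")
  }
  names(extra) <- paste0(names(seqs)[seq_len(nfam)], "p")
  out <- c(seqs, extra)
  attr(out, "class_label") <- c(class_label, class_label[seq_len(nfam)])
  out
}

# expression level of each CDS in one library given planted effects
library_expression <- function(truth, stage, region, noise) {
  eff <- rep(1, nrow(truth))
  hit <- !is.na(truth$effect_target) &
    (truth$effect_target == paste0("stage:", stage) |
       truth$effect_target == paste0("region:", region))
  eff[hit] <- truth$effect_fold[hit]
  truth$baseline_expr * eff * noise
}

#' Simulate stage/region-structured read libraries
#'
#' For each library of the design, the expected read share of a CDS is
#' proportional to its length times its expression level in that library
#' (baseline x planted effect x per-library noise). Reads are sampled
#' uniformly along the CDS on either strand with per-base substitution
#' errors; qualities follow a two-component model (good reads Q35-40, a
#' fraction with low-quality Q2-9 3' tails, and a `bad_read_fraction` of
#' whole reads below mean Q20 that the QC filter must reject).
#'
#' @param cds A `cds_set` from [simulate_cds()].
#' @param truth Matching truth table.
#' @param config The [sim_config()].
#' @return Named list (one element per library) of read data.frames
#'   (`id`, `sequence`, `quality`); attributes `truth_counts` and
#'   `truth_counts_qc_pass` hold per-CDS generated counts (all reads, and
#'   reads not drawn from the bad-quality component).
#' @export
simulate_reads <- function(cds, truth, config) {
  stopifnot(inherits(cds, "cds_set"), nrow(cds) == nrow(truth))
  L <- config$read_length
  if (L > min(cds$length_nt)) {
    stop("read_length exceeds the shortest CDS length")
  }
  set.seed(config$seed + 1L)
  design <- config$design
  libs <- vector("list", nrow(design))
  names(libs) <- design$library_id
  truth_counts <- matrix(0L, nrow(cds), nrow(design),
                         dimnames = list(cds$id, design$library_id))
  qc_counts <- truth_counts
  qchar <- function(q) intToUtf8(q + 33L)
  for (li in seq_len(nrow(design))) {
    noise <- rlnorm(nrow(cds), 0, config$library_noise_sdlog)
    expr <- library_expression(truth, design$stage[li], design$region[li],
                               noise)
    w <- expr * cds$length_nt
    counts <- as.integer(rmultinom(1, config$reads_per_library, w / sum(w)))
    truth_counts[, li] <- counts
    src <- rep.int(seq_len(nrow(cds)), counts)
    nread <- length(src)
    start <- floor(runif(nread) * (cds$length_nt[src] - L + 1)) + 1L
    seqs <- substring(cds$sequence[src], start, start + L - 1L)
    minus <- runif(nread) < 0.5
    seqs[minus] <- revcomp(seqs[minus])
    # substitution errors
    nerr <- rbinom(nread, L, config$error_rate)
    has <- which(nerr > 0L)
    if (length(has) > 0L) {
      ridx <- rep.int(has, nerr[has])
      pos <- sample.int(L, length(ridx), replace = TRUE)
      cur <- substring(seqs[ridx], pos, pos)
      cur[!cur %in% c("A", "C", "G", "T")] <- "A"
      # substitute by rotating 1-3 places in ACGT order (never the same base)
      shift <- sample.int(3L, length(ridx), replace = TRUE)
      rot <- matrix(c("C", "G", "T", "A",
                      "G", "T", "A", "C",
                      "T", "A", "C", "G"), nrow = 3L, byrow = TRUE)
      alt <- rot[cbind(shift, match(cur, c("A", "C", "G", "T")))]
      seqs <- .apply_substitutions_cpp(seqs, ridx, pos, alt)
    }
    # two-component qualities
    bad <- runif(nread) < config$bad_read_fraction
    core_q <- sample(35:40, nread, replace = TRUE)
    core_q[bad] <- sample(12:19, sum(bad), replace = TRUE)
    tail_len <- integer(nread)
    tailed <- !bad & runif(nread) < config$low_tail_fraction
    tail_len[tailed] <- pmin(rpois(sum(tailed), 15) + 1L, L - 30L)
    tail_q <- sample(2:9, nread, replace = TRUE)
    quals <- strrep(vapply(core_q, qchar, character(1)), L - tail_len)
    tl <- which(tail_len > 0L)
    quals[tl] <- paste0(quals[tl],
                        strrep(vapply(tail_q[tl], qchar, character(1)),
                               tail_len[tl]))
    qc <- tabulate(src[!bad], nbins = nrow(cds))
    qc_counts[, li] <- qc
    libs[[li]] <- data.frame(
      id = sprintf("%s|%06d|%s", design$library_id[li], seq_len(nread),
                   cds$id[src]),
      sequence = seqs, quality = quals, row.names = NULL,
      stringsAsFactors = FALSE)
  }
  attr(libs, "truth_counts") <- truth_counts
  attr(libs, "truth_counts_qc_pass") <- qc_counts
  libs
}

# single-base changes of every codon, split by effect under the standard
# genetic code; computed once at first use
codon_change_table <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    bases <- c("A", "C", "G", "T")
    tab <- list()
    for (codon in names(CODON_TABLE)) {
      s <- list(syn = NULL, nonsyn = NULL)
      for (p in 1:3) {
        for (b in setdiff(bases, substr(codon, p, p))) {
          alt <- codon
          substr(alt, p, p) <- b
          kind <- if (CODON_TABLE[[codon]] == CODON_TABLE[[alt]]) "syn"
                  else "nonsyn"
          s[[kind]] <- rbind(s[[kind]], data.frame(pos = p, alt = b,
                                                   stringsAsFactors = FALSE))
        }
      }
      tab[[codon]] <- s
    }
    cache <<- tab
    tab
  }
})

#' Plant SNPs with class-dependent S/NS rates
#'
#' For each CDS, synonymous and non-synonymous changes are planted at the
#' class's configured rates per 100 codons (Poisson counts); each planted
#' change is chosen from the codon's single-base substitutions whose effect
#' is verified against the genetic code at generation time. Depth and
#' quality are drawn with `snp_low_conf_fraction` of calls below the 20/13
#' acceptance thresholds to exercise filtering.
#'
#' @param cds A `cds_set` with truth class labels (from [simulate_cds()]).
#' @param config The [sim_config()].
#' @param rate_scale Multiplier applied to both rate sets (useful for
#'   simulating libraries with different polymorphism levels).
#' @return A `snp_calls` data.frame with extra truth columns
#'   `effect_truth` and `pass_filter`.
#' @export
simulate_snps <- function(cds, config, rate_scale = 1) {
  stopifnot(inherits(cds, "cds_set"))
  if (anyNA(cds$class_label)) stop("CDS set has unassigned class labels")
  miss <- setdiff(unique(cds$class_label), names(config$snp_rate_s))
  if (length(miss) > 0L) {
    stop("no SNP rates configured for class(es): ",
         paste(miss, collapse = ", "))
  }
  set.seed(config$seed + 2L)
  changes <- codon_change_table()
  n_codons <- cds$length_nt %/% 3L
  lam_s <- rate_scale * config$snp_rate_s[cds$class_label] * n_codons / 100
  lam_ns <- rate_scale * config$snp_rate_ns[cds$class_label] * n_codons / 100
  n_s <- rpois(nrow(cds), lam_s)
  n_ns <- rpois(nrow(cds), lam_ns)
  rows <- vector("list", nrow(cds))
  for (i in seq_len(nrow(cds))) {
    tot <- n_s[i] + n_ns[i]
    if (tot == 0L) next
    starts <- seq.int(1L, cds$length_nt[i], by = 3L)
    codons <- substring(cds$sequence[i], starts, starts + 2L)
    kinds <- rep(c("syn", "nonsyn"), c(n_s[i], n_ns[i]))
    pos <- integer(tot); ref <- character(tot); alt <- character(tot)
    ok <- logical(tot)
    for (j in seq_len(tot)) {
      for (try in 1:50) {
        ci <- sample.int(length(codons), 1L)
        opts <- changes[[codons[ci]]][[kinds[j]]]
        if (is.null(opts)) next
        o <- opts[sample.int(nrow(opts), 1L), ]
        pos[j] <- (ci - 1L) * 3L + o$pos
        ref[j] <- substr(codons[ci], o$pos, o$pos)
        alt[j] <- o$alt
        ok[j] <- TRUE
        break
      }
    }
    keep <- ok & !duplicated(pos)
    if (!any(keep)) next
    rows[[i]] <- data.frame(
      cds_id = cds$id[i], pos_1based = pos[keep], ref = ref[keep],
      alt = alt[keep],
      effect_truth = ifelse(kinds[keep] == "syn", "synonymous",
                            "nonsynonymous"),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(cds_id = character(), pos_1based = integer(),
                      ref = character(), alt = character(),
                      effect_truth = character(), stringsAsFactors = FALSE)
  }
  n <- nrow(out)
  low <- runif(n) < config$snp_low_conf_fraction
  depth <- 20L + rpois(n, 30)
  qual <- round(runif(n, 20, 60), 1)
  # low-confidence calls fail depth or quality (or both), chosen at random
  which_fail <- sample(1:3, n, replace = TRUE)
  depth[low & which_fail != 2L] <- sample(1:19, sum(low & which_fail != 2L),
                                          replace = TRUE)
  qual[low & which_fail != 1L] <- round(runif(sum(low & which_fail != 1L),
                                              0, 12.9), 1)
  out$depth <- depth
  out$quality <- qual
  out$effect <- "unset"
  out$pass_filter <- !low
  out <- out[order(out$cds_id, out$pos_1based),
             c("cds_id", "pos_1based", "ref", "alt", "depth", "quality",
               "effect", "effect_truth", "pass_filter")]
  rownames(out) <- NULL
  class(out) <- c("snp_calls", "data.frame")
  out
}
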