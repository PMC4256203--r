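#' Run the full pipeline on a synthetic design
#'
#' Simulates a CDS population and its read libraries, counts every library
#' onto the CDS with the seed-and-extend mapper, builds the stage and
#' region contrasts, calls >= `fold` overexpression, and scores recovery of
#' the planted effects. Separately plants SNPs, runs the
#' filter/classify/rate chain, and scores recovery of the configured
#' class-level NS/S ratios.
#'
#' @param config A [sim_config()].
#' @param fold,alpha,mtc Overexpression-call parameters (see
#'   [call_overexpression()]).
#' @return List with the simulated objects (`cds`, `truth`), per-library
#'   `counts`, `calls` per contrast, `de_recovery`
#'   (sensitivity/FDR/TP/FP/FN), `per_class` polymorphism table and
#'   `ns_s_recovery` (observed vs configured NS/S per class).
#' @export
run_synthetic_pipeline <- function(config, fold = 10, alpha = 0.05,
                                   mtc = "bonferroni") {
  sim <- simulate_cds(config)
  reads <- simulate_reads(sim$cds, sim$truth, config)
  index <- build_index(sim$cds)
  libs <- lapply(names(reads), function(lib)
    count_library(reads[[lib]], index, library_id = lib))
  contrasts <- build_contrasts(libs, config$design)
  calls <- lapply(contrasts, call_overexpression, fold = fold,
                  alpha = alpha, mtc = mtc)
  der <- de_recovery(calls, sim$truth, fold = fold)
  snps <- simulate_snps(sim$cds, config)
  kept <- classify_snps(filter_snps(snps), sim$cds)
  per_cds <- rates_per_cds(kept, sim$cds)
  per_class <- rates_per_class(per_cds)
  nsr <- ns_s_recovery(per_class, config)
  list(cds = sim$cds, truth = sim$truth, counts = libs, calls = calls,
       de_recovery = der, snps = kept, per_class = per_class,
       ns_s_recovery = nsr)
}

#' Score recovery of planted overexpression effects
#'
#' A planted effect is recovered when its CDS is called in the matching
#' contrast with the matching direction (stage:nymph -> `over_in_1` in the
#' stage contrast; region:X -> `over_in_1` in contrast `region:X`). A call
#' counts as a false positive only when no planted effect on that CDS
#' implies it; a strong planted region effect legitimately surfaces as
#' `over_in_2` in the other regions' contrasts (the pooled "others" side
#' carries it), so such induced calls are not errors of the method.
#'
#' @param calls Named list of called `de_comparison`s from
#'   [build_contrasts()] + [call_overexpression()].
#' @param truth Truth table from [simulate_cds()].
#' @param fold The fold threshold used for the calls.
#' @return List with `sensitivity`, `fdr`, `tp`, `fp`, `fn`, `n_planted`
#'   and the per-CDS `detected` table.
#' @export
de_recovery <- function(calls, truth, fold = 10) {
  planted <- truth[!is.na(truth$effect_target) &
                     truth$effect_fold >= fold, , drop = FALSE]
  expected_call <- function(target, contrast) {
    # direction a planted effect implies in a given contrast, or NA
    if (startsWith(target, "stage:")) {
      if (contrast != "stage") return(NA_character_)
      return(if (target == "stage:nymph") "over_in_1" else "over_in_2")
    }
    reg <- sub("^region:", "", target)
    if (contrast == paste0("region:", reg)) return("over_in_1")
    if (startsWith(contrast, "region:")) return("over_in_2")
    NA_character_
  }
  tp <- 0L; fn <- 0L
  detected <- logical(nrow(planted))
  for (i in seq_len(nrow(planted))) {
    tgt <- planted$effect_target[i]
    contrast <- if (startsWith(tgt, "stage:")) "stage" else tgt
    want <- expected_call(tgt, contrast)
    cc <- calls[[contrast]]
    got <- as.character(cc$call[cc$cds_id == planted$cds_id[i]])
    detected[i] <- length(got) == 1L && got == want
  }
  tp <- sum(detected); fn <- sum(!detected)
  fp <- 0L
  for (contrast in names(calls)) {
    cc <- calls[[contrast]]
    called <- cc[cc$call != "ns", , drop = FALSE]
    for (j in seq_len(nrow(called))) {
      tgts <- planted$effect_target[planted$cds_id == called$cds_id[j]]
      ok <- any(vapply(tgts, function(t) {
        e <- expected_call(t, contrast)
        !is.na(e) && e == as.character(called$call[j])
      }, logical(1)))
      if (!ok) fp <- fp + 1L
    }
  }
  n_called <- tp + fp
  list(sensitivity = if (nrow(planted) > 0L) tp / nrow(planted) else NA_real_,
       fdr = if (n_called > 0L) fp / n_called else 0,
       tp = tp, fp = fp, fn = fn, n_planted = nrow(planted),
       detected = data.frame(cds_id = planted$cds_id,
                             effect_target = planted$effect_target,
                             effect_fold = planted$effect_fold,
                             detected = detected,
                             stringsAsFactors = FALSE))
}

#' Compare recovered class NS/S ratios with the configured rates
#'
#' @param per_class Output of [rates_per_class()] on the recovered SNPs.
#' @param config The [sim_config()] whose `snp_rate_s`/`snp_rate_ns` were
#'   planted.
#' @return data.frame with observed and configured NS/S per class and the
#'   relative error.
#' @export
ns_s_recovery <- function(per_class, config) {
  cfg_ratio <- config$snp_rate_ns / config$snp_rate_s
  i <- match(per_class$class, names(cfg_ratio))
  out <- data.frame(class = per_class$class,
                    ns_over_s = per_class$ns_over_s,
                    configured = unname(cfg_ratio[i]),
                    n_cds = per_class$n_cds,
                    stringsAsFactors = FALSE)
  out$rel_error <- abs(out$ns_over_s - out$configured) / out$configured
  out
}
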