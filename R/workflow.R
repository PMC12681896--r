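#' Quality-control thresholds
#'
#' Diagnostic exclusion rules for a single biopsy: minimum tumor-cell
#' percentage (default 20%) and minimum total sWGS read count
#' (default 500,000); both comparisons are strict.
#'
#' @param min_tumor_pct minimum tumor percentage (0-100).
#' @param min_reads minimum read count.
#' @return list of class `QCThresholds`.
#' @export
qc_thresholds <- function(min_tumor_pct = 20, min_reads = 500000) {
  if (min_tumor_pct < 0 || min_tumor_pct > 100) validation_error("min_tumor_pct outside [0, 100]")
  if (min_reads < 0) validation_error("min_reads must be >= 0")
  structure(list(min_tumor_pct = min_tumor_pct, min_reads = min_reads),
            class = "QCThresholds")
}

#' QC gate for one sample
#'
#' Fails when the tumor percentage or read count falls strictly below its
#' threshold; a missing value fails with reason "unknown". All violated
#' rules are reported.
#'
#' @param sample list with `tumor_pct` and `total_reads` (either may be
#'   `NA`/`NULL`).
#' @param qc a [qc_thresholds()].
#' @return list with `pass` (logical) and `reasons` (character).
#' @export
qc_gate <- function(sample, qc = qc_thresholds()) {
  reasons <- character()
  tp <- sample$tumor_pct
  rd <- sample$total_reads
  if (is.null(tp) || is.na(tp)) {
    reasons <- c(reasons, "tumor percentage unknown")
  } else if (tp < qc$min_tumor_pct) {
    reasons <- c(reasons, sprintf("tumor percentage %g%% < %g%%", tp, qc$min_tumor_pct))
  }
  if (is.null(rd) || is.na(rd)) {
    reasons <- c(reasons, "read count unknown")
  } else if (rd < qc$min_reads) {
    reasons <- c(reasons, sprintf("read count %g < %g", rd, qc$min_reads))
  }
  list(pass = length(reasons) == 0, reasons = reasons)
}

#' Assemble a sample pair for classification
#'
#' @param pair_id identifier.
#' @param tumor_a,tumor_b lists with `variants` (a [variant_records()]
#'   data.frame), `profile` (a raw-count [binned_profile()], may be `NULL`
#'   when only the mutation tier is wanted), and optional `tumor_pct`,
#'   `total_reads`, `sample_id`.
#' @param histology shared histology label (one per pair; reference
#'   frequencies are looked up by it).
#' @param truth optional gold-standard label.
#' @param timing optional "synchronous"/"metachronous".
#' @return list of class `SamplePair`.
#' @export
sample_pair <- function(pair_id, tumor_a, tumor_b, histology,
                        truth = NA_character_, timing = NA_character_) {
  structure(list(pair_id = pair_id, tumor_a = tumor_a, tumor_b = tumor_b,
                 histology = histology, truth = truth, timing = timing),
            class = "SamplePair")
}

as_sample_pair <- function(p) {
  if (inherits(p, "SamplePair")) return(p)
  if (inherits(p, "SimulatedPair")) {
    return(sample_pair(p$pair_id, p$tumor_a, p$tumor_b, p$histology,
                       truth = p$truth, timing = p$timing))
  }
  validation_error("expected a SamplePair or SimulatedPair")
}

#' Compare two tumors' CNA profiles with the two-metric classifier
#'
#' Runs the full CNA tier for one pair: median normalization, CBS-style
#' segmentation, arm-state calling, then PCC (bin level) and LLR (arm level
#' against the reference frequencies) and the predefined classification.
#'
#' @param pair a [sample_pair()] (or a pair from [simulate_cohort()]) whose
#'   tumors carry raw-count [binned_profile()]s.
#' @param freqs a [reference_frequencies()] table covering the pair's
#'   histology.
#' @param config a [run_config()]; `config$layout` may hold a prebuilt
#'   [genome_layout()] matching the profiles.
#' @return list of class `CnaComparison`: `pcc`, `llr`, `n_bins`, `n_arms`,
#'   `cna_class`.
#' @export
cna_comparison <- function(pair, freqs, config = run_config()) {
  pair <- as_sample_pair(pair)
  prep <- function(t) {
    prof <- normalize_log2(t$profile)
    seg <- segment_cbs(prof, alpha = config$alpha, min_width = config$min_width,
                       n_perm = config$n_perm)
    arms <- call_arm_states(seg, layout_for(pair, config),
                            gain_thr = config$gain_thr, loss_thr = config$loss_thr,
                            min_coverage = config$min_coverage)
    list(prof = prof, arms = arms)
  }
  a <- prep(pair$tumor_a)
  b <- prep(pair$tumor_b)
  pcc_val <- pcc(a$prof, b$prof, min_bins = config$min_bins)
  llr_val <- llr(a$arms, b$arms, freqs, floor = config$llr_floor,
                 histology = pair$histology)
  structure(list(pcc = as.numeric(pcc_val), llr = as.numeric(llr_val),
                 n_bins = attr(pcc_val, "n_bins"), n_arms = attr(llr_val, "n_arms"),
                 cna_class = classify_cna(as.numeric(pcc_val), as.numeric(llr_val),
                                          config$thresholds)),
            class = "CnaComparison")
}

layout_for <- function(pair, config) {
  lay <- config$layout
  if (is.null(lay)) lay <- genome_layout(pair$tumor_a$profile$bin_size,
                                         arm_table = config$arm_table)
  lay
}

#' Two-tier clonality classification of one tumor pair
#'
#' The mutation tier (panel restriction + adapted IASLC tree) is computed
#' first; a definitive call (clonal / nonclonal) is final and the CNA
#' metrics are never computed. Ambiguous calls (probable nonclonal /
#' inconclusive) are passed to the CNA tier: PCC on normalized bin-level
#' log2 ratios, LLR on segmentation-derived arm states against the
#' reference frequencies, classified with the predefined cutoffs. A pair
#' whose profiles cannot support the CNA tier ends inconclusive with an
#' error annotation.
#'
#' @param pair a [sample_pair()] (or a pair from [simulate_cohort()]).
#' @param freqs a [reference_frequencies()] table covering the pair's
#'   histology.
#' @param panel a [panel_definition()].
#' @param config a [run_config()]; `config$layout` may hold a prebuilt
#'   [genome_layout()] matching the profiles.
#' @param apply_germline_filter run [filter_germline()] on both variant sets
#'   first (default FALSE; simulated calls are already somatic).
#' @return list of class `FinalCall`: `pair_id`, `mutation_class`,
#'   `cna_class` (or "not_evaluated"), `final_class`, `resolved_by`
#'   ("mutation", "cna" or "unresolved"), metric values, shared counts,
#'   rationale and error annotation.
#' @export
classify_pair <- function(pair, freqs, panel = panel_definition(),
                          config = run_config(), apply_germline_filter = FALSE) {
  pair <- as_sample_pair(pair)
  va <- pair$tumor_a$variants
  vb <- pair$tumor_b$variants
  if (apply_germline_filter) {
    va <- filter_germline(va)
    vb <- filter_germline(vb)
  }
  mut <- classify_mutational(suppressWarnings(restrict_to_panel(va, panel)),
                             suppressWarnings(restrict_to_panel(vb, panel)),
                             panel)
  out <- list(pair_id = pair$pair_id, mutation_class = mut$class,
              shared_panel = mut$shared_count, rationale = mut$rationale,
              cna_class = "not_evaluated", pcc = NA_real_, llr = NA_real_,
              n_bins = NA_integer_, n_arms = NA_integer_,
              error = NA_character_)
  if (mut$class %in% c("clonal", "nonclonal")) {
    out$final_class <- mut$class
    out$resolved_by <- "mutation"
    return(structure(out, class = "FinalCall"))
  }
  res <- tryCatch(cna_comparison(pair, freqs, config),
                  clonalpair_error = function(e) e)
  if (inherits(res, "error")) {
    out$final_class <- "inconclusive"
    out$resolved_by <- "unresolved"
    out$error <- conditionMessage(res)
    return(structure(out, class = "FinalCall"))
  }
  out[c("pcc", "llr", "n_bins", "n_arms", "cna_class")] <-
    res[c("pcc", "llr", "n_bins", "n_arms", "cna_class")]
  if (res$cna_class %in% c("clonal", "nonclonal")) {
    out$final_class <- res$cna_class
    out$resolved_by <- "cna"
  } else {
    out$final_class <- "inconclusive"
    out$resolved_by <- "unresolved"
  }
  structure(out, class = "FinalCall")
}

#' @export
print.FinalCall <- function(x, ...) {
  cat(sprintf("%s: %s (mutation: %s, CNA: %s, resolved by %s)\n", x$pair_id,
              x$final_class, x$mutation_class, x$cna_class, x$resolved_by))
  if (!is.na(x$pcc)) cat(sprintf("  PCC %.3f over %d bins; LLR %.3f over %d arms\n",
                                 x$pcc, x$n_bins, x$llr, x$n_arms))
  invisible(x)
}

#' Run the two-tier workflow over a cohort
#'
#' Applies the QC gate to both tumors of every pair, classifies the passing
#' pairs in input order, and reports excluded pairs with their reasons.
#'
#' @param pairs list of [sample_pair()]s or a [simulate_cohort()] result.
#' @param freqs a [reference_frequencies()] table covering all histologies
#'   present (for a simulated cohort, defaults to its generating tables).
#' @param panel a [panel_definition()].
#' @param config a [run_config()].
#' @param qc a [qc_thresholds()], or `NULL` to disable gating.
#' @return list with `calls` (list of `FinalCall`) and `excluded`
#'   (data.frame of pair id and reasons).
#' @export
run_cohort <- function(pairs, freqs = NULL, panel = panel_definition(),
                       config = run_config(), qc = qc_thresholds()) {
  if (is.null(freqs) && inherits(pairs, "SimulatedCohort")) {
    fl <- attr(pairs, "freqs")
    freqs <- do.call(rbind, unname(fl))
    attr(freqs, "eps") <- attr(fl[[1]], "eps")
    class(freqs) <- class(fl[[1]])
    if (is.null(config$layout)) config$layout <- attr(pairs, "config")$layout
  }
  calls <- list()
  excluded <- data.frame(pair_id = character(), reasons = character(),
                         stringsAsFactors = FALSE)
  for (p in pairs) {
    sp <- as_sample_pair(p)
    if (!is.null(qc)) {
      ga <- qc_gate(sp$tumor_a, qc)
      gb <- qc_gate(sp$tumor_b, qc)
      if (!ga$pass || !gb$pass) {
        excluded <- rbind(excluded, data.frame(
          pair_id = sp$pair_id,
          reasons = paste(c(ga$reasons, gb$reasons), collapse = "; "),
          stringsAsFactors = FALSE))
        next
      }
    }
    calls[[length(calls) + 1]] <- classify_pair(sp, freqs, panel, config)
  }
  list(calls = calls, excluded = excluded)
}

ambiguous_classes <- c("probable_nonclonal", "inconclusive")

#' Cross-tabulate calls against gold-standard truth
#'
#' Counts of final class by truth, per-truth concordance, the mutation
#' tier's ambiguity rate, and the CNA tier's performance among ambiguous
#' pairs (how many received a definitive call, and how many of those were
#' correct).
#'
#' @param calls list of `FinalCall`s.
#' @param truths character vector of truth labels ("clonal"/"nonclonal"),
#'   one per call.
#' @return list of class `CohortEvaluation`: `crosstab`,
#'   `concordance` (per truth class), `mutation_ambiguity_rate`,
#'   `cna_definitive_rate`, `cna_correct_rate` (among ambiguous pairs),
#'   `n`.
#' @export
crosstab_vs_truth <- function(calls, truths) {
  if (length(calls) != length(truths)) validation_error("calls/truths length mismatch")
  if (length(calls) == 0) validation_error("empty call list")
  final <- vapply(calls, function(x) x$final_class, character(1))
  mut <- vapply(calls, function(x) x$mutation_class, character(1))
  cna <- vapply(calls, function(x) x$cna_class, character(1))
  lv_final <- c("clonal", "nonclonal", "inconclusive")
  ct <- table(factor(final, levels = lv_final),
              factor(truths, levels = unique(truths)))
  conc <- vapply(unique(truths), function(tr) {
    mean(final[truths == tr] == tr)
  }, numeric(1))
  amb <- mut %in% ambiguous_classes
  cna_def <- amb & cna %in% c("clonal", "nonclonal")
  structure(list(
    crosstab = ct,
    concordance = conc,
    mutation_ambiguity_rate = mean(amb),
    cna_definitive_rate = if (any(amb)) mean(cna_def[amb]) else NA_real_,
    cna_correct_rate = if (any(amb)) mean((cna_def & cna == truths)[amb]) else NA_real_,
    n = length(calls)), class = "CohortEvaluation")
}

#' @export
print.CohortEvaluation <- function(x, ...) {
  cat(sprintf("Cohort of %d pairs; mutation tier ambiguous in %.0f%%\n",
              x$n, 100 * x$mutation_ambiguity_rate))
  print(x$crosstab)
  cat("Per-truth concordance:",
      paste(sprintf("%s %.2f", names(x$concordance), x$concordance), collapse = ", "),
      "\n")
  if (!is.na(x$cna_definitive_rate)) {
    cat(sprintf("Among ambiguous pairs: %.0f%% definitive by CNA, %.0f%% definitive and correct\n",
                100 * x$cna_definitive_rate, 100 * x$cna_correct_rate))
  }
  invisible(x)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact p-value by summing hypergeometric probabilities no larger than that
#' of the observed table (fixed margins). All four margins must be positive.
#'
#' @param m 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(m) {
  m <- as.matrix(m)
  stopifnot(all(dim(m) == c(2, 2)))
  if (any(m < 0)) validation_error("negative counts")
  if (any(m != round(m))) validation_error("counts must be integers")
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1]); c2 <- sum(m[, 2])
  if (min(r1, r2, c1, c2) <= 0) validation_error("all margins must be > 0")
  support <- max(0, c1 - r2):min(r1, c1)
  dens <- stats::dhyper(support, r1, r2, c1)
  obs <- stats::dhyper(m[1, 1], r1, r2, c1)
  sum(dens[dens <= obs * (1 + 1e-7)])
}
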