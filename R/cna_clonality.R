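#' Classifier thresholds for the two-metric CNA classifier
#'
#' Predefined diagnostic cutoffs: clonal requires PCC > 0.54 and LLR > 0;
#' nonclonal requires PCC < 0.45 and LLR < -5; everything else (gray area
#' and metric-conflict quadrants) is inconclusive.
#'
#' @param pcc_clonal,pcc_nonclonal,llr_clonal,llr_nonclonal numeric cutoffs.
#' @return list of class `ClassifierThresholds`.
#' @export
classifier_thresholds <- function(pcc_clonal = 0.54, pcc_nonclonal = 0.45,
                                  llr_clonal = 0, llr_nonclonal = -5) {
  if (!(pcc_nonclonal < pcc_clonal)) validation_error("pcc_nonclonal must be < pcc_clonal")
  if (!(llr_nonclonal < llr_clonal)) validation_error("llr_nonclonal must be < llr_clonal")
  structure(list(pcc_clonal = pcc_clonal, pcc_nonclonal = pcc_nonclonal,
                 llr_clonal = llr_clonal, llr_nonclonal = llr_nonclonal),
            class = "ClassifierThresholds")
}

#' Estimate reference arm-aberration frequencies from a cohort
#'
#' `p_gain(arm)` is the fraction of cohort profiles whose arm state is +1,
#' with missing arms excluded from numerator and denominator (`p_loss`
#' analogous). Estimates are then clipped into `[eps, 1 - eps]`, with
#' proportional renormalization only when `p_gain + p_loss` exceeds
#' `1 - eps`.
#'
#' @param cohort list of arm-state vectors (see [call_arm_states()]).
#' @param histology histology label stored on the result (e.g. "LUAD").
#' @param eps clip bound, default 0.01.
#' @return A [reference_frequencies()] table.
#' @export
compute_arm_frequencies <- function(cohort, histology, eps = 0.01) {
  if (length(cohort) == 0) validation_error("empty cohort")
  arms <- cohort[[1]]$arm
  for (v in cohort) {
    if (!identical(v$arm, arms)) validation_error("cohort arm-state vectors on different arm sets")
  }
  states <- vapply(cohort, function(v) v$state, numeric(length(arms)))
  states <- matrix(states, nrow = length(arms))
  n_obs <- rowSums(!is.na(states))
  p_gain <- rowSums(states == 1, na.rm = TRUE) / pmax(n_obs, 1)
  p_loss <- rowSums(states == -1, na.rm = TRUE) / pmax(n_obs, 1)
  p_gain[n_obs == 0] <- NA
  p_loss[n_obs == 0] <- NA
  freq <- reference_frequencies(
    data.frame(arm = arms, histology = histology, p_gain = p_gain,
               p_loss = p_loss, stringsAsFactors = FALSE), eps = eps)
  clip_reference_frequencies(freq, eps)
}

#' Clip reference frequencies away from 0 and 1
#'
#' Zero-probability arms would dominate the likelihood ratio; clipping into
#' `[eps, 1 - eps]` (renormalizing gain/loss proportionally only when their
#' clipped sum exceeds 1, with the `eps` floors preserved) keeps every
#' aberrant arm state possible under the null.
#'
#' @param freq a [reference_frequencies()] table.
#' @param eps clip bound; default the table's own `eps` attribute.
#' @return Clipped [reference_frequencies()].
#' @export
clip_reference_frequencies <- function(freq, eps = attr(freq, "eps")) {
  if (is.null(eps)) eps <- 0.01
  g <- pmin(pmax(freq$p_gain, eps), 1 - eps)
  l <- pmin(pmax(freq$p_loss, eps), 1 - eps)
  s <- g + l
  over <- !is.na(s) & s > 1
  g[over] <- g[over] / s[over]
  l[over] <- l[over] / s[over]
  # rescaling may push one side back under the floor; restore it from the other
  fix <- over & l < eps
  g[fix] <- g[fix] - (eps - l[fix]); l[fix] <- eps
  fix <- over & g < eps
  l[fix] <- l[fix] - (eps - g[fix]); g[fix] <- eps
  freq$p_gain <- g
  freq$p_loss <- l
  attr(freq, "eps") <- eps
  freq
}

#' Pearson correlation of two binned profiles
#'
#' Sample Pearson correlation of paired bin-level log2 ratios over the bins
#' usable (and finite) in both profiles. This is the bin-level metric of
#' the two-metric classifier; arm states are not involved.
#'
#' @param profile_a,profile_b [binned_profile()]s on the same layout.
#' @param min_bins minimum shared usable bins (default 500).
#' @return Correlation in `[-1, 1]`, with attribute `n_bins`.
#' @export
pcc <- function(profile_a, profile_b, min_bins = 500) {
  a <- profile_a$bins
  b <- profile_b$bins
  if (nrow(a) != nrow(b) || !all(a$chrom == b$chrom & a$start == b$start)) {
    validation_error("profiles are not on the same bin layout")
  }
  keep <- a$use & b$use & is.finite(a$log2ratio) & is.finite(b$log2ratio)
  n <- sum(keep)
  if (n < min_bins) {
    insufficient_data_error(sprintf("only %d shared usable bins (need >= %d)", n, min_bins))
  }
  x <- a$log2ratio[keep]
  y <- b$log2ratio[keep]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    undefined_metric_error("zero variance in at least one profile")
  }
  structure(stats::cor(x, y), n_bins = n)
}

#' Arm-level log-likelihood ratio for clonality
#'
#' Compares the likelihood of the two tumors' arm states (loss/neutral/gain)
#' under a shared-clonal-event model against independence, on a log10 scale.
#' Under independence each arm k contributes the product of its marginal
#' state probabilities `P_k(s_a)·P_k(s_b)` taken from the reference
#' frequencies. Under the clonal model one latent arm j (uniform prior over
#' the K informative arms) carries a truncal event shared by both tumors:
#' that arm contributes `P_j(s)` once, and only if its states are
#' concordantly aberrant; all other arms stay independent. The ratio
#' simplifies to `log10( (1/K) * sum over concordant aberrant arms of
#' 1/P_j(s_j) )`. Arms missing in either tumor are dropped; `floor` is
#' returned when no arm is concordantly aberrant (clonal likelihood zero).
#'
#' @param arms_a,arms_b arm-state vectors (see [call_arm_states()]).
#' @param freqs a [reference_frequencies()] table (single histology, or use
#'   `histology` to select one); clipped via [clip_reference_frequencies()].
#' @param floor value returned when the clonal likelihood is 0 (default -50).
#' @param histology optional histology selector when `freqs` has several.
#' @return LLR (log10), with attribute `n_arms` = number of informative arms.
#' @export
llr <- function(arms_a, arms_b, freqs, floor = -50, histology = NULL) {
  if (!is.null(histology)) freqs <- freqs[freqs$histology == histology, ]
  freqs <- clip_reference_frequencies(freqs)
  m <- merge(merge(data.frame(arm = arms_a$arm, sa = arms_a$state),
                   data.frame(arm = arms_b$arm, sb = arms_b$state), by = "arm"),
             freqs[, c("arm", "p_gain", "p_loss")], by = "arm")
  m <- m[!is.na(m$sa) & !is.na(m$sb) & !is.na(m$p_gain) & !is.na(m$p_loss), ]
  K <- nrow(m)
  if (K == 0) insufficient_data_error("zero informative arms")
  conc <- m$sa == m$sb & m$sa != 0
  p_state <- ifelse(m$sa == 1, m$p_gain, m$p_loss)
  s <- sum(ifelse(conc, 1 / p_state, 0))
  out <- if (s == 0) floor else log10(s / K)
  structure(out, n_arms = K)
}

#' Classify a tumor pair from its PCC and LLR values
#'
#' Clonal iff PCC exceeds the clonal cutoff AND LLR exceeds its clonal
#' cutoff; nonclonal iff both metrics fall below their nonclonal cutoffs;
#' every other combination (gray area and conflicting metrics) is
#' inconclusive.
#'
#' @param pcc_value,llr_value metric values; `llr_value` may be the floor.
#' @param thresholds a [classifier_thresholds()].
#' @return One of "clonal", "nonclonal", "inconclusive".
#' @export
classify_cna <- function(pcc_value, llr_value, thresholds = classifier_thresholds()) {
  if (!is.finite(pcc_value) || !is.finite(llr_value)) {
    validation_error("classify_cna requires finite (or floored) metric values")
  }
  if (pcc_value > thresholds$pcc_clonal && llr_value > thresholds$llr_clonal) {
    "clonal"
  } else if (pcc_value < thresholds$pcc_nonclonal && llr_value < thresholds$llr_nonclonal) {
    "nonclonal"
  } else {
    "inconclusive"
  }
}
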