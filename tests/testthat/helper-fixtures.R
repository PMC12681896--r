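# Small in-code fixtures shared across test files.

# Two 10-Mb chromosomes with 5-Mb p/q arms; 100-kb bins -> 200 bins total.
toy_arm_table <- function() {
  data.frame(arm = c("1p", "1q", "2p", "2q"),
             chrom = c("1", "1", "2", "2"),
             start = c(1, 5e6 + 1, 1, 5e6 + 1),
             end = c(5e6, 1e7, 5e6, 1e7),
             stringsAsFactors = FALSE)
}

toy_layout <- function(bin_size = 1e5) {
  genome_layout(bin_size, arm_table = toy_arm_table())
}

# Profile with given per-bin log2 ratios (counts filled consistently).
toy_profile <- function(layout, log2, sample_id = "s", use = TRUE,
                        counts = NULL) {
  bins <- layout$bins
  n <- nrow(bins)
  if (is.null(counts)) counts <- round(100 * 2^ifelse(is.na(log2), 0, log2))
  binned_profile(sample_id,
                 data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
                            readcount = rep_len(counts, n),
                            log2ratio = rep_len(log2, n),
                            use = rep_len(use, n), stringsAsFactors = FALSE),
                 bin_size = layout$bin_size)
}

# A random but valid binned profile for round-trip property tests.
random_profile <- function(layout, seed) {
  set.seed(seed)
  bins <- layout$bins
  n <- nrow(bins)
  l2 <- round(stats::rnorm(n, 0, 0.4), 4)
  l2[sample(n, n %/% 10)] <- NA
  binned_profile(sprintf("rand%02d", seed),
                 data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
                            readcount = stats::rpois(n, 120),
                            log2ratio = l2,
                            use = stats::runif(n) > 0.1, stringsAsFactors = FALSE),
                 bin_size = layout$bin_size)
}

arm_states <- function(arms, states, sample_id = "s") {
  structure(data.frame(arm = arms, state = states,
                       mean_log2 = 0.3 * states, coverage = 1,
                       stringsAsFactors = FALSE),
            sample_id = sample_id, class = c("ArmStateVector", "data.frame"))
}

ref_freqs <- function(arms, p_gain, p_loss, histology = "LUAD", eps = 0.01) {
  reference_frequencies(data.frame(arm = arms, histology = histology,
                                   p_gain = p_gain, p_loss = p_loss,
                                   stringsAsFactors = FALSE), eps = eps)
}

# Variant building blocks for decision-tree tests.
v_egfr_l858r <- function() variant_records("7", 55259515, "T", "G", gene = "EGFR", protein_change = "L858R")
v_braf_v600e <- function() variant_records("7", 140453136, "A", "T", gene = "BRAF", protein_change = "V600E")
v_kras_g12c <- function() variant_records("12", 25398285, "C", "A", gene = "KRAS", protein_change = "G12C")
v_kras_g12v <- function() variant_records("12", 25398284, "C", "A", gene = "KRAS", protein_change = "G12V")
v_tp53_a <- function() variant_records("17", 7578406, "C", "T", gene = "TP53", protein_change = "R175H")
v_tp53_b <- function() variant_records("17", 7577120, "G", "A", gene = "TP53", protein_change = "R273L")
v_other <- function(pos = 47060000) variant_records("3", pos, "G", "A", gene = "SETD2", protein_change = "E100K")
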