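# A 600-bin toy genome (three 20-Mb chromosomes, 10-Mb arms) lets the CNA
# tier run in milliseconds with min_bins lowered accordingly.
wf_arm_table <- function() {
  data.frame(arm = c("1p", "1q", "2p", "2q", "3p", "3q"),
             chrom = rep(c("1", "2", "3"), each = 2),
             start = rep(c(1, 1e7 + 1), 3), end = rep(c(1e7, 2e7), 3))
}

wf_layout <- function() genome_layout(1e5, arm_table = wf_arm_table())

wf_config <- function(lay) {
  run_config(layout = lay, min_bins = 50, n_perm = 100,
             qc = qc_thresholds(min_reads = 0))
}

wf_freqs <- function() {
  # a shared 1q gain at p = 0.05 gives LLR = log10((1/6) / 0.05) > 0
  ref_freqs(c("1p", "1q", "2p", "2q", "3p", "3q"),
            p_gain = 0.05, p_loss = 0.05, histology = "LUAD")
}

# raw-count profile for given arm states, Poisson noise around depth 100
wf_profile <- function(lay, states, seed, sample_id = "t") {
  set.seed(seed)
  bins <- lay$bins
  cn <- 2 + states[bins$arm]
  mu <- 100 * (0.8 * cn / 2 + 0.2)
  binned_profile(sample_id,
                 data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
                            readcount = rpois(nrow(bins), mu),
                            log2ratio = NA_real_, use = TRUE),
                 bin_size = lay$bin_size)
}

wf_pair <- function(states_a, states_b, va, vb, seed = 1, pair_id = "p1") {
  lay <- wf_layout()
  sample_pair(pair_id,
              list(variants = va, profile = wf_profile(lay, states_a, seed),
                   tumor_pct = 80, total_reads = 60000),
              list(variants = vb, profile = wf_profile(lay, states_b, seed + 1),
                   tumor_pct = 80, total_reads = 60000),
              histology = "LUAD")
}

st <- function(...) setNames(c(...), c("1p", "1q", "2p", "2q", "3p", "3q"))

test_that("qc gate applies the strict tumor-percentage and read-count rules", {
  g <- qc_gate(list(tumor_pct = 15, total_reads = 1e7))
  expect_false(g$pass)
  expect_match(g$reasons, "tumor percentage")

  g <- qc_gate(list(tumor_pct = 30, total_reads = 4e5))
  expect_false(g$pass)
  expect_match(g$reasons, "read count")

  expect_true(qc_gate(list(tumor_pct = 30, total_reads = 1e7))$pass)
  # boundaries pass (strictly-below fails)
  expect_true(qc_gate(list(tumor_pct = 20, total_reads = 5e5))$pass)
  # missing values fail with reason "unknown"
  g <- qc_gate(list(tumor_pct = NA, total_reads = NULL))
  expect_false(g$pass)
  expect_length(g$reasons, 2)
  expect_match(g$reasons, "unknown", all = TRUE)
})

test_that("a definitive mutation call short-circuits the CNA tier", {
  two_shared <- rbind(v_egfr_l858r(), v_tp53_a())
  # profiles deliberately absent: touching the CNA tier would error
  pair <- sample_pair("p", list(variants = two_shared, profile = NULL),
                      list(variants = two_shared, profile = NULL), "LUAD")
  out <- classify_pair(pair, wf_freqs(), config = wf_config(wf_layout()))
  expect_equal(out$final_class, "clonal")
  expect_equal(out$resolved_by, "mutation")
  expect_equal(out$cna_class, "not_evaluated")
  expect_true(is.na(out$pcc))

  pair <- sample_pair("p", list(variants = v_egfr_l858r(), profile = NULL),
                      list(variants = v_braf_v600e(), profile = NULL), "LUAD")
  out <- classify_pair(pair, wf_freqs(), config = wf_config(wf_layout()))
  expect_equal(out$final_class, "nonclonal")
  expect_equal(out$resolved_by, "mutation")
})

test_that("ambiguous mutation calls are resolved by the CNA tier", {
  # no panel variants -> mutation tier inconclusive; identical rare 1q gain
  # in both tumors -> CNA clonal
  pair <- wf_pair(st(0, 1, 0, 0, 0, 0), st(0, 1, 0, 0, 0, 0),
                  variant_records(), variant_records(), seed = 3)
  out <- classify_pair(pair, wf_freqs(), config = wf_config(wf_layout()))
  expect_equal(out$mutation_class, "inconclusive")
  expect_equal(out$final_class, "clonal")
  expect_equal(out$resolved_by, "cna")
  expect_gt(out$pcc, 0.54)
  expect_gt(out$llr, 0)

  # discordant KRAS -> probable nonclonal; disjoint profiles -> CNA nonclonal
  pair <- wf_pair(st(0, 1, 0, 0, 0, 0), st(0, 0, 0, -1, 0, 0),
                  v_kras_g12c(), v_kras_g12v(), seed = 5)
  out <- classify_pair(pair, wf_freqs(), config = wf_config(wf_layout()))
  expect_equal(out$mutation_class, "probable_nonclonal")
  expect_equal(out$final_class, "nonclonal")
  expect_equal(out$resolved_by, "cna")
  expect_lt(out$pcc, 0.45)
  expect_equal(out$llr, -50)
})

test_that("a pair unusable by both tiers ends inconclusive with an annotation", {
  pair <- wf_pair(st(0, 0, 0, 0, 0, 0), st(0, 0, 0, 0, 0, 0),
                  variant_records(), variant_records(), seed = 7)
  cfg <- wf_config(wf_layout())
  cfg$min_bins <- 1e5  # force an insufficient-data failure in the CNA tier
  out <- classify_pair(pair, wf_freqs(), config = cfg)
  expect_equal(out$final_class, "inconclusive")
  expect_equal(out$resolved_by, "unresolved")
  expect_match(out$error, "bins")
})

test_that("run_cohort reports exclusions and preserves input order", {
  p1 <- wf_pair(st(0, 1, 0, 0, 0, 0), st(0, 1, 0, 0, 0, 0),
                variant_records(), variant_records(), seed = 3, pair_id = "a")
  p2 <- wf_pair(st(0, 1, 0, 0, 0, 0), st(0, 1, 0, 0, 0, 0),
                variant_records(), variant_records(), seed = 9, pair_id = "b")
  p2$tumor_a$tumor_pct <- 10
  cfg <- wf_config(wf_layout())
  res <- run_cohort(list(p1, p2), wf_freqs(), config = cfg,
                    qc = qc_thresholds(min_reads = 0))
  expect_length(res$calls, 1)
  expect_equal(res$calls[[1]]$pair_id, "a")
  expect_equal(res$excluded$pair_id, "b")
  expect_match(res$excluded$reasons, "tumor percentage")

  expect_length(run_cohort(list(), wf_freqs(), config = cfg)$calls, 0)
})

test_that("a seeded cohort run is deterministic end to end", {
  lay <- genome_layout(5e5)
  cfg <- simulation_config(layout = lay)
  run_once <- function() {
    co <- simulate_cohort(2, 2, cfg, seed = 19)
    rc <- run_cohort(co, config = run_config(layout = lay, n_perm = 100, seed = 1))
    vapply(rc$calls, function(x) {
      paste(x$pair_id, x$final_class, x$resolved_by,
            format(c(x$pcc, x$llr), digits = 12), collapse = "|")
    }, "")
  }
  expect_identical(run_once(), run_once())
})

test_that("crosstabs count calls against truth and rate the tiers", {
  fake <- function(final, mut, cna) {
    structure(list(pair_id = "x", final_class = final, mutation_class = mut,
                   cna_class = cna), class = "FinalCall")
  }
  calls <- list(fake("clonal", "clonal", "not_evaluated"),
                fake("clonal", "clonal", "not_evaluated"))
  ev <- crosstab_vs_truth(calls, c("clonal", "clonal"))
  expect_equal(unname(ev$concordance["clonal"]), 1.0)
  expect_equal(ev$mutation_ambiguity_rate, 0)

  calls <- list(fake("clonal", "clonal", "not_evaluated"),
                fake("inconclusive", "inconclusive", "inconclusive"))
  ev <- crosstab_vs_truth(calls, c("clonal", "clonal"))
  expect_equal(unname(ev$concordance["clonal"]), 0.5)
  expect_equal(ev$mutation_ambiguity_rate, 0.5)
  expect_equal(ev$cna_definitive_rate, 0)
  expect_equal(sum(ev$crosstab), 2)

  calls <- list(fake("nonclonal", "probable_nonclonal", "nonclonal"),
                fake("clonal", "inconclusive", "clonal"),
                fake("clonal", "clonal", "not_evaluated"))
  ev <- crosstab_vs_truth(calls, c("nonclonal", "clonal", "clonal"))
  expect_equal(ev$cna_definitive_rate, 1)
  expect_equal(ev$cna_correct_rate, 1)
  expect_error(crosstab_vs_truth(calls, "clonal"),
               class = "clonalpair_validation_error")
})

test_that("fisher_exact_2x2 matches known values and the enumeration oracle", {
  expect_equal(fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2)), 1 / 3, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2)), 1.0)
  expect_error(fisher_exact_2x2(matrix(c(1, 0, 0, 0), 2)),
               class = "clonalpair_validation_error")
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)),
               class = "clonalpair_validation_error")

  set.seed(77)
  for (i in 1:200) {
    m <- matrix(sample(0:12, 4, replace = TRUE), 2)
    if (min(rowSums(m), colSums(m)) == 0) next
    expect_equal(fisher_exact_2x2(m), fisher_oracle(m), tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(m), stats::fisher.test(m)$p.value,
                 tolerance = 1e-7)
  }
})
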