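test_that("on-target exclusion respects padding arithmetic", {
  targets <- data.frame(chrom = "1", start = 1000, end = 2000)
  inside <- data.frame(chrom = "1", pos = 1500)
  expect_equal(nrow(exclude_on_target(inside, targets, 0)), 0)

  near <- data.frame(chrom = "1", pos = 2150)  # 150 bp beyond the end
  expect_equal(nrow(exclude_on_target(near, targets, 200)), 0)
  expect_equal(nrow(exclude_on_target(near, targets, 100)), 1)
  expect_error(exclude_on_target(near, targets, -1),
               class = "clonalpair_validation_error")
})

test_that("uniform positions against 30% target coverage keep about 70%", {
  # one 10-Mb chromosome; 100 targets of 29.6 kb, padded 200 bp -> 30 kb each
  targets <- data.frame(chrom = "1", start = seq(0, 99) * 1e5 + 201,
                        end = seq(0, 99) * 1e5 + 29800)
  set.seed(12)
  pos <- data.frame(chrom = "1", pos = sample.int(1e7, 10000))
  kept <- nrow(exclude_on_target(pos, targets, 200)) / 10000
  expect_lt(abs(kept - 0.70), 0.02)
})

test_that("positions are counted into half-open bins", {
  lay <- toy_layout(1e5)
  pos <- data.frame(chrom = rep("1", 4),
                    pos = c(5, 50, 99999, 100001))
  p <- bin_counts(pos, lay)
  expect_equal(p$bins$readcount[1], 3)
  # 1-based 100001 is the first base of the second bin
  expect_equal(p$bins$readcount[2], 1)
  expect_equal(sum(p$bins$readcount), 4)
  expect_equal(p$metadata$total_reads, 4)
})

test_that("re-binning 100-kb counts to 500 kb sums the five fine bins", {
  fine <- toy_layout(1e5)
  coarse <- toy_layout(5e5)
  set.seed(3)
  p <- random_profile(fine, 1)
  q <- bin_counts(p, coarse)
  expect_equal(nrow(q$bins), 40)
  grp <- paste(p$bins$chrom, p$bins$start %/% 5e5)
  sums <- tapply(p$bins$readcount, grp, sum)
  expect_equal(q$bins$readcount,
               as.numeric(sums[paste(q$bins$chrom, q$bins$start %/% 5e5)]))
})

test_that("bin size validation rejects nonstandard sizes", {
  lay <- toy_layout(25e4)
  expect_error(bin_counts(data.frame(chrom = "1", pos = 1), lay),
               "allowed", class = "clonalpair_validation_error")
  expect_equal(nrow(bin_counts(data.frame(chrom = "1", pos = 1), lay,
                               allowed_bin_sizes = NULL)$bins), 80)
})

test_that("blacklist and mappability filtering flip use flags only", {
  lay <- toy_layout()
  p <- toy_profile(lay, 0)
  bl <- data.frame(chrom = "1", start = 1, end = 100000)
  q <- filter_bins(p, bl)
  expect_false(q$bins$use[1])
  expect_true(all(q$bins$use[-1]))
  expect_equal(q$bins$readcount, p$bins$readcount)

  expect_identical(filter_bins(p, NULL, 0)$bins, p$bins)

  mp <- rep(1, nrow(p$bins)); mp[5] <- 0.2
  expect_false(filter_bins(p, NULL, 0.5, mp)$bins$use[5])
})

test_that("a fully blacklisted arm is later reported missing", {
  lay <- toy_layout()
  p <- toy_profile(lay, 0, counts = 100)
  bl <- data.frame(chrom = "1", start = 1, end = 5e6)  # all of 1p
  p <- filter_bins(p, bl)
  p <- normalize_log2(p)
  seg <- segment_cbs(p, n_perm = 100, seed = 1)
  st <- call_arm_states(seg, lay)
  expect_true(is.na(st$state[st$arm == "1p"]))
  expect_equal(st$state[st$arm == "2q"], 0)
})

test_that("median normalization follows the pseudo-count formula", {
  lay <- toy_layout()
  p <- toy_profile(lay, NA_real_, counts = 100)
  q <- normalize_log2(p)
  expect_true(all(q$bins$log2ratio == 0))

  counts <- rep(100, 200); counts[7] <- 200
  p <- toy_profile(lay, NA_real_, counts = counts)
  q <- normalize_log2(p)
  expect_equal(q$bins$log2ratio[7], log2(200.5 / 100.5))
  expect_equal(median(q$bins$log2ratio), 0)

  p$bins$use[7] <- FALSE
  q <- normalize_log2(p)
  expect_true(is.na(q$bins$log2ratio[7]))

  p0 <- toy_profile(lay, NA_real_, counts = 0)
  expect_error(normalize_log2(p0), "zero", class = "clonalpair_validation_error")
})

test_that("covariate hook flattens a count trend", {
  lay <- toy_layout()
  gc <- seq(0.3, 0.7, length.out = 200)
  counts <- round(100 * (0.5 + gc))  # counts proportional to the covariate
  p <- toy_profile(lay, NA_real_, counts = counts)
  q_raw <- normalize_log2(p)
  q_cor <- normalize_log2(p, covariate = gc)
  trend <- function(x) abs(stats::cor(x$bins$log2ratio, gc))
  expect_lt(trend(q_cor), trend(q_raw))
})

test_that("constant signal yields one segment per chromosome", {
  lay <- toy_layout()
  p <- toy_profile(lay, 0.25)
  seg <- segment_cbs(p, n_perm = 200, seed = 5)
  expect_equal(nrow(seg$segments), 2)
  expect_equal(seg$segments$seg_mean, c(0.25, 0.25))
})

test_that("a noiseless step is recovered exactly", {
  lay <- toy_layout()
  l2 <- c(rep(0, 50), rep(1, 50), rep(0, 100))  # step on chromosome 1 only
  p <- toy_profile(lay, l2)
  seg <- segment_cbs(p, n_perm = 200, seed = 6)
  s1 <- seg$segments[seg$segments$chrom == "1", ]
  expect_equal(nrow(s1), 2)
  expect_equal(s1$seg_mean, c(0, 1))
  expect_equal(s1$num_bins, c(50, 50))
  expect_equal(s1$end[1], 50 * 1e5)  # breakpoint between bins 50 and 51
})

test_that("planted breakpoints are recovered within two bins under noise", {
  at <- data.frame(arm = c("1p", "1q"), chrom = "1", start = c(1, 15e6 + 1),
                   end = c(15e6, 3e7))
  lay <- genome_layout(1e5, arm_table = at)  # 300 bins
  truth <- c(80, 150, 230)
  means <- c(0, 0.5, -0.4, 0.3)
  l2 <- rep(means, diff(c(0, truth, 300)))
  set.seed(41)
  p <- toy_profile(lay, l2 + rnorm(300, 0, 0.15))
  seg <- segment_cbs(p, n_perm = 500, seed = 42)
  ends <- cumsum(seg$segments$num_bins)
  found <- ends[-length(ends)]
  for (b in truth) expect_lte(min(abs(found - b)), 2)
})

test_that("segment means conserve the chromosome totals", {
  lay <- toy_layout()
  set.seed(9)
  p <- toy_profile(lay, rnorm(200, 0, 0.3))
  p$bins$use[sample(200, 20)] <- FALSE
  seg <- segment_cbs(p, n_perm = 100, seed = 10)
  for (ch in c("1", "2")) {
    s <- seg$segments[seg$segments$chrom == ch, ]
    tot <- sum(p$bins$log2ratio[p$bins$use & p$bins$chrom == ch])
    expect_equal(sum(s$seg_mean * s$num_bins), tot, tolerance = 1e-9)
  }
})

test_that("segmentation is deterministic given the seed and rejects bad input", {
  lay <- toy_layout()
  set.seed(2)
  p <- toy_profile(lay, rnorm(200, 0, 0.2))
  s1 <- segment_cbs(p, n_perm = 150, seed = 77)
  s2 <- segment_cbs(p, n_perm = 150, seed = 77)
  expect_identical(s1$segments, s2$segments)

  p$bins$log2ratio[3] <- Inf
  expect_error(segment_cbs(p, seed = 1), "finite",
               class = "clonalpair_validation_error")
})

test_that("arm states follow the bin-weighted mean rule", {
  lay <- toy_layout()
  flat <- segmented_profile("s", data.frame(
    chrom = c("1", "2"), start = 0, end = 1e7, num_bins = 100, seg_mean = 0))
  st <- call_arm_states(flat, lay)
  expect_true(all(st$state == 0))

  gain <- segmented_profile("s", data.frame(
    chrom = c("1", "1", "2"), start = c(0, 5e6, 0), end = c(5e6, 1e7, 1e7),
    num_bins = c(50, 50, 100), seg_mean = c(0.3, 0, 0)))
  st <- call_arm_states(gain, lay)
  expect_equal(st$state[st$arm == "1p"], 1)
  expect_equal(st$state[st$arm == "1q"], 0)

  # 60% of the arm at +0.3, 40% at -0.3: weighted mean 0.06 -> neutral
  mix2 <- segmented_profile("s", data.frame(
    chrom = c("1", "1", "1", "2"), start = c(0, 3e6, 5e6, 0),
    end = c(3e6, 5e6, 1e7, 1e7), num_bins = c(30, 20, 50, 100),
    seg_mean = c(0.3, -0.3, 0, 0)))
  st <- call_arm_states(mix2, lay)
  expect_equal(st$mean_log2[st$arm == "1p"], 0.3 * 0.6 - 0.3 * 0.4)
  expect_equal(st$state[st$arm == "1p"], 0)

  expect_error(call_arm_states(flat, lay, gain_thr = -0.1, loss_thr = -0.2),
               class = "clonalpair_validation_error")
})

test_that("arm states are invariant to re-binning a noiseless genotype", {
  lay100 <- genome_layout(1e5)
  lay500 <- genome_layout(5e5)
  cfg <- simulation_config(layout = lay100)
  f <- draw_reference_frequencies(cfg, "LUAD", seed = 3)
  set.seed(4)
  g <- simulate_genotype(f, simulation_config(layout = lay100, exome_rate = 0,
                                              focal_rate = 0))
  states <- list()
  for (lay in list(lay100, lay500)) {
    # noiseless: expected counts, no sampling
    bins <- lay$bins
    cn <- rep(2, nrow(bins))
    on_arm <- !is.na(bins$arm)
    cn[on_arm] <- cn[on_arm] + g$arm_events[bins$arm[on_arm]]
    r <- g$purity * cn / 2 + (1 - g$purity)
    p <- binned_profile("nl", data.frame(
      chrom = bins$chrom, start = bins$start, end = bins$end,
      readcount = round(1000 * r), log2ratio = NA_real_, use = on_arm),
      bin_size = lay$bin_size)
    seg <- segment_cbs(normalize_log2(p), n_perm = 100, seed = 5)
    states[[length(states) + 1]] <- call_arm_states(seg, lay)$state
  }
  ok <- !is.na(states[[1]]) & !is.na(states[[2]])
  expect_true(all(states[[1]][ok] == states[[2]][ok]))
})

test_that("arm states recover the generating genotype at default noise", {
  lay <- genome_layout(5e5)
  cfg <- simulation_config(layout = lay)
  f <- draw_reference_frequencies(cfg, "LUSC", seed = 6)
  set.seed(61)
  hits <- total <- 0
  for (i in 1:3) {
    g <- simulate_genotype(f, cfg)
    pr <- normalize_log2(emit_binned_counts(g, lay, cfg))
    st <- call_arm_states(segment_cbs(pr, n_perm = 200), lay)
    ok <- !is.na(st$state)
    hits <- hits + sum(st$state[ok] == g$arm_events[st$arm][ok])
    total <- total + sum(ok)
  }
  expect_gte(hits / total, 0.95)
})
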