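#' Drop read positions overlapping capture targets
#'
#' Off-target copy-number profiling from exome data keeps only reads falling
#' outside the capture design, expanded by a safety margin on both sides
#' (on-target coverage tracks the design, not copy number).
#'
#' @param read_positions data.frame with `chrom` and `pos` (1-based).
#' @param targets data.frame with `chrom`, `start`, `end`
#'   (1-based inclusive capture intervals).
#' @param padding_bp margin added to both sides of every target (default 200).
#' @return The off-target subset of `read_positions`.
#' @export
exclude_on_target <- function(read_positions, targets, padding_bp = 200) {
  if (padding_bp < 0) validation_error("padding_bp must be >= 0")
  if (nrow(targets) == 0 || nrow(read_positions) == 0) return(read_positions)
  reads <- GenomicRanges::GRanges(strip_chr(read_positions$chrom),
                                  IRanges::IRanges(read_positions$pos,
                                                   read_positions$pos))
  tg <- GenomicRanges::GRanges(strip_chr(targets$chrom),
                               IRanges::IRanges(pmax(1, targets$start - padding_bp),
                                                targets$end + padding_bp))
  hits <- GenomicRanges::countOverlaps(reads, tg)
  read_positions[hits == 0, , drop = FALSE]
}

#' Count read positions into genomic bins
#'
#' Tallies read positions into the half-open bins of a layout (a position on
#' a bin boundary belongs to the later bin). Positions on excluded territory
#' (centromeres, acrocentric p arms) are dropped; the kept total is recorded
#' in the profile metadata. Alternatively re-bins an existing finer profile:
#' each coarse bin's count is the sum of the fine bins it contains.
#'
#' @param x data.frame with `chrom`, `pos` (1-based positions), or a
#'   [binned_profile()] to re-bin.
#' @param layout target [genome_layout()]; its `bin_size` must be one of
#'   `allowed_bin_sizes` (and, when re-binning, a multiple of the source
#'   bin size).
#' @param sample_id sample identifier for the result.
#' @param allowed_bin_sizes admissible bin sizes in bp
#'   (default 100 kb / 500 kb / 1 Mb); `NULL` admits any.
#' @return A [binned_profile()]; counts on excluded territory are zeroed and
#'   flagged unusable.
#' @export
bin_counts <- function(x, layout, sample_id = "sample",
                       allowed_bin_sizes = c(100000, 500000, 1000000)) {
  bs <- layout$bin_size
  if (!is.numeric(bs) || bs <= 0 || bs != round(bs)) {
    validation_error("bin size must be a positive integer")
  }
  if (!is.null(allowed_bin_sizes) && !bs %in% allowed_bin_sizes) {
    validation_error(sprintf("bin size %g not among allowed sizes (%s)",
                             bs, paste(allowed_bin_sizes, collapse = ", ")))
  }
  bins <- layout$bins
  counts <- numeric(nrow(bins))
  if (inherits(x, "BinnedProfile")) {
    if (bs %% x$bin_size != 0) {
      validation_error("target bin size must be a multiple of the source bin size")
    }
    src <- x$bins
    key <- paste(bins$chrom, bins$start %/% bs)
    src_key <- paste(src$chrom, src$start %/% bs)
    agg <- tapply(src$readcount, src_key, sum)
    counts <- as.numeric(agg[key])
    counts[is.na(counts)] <- 0
    sample_id <- x$sample_id
  } else {
    stopifnot(all(c("chrom", "pos") %in% names(x)))
    ch <- strip_chr(x$chrom)
    pos0 <- x$pos - 1  # internal 0-based; boundary position falls in later bin
    key <- paste(ch, pos0 %/% bs)
    tab <- table(key)
    bin_key <- paste(bins$chrom, bins$start %/% bs)
    counts <- as.numeric(tab[bin_key])
    counts[is.na(counts)] <- 0
  }
  use <- !is.na(bins$arm)
  kept <- sum(counts[use])
  counts[!use] <- 0
  binned_profile(sample_id,
                 data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
                            readcount = counts, log2ratio = NA_real_, use = use,
                            stringsAsFactors = FALSE),
                 bin_size = bs,
                 metadata = list(total_reads = kept))
}

#' Flag bins on blacklisted or low-mappability regions
#'
#' Bins overlapping any blacklist interval, or whose mappability falls below
#' `min_mappability`, get `use = FALSE`; read counts are preserved.
#'
#' @param profile a [binned_profile()].
#' @param blacklist data.frame with `chrom`, `start`, `end` (1-based
#'   inclusive), or `NULL`.
#' @param min_mappability minimum per-bin mappability fraction (default 0).
#' @param mappability optional numeric vector, one value per bin.
#' @return The profile with updated `use` flags.
#' @export
filter_bins <- function(profile, blacklist = NULL, min_mappability = 0,
                        mappability = NULL) {
  b <- profile$bins
  drop <- rep(FALSE, nrow(b))
  if (!is.null(blacklist) && nrow(blacklist) > 0) {
    dc <- coords_to_disk(b$start, b$end)
    binsr <- GenomicRanges::GRanges(b$chrom, IRanges::IRanges(dc$start, dc$end))
    blr <- GenomicRanges::GRanges(strip_chr(blacklist$chrom),
                                  IRanges::IRanges(blacklist$start, blacklist$end))
    drop <- drop | GenomicRanges::countOverlaps(binsr, blr) > 0
  }
  if (!is.null(mappability)) {
    stopifnot(length(mappability) == nrow(b))
    drop <- drop | mappability < min_mappability
  }
  profile$bins$use <- b$use & !drop
  profile
}

#' Median-normalize bin counts to log2 ratios
#'
#' `log2ratio = log2((count + 0.5) / (median usable count + 0.5))`; the 0.5
#' pseudo-count keeps zero-count bins finite. Unusable bins get `NA`.
#' An optional per-bin covariate (e.g. GC content) triggers a
#' median-by-quantile-bucket correction before the ratio is taken.
#'
#' @param profile a [binned_profile()] with read counts.
#' @param covariate optional numeric per-bin covariate for bucket correction.
#' @param n_buckets number of quantile buckets for the correction.
#' @return The profile with `log2ratio` filled in.
#' @export
normalize_log2 <- function(profile, covariate = NULL, n_buckets = 20) {
  b <- profile$bins
  counts <- b$readcount
  if (!any(b$use)) insufficient_data_error("no usable bins")
  if (all(counts[b$use] == 0)) validation_error("all usable bins have zero counts")
  if (!is.null(covariate)) {
    stopifnot(length(covariate) == nrow(b))
    grand <- stats::median(counts[b$use])
    br <- unique(stats::quantile(covariate[b$use], probs = seq(0, 1, length.out = n_buckets + 1),
                                 na.rm = TRUE))
    bucket <- cut(covariate, breaks = br, include.lowest = TRUE)
    for (lv in levels(bucket)) {
      sel <- b$use & !is.na(bucket) & bucket == lv
      m <- stats::median(counts[sel])
      if (!is.na(m) && m > 0) counts[sel] <- counts[sel] * grand / m
    }
  }
  med <- stats::median(counts[b$use])
  l2 <- log2((counts + 0.5) / (med + 0.5))
  l2[!b$use] <- NA_real_
  profile$bins$log2ratio <- l2
  profile
}

#' Segment a log2-ratio profile (CBS-style)
#'
#' Recursive circular-binary-segmentation style breakpoint search per
#' chromosome: at each step the arc maximizing the standardized
#' mean-difference statistic is tested against `n_perm` permutations of the
#' segment (seeded); the split is kept if its permutation p-value is below
#' `alpha`. Segments narrower than `min_width` usable bins are merged into
#' the neighbor with the closer mean. `seg_mean` is the plain mean of member
#' bins' log2 ratios, so the bin-weighted segment means conserve each
#' chromosome's total log2 signal.
#'
#' @param profile a normalized [binned_profile()].
#' @param alpha permutation significance level (default 0.01).
#' @param min_width minimum segment width in bins (default 3).
#' @param n_perm permutations per test (default 1000).
#' @param seed optional integer seed (RNG untouched when `NULL`).
#' @return A [segmented_profile()].
#' @export
segment_cbs <- function(profile, alpha = 0.01, min_width = 3, n_perm = 1000,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  b <- profile$bins
  if (any(b$use & !is.finite(b$log2ratio))) {
    validation_error("non-finite log2 ratios among usable bins (normalize first)")
  }
  segs <- list()
  for (ch in unique(b$chrom)) {
    idx <- which(b$chrom == ch & b$use)
    if (length(idx) == 0) next
    x <- b$log2ratio[idx]
    n <- length(x)
    bps <- .cbs_breakpoints_cpp(as.numeric(x), alpha, as.integer(min_width),
                                as.integer(n_perm))
    bounds <- c(0, bps, n)
    runs <- data.frame(from = bounds[-length(bounds)] + 1, to = bounds[-1])
    runs <- merge_narrow_runs(runs, x, min_width)
    segs[[ch]] <- data.frame(
      chrom = ch,
      start = b$start[idx[runs$from]],
      end = b$end[idx[runs$to]],
      num_bins = runs$to - runs$from + 1,
      seg_mean = vapply(seq_len(nrow(runs)),
                        function(i) mean(x[runs$from[i]:runs$to[i]]), numeric(1)),
      stringsAsFactors = FALSE)
  }
  if (!length(segs)) insufficient_data_error("no usable bins to segment")
  segmented_profile(profile$sample_id, do.call(rbind, segs),
                    bin_size = profile$bin_size)
}

merge_narrow_runs <- function(runs, x, min_width) {
  run_mean <- function(r) mean(x[r[1]:r[2]])
  repeat {
    w <- runs$to - runs$from + 1
    if (nrow(runs) <= 1 || all(w >= min_width)) return(runs)
    i <- which.min(w)
    means <- apply(runs, 1, run_mean)
    nb <- c(if (i > 1) i - 1, if (i < nrow(runs)) i + 1)
    j <- nb[which.min(abs(means[nb] - means[i]))]
    a <- min(i, j); z <- max(i, j)
    runs$to[a] <- runs$to[z]
    runs <- runs[-z, , drop = FALSE]
  }
}

#' Reduce a segmented profile to per-arm trinary states
#'
#' Per arm, the bin-weighted mean of segment values is compared with the
#' gain/loss thresholds: state +1 if above `gain_thr`, -1 if below
#' `loss_thr`, else 0. Arms whose segment-covered fraction of layout bins
#' falls below `min_coverage` are reported missing (`NA`), not neutral.
#'
#' @param seg a [segmented_profile()].
#' @param layout the [genome_layout()] the profile was binned on.
#' @param gain_thr,loss_thr log2 thresholds (defaults +0.1 / -0.1).
#' @param min_coverage minimum covered fraction of an arm's bins (default 0.5).
#' @return data.frame of class `ArmStateVector` with columns `arm`, `state`,
#'   `mean_log2`, `coverage`, plus a `sample_id` attribute.
#' @export
call_arm_states <- function(seg, layout, gain_thr = 0.1, loss_thr = -0.1,
                            min_coverage = 0.5) {
  if (!(loss_thr < 0 && 0 < gain_thr)) {
    validation_error("thresholds must satisfy loss_thr < 0 < gain_thr")
  }
  bins <- layout$bins
  mid <- (bins$start + bins$end) / 2
  s <- seg$segments
  out <- data.frame(arm = layout$arms$arm, state = NA_real_,
                    mean_log2 = NA_real_, coverage = 0, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(layout$arms))) {
    a <- layout$arms[i, ]
    in_arm <- bins$chrom == a$chrom & !is.na(bins$arm) & bins$arm == a$arm
    total <- sum(in_arm)
    if (total == 0) next
    ss <- s[s$chrom == a$chrom, , drop = FALSE]
    if (nrow(ss) == 0) next
    # weight each segment by the number of arm bins whose midpoint it covers
    wsum <- 0; msum <- 0
    for (k in seq_len(nrow(ss))) {
      w <- sum(in_arm & mid >= ss$start[k] & mid < ss$end[k])
      wsum <- wsum + w
      msum <- msum + w * ss$seg_mean[k]
    }
    cov <- wsum / total
    out$coverage[i] <- cov
    if (wsum == 0 || cov < min_coverage) next
    m <- msum / wsum
    out$mean_log2[i] <- m
    out$state[i] <- if (m > gain_thr) 1 else if (m < loss_thr) -1 else 0
  }
  structure(out, sample_id = seg$sample_id,
            class = c("ArmStateVector", "data.frame"))
}
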