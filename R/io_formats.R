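#' Construct a binned read-count profile
#'
#' The substrate of the PCC metric: per-bin genomic read counts and (after
#' normalization) log2 ratios, with a usability flag. Coordinates are
#' internal 0-based half-open.
#'
#' @param sample_id sample identifier.
#' @param bins data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `readcount`, `log2ratio` (may be `NA`), `use` (logical).
#' @param bin_size bin width in bp.
#' @param metadata optional named list (histology, total reads, ...).
#' @return A `BinnedProfile` object.
#' @export
binned_profile <- function(sample_id, bins, bin_size, metadata = list()) {
  need <- c("chrom", "start", "end", "readcount", "log2ratio", "use")
  stopifnot(all(need %in% names(bins)))
  bins <- bins[, need]
  bins$chrom <- strip_chr(bins$chrom)
  validate_bins(bins)
  structure(list(sample_id = sample_id, bins = bins, bin_size = bin_size,
                 metadata = metadata),
            class = "BinnedProfile")
}

validate_bins <- function(bins, line_offset = 1L) {
  # line_offset maps row i to file line i + offset (header = line 1)
  ln <- function(i) i + line_offset
  r <- match(bins$chrom, karyotype_chroms())
  if (anyNA(r)) format_error(sprintf("unknown chromosome '%s'", bins$chrom[which(is.na(r))[1]]),
                             line = ln(which(is.na(r))[1]))
  bad <- which(bins$start >= bins$end)
  if (length(bad)) format_error("bin with start > end", line = ln(bad[1]))
  if (any(bins$readcount < 0, na.rm = TRUE)) {
    format_error("negative readcount", line = ln(which(bins$readcount < 0)[1]))
  }
  o <- order(r, bins$start)
  if (is.unsorted(o) && any(o != seq_along(o))) {
    format_error("bins not sorted by (chromosome, start)",
                 line = ln(which(o != seq_along(o))[1]))
  }
  ov <- which(bins$chrom[-1] == bins$chrom[-nrow(bins)] &
                bins$start[-1] < bins$end[-nrow(bins)])
  if (length(ov)) format_error("overlapping bins", line = ln(ov[1] + 1L))
  invisible(TRUE)
}

#' @export
print.BinnedProfile <- function(x, ...) {
  cat(sprintf("BinnedProfile '%s': %d bins (%d usable), bin size %g bp\n",
              x$sample_id, nrow(x$bins), sum(x$bins$use), x$bin_size))
  invisible(x)
}

#' Read a bin table
#'
#' Tab-separated with header columns `chromosome`, `start`, `end`,
#' `readcount`, `log2ratio`, `use`; coordinates 1-based inclusive on disk.
#' Missing log2 ratios are written/read as `NA` (never coerced to zero).
#' Malformed rows raise a format error naming the offending line.
#'
#' @param path file path.
#' @param sample_id sample identifier; defaults to the file base name.
#' @return A [binned_profile()].
#' @export
read_bin_table <- function(path, sample_id = NULL) {
  if (!file.exists(path)) format_error(sprintf("no such file: %s", path))
  d <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  need <- c("chromosome", "start", "end", "readcount", "log2ratio", "use")
  if (!all(need %in% names(d))) {
    format_error(sprintf("bin table must have columns: %s", paste(need, collapse = ", ")),
                 line = 1)
  }
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  d$chromosome <- strip_chr(d$chromosome)
  bad <- which(d$start > d$end)
  if (length(bad)) format_error("bin with start > end", line = bad[1] + 1L)
  ic <- coords_to_internal(d$start, d$end)
  bins <- data.frame(chrom = d$chromosome, start = ic$start, end = ic$end,
                     readcount = d$readcount,
                     log2ratio = as.numeric(d$log2ratio),
                     use = as.logical(d$use), stringsAsFactors = FALSE)
  validate_bins(bins)
  widths <- bins$end - bins$start
  binned_profile(sample_id, bins, bin_size = max(widths),
                 metadata = list(total_reads = sum(bins$readcount)))
}

fmt6 <- function(x) {
  # fixed float dialect: 6 significant digits, "NA" for missing
  ifelse(is.na(x), "NA", formatC(x, digits = 6, format = "g"))
}

#' Write a bin table
#'
#' Deterministic byte output: fixed column order, floats at 6 significant
#' digits, `NA` for missing values, 1-based inclusive coordinates.
#'
#' @param profile a [binned_profile()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bin_table <- function(profile, path) {
  b <- profile$bins
  dc <- coords_to_disk(b$start, b$end)
  out <- data.frame(chromosome = b$chrom, start = dc$start, end = dc$end,
                    readcount = b$readcount, log2ratio = fmt6(b$log2ratio),
                    use = ifelse(b$use, "TRUE", "FALSE"), stringsAsFactors = FALSE)
  con <- tryCatch(file(path, "w"), error = function(e)
    stop(errorCondition(sprintf("cannot write %s", path),
                        class = c("clonalpair_io_error", "clonalpair_error"))))
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a segmented copy-number profile
#'
#' Piecewise-constant segment means in log2 units, the substrate of
#' arm-state calling and the LLR. Internal coordinates 0-based half-open.
#'
#' @param sample_id sample identifier.
#' @param segments data.frame with `chrom`, `start`, `end`, `num_bins`,
#'   `seg_mean`.
#' @param bin_size the source bin size in bp.
#' @return A `SegmentedProfile`.
#' @export
segmented_profile <- function(sample_id, segments, bin_size = NA) {
  need <- c("chrom", "start", "end", "num_bins", "seg_mean")
  stopifnot(all(need %in% names(segments)))
  segments <- segments[, need]
  segments$chrom <- strip_chr(segments$chrom)
  validate_segments(segments)
  structure(list(sample_id = sample_id, segments = segments, bin_size = bin_size),
            class = "SegmentedProfile")
}

validate_segments <- function(s, line_offset = 1L) {
  ln <- function(i) i + line_offset
  bad <- which(s$num_bins < 1)
  if (length(bad)) format_error("segment with num_bins < 1", line = ln(bad[1]))
  bad <- which(s$start >= s$end)
  if (length(bad)) format_error("segment with start > end", line = ln(bad[1]))
  if (any(!is.finite(s$seg_mean))) {
    format_error("non-finite seg_mean", line = ln(which(!is.finite(s$seg_mean))[1]))
  }
  o <- order(chrom_rank(s$chrom), s$start)
  s <- s[o, ]
  ov <- which(s$chrom[-1] == s$chrom[-nrow(s)] & s$start[-1] < s$end[-nrow(s)])
  if (length(ov)) format_error("overlapping segments", line = ln(ov[1] + 1L))
  invisible(TRUE)
}

#' @export
print.SegmentedProfile <- function(x, ...) {
  cat(sprintf("SegmentedProfile '%s': %d segments\n", x$sample_id, nrow(x$segments)))
  invisible(x)
}

#' Read a SEG file (IGV dialect)
#'
#' Tab-separated with columns `ID`, `chrom`, `loc.start`, `loc.end`,
#' `num.mark`, `seg.mean`; 1-based inclusive coordinates. Segments are
#' grouped per sample, sorted and invariant-checked.
#'
#' @param path file path.
#' @return Named list of [segmented_profile()], one per sample ID.
#' @export
read_seg <- function(path) {
  if (!file.exists(path)) format_error(sprintf("no such file: %s", path))
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("ID", "chrom", "loc.start", "loc.end", "num.mark", "seg.mean")
  if (!all(need %in% names(d))) {
    format_error(sprintf("SEG file must have columns: %s", paste(need, collapse = ", ")),
                 line = 1)
  }
  d$chrom <- strip_chr(d$chrom)
  ic <- coords_to_internal(d$loc.start, d$loc.end)
  segs <- data.frame(sample_id = d$ID, chrom = d$chrom, start = ic$start,
                     end = ic$end, num_bins = d$num.mark, seg_mean = d$seg.mean,
                     line = seq_len(nrow(d)) + 1L, stringsAsFactors = FALSE)
  out <- list()
  for (sid in unique(segs$sample_id)) {
    s <- segs[segs$sample_id == sid, ]
    s <- s[order(chrom_rank(s$chrom), s$start), ]
    bad <- which(s$num_bins < 1)
    if (length(bad)) format_error("segment with num.mark < 1", line = s$line[bad[1]])
    ov <- which(s$chrom[-1] == s$chrom[-nrow(s)] & s$start[-1] < s$end[-nrow(s)])
    if (length(ov)) {
      format_error(sprintf("overlapping segments in sample %s", sid),
                   line = s$line[ov[1] + 1L])
    }
    out[[sid]] <- segmented_profile(sid, s[, c("chrom", "start", "end",
                                               "num_bins", "seg_mean")])
  }
  out
}

#' Write SEG (IGV dialect)
#'
#' @param profiles a [segmented_profile()] or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_seg <- function(profiles, path) {
  if (inherits(profiles, "SegmentedProfile")) profiles <- list(profiles)
  rows <- do.call(rbind, lapply(profiles, function(p) {
    s <- p$segments
    dc <- coords_to_disk(s$start, s$end)
    data.frame(ID = p$sample_id, chrom = s$chrom, loc.start = dc$start,
               loc.end = dc$end, num.mark = s$num_bins,
               seg.mean = fmt6(s$seg_mean), stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a table of somatic variant records
#'
#' Variants are keyed by exact DNA change (chrom, pos, ref, alt); gene and
#' protein annotation are carried for panel logic only.
#'
#' @param chrom,pos,ref,alt required fields; `pos` 1-based.
#' @param gene,protein_change,vaf,population_af optional annotation.
#' @return data.frame of class `VariantSet`.
#' @export
variant_records <- function(chrom = character(), pos = integer(),
                            ref = character(), alt = character(),
                            gene = NA, protein_change = NA,
                            vaf = NA, population_af = NA) {
  n <- length(chrom)
  v <- data.frame(chrom = strip_chr(chrom), pos = rep_len(as.numeric(pos), n),
                  ref = rep_len(toupper(as.character(ref)), n),
                  alt = rep_len(toupper(as.character(alt)), n),
                  gene = rep_len(as.character(gene), n),
                  protein_change = rep_len(as.character(protein_change), n),
                  vaf = rep_len(as.numeric(vaf), n),
                  population_af = rep_len(as.numeric(population_af), n),
                  stringsAsFactors = FALSE)
  if (any(v$pos < 1)) validation_error("variant with pos < 1")
  if (any(v$ref == v$alt)) validation_error("variant with ref == alt")
  class(v) <- c("VariantSet", "data.frame")
  v
}

#' Read a minimal VCF
#'
#' VCF v4.2; only CHROM/POS/REF/ALT are required. Gene symbol, protein
#' change and allele frequencies are taken from INFO keys `GENE`,
#' `PCHANGE`, `AF` and `POPAF` when present. Multi-allelic rows are split
#' into one record per ALT; rows whose FILTER is neither `PASS` nor `.`
#' are excluded unless `pass_only = FALSE`.
#'
#' @param path file path.
#' @param pass_only drop filtered rows (default TRUE).
#' @return A [variant_records()] data.frame.
#' @export
read_vcf_minimal <- function(path, pass_only = TRUE) {
  if (!file.exists(path)) format_error(sprintf("no such file: %s", path))
  head_lines <- readLines(path, n = 200L)
  if (!any(startsWith(head_lines, "#CHROM"))) {
    format_error("missing #CHROM header line in VCF")
  }
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0) return(variant_records())
  filt <- fix[, "FILTER"]
  keep <- if (pass_only) is.na(filt) | filt %in% c("PASS", ".") else rep(TRUE, nrow(fix))
  fix <- fix[keep, , drop = FALSE]
  if (nrow(fix) == 0) return(variant_records())
  gene <- info_or_na(v, "GENE")[keep]
  pchg <- info_or_na(v, "PCHANGE")[keep]
  af <- info_or_na(v, "AF")[keep]
  popaf <- info_or_na(v, "POPAF")[keep]
  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  nalt <- lengths(alts)
  i <- rep(seq_len(nrow(fix)), nalt)
  # AF is per-ALT (Number=A); other keys are per-site
  af_split <- strsplit(ifelse(is.na(af), "", af), ",", fixed = TRUE)
  af_per_alt <- unlist(lapply(seq_along(af_split), function(k) {
    x <- suppressWarnings(as.numeric(af_split[[k]]))
    length(x) <- nalt[k]
    x
  }))
  variant_records(chrom = fix[i, "CHROM"], pos = as.numeric(fix[i, "POS"]),
                  ref = fix[i, "REF"], alt = unlist(alts),
                  gene = gene[i], protein_change = pchg[i],
                  vaf = af_per_alt,
                  population_af = suppressWarnings(as.numeric(popaf[i])))
}

info_or_na <- function(vcf, key) {
  x <- tryCatch(vcfR::extract.info(vcf, element = key),
                error = function(e) NULL)
  if (is.null(x)) rep(NA_character_, nrow(vcf@fix)) else x
}

#' Write a minimal VCF
#'
#' Emits VCF v4.2 with annotation in INFO keys `GENE`, `PCHANGE`, `AF`,
#' `POPAF`; FILTER is `PASS` for every record.
#'
#' @param variants a [variant_records()] data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf_minimal <- function(variants, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
           "##INFO=<ID=PCHANGE,Number=1,Type=String,Description=\"Protein change\">",
           "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Variant allele fraction\">",
           "##INFO=<ID=POPAF,Number=1,Type=Float,Description=\"Population allele frequency\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- vapply(seq_len(nrow(variants)), function(i) {
    parts <- character()
    if (!is.na(variants$gene[i])) parts <- c(parts, paste0("GENE=", variants$gene[i]))
    if (!is.na(variants$protein_change[i])) parts <- c(parts, paste0("PCHANGE=", variants$protein_change[i]))
    if (!is.na(variants$vaf[i])) parts <- c(parts, paste0("AF=", fmt6(variants$vaf[i])))
    if (!is.na(variants$population_af[i])) parts <- c(parts, paste0("POPAF=", fmt6(variants$population_af[i])))
    if (length(parts)) paste(parts, collapse = ";") else "."
  }, character(1))
  o <- order(chrom_rank(variants$chrom), variants$pos)
  body <- if (nrow(variants)) {
    paste(variants$chrom[o], format(variants$pos[o], scientific = FALSE, trim = TRUE),
          ".", variants$ref[o], variants$alt[o], ".", "PASS", info[o], sep = "\t")
  } else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Construct reference arm-aberration frequencies
#'
#' Per (arm, histology) probabilities of arm gain and loss in a reference
#' cohort; the null model of the LLR. `eps` is the clipping bound applied
#' when the table is used in likelihood computations (see
#' [clip_reference_frequencies()]).
#'
#' @param freq data.frame with columns `arm`, `histology`, `p_gain`, `p_loss`.
#' @param eps clip bound, default 0.01.
#' @return data.frame of class `ReferenceFrequencies`.
#' @export
reference_frequencies <- function(freq, eps = 0.01) {
  need <- c("arm", "histology", "p_gain", "p_loss")
  stopifnot(all(need %in% names(freq)))
  freq <- freq[, need]
  if (any(freq$p_gain < 0 | freq$p_gain > 1 | freq$p_loss < 0 | freq$p_loss > 1)) {
    validation_error("p_gain/p_loss outside [0, 1]")
  }
  if (any(freq$p_gain + freq$p_loss > 1 + 1e-12)) {
    validation_error("p_gain + p_loss > 1")
  }
  key <- paste(freq$arm, freq$histology)
  if (anyDuplicated(key)) {
    validation_error(sprintf("duplicate (arm, histology) entry: %s", key[anyDuplicated(key)]))
  }
  attr(freq, "eps") <- eps
  class(freq) <- c("ReferenceFrequencies", "data.frame")
  freq
}

#' Read a reference-frequency table
#'
#' TSV with columns `arm`, `histology`, `p_gain`, `p_loss`.
#'
#' @param path file path.
#' @param eps clip bound stored on the result (default 0.01).
#' @return A [reference_frequencies()] table.
#' @export
read_reference_freq <- function(path, eps = 0.01) {
  if (!file.exists(path)) format_error(sprintf("no such file: %s", path))
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("arm", "histology", "p_gain", "p_loss")
  if (!all(need %in% names(d))) {
    format_error(sprintf("reference-frequency table must have columns: %s",
                         paste(need, collapse = ", ")), line = 1)
  }
  reference_frequencies(d, eps = eps)
}

#' Write a reference-frequency table
#' @param freq a [reference_frequencies()] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reference_freq <- function(freq, path) {
  out <- data.frame(arm = freq$arm, histology = freq$histology,
                    p_gain = fmt6(freq$p_gain), p_loss = fmt6(freq$p_loss))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' All tunables of the two-tier workflow in one validated list: classifier
#' thresholds (PCC 0.54/0.45, LLR 0/-5), the shared-mutation threshold
#' (strictly more than 2), QC limits (tumor fraction 20%, 500,000 reads),
#' bin size, segmentation settings and seed.
#'
#' @param ... named overrides of any default.
#' @return list of class `RunConfig`.
#' @export
run_config <- function(...) {
  cfg <- list(
    thresholds = classifier_thresholds(),
    shared_mutation_threshold = 2,
    qc = qc_thresholds(),
    bin_size = 100000,
    alpha = 0.01, min_width = 3, n_perm = 1000,
    gain_thr = 0.1, loss_thr = -0.1, min_coverage = 0.5,
    min_bins = 500, llr_floor = -50, eps = 0.01,
    arm_table = NULL, layout = NULL, seed = 1L
  )
  ov <- list(...)
  for (nm in names(ov)) cfg[[nm]] <- ov[[nm]]
  validate_run_config(cfg)
  structure(cfg, class = "RunConfig")
}

validate_run_config <- function(cfg) {
  th <- cfg$thresholds
  if (!(th$pcc_nonclonal < th$pcc_clonal)) validation_error("pcc_nonclonal must be < pcc_clonal")
  if (!(th$llr_nonclonal < th$llr_clonal)) validation_error("llr_nonclonal must be < llr_clonal")
  if (cfg$qc$min_tumor_pct < 0 || cfg$qc$min_tumor_pct > 100) validation_error("min_tumor_pct outside [0, 100]")
  if (cfg$qc$min_reads < 0) validation_error("min_reads must be >= 0")
  if (cfg$bin_size <= 0) validation_error("bin_size must be positive")
  invisible(TRUE)
}

#' Read a YAML run configuration
#'
#' Keys mirror [run_config()]; unknown keys are rejected, missing keys take
#' the defaults. Nested keys `thresholds` and `qc` override individual
#' cutoffs.
#'
#' @param path YAML file path.
#' @return A [run_config()] list.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- run_config()
  for (nm in names(y)) {
    if (nm %in% c("thresholds", "qc")) {
      for (k in names(y[[nm]])) {
        if (!k %in% names(cfg[[nm]])) validation_error(sprintf("unknown config key %s$%s", nm, k))
        cfg[[nm]][[k]] <- y[[nm]][[k]]
      }
    } else {
      if (!nm %in% names(cfg)) validation_error(sprintf("unknown config key %s", nm))
      cfg[[nm]] <- y[[nm]]
    }
  }
  validate_run_config(cfg)
  cfg
}
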