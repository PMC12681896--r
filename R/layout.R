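#' Karyotype chromosome order
#'
#' Chromosome names in karyotype order ("1".."22", "X", "Y"). All readers
#' strip a leading "chr" prefix and sort by this order.
#'
#' @return Character vector of chromosome names.
#' @export
karyotype_chroms <- function() c(as.character(1:22), "X", "Y")

#' @keywords internal
chrom_rank <- function(chrom) {
  r <- match(chrom, karyotype_chroms())
  if (anyNA(r)) {
    bad <- unique(chrom[is.na(r)])
    validation_error(sprintf("unknown chromosome(s): %s", paste(bad, collapse = ", ")))
  }
  r
}

#' @keywords internal
strip_chr <- function(chrom) sub("^chr", "", as.character(chrom))

# On-disk coordinates are 1-based inclusive (SEG/VCF convention); internal
# coordinates are 0-based half-open. These two helpers are the single
# conversion point.

#' Convert 1-based inclusive (on-disk) to 0-based half-open (internal)
#' @param start,end integer vectors, 1-based inclusive
#' @return list with `start` and `end`, 0-based half-open
#' @export
coords_to_internal <- function(start, end) list(start = start - 1, end = end)

#' Convert 0-based half-open (internal) to 1-based inclusive (on-disk)
#' @param start,end integer vectors, 0-based half-open
#' @return list with `start` and `end`, 1-based inclusive
#' @export
coords_to_disk <- function(start, end) list(start = start + 1, end = end)

#' Build a genome layout of chromosomes, arms and bins
#'
#' A layout ties together chromosome lengths, chromosome-arm intervals and a
#' tiling of fixed-size bins. The default arm table is the hg19 autosomal
#' karyotype (39 arms; the acrocentric p arms 13p/14p/15p/21p/22p and the
#' sex chromosomes are treated as excluded territory). Bins are assigned to
#' the arm containing their midpoint; bins on excluded territory carry an
#' `NA` arm.
#'
#' @param bin_size bin width in bp (default 100000, the 100-kbp dialect).
#' @param arm_table data.frame with columns `arm`, `chrom`, `start`, `end`
#'   (1-based inclusive), or a path to such a TSV. `NULL` uses the shipped
#'   hg19 table.
#' @return A `GenomeLayout` object: list with `bin_size`, `chroms`
#'   (chrom, length), `arms` and `bins` (internal 0-based half-open
#'   coordinates; `bins$arm` is `NA` on excluded territory).
#' @export
genome_layout <- function(bin_size = 100000, arm_table = NULL) {
  if (!is.numeric(bin_size) || length(bin_size) != 1 || is.na(bin_size) ||
      bin_size <= 0 || bin_size != round(bin_size)) {
    validation_error("bin_size must be a positive integer number of bp")
  }
  if (is.null(arm_table)) {
    arm_table <- system.file("extdata", "hg19_arms.tsv", package = "clonalpair")
  }
  if (is.character(arm_table)) {
    arm_table <- utils::read.delim(arm_table, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("arm", "chrom", "start", "end") %in% names(arm_table)))
  arm_table$chrom <- strip_chr(arm_table$chrom)
  arm_table <- arm_table[order(chrom_rank(arm_table$chrom), arm_table$start), ]
  ic <- coords_to_internal(arm_table$start, arm_table$end)
  arms <- data.frame(arm = arm_table$arm, chrom = arm_table$chrom,
                     start = ic$start, end = ic$end, stringsAsFactors = FALSE)
  if (any(arms$start >= arms$end)) validation_error("arm with start >= end")
  # arms within a chromosome must be disjoint and ordered
  for (ch in unique(arms$chrom)) {
    a <- arms[arms$chrom == ch, ]
    if (nrow(a) > 1 && any(a$start[-1] < a$end[-nrow(a)])) {
      validation_error(sprintf("overlapping arms on chromosome %s", ch))
    }
  }
  chroms <- data.frame(
    chrom = unique(arms$chrom),
    length = vapply(unique(arms$chrom),
                    function(ch) max(arms$end[arms$chrom == ch]), numeric(1)),
    stringsAsFactors = FALSE
  )
  bins <- do.call(rbind, lapply(seq_len(nrow(chroms)), function(i) {
    len <- chroms$length[i]
    s <- seq(0, len - 1, by = bin_size)
    data.frame(chrom = chroms$chrom[i], start = s, end = pmin(s + bin_size, len),
               stringsAsFactors = FALSE)
  }))
  mid <- (bins$start + bins$end) / 2
  bins$arm <- NA_character_
  for (k in seq_len(nrow(arms))) {
    hit <- bins$chrom == arms$chrom[k] & mid >= arms$start[k] & mid < arms$end[k]
    bins$arm[hit] <- arms$arm[k]
  }
  structure(list(bin_size = bin_size, chroms = chroms, arms = arms, bins = bins),
            class = "GenomeLayout")
}

#' @export
print.GenomeLayout <- function(x, ...) {
  cat(sprintf("GenomeLayout: %d chromosomes, %d arms, %d bins of %g bp (%d on arms)\n",
              nrow(x$chroms), nrow(x$arms), nrow(x$bins), x$bin_size,
              sum(!is.na(x$bins$arm))))
  invisible(x)
}

#' Arm names of a layout
#' @param layout a `GenomeLayout`
#' @return character vector of arm names in karyotype order
#' @export
layout_arms <- function(layout) layout$arms$arm
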