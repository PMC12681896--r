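#' Synthetic gene model for the 27-gene NSCLC panel
#'
#' Approximate hg19 loci for the default panel genes, used by the simulator
#' to place panel variants and by [restrict_to_panel()] to resolve
#' unannotated variants. This is a synthetic convenience table, not an
#' annotation resource.
#'
#' @return data.frame with `gene`, `chrom`, `start`, `end` (1-based inclusive).
#' @export
nsclc_gene_map <- function() {
  read.table(header = TRUE, stringsAsFactors = FALSE, text = "
gene chrom start end
BRAF 7 140419127 140624564
EGFR 7 55086714 55324313
ERBB2 17 37844167 37886679
KRAS 12 25357723 25403870
MET 7 116312444 116438440
TP53 17 7571720 7590868
PIK3CA 3 178866311 178952497
STK11 19 1205798 1228434
KEAP1 19 10596796 10614417
NF1 17 29421945 29704695
RB1 13 48877883 49056026
CDKN2A 9 21967751 21995300
SMARCA4 19 11071598 11176071
ARID1A 1 27022522 27108595
PTEN 10 89623195 89728532
ATM 11 108093559 108239826
CTNNB1 3 41240942 41281939
NRAS 1 115247085 115259515
MAP2K1 15 66679211 66783882
RIT1 1 155867619 155881195
U2AF1 21 44513066 44527688
RBM10 X 47004656 47046212
SETD2 3 47057898 47205467
MGA 15 41952651 42062141
FAT1 4 187508937 187647876
NOTCH1 9 139388896 139440314
KMT2D 12 49412758 49453557
")
}

# Recurrent hotspot alleles with reuse weights: independent tumors can
# collide on exactly these DNA changes, which is what exercises the
# shared-hotspot -> inconclusive branch of the decision tree.
hotspot_table <- function() {
  read.table(header = TRUE, stringsAsFactors = FALSE, text = "
gene protein_change chrom pos ref alt weight
KRAS G12C 12 25398285 C A 0.30
KRAS G12V 12 25398284 C A 0.25
KRAS G12D 12 25398284 C T 0.25
KRAS G13D 12 25398281 C T 0.10
KRAS Q61H 12 25380275 T G 0.10
EGFR L858R 7 55259515 T G 0.50
EGFR T790M 7 55249071 C T 0.20
EGFR G719A 7 55241707 G C 0.30
BRAF V600E 7 140453136 A T 1.00
TP53 R175H 17 7578406 C T 0.30
TP53 R248Q 17 7577538 C T 0.35
TP53 R273H 17 7577120 C T 0.35
")
}

hotspot_use_prob <- c(KRAS = 1.0, EGFR = 0.8, BRAF = 0.7, TP53 = 0.15)

default_panel_probs <- function(histology) {
  genes <- panel_definition()$panel_genes
  p <- stats::setNames(rep(0.03, length(genes)), genes)
  if (histology == "LUAD") {
    p[c("TP53", "KRAS", "EGFR", "BRAF", "MET", "ERBB2", "STK11", "KEAP1")] <-
      c(0.50, 0.30, 0.10, 0.05, 0.03, 0.02, 0.10, 0.10)
  } else if (histology == "LUSC") {
    p[c("TP53", "KRAS", "EGFR", "PIK3CA", "CDKN2A", "PTEN", "NOTCH1", "KMT2D")] <-
      c(0.50, 0.02, 0.02, 0.10, 0.08, 0.06, 0.08, 0.08)
  } else {
    validation_error(sprintf("unknown histology '%s'", histology))
  }
  p
}

# Arm-level aberration prior means per histology: elevated arms follow the
# published lung landscape (LUAD: gains 1q/5p/7/8q/20, losses 6/9/17p/18;
# LUSC: gains 3q/5p/8q, losses 3p/5q/8p/9p/13), everything else a low
# baseline.
default_arm_priors <- function() {
  list(
    LUAD = list(
      gain = c(baseline = 0.08, "1q" = 0.45, "5p" = 0.45, "7p" = 0.40,
               "7q" = 0.35, "8q" = 0.40, "20p" = 0.30, "20q" = 0.35),
      loss = c(baseline = 0.08, "6p" = 0.20, "6q" = 0.30, "9p" = 0.40,
               "9q" = 0.30, "17p" = 0.45, "18p" = 0.25, "18q" = 0.30,
               "8p" = 0.30)),
    LUSC = list(
      gain = c(baseline = 0.08, "3q" = 0.60, "5p" = 0.50, "8q" = 0.45,
               "1q" = 0.35, "7p" = 0.30, "12p" = 0.25, "20q" = 0.30),
      loss = c(baseline = 0.08, "3p" = 0.55, "5q" = 0.45, "8p" = 0.40,
               "9p" = 0.45, "13q" = 0.40, "4q" = 0.30, "17p" = 0.40))
  )
}

#' Simulation configuration for synthetic tumor pairs
#'
#' Defaults emulate the statistical structure of paired lung-cancer
#' biopsies profiled by shallow WGS: clonal pairs share truncal arm events
#' and hundreds of truncal exome variants (0-5 of which fall in the 27-gene
#' panel), nonclonal pairs share essentially nothing beyond chance hotspot
#' collisions. Per-bin counts are negative-binomial with mean
#' `depth * r` and variance `mu * (1 + dispersion)` (mild sWGS/FFPE
#' overdispersion above Poisson); purity is uniform on `purity_range`.
#'
#' @param layout a [genome_layout()] (default hg19 at 100-kb bins).
#' @param arm_priors per-histology prior means for arm gain/loss
#'   frequencies (see source for structure); `prior_concentration` is the
#'   Beta concentration of [draw_reference_frequencies()].
#' @param arm_retention,arm_private per-arm truncal retention and private
#'   event probabilities for clonal daughters (defaults 0.95 / 0.05).
#' @param variant_retention truncal variant retention (default 0.95).
#' @param exome_rate,private_exome_rate Poisson means of truncal and private
#'   exome-wide variant counts (defaults 480 / 75).
#' @param panel_probs optional named list `LUAD`/`LUSC` of per-gene mutation
#'   probabilities; `NULL` uses the built-in defaults (TP53 0.5, KRAS 0.3
#'   in LUAD, others 0.02-0.10).
#' @param private_panel_factor scale applied to per-gene probabilities for
#'   private (non-truncal) panel mutations (default 0.1).
#' @param focal_rate Poisson mean of focal events per tumor (default 1).
#' @param focal_len_range focal length as a fraction of the arm (default
#'   0.05-0.3).
#' @param depth mean reads per bin (default 100).
#' @param dispersion excess-Poisson dispersion, `var = mu (1 + dispersion)`
#'   (default 0.05).
#' @param purity_range tumor-cell fraction range (default 0.3-0.9).
#' @param p_luad probability a simulated pair is LUAD rather than LUSC.
#' @param eps reference-frequency clip bound.
#' @return list of class `SimulationConfig`.
#' @export
simulation_config <- function(layout = NULL, arm_priors = default_arm_priors(),
                              prior_concentration = 60,
                              arm_retention = 0.95, arm_private = 0.05,
                              variant_retention = 0.95,
                              exome_rate = 480, private_exome_rate = 75,
                              panel_probs = NULL, private_panel_factor = 0.1,
                              focal_rate = 1, focal_len_range = c(0.05, 0.3),
                              depth = 100, dispersion = 0.05,
                              purity_range = c(0.3, 0.9), p_luad = 0.5,
                              eps = 0.01) {
  if (is.null(layout)) layout <- genome_layout(100000)
  probs <- c(arm_retention, arm_private, variant_retention,
             private_panel_factor, p_luad)
  if (any(probs < 0 | probs > 1)) validation_error("probabilities must be in [0, 1]")
  if (any(c(exome_rate, private_exome_rate, focal_rate) < 0)) {
    validation_error("rates must be >= 0")
  }
  if (depth < 0 || dispersion < 0) validation_error("depth and dispersion must be >= 0")
  structure(list(layout = layout, arm_priors = arm_priors,
                 prior_concentration = prior_concentration,
                 arm_retention = arm_retention, arm_private = arm_private,
                 variant_retention = variant_retention,
                 exome_rate = exome_rate, private_exome_rate = private_exome_rate,
                 panel_probs = panel_probs, private_panel_factor = private_panel_factor,
                 focal_rate = focal_rate, focal_len_range = focal_len_range,
                 depth = depth, dispersion = dispersion,
                 purity_range = purity_range, p_luad = p_luad, eps = eps),
            class = "SimulationConfig")
}

arm_prior_means <- function(config, histology, type) {
  pri <- config$arm_priors[[histology]]
  if (is.null(pri)) validation_error(sprintf("unknown histology '%s'", histology))
  v <- pri[[type]]
  arms <- layout_arms(config$layout)
  out <- stats::setNames(rep(unname(v["baseline"]), length(arms)), arms)
  ov <- setdiff(names(v), "baseline")
  out[ov[ov %in% arms]] <- v[ov[ov %in% arms]]
  out
}

#' Draw a reference arm-frequency table from the configured priors
#'
#' Per arm, gain and loss frequencies are drawn from Beta distributions
#' centered on the configured prior means (concentration
#' `prior_concentration`); a zero prior mean is a point mass at zero. The
#' pair is rescaled if gain + loss would exceed `1 - eps`. Plays the role a
#' large external reference cohort (e.g. SNP-array profiles of several
#' hundred LUAD/LUSC tumors) plays on real data.
#'
#' @param config a [simulation_config()].
#' @param histology "LUAD" or "LUSC".
#' @param seed optional integer seed.
#' @return A [reference_frequencies()] table for the histology.
#' @export
draw_reference_frequencies <- function(config, histology, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mg <- arm_prior_means(config, histology, "gain")
  ml <- arm_prior_means(config, histology, "loss")
  conc <- config$prior_concentration
  draw <- function(m) {
    ifelse(m <= 0, 0, ifelse(m >= 1, 1,
                             stats::rbeta(length(m), m * conc, (1 - m) * conc)))
  }
  g <- draw(mg)
  l <- draw(ml)
  s <- g + l
  over <- s > 1 - config$eps & s > 0
  g[over] <- g[over] * (1 - config$eps) / s[over]
  l[over] <- l[over] * (1 - config$eps) / s[over]
  reference_frequencies(data.frame(arm = names(mg), histology = histology,
                                   p_gain = unname(g), p_loss = unname(l),
                                   stringsAsFactors = FALSE), eps = config$eps)
}

rand_base_pair <- function(n) {
  b <- c("A", "C", "G", "T")
  ref <- sample(b, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(b, r), 1), character(1))
  list(ref = ref, alt = unname(alt))
}

draw_exome_variants <- function(n, layout) {
  if (n == 0) return(variant_records())
  w <- layout$chroms$length
  ch <- sample(layout$chroms$chrom, n, replace = TRUE, prob = w)
  pos <- floor(stats::runif(n) * layout$chroms$length[match(ch, layout$chroms$chrom)]) + 1
  bp <- rand_base_pair(n)
  variant_records(chrom = ch, pos = pos, ref = bp$ref, alt = bp$alt)
}

draw_panel_variant <- function(gene) {
  hs <- hotspot_table()
  p_hot <- hotspot_use_prob[gene]
  if (!is.na(p_hot) && stats::runif(1) < p_hot) {
    h <- hs[hs$gene == gene, ]
    i <- sample(nrow(h), 1, prob = h$weight)
    return(variant_records(chrom = h$chrom[i], pos = h$pos[i], ref = h$ref[i],
                           alt = h$alt[i], gene = gene,
                           protein_change = h$protein_change[i]))
  }
  gm <- nsclc_gene_map()
  g <- gm[gm$gene == gene, ]
  pos <- floor(stats::runif(1) * (g$end - g$start)) + g$start
  bp <- rand_base_pair(1)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  codon <- (pos - g$start) %/% 3 + 1
  variant_records(chrom = g$chrom, pos = pos, ref = bp$ref, alt = bp$alt,
                  gene = gene,
                  protein_change = paste0(sample(aa, 1), codon, sample(aa, 1)))
}

draw_panel_variants <- function(config, histology, scale = 1) {
  probs <- if (!is.null(config$panel_probs)) config$panel_probs[[histology]]
           else default_panel_probs(histology)
  mutated <- names(probs)[stats::runif(length(probs)) < probs * scale]
  if (!length(mutated)) return(variant_records())
  do.call(rbind, lapply(mutated, draw_panel_variant))
}

draw_focal_events <- function(config) {
  n <- stats::rpois(1, config$focal_rate)
  if (n == 0) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      effect = numeric(), stringsAsFactors = FALSE))
  }
  arms <- config$layout$arms
  i <- sample(nrow(arms), n, replace = TRUE)
  len <- (arms$end[i] - arms$start[i]) *
    stats::runif(n, config$focal_len_range[1], config$focal_len_range[2])
  start <- arms$start[i] + floor(stats::runif(n) * (arms$end[i] - arms$start[i] - len))
  data.frame(chrom = arms$chrom[i], start = start, end = start + ceiling(len),
             effect = sample(c(-1, 1), n, replace = TRUE), stringsAsFactors = FALSE)
}

#' Simulate a single tumor genotype
#'
#' Each arm independently takes a gain (+1) with probability `p_gain`, a
#' loss (-1) with probability `p_loss`, else stays neutral; purity is drawn
#' from the configured range; exome variants are a Poisson draw placed
#' uniformly on the genome plus per-gene panel mutations (with hotspot
#' allele reuse); focal events are Poisson.
#'
#' @param freqs a [reference_frequencies()] table (single histology) whose
#'   probabilities drive the arm events.
#' @param config a [simulation_config()].
#' @param seed optional integer seed.
#' @return list of class `TumorGenotype` with `arm_events`, `focal_events`,
#'   `variants`, `purity`, `histology`.
#' @export
simulate_genotype <- function(freqs, config = simulation_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  arms <- layout_arms(config$layout)
  if (!all(arms %in% freqs$arm)) validation_error("freqs do not cover all layout arms")
  f <- freqs[match(arms, freqs$arm), ]
  u <- stats::runif(length(arms))
  ev <- ifelse(u < f$p_gain, 1, ifelse(u < f$p_gain + f$p_loss, -1, 0))
  histology <- f$histology[1]
  variants <- rbind(draw_exome_variants(stats::rpois(1, config$exome_rate), config$layout),
                    draw_panel_variants(config, histology))
  structure(list(arm_events = stats::setNames(ev, arms),
                 focal_events = draw_focal_events(config),
                 variants = variants,
                 purity = stats::runif(1, config$purity_range[1], config$purity_range[2]),
                 histology = histology),
            class = "TumorGenotype")
}

derive_one_daughter <- function(ancestor, config) {
  ev <- ancestor$arm_events
  keep <- stats::runif(length(ev)) < config$arm_retention
  ev[!keep | ev == 0] <- 0
  ev[ancestor$arm_events == 0] <- 0
  free <- ev == 0
  priv <- free & stats::runif(length(ev)) < config$arm_private
  ev[priv] <- sample(c(-1, 1), sum(priv), replace = TRUE)
  fe <- ancestor$focal_events
  fe <- fe[stats::runif(nrow(fe)) < config$arm_retention, , drop = FALSE]
  fe <- rbind(fe, draw_focal_events(config))
  v <- ancestor$variants
  v <- v[stats::runif(nrow(v)) < config$variant_retention, , drop = FALSE]
  v <- rbind(v,
             draw_exome_variants(stats::rpois(1, config$private_exome_rate), config$layout),
             draw_panel_variants(config, ancestor$histology,
                                 scale = config$private_panel_factor))
  # a private hit may duplicate a truncal hotspot; identity is DNA-level
  v <- v[!duplicated(variant_keys(v)), , drop = FALSE]
  structure(list(arm_events = ev, focal_events = fe, variants = v,
                 purity = stats::runif(1, config$purity_range[1], config$purity_range[2]),
                 histology = ancestor$histology),
            class = "TumorGenotype")
}

#' Derive two clonal daughter tumors from an ancestor
#'
#' Each daughter keeps every ancestral arm event with probability
#' `arm_retention`, gains private arm events with probability `arm_private`
#' (on arms left free), keeps each truncal variant with
#' `variant_retention`, adds private Poisson variants, and draws an
#' independent purity.
#'
#' @param ancestor a [simulate_genotype()] result.
#' @param config a [simulation_config()].
#' @param seed optional integer seed.
#' @return list of two `TumorGenotype`s.
#' @export
derive_clonal_daughters <- function(ancestor, config = simulation_config(),
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  list(derive_one_daughter(ancestor, config),
       derive_one_daughter(ancestor, config))
}

#' Emit noisy binned read counts for a genotype
#'
#' Every bin's expected relative copy ratio is
#' `r = purity * c / 2 + (1 - purity)` with `c = 2` plus the arm and focal
#' event effects covering the bin; counts are negative-binomial with mean
#' `depth * r` and variance `mu * (1 + dispersion)`. Log2 ratios are left
#' unset (computed by [normalize_log2()]). Bins on excluded territory are
#' emitted at `c = 2` and flagged unusable.
#'
#' @param genotype a `TumorGenotype`.
#' @param layout a [genome_layout()] (defaults to the config's).
#' @param config a [simulation_config()].
#' @param seed optional integer seed.
#' @param sample_id sample identifier.
#' @return A [binned_profile()] of raw counts.
#' @export
emit_binned_counts <- function(genotype, layout = config$layout,
                               config = simulation_config(), seed = NULL,
                               sample_id = "tumor") {
  if (!is.null(seed)) set.seed(seed)
  if (config$depth <= 0) validation_error("depth must be > 0")
  bins <- layout$bins
  cn <- rep(2, nrow(bins))
  on_arm <- !is.na(bins$arm)
  cn[on_arm] <- cn[on_arm] + genotype$arm_events[bins$arm[on_arm]]
  fe <- genotype$focal_events
  mid <- (bins$start + bins$end) / 2
  for (k in seq_len(nrow(fe))) {
    hit <- bins$chrom == fe$chrom[k] & mid >= fe$start[k] & mid < fe$end[k]
    cn[hit] <- pmax(0, cn[hit] + fe$effect[k])
  }
  r <- genotype$purity * cn / 2 + (1 - genotype$purity)
  mu <- config$depth * r
  size <- ifelse(mu > 0, mu / config$dispersion, 1)
  counts <- ifelse(mu > 0, stats::rnbinom(length(mu), mu = mu, size = size), 0)
  binned_profile(sample_id,
                 data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
                            readcount = counts, log2ratio = NA_real_,
                            use = on_arm, stringsAsFactors = FALSE),
                 bin_size = layout$bin_size,
                 metadata = list(total_reads = sum(counts),
                                 histology = genotype$histology,
                                 purity = genotype$purity,
                                 tumor_pct = 100 * genotype$purity))
}

wrap_tumor <- function(genotype, config, sample_id) {
  profile <- emit_binned_counts(genotype, config$layout, config,
                                sample_id = sample_id)
  list(sample_id = sample_id, genotype = genotype, profile = profile,
       variants = genotype$variants, tumor_pct = 100 * genotype$purity,
       total_reads = profile$metadata$total_reads)
}

#' Simulate a cohort of clonal and nonclonal tumor pairs
#'
#' Clonal pairs are two daughters of one simulated ancestor (two biopsies of
#' the same tumor); nonclonal pairs are two independent genotypes of the
#' same histologic subtype (biopsies of different patients). Reference
#' frequencies per histology are drawn once per cohort and attached as the
#' `freqs` attribute; truth labels, histology and timing are attached per
#' pair. Deterministic given the seed.
#'
#' @param n_clonal,n_nonclonal pair counts.
#' @param config a [simulation_config()].
#' @param seed integer seed (default 1).
#' @return list of `SimulatedPair` objects, class `SimulatedCohort`, with
#'   attributes `freqs` (named list of [reference_frequencies()]) and
#'   `config`.
#' @export
simulate_cohort <- function(n_clonal, n_nonclonal, config = simulation_config(),
                            seed = 1) {
  stopifnot(n_clonal >= 0, n_nonclonal >= 0)
  set.seed(seed)
  freqs <- list(LUAD = draw_reference_frequencies(config, "LUAD"),
                LUSC = draw_reference_frequencies(config, "LUSC"))
  pairs <- vector("list", n_clonal + n_nonclonal)
  truth <- rep(c("clonal", "nonclonal"), c(n_clonal, n_nonclonal))
  for (i in seq_along(pairs)) {
    histology <- if (stats::runif(1) < config$p_luad) "LUAD" else "LUSC"
    pid <- sprintf("pair%03d", i)
    if (truth[i] == "clonal") {
      anc <- simulate_genotype(freqs[[histology]], config)
      d <- derive_clonal_daughters(anc, config)
      ta <- wrap_tumor(d[[1]], config, paste0(pid, "_A"))
      tb <- wrap_tumor(d[[2]], config, paste0(pid, "_B"))
    } else {
      ta <- wrap_tumor(simulate_genotype(freqs[[histology]], config), config,
                       paste0(pid, "_A"))
      tb <- wrap_tumor(simulate_genotype(freqs[[histology]], config), config,
                       paste0(pid, "_B"))
    }
    pairs[[i]] <- structure(
      list(pair_id = pid, tumor_a = ta, tumor_b = tb, truth = truth[i],
           histology = histology,
           timing = sample(c("synchronous", "metachronous"), 1)),
      class = "SimulatedPair")
  }
  structure(pairs, class = "SimulatedCohort", freqs = freqs, config = config)
}

#' Write a simulated cohort to disk
#'
#' One bin-table TSV and one minimal VCF per tumor, plus a cohort manifest
#' TSV (pair id, tumor ids, truth, histology, timing, purity) and the drawn
#' reference-frequency tables.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(p) {
    for (t in list(p$tumor_a, p$tumor_b)) {
      write_bin_table(t$profile, file.path(dir, paste0(t$sample_id, "_bins.tsv")))
      write_vcf_minimal(t$variants, file.path(dir, paste0(t$sample_id, ".vcf")))
    }
    data.frame(pair_id = p$pair_id, tumor_a = p$tumor_a$sample_id,
               tumor_b = p$tumor_b$sample_id, truth = p$truth,
               histology = p$histology, timing = p$timing,
               purity_a = fmt6(p$tumor_a$genotype$purity),
               purity_b = fmt6(p$tumor_b$genotype$purity),
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  freqs <- attr(cohort, "freqs")
  for (h in names(freqs)) {
    write_reference_freq(freqs[[h]], file.path(dir, paste0("reference_", h, ".tsv")))
  }
  invisible(dir)
}
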