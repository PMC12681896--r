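#' Conventional NSCLC mutation panel definition
#'
#' The default 27-gene panel: the guideline oncogenes for predictive
#' biomarker testing in NSCLC (BRAF, EGFR, ERBB2, KRAS, MET) plus TP53 and
#' 21 further genes recurrently mutated in NSCLC. Subsets drive the decision
#' tree: discordance of `definitive_driver_genes` between the two tumors is
#' definitive evidence of independence; discordance involving
#' `cautious_genes` (KRAS, TP53 — subclonal or convergent in practice) is
#' downgraded to "probable nonclonal"; sharing a single variant matching a
#' `cautious_hotspots` pattern (recurrent hotspots two independent tumors
#' can hit by chance) is downgraded to "inconclusive".
#'
#' @param panel_genes character vector of panel gene symbols.
#' @param definitive_driver_genes subset whose discordance is definitive.
#' @param cautious_genes subset whose discordance is downgraded.
#' @param cautious_hotspots data.frame with `gene` and `codon` columns.
#' @return list of class `PanelDefinition`.
#' @export
panel_definition <- function(
    panel_genes = c("BRAF", "EGFR", "ERBB2", "KRAS", "MET", "TP53",
                    "PIK3CA", "STK11", "KEAP1", "NF1", "RB1", "CDKN2A",
                    "SMARCA4", "ARID1A", "PTEN", "ATM", "CTNNB1", "NRAS",
                    "MAP2K1", "RIT1", "U2AF1", "RBM10", "SETD2", "MGA",
                    "FAT1", "NOTCH1", "KMT2D"),
    definitive_driver_genes = c("EGFR", "BRAF", "ERBB2", "MET"),
    cautious_genes = c("KRAS", "TP53"),
    cautious_hotspots = data.frame(gene = "KRAS", codon = c(12, 13, 61))) {
  if (length(intersect(definitive_driver_genes, cautious_genes))) {
    validation_error("cautious_genes and definitive_driver_genes must be disjoint")
  }
  if (!all(definitive_driver_genes %in% panel_genes) ||
      !all(cautious_genes %in% panel_genes) ||
      !all(cautious_hotspots$gene %in% panel_genes)) {
    validation_error("all gene subsets must be contained in panel_genes")
  }
  structure(list(panel_genes = panel_genes,
                 definitive_driver_genes = definitive_driver_genes,
                 cautious_genes = cautious_genes,
                 cautious_hotspots = cautious_hotspots),
            class = "PanelDefinition")
}

#' Read / write a panel definition as YAML
#' @param path YAML file path.
#' @return A [panel_definition()].
#' @export
read_panel_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  hs <- if (!is.null(y$cautious_hotspots)) {
    data.frame(gene = vapply(y$cautious_hotspots, `[[`, "", "gene"),
               codon = vapply(y$cautious_hotspots, function(h) as.numeric(h$codon), 0))
  } else data.frame(gene = character(), codon = numeric())
  panel_definition(panel_genes = unlist(y$panel_genes),
                   definitive_driver_genes = unlist(y$definitive_driver_genes),
                   cautious_genes = unlist(y$cautious_genes),
                   cautious_hotspots = hs)
}

#' @rdname read_panel_yaml
#' @param panel a [panel_definition()].
#' @export
write_panel_yaml <- function(panel, path) {
  yaml::write_yaml(list(
    panel_genes = panel$panel_genes,
    definitive_driver_genes = panel$definitive_driver_genes,
    cautious_genes = panel$cautious_genes,
    cautious_hotspots = lapply(seq_len(nrow(panel$cautious_hotspots)), function(i) {
      list(gene = panel$cautious_hotspots$gene[i],
           codon = panel$cautious_hotspots$codon[i])
    })), path)
  invisible(path)
}

variant_keys <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")

#' Heuristic germline filter for tumors without a matched normal
#'
#' Removes variants that are (1) common in the population
#' (`population_af > max_population_af`), (2) on a supplied blacklist of
#' recurrent artifacts/germline sites, or (3) have a variant allele fraction
#' inside the heterozygous-germline window while their population frequency
#' is unknown. Retained variants are unchanged; the filter is idempotent.
#'
#' @param variants a [variant_records()] data.frame.
#' @param max_population_af population-frequency cutoff (default 0.001).
#' @param vaf_window heterozygous VAF window (default `c(0.45, 0.55)`),
#'   applied only to variants with missing `population_af`; `NULL` disables.
#' @param blacklist optional [variant_records()] of sites to drop.
#' @return The filtered variant data.frame.
#' @export
filter_germline <- function(variants, max_population_af = 0.001,
                            vaf_window = c(0.45, 0.55), blacklist = NULL) {
  if (nrow(variants) == 0) return(variants)
  drop <- !is.na(variants$population_af) & variants$population_af > max_population_af
  if (!is.null(blacklist) && nrow(blacklist) > 0) {
    drop <- drop | variant_keys(variants) %in% variant_keys(blacklist)
  }
  if (!is.null(vaf_window)) {
    drop <- drop | (is.na(variants$population_af) & !is.na(variants$vaf) &
                      variants$vaf >= vaf_window[1] & variants$vaf <= vaf_window[2])
  }
  variants[!drop, , drop = FALSE]
}

#' Variants shared by two tumors at the DNA level
#'
#' Intersection keyed on exact (chrom, pos, ref, alt); gene and protein
#' annotation are ignored for identity.
#'
#' @param a,b [variant_records()] data.frames.
#' @return The shared subset of `a`.
#' @export
shared_variants <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(a[0, , drop = FALSE])
  a[variant_keys(a) %in% variant_keys(b), , drop = FALSE]
}

#' Gold-standard clonality from exome-wide sharing
#'
#' A tumor pair is clonal iff it shares strictly more than `threshold`
#' somatic variants at the DNA level (default: more than two).
#'
#' @param a,b germline-filtered exome-wide [variant_records()].
#' @param threshold sharing threshold (strict, default 2).
#' @return list of class `GoldStandardCall` with `shared_count` and `class`.
#' @export
gold_standard_class <- function(a, b, threshold = 2) {
  n <- nrow(shared_variants(a, b))
  structure(list(shared_count = n,
                 class = if (n > threshold) "clonal" else "nonclonal"),
            class = "GoldStandardCall")
}

#' Restrict variants to the mutation panel
#'
#' Keeps variants whose gene symbol is in the panel. Variants without a gene
#' annotation are resolved against an optional gene-interval map; otherwise
#' they are dropped with a warning.
#'
#' @param variants a [variant_records()] data.frame.
#' @param panel a [panel_definition()].
#' @param gene_map optional data.frame with `gene`, `chrom`, `start`, `end`
#'   (1-based inclusive) used to annotate unannotated variants.
#' @return The panel-restricted variant data.frame.
#' @export
restrict_to_panel <- function(variants, panel = panel_definition(), gene_map = NULL) {
  if (nrow(variants) == 0) return(variants)
  gene <- variants$gene
  una <- which(is.na(gene))
  if (length(una) && !is.null(gene_map)) {
    for (i in una) {
      hit <- which(gene_map$chrom == variants$chrom[i] &
                     gene_map$start <= variants$pos[i] &
                     gene_map$end >= variants$pos[i])
      if (length(hit)) gene[i] <- gene_map$gene[hit[1]]
    }
    una <- which(is.na(gene))
  }
  if (length(una)) {
    warning(sprintf("dropping %d variant(s) without gene annotation", length(una)))
  }
  variants$gene <- gene
  variants[!is.na(gene) & gene %in% panel$panel_genes, , drop = FALSE]
}

# codon number from a protein-change string like "G12C", "p.Q61H", "R273*"
protein_codon <- function(protein_change) {
  s <- sub("^p\\.", "", protein_change)
  r <- regexpr("[0-9]+", s)
  out <- rep(NA_real_, length(s))
  ok <- !is.na(s) & r > 0
  out[ok] <- as.numeric(substr(s[ok], r[ok],
                               r[ok] + attr(r, "match.length")[ok] - 1))
  out
}

is_cautious_hotspot <- function(variant_row, panel) {
  hs <- panel$cautious_hotspots
  if (is.na(variant_row$gene) || nrow(hs) == 0) return(FALSE)
  if (is.na(variant_row$protein_change)) return(FALSE)  # no annotation, no downgrade
  codon <- protein_codon(variant_row$protein_change)
  any(hs$gene == variant_row$gene & hs$codon == codon, na.rm = TRUE)
}

#' Adapted IASLC decision tree on panel mutations
#'
#' Classifies a tumor pair from its panel-restricted, germline-filtered
#' variant sets into clonal / nonclonal / probable nonclonal / inconclusive:
#'
#' 1. two or more shared panel variants: **clonal**;
#' 2. exactly one shared variant: **inconclusive** if it matches a cautious
#'    hotspot pattern (e.g. KRAS codon 12/13/61), else **clonal**;
#' 3. nothing shared and both tumors carry panel variants: **nonclonal**
#'    when each tumor carries a definitive-driver variant (necessarily
#'    different, e.g. EGFR vs BRAF); otherwise **probable nonclonal**
#'    (covers discordant KRAS, discordant TP53 and discordance of
#'    non-definitive genes);
#' 4. at least one tumor without panel variants: **inconclusive**.
#'
#' @param a_panel,b_panel panel-restricted [variant_records()].
#' @param panel a [panel_definition()].
#' @return list of class `MutationClonalityCall` with `class`,
#'   `shared_count`, `shared` (the shared variants) and `rationale`.
#' @export
classify_mutational <- function(a_panel, b_panel, panel = panel_definition()) {
  sh <- shared_variants(a_panel, b_panel)
  n_shared <- nrow(sh)
  mk <- function(class, rationale) {
    structure(list(class = class, shared_count = n_shared, shared = sh,
                   rationale = rationale), class = "MutationClonalityCall")
  }
  if (n_shared >= 2) {
    return(mk("clonal", sprintf("%d shared panel variants", n_shared)))
  }
  if (n_shared == 1) {
    if (is_cautious_hotspot(sh[1, ], panel)) {
      return(mk("inconclusive",
                sprintf("single shared variant is a cautious hotspot (%s %s)",
                        sh$gene[1], sh$protein_change[1])))
    }
    return(mk("clonal", "single shared non-hotspot panel variant"))
  }
  if (nrow(a_panel) == 0 || nrow(b_panel) == 0) {
    return(mk("inconclusive", "at least one tumor without panel variants"))
  }
  a_drv <- any(a_panel$gene %in% panel$definitive_driver_genes)
  b_drv <- any(b_panel$gene %in% panel$definitive_driver_genes)
  if (a_drv && b_drv) {
    return(mk("nonclonal", "discordant definitive driver variants"))
  }
  mk("probable_nonclonal", "discordant panel variants without definitive drivers on both sides")
}

#' @export
print.MutationClonalityCall <- function(x, ...) {
  cat(sprintf("Mutation tier: %s (%d shared) - %s\n", x$class, x$shared_count,
              x$rationale))
  invisible(x)
}
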