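#' Genome saturation of a screen
#'
#' The fraction of annotated autosomal protein-coding genes that the screen
#' interrogated with damaging and/or null alleles tested at least twice in
#' the homozygous state.
#'
#' @param genes_dn_hom_x2 Number of autosomal protein-coding genes carrying
#'   damaging/null alleles screened two or more times as homozygotes.
#' @param total_autosomal_genes Number of annotated autosomal protein-coding
#'   genes (default 20000).
#' @return The saturation fraction.
#' @examples
#' genome_saturation(70, 20000)  # 0.0035, i.e. 0.35%
#' @export
genome_saturation <- function(genes_dn_hom_x2, total_autosomal_genes = 20000) {
  if (!is.numeric(total_autosomal_genes) || total_autosomal_genes <= 0) {
    stop_bad_arg("`total_autosomal_genes` must be positive.")
  }
  if (genes_dn_hom_x2 < 0 || genes_dn_hom_x2 > total_autosomal_genes) {
    stop_bad_arg(
      "`genes_dn_hom_x2` must lie between 0 and `total_autosomal_genes`.")
  }
  genes_dn_hom_x2 / total_autosomal_genes
}

#' Tally genome saturation from a screen's own tables
#'
#' Counts the genes whose mutations are annotated damaging or null
#' (`probably_damaging` or `probably_null`) and were phenotypically
#' screened in at least `min_hom` homozygous-mutant mice, then divides by
#' the annotated autosomal gene total.
#'
#' @param screen An `amm_screen` object.
#' @param total_autosomal_genes Denominator gene count (default 20000).
#' @param min_hom Minimum screened homozygotes per gene (default 2).
#' @return One-row tibble with `n_genes`, `total_autosomal_genes`,
#'   `saturation`.
#' @export
screen_saturation <- function(screen, total_autosomal_genes = 20000,
                              min_hom = 2) {
  check_screen_tables(screen)
  zyg <- pedigree_stats(screen)$zygosity
  tally <- screen$mutations %>%
    filter(.data$damage_class %in% c("probably_damaging", "probably_null")) %>%
    left_join(zyg, by = c(id = "mutation_id", "pedigree_id")) %>%
    filter(.data$hom_var_screened >= min_hom) %>%
    distinct(.data$gene)
  tibble(n_genes = nrow(tally),
         total_autosomal_genes = total_autosomal_genes,
         saturation = genome_saturation(nrow(tally), total_autosomal_genes))
}

#' Genomic footprint of a modifier class
#'
#' Extrapolates from the number of detected modifier mutations of one
#' direction class to the total number of genes in which loss of function
#' would produce that phenotype class, as hits divided by genome
#' saturation. The headline figure is rounded to the nearest hundred
#' (halves away from zero); the raw value is always reported alongside.
#'
#' @param n_hits Detected modifier mutations of the class.
#' @param saturation Genome saturation fraction (in (0, 1]).
#' @return One-row tibble with `n_hits`, `saturation`, `footprint`,
#'   `footprint_rounded`.
#' @examples
#' genomic_footprint(7, 0.0035)  # about 2000 genes
#' genomic_footprint(5, 0.0035)  # about 1400 genes
#' @export
genomic_footprint <- function(n_hits, saturation) {
  if (!is.numeric(saturation) || saturation <= 0 || saturation > 1) {
    stop_bad_arg("`saturation` must lie in (0, 1].")
  }
  if (!is.numeric(n_hits) || n_hits < 0) {
    stop_bad_arg("`n_hits` must be non-negative.")
  }
  fp <- n_hits / saturation
  tibble(n_hits = n_hits, saturation = saturation, footprint = fp,
         footprint_rounded = round_half_away(fp / 100) * 100)
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
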