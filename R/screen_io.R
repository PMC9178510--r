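# On-disk screen layout (plain text, UTF-8, `NA` for missing, ids unquoted):
#   mutations.tsv  - VCF-lite TSV, header "#id chrom pos ref alt gene
#                    damage_class pedigree_id" (1-based positions)
#   genotypes.tsv  - mouse_id plus one REF/HET/VAR/NA column per mutation id
#   phenotypes.csv - mouse_id,onset_week,event with event in {1,0}
#   pedigree.tsv   - mouse_id pedigree_id generation sex dam_id sire_id
#   manifest.yaml  - seed and simulation parameters of the run

#' Write a screen to a directory of plain-text tables
#'
#' @param screen An `amm_screen` object.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @seealso [read_screen()] for the lossless inverse.
#' @export
write_screen <- function(screen, dir) {
  check_screen_tables(screen)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) {
    abort(paste0("cannot create screen directory: ", dir),
          class = "ammscreen_io_error")
  }
  mut <- screen$mutations %>%
    select("id", "chrom", "pos", ref = "ref_allele", alt = "alt_allele",
           "gene", "damage_class", "pedigree_id") %>%
    rename(`#id` = "id")
  readr::write_tsv(mut, file.path(dir, "mutations.tsv"))
  readr::write_tsv(screen$genotypes, file.path(dir, "genotypes.tsv"))
  ph <- mutate(screen$phenotypes, event = as.integer(.data$event))
  readr::write_csv(ph, file.path(dir, "phenotypes.csv"))
  readr::write_tsv(screen$pedigree, file.path(dir, "pedigree.tsv"))
  manifest <- screen$params %||% list()
  manifest$effects <- if (!is.null(manifest$effects))
    lapply(seq_len(nrow(manifest$effects)),
           function(i) as.list(manifest$effects[i, ]))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read and validate a screen directory
#'
#' Reads the four tables written by [write_screen()] and cross-validates
#' them: every genotyped or phenotyped mouse must have a pedigree row,
#' phenotyped mice must be female G2/G3 (screening is restricted to
#' females), genotype cells must be REF/HET/VAR/NA, onset weeks must lie in
#' (0, horizon] with censored records exactly at the horizon.
#'
#' @param dir Directory containing the screen tables.
#' @param horizon Censoring horizon in weeks (default 40).
#' @return An `amm_screen` object.
#' @export
read_screen <- function(dir, horizon = 40) {
  files <- c(mutations = "mutations.tsv", genotypes = "genotypes.tsv",
             phenotypes = "phenotypes.csv", pedigree = "pedigree.tsv")
  paths <- file.path(dir, files)
  missing <- files[!file.exists(paths)]
  if (length(missing)) {
    abort(paste0("screen directory ", dir, " lacks: ",
                 paste(missing, collapse = ", ")),
          class = "ammscreen_io_error")
  }
  mut <- readr::read_tsv(paths[1], show_col_types = FALSE,
                         na = "NA", progress = FALSE)
  names(mut)[names(mut) == "#id"] <- "id"
  mut <- mut %>%
    rename(ref_allele = "ref", alt_allele = "alt") %>%
    mutate(chrom = as.character(.data$chrom), pos = as.integer(.data$pos)) %>%
    select("id", "chrom", "pos", "gene", "ref_allele", "alt_allele",
           "damage_class", "pedigree_id")
  geno <- readr::read_tsv(paths[2], show_col_types = FALSE, na = "NA",
                          progress = FALSE,
                          col_types = readr::cols(.default = "c"))
  ph <- readr::read_csv(paths[3], show_col_types = FALSE, na = "NA",
                        progress = FALSE)
  ph <- mutate(ph, event = as.logical(as.integer(.data$event)))
  ped <- readr::read_tsv(paths[4], show_col_types = FALSE, na = "NA",
                         progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  params <- NULL
  if (file.exists(file.path(dir, "manifest.yaml"))) {
    params <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
    if (!is.null(params$effects)) {
      params$effects <- bind_rows(lapply(params$effects, as_tibble))
    }
  }
  screen <- structure(list(pedigree = ped, mutations = mut,
                           genotypes = geno, phenotypes = ph,
                           params = params),
                      class = "amm_screen")
  validate_screen(screen, horizon = horizon)
  screen
}

#' Validate the internal consistency of a screen
#'
#' @inheritParams read_screen
#' @param screen An `amm_screen` object or equivalent list of tables.
#' @return `screen`, invisibly; aborts with a validation error naming the
#'   offending table/row otherwise.
#' @export
validate_screen <- function(screen, horizon = 40) {
  check_screen_tables(screen)
  ped <- screen$pedigree
  fail <- function(msg) abort(msg, class = "ammscreen_validation_error")

  need_ped <- c("mouse_id", "pedigree_id", "generation", "sex", "dam_id",
                "sire_id")
  if (!all(need_ped %in% names(ped))) fail("pedigree table: missing columns.")
  if (anyDuplicated(ped$mouse_id)) fail("pedigree table: duplicate mouse_id.")
  if (!all(ped$generation %in% c("G0", "G1", "G2", "G3", "WT"))) {
    fail("pedigree table: unknown generation label.")
  }
  if (!all(ped$sex %in% c("F", "M"))) fail("pedigree table: sex must be F/M.")

  mut <- screen$mutations
  if (anyDuplicated(mut$id)) fail("mutation table: duplicate mutation id.")
  if (any(mut$pos < 1)) fail("mutation table: positions must be >= 1.")
  if (any(mut$ref_allele == mut$alt_allele)) {
    fail("mutation table: ref and alt allele identical.")
  }
  if (!all(mut$damage_class %in% DAMAGE_CLASSES)) {
    fail("mutation table: unknown damage_class.")
  }

  geno <- screen$genotypes
  if (!"mouse_id" %in% names(geno)) fail("genotype table: no mouse_id.")
  orphan <- setdiff(geno$mouse_id, ped$mouse_id)
  if (length(orphan)) {
    fail(paste0("genotype table: mouse without pedigree row: ",
                orphan[1]))
  }
  mut_cols <- setdiff(names(geno), "mouse_id")
  if (!setequal(mut_cols, mut$id)) {
    fail("genotype table: columns do not match mutation ids.")
  }
  for (m in mut_cols) {
    bad <- !is.na(geno[[m]]) & !geno[[m]] %in% GENO_LEVELS
    if (any(bad)) {
      fail(sprintf("genotype table: malformed call in column %s (%s).",
                   m, geno[[m]][which(bad)[1]]))
    }
  }

  ph <- screen$phenotypes
  if (!all(c("mouse_id", "onset_week", "event") %in% names(ph))) {
    fail("phenotype table: missing columns.")
  }
  orphan <- setdiff(ph$mouse_id, ped$mouse_id)
  if (length(orphan)) {
    fail(paste0("phenotype table: row for unknown mouse: ", orphan[1]))
  }
  info <- ped[match(ph$mouse_id, ped$mouse_id), ]
  if (any(info$sex != "F")) {
    fail(paste0("phenotype table: male mouse phenotyped (screening is ",
                "restricted to females): ",
                ph$mouse_id[which(info$sex != "F")[1]]))
  }
  if (any(!info$generation %in% c("G2", "G3"))) {
    fail(paste0("phenotype table: phenotyped mouse is not G2/G3: ",
                ph$mouse_id[which(!info$generation %in% c("G2", "G3"))[1]]))
  }
  if (any(ph$onset_week <= 0 | ph$onset_week > horizon)) {
    fail("phenotype table: onset_week outside (0, horizon].")
  }
  if (any(!ph$event & ph$onset_week != horizon)) {
    fail("phenotype table: censored record not at the horizon.")
  }

  # Mendelian consistency where parents are genotyped: an offspring cannot
  # be homozygous mutant if its recorded dam is homozygous reference.
  dam_of <- setNames(ped$dam_id, ped$mouse_id)
  for (m in mut_cols) {
    calls <- setNames(geno[[m]], geno$mouse_id)
    kids <- names(calls)[!is.na(calls) & calls == "VAR"]
    dams <- dam_of[kids]
    dams <- dams[!is.na(dams) & dams %in% names(calls)]
    bad <- dams[!is.na(calls[dams]) & calls[dams] == "REF"]
    if (length(bad)) {
      fail(sprintf(
        "genotype table: Mendelian violation at %s (VAR offspring of REF dam %s).",
        m, bad[1]))
    }
  }
  invisible(screen)
}
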