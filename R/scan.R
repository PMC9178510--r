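#' Encode genotype calls as a numeric dose under an inheritance model
#'
#' Maps zygosity calls to the dose covariate of the linkage model:
#' recessive REF/HET/VAR -> 0/0/1, additive -> 0/0.5/1, dominant -> 0/1/1.
#' Missing calls (`NA`) stay `NA` and are dropped, together with their
#' phenotype rows, by [lrt_association()].
#'
#' @param model `"recessive"`, `"additive"` or `"dominant"`.
#' @param calls Character vector of `"REF"`, `"HET"`, `"VAR"` or `NA`.
#' @return Numeric dose vector of the same length.
#' @examples
#' encode("additive", c("REF", "HET", "VAR"))
#' @export
encode <- function(model, calls) {
  model <- match.arg(model, INHERITANCE_MODELS)
  bad <- !is.na(calls) & !calls %in% GENO_LEVELS
  if (any(bad)) {
    stop_bad_arg(paste0("unknown genotype call token(s): ",
                        paste(unique(calls[bad]), collapse = ", ")))
  }
  het <- switch(model, recessive = 0, additive = 0.5, dominant = 1)
  unname(c(REF = 0, HET = het, VAR = 1)[calls])
}

#' Single-locus linkage scan of a screen
#'
#' The core mapping step: for every mutation in every pedigree and every
#' requested inheritance model, tests association between genotype dose and
#' censored onset age with a Weibull proportional-hazards likelihood-ratio
#' test ([lrt_association()]), then applies a Bonferroni correction with
#' family size m = (mutations in the pedigree) x (models), separately per
#' pedigree. Direction is read off the sign of the fitted dose effect:
#' a positive log hazard ratio accelerates onset, a negative one
#' suppresses/delays it.
#'
#' @param screen An `amm_screen` object (or list with `pedigree`,
#'   `mutations`, `genotypes`, `phenotypes` tibbles).
#' @param models Inheritance models to test (default all three).
#' @param mixed If `TRUE`, include a dam-level frailty term in both null
#'   and alternative fits (G3 mice cluster by their G2 dam).
#' @return A tibble, one row per mutation x model: `pedigree_id`,
#'   `mutation_id`, `model`, `n_ref`, `n_het`, `n_var`, `beta`, `lrt_stat`,
#'   `p_raw`, `p_bonferroni` (= min(1, p_raw * m)), `n_tests`, `direction`
#'   (`"accelerate"`, `"suppress"` or `"none"`), `flag`.
#' @examples
#' scr <- simulate_screen(n_pedigrees = 1, n_mutations_per_founder = 5,
#'                        g2_per_g1 = 4, g3_per_g2 = 6, seed = 3)
#' amm_scan(scr)
#' @export
amm_scan <- function(screen, models = INHERITANCE_MODELS, mixed = FALSE) {
  models <- match.arg(models, INHERITANCE_MODELS, several.ok = TRUE)
  check_screen_tables(screen)
  ana <- scan_frame(screen)
  if (nrow(ana) == 0) stop_bad_arg("no screenable (phenotyped) mice found.")
  res <- lapply(split(screen$mutations$id, screen$mutations$pedigree_id),
                function(mut_ids) {
    ped_id <- screen$mutations$pedigree_id[match(mut_ids[1],
                                                 screen$mutations$id)]
    frame <- ana[ana$pedigree_id == ped_id, , drop = FALSE]
    if (nrow(frame) == 0) return(NULL)
    m_tests <- length(mut_ids) * length(models)
    null_cache <- new.env(parent = emptyenv())
    rows <- lapply(mut_ids, function(mid) {
      calls <- frame[[mid]]
      counts <- c(n_ref = sum(calls == "REF", na.rm = TRUE),
                  n_het = sum(calls == "HET", na.rm = TRUE),
                  n_var = sum(calls == "VAR", na.rm = TRUE))
      per_model <- lapply(models, function(mod) {
        dose <- encode(mod, calls)
        fit <- lrt_cached(frame, dose, mixed, null_cache)
        tibble(pedigree_id = ped_id, mutation_id = mid, model = mod,
               n_ref = counts[["n_ref"]], n_het = counts[["n_het"]],
               n_var = counts[["n_var"]], beta = fit$beta,
               lrt_stat = fit$lrt_stat, p_raw = fit$p_raw,
               p_bonferroni = pmin(1, fit$p_raw * m_tests),
               n_tests = m_tests,
               direction = lrt_direction(fit), flag = fit$flag)
      })
      bind_rows(per_model)
    })
    bind_rows(rows)
  })
  bind_rows(res)
}

lrt_direction <- function(fit) {
  if (fit$flag != "ok" || is.na(fit$beta) || fit$beta == 0) "none"
  else if (fit$beta > 0) "accelerate"
  else "suppress"
}

# The null (no-dose) fit depends only on which phenotype rows survive the
# missing-genotype drop, so it is shared across the mutations and models of
# a pedigree; cache it keyed on the retained-row pattern.
lrt_cached <- function(frame, dose, mixed, null_cache) {
  cluster <- if (mixed) frame$cluster_id
  keep <- !is.na(dose)
  key <- paste(which(keep), collapse = ",")
  cached <- get0(key, envir = null_cache)
  time <- frame$onset_week[keep]
  event <- as.logical(frame$event)[keep]
  d <- dose[keep]
  cl <- if (mixed) cluster[keep]
  out <- structure(
    list(lrt_stat = NA_real_, p_raw = NA_real_, beta = NA_real_,
         loglik_null = NA_real_, loglik_alt = NA_real_,
         n = length(time), flag = "not_testable", mixed = mixed),
    class = "amm_lrt")
  if (length(time) < 4 || length(unique(d)) < 2 || !any(event)) return(out)
  if (is.null(cached)) {
    cached <- fit_weibull_ph(time, event, dose = NULL, cluster = cl)
    assign(key, cached, envir = null_cache)
  }
  alt_fit <- fit_weibull_ph(time, event, dose = d, cluster = cl)
  if (!cached$converged || !alt_fit$converged) {
    out$flag <- "no_convergence"
    return(out)
  }
  lrt <- max(0, 2 * (alt_fit$loglik - cached$loglik))
  out$lrt_stat <- lrt
  out$p_raw <- lrt_pvalue(lrt, sum(event), mixed = mixed)
  out$beta <- alt_fit$beta
  out$loglik_null <- cached$loglik
  out$loglik_alt <- alt_fit$loglik
  out$flag <- "ok"
  out
}

# Analysis frame: phenotyped female G2/G3 mice joined to their genotypes,
# with a dam-cluster label (G3 cluster by dam, G2 mice are their own
# singleton clusters).
scan_frame <- function(screen) {
  ped <- screen$pedigree
  ph <- screen$phenotypes
  frame <- ph %>%
    left_join(select(ped, "mouse_id", "pedigree_id", "generation", "sex",
                     "dam_id"),
              by = "mouse_id") %>%
    filter(.data$sex == "F", .data$generation %in% c("G2", "G3")) %>%
    mutate(cluster_id = ifelse(.data$generation == "G3", .data$dam_id,
                               .data$mouse_id)) %>%
    left_join(screen$genotypes, by = "mouse_id")
  frame
}

check_screen_tables <- function(screen) {
  need <- c("pedigree", "mutations", "genotypes", "phenotypes")
  if (!is.list(screen) || !all(need %in% names(screen)) ||
      any(vapply(screen[need], is.null, logical(1)))) {
    stop_bad_arg(
      "`screen` needs pedigree, mutations, genotypes and phenotypes tables.")
  }
  invisible(screen)
}

#' Per-mutation summary for Manhattan plotting
#'
#' Collapses a scan to one row per mutation: the best (smallest) raw
#' p-value across inheritance models, expressed as -log10(p), the model
#' achieving it (ties broken in the order recessive, additive, dominant),
#' and the mutation's genomic position including a cumulative coordinate
#' with per-chromosome offsets for plotting.
#'
#' @param results Scan results from [amm_scan()].
#' @param mutations Mutation table of the screen.
#' @return Tibble with `pedigree_id`, `mutation_id`, `gene`, `chrom`,
#'   `pos`, `genome_pos`, `best_model`, `p_raw`, `p_bonferroni`,
#'   `neg_log10_p`.
#' @export
manhattan_table <- function(results, mutations) {
  offsets <- c(0, cumsum(as.numeric(MOUSE_AUTOSOME_LENGTHS)))[1:19]
  names(offsets) <- as.character(1:19)
  results %>%
    filter(.data$flag == "ok") %>%
    mutate(model = factor(.data$model, levels = INHERITANCE_MODELS)) %>%
    group_by(.data$pedigree_id, .data$mutation_id) %>%
    arrange(.data$p_raw, .data$model, .by_group = TRUE) %>%
    dplyr::slice(1) %>%
    ungroup() %>%
    mutate(best_model = as.character(.data$model),
           neg_log10_p = -log10(.data$p_raw)) %>%
    left_join(select(mutations, "id", "gene", "chrom", "pos"),
              by = c(mutation_id = "id")) %>%
    mutate(genome_pos = offsets[.data$chrom] + .data$pos) %>%
    select("pedigree_id", "mutation_id", "gene", "chrom", "pos",
           "genome_pos", "best_model", "p_raw", "p_bonferroni",
           "neg_log10_p")
}

#' Conditional re-analysis after excluding a genotype class
#'
#' Removes every screened mouse whose genotype at one mutation falls in the
#' given zygosity class (e.g. all homozygous mutants at a confounding
#' locus), then recomputes the association for a target mutation on the
#' retained cohort. This is the screen's device for disentangling two
#' modifier loci segregating in the same pedigree.
#'
#' @param screen An `amm_screen` object.
#' @param exclude_mutation Mutation id defining the exclusion.
#' @param exclude_class Zygosity class(es) to exclude, subset of
#'   `c("REF", "HET", "VAR")`.
#' @param target_mutation Mutation whose association is recomputed.
#' @param models Inheritance models to test.
#' @param mixed Include the dam-frailty term.
#' @return List with `results` (scan rows for the target mutation on the
#'   retained cohort, Bonferroni family size unchanged from the full scan)
#'   and `retained_counts` (tibble `n_ref`/`n_het`/`n_var`/`n_total` of the
#'   retained cohort at the target mutation).
#' @examples
#' scr <- simulate_screen(n_pedigrees = 1, n_mutations_per_founder = 4,
#'                        g2_per_g1 = 4, g3_per_g2 = 8, seed = 5)
#' ids <- scr$mutations$id
#' exclude_and_rescan(scr, ids[1], "VAR", ids[2])
#' @export
exclude_and_rescan <- function(screen, exclude_mutation, exclude_class,
                               target_mutation,
                               models = INHERITANCE_MODELS, mixed = FALSE) {
  check_screen_tables(screen)
  if (!exclude_mutation %in% screen$mutations$id ||
      !target_mutation %in% screen$mutations$id) {
    stop_bad_arg("exclude/target mutation id not present in the screen.")
  }
  if (!all(exclude_class %in% GENO_LEVELS)) {
    stop_bad_arg("`exclude_class` must be a subset of REF/HET/VAR.")
  }
  calls <- screen$genotypes[[exclude_mutation]]
  drop_ids <- screen$genotypes$mouse_id[!is.na(calls) &
                                          calls %in% exclude_class]
  sub <- screen
  sub$genotypes <- filter(screen$genotypes,
                          !.data$mouse_id %in% drop_ids)
  sub$phenotypes <- filter(screen$phenotypes,
                           !.data$mouse_id %in% drop_ids)
  if (nrow(sub$phenotypes) == 0) {
    stop_bad_arg("exclusion removes every screened mouse.")
  }
  ped_id <- screen$mutations$pedigree_id[match(target_mutation,
                                               screen$mutations$id)]
  n_mut <- sum(screen$mutations$pedigree_id == ped_id)
  sub$mutations <- filter(screen$mutations, .data$id == target_mutation)
  res <- amm_scan(sub, models = models, mixed = mixed) %>%
    mutate(n_tests = n_mut * length(models),
           p_bonferroni = pmin(1, .data$p_raw * .data$n_tests))
  counts <- res %>%
    dplyr::slice(1) %>%
    mutate(n_total = .data$n_ref + .data$n_het + .data$n_var) %>%
    select("n_ref", "n_het", "n_var", "n_total")
  list(results = res, retained_counts = counts)
}
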