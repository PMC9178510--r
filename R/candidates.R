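#' Candidate-calling criteria
#'
#' The four filters a mutation must pass to be called a candidate modifier:
#' (1) its pedigree contains at least `min_g3_per_pedigree` G3 females;
#' (2) at least `min_hom_var_screened` homozygous-mutant mice were
#' phenotypically screened; (3) at least `min_hom_ref_screened` homozygous
#' reference mice were screened; (4) the Bonferroni-adjusted p-value of the
#' best model falls below `alpha`. Homozygote counts refer to phenotyped
#' mice, since the criteria concern phenotypic evidence.
#'
#' @param min_g3_per_pedigree Minimum G3 females in the pedigree (default 20).
#' @param min_hom_var_screened Minimum screened homozygous mutants (default 2).
#' @param min_hom_ref_screened Minimum screened homozygous reference mice
#'   (default 2).
#' @param alpha Significance level on the Bonferroni-adjusted p (default 0.05).
#' @return A list of class `candidate_criteria`.
#' @export
candidate_criteria <- function(min_g3_per_pedigree = 20,
                               min_hom_var_screened = 2,
                               min_hom_ref_screened = 2,
                               alpha = 0.05) {
  if (min_g3_per_pedigree < 1 || min_hom_var_screened < 1 ||
      min_hom_ref_screened < 1) {
    stop_bad_arg("candidate-criteria thresholds must be positive.")
  }
  if (alpha <= 0 || alpha >= 1) stop_bad_arg("`alpha` must lie in (0, 1).")
  structure(list(min_g3_per_pedigree = min_g3_per_pedigree,
                 min_hom_var_screened = min_hom_var_screened,
                 min_hom_ref_screened = min_hom_ref_screened,
                 alpha = alpha),
            class = "candidate_criteria")
}

#' Call candidate modifier mutations from a linkage scan
#'
#' Picks, for each mutation, the best inheritance model (minimum adjusted
#' p-value; ties broken recessive, then additive, then dominant), evaluates
#' the four calling criteria of [candidate_criteria()], and emits one call
#' per mutation passing all four. Flagged (non-converged or untestable)
#' model fits never support a call, and a mutation whose significant models
#' disagree on direction is flagged and not called. Directions are reported
#' in phenotype terms: `"accelerate"` for a positive fitted hazard effect,
#' `"delay"` for a negative one.
#'
#' @param results Scan results from [amm_scan()].
#' @param screen The `amm_screen` the scan was run on (source of pedigree
#'   sizes and screened-homozygote counts).
#' @param criteria A [candidate_criteria()] object.
#' @return Tibble of candidate calls: `pedigree_id`, `mutation_id`, `gene`,
#'   `best_model`, `p_raw`, `p_bonferroni`, `direction`, the screened
#'   genotype-class counts, and four logical `crit_*` columns (the
#'   criteria trace; all `TRUE` for emitted calls). The full per-mutation
#'   evaluation table, including failed mutations, is attached as
#'   `attr(, "trace")`.
#' @examples
#' scr <- simulate_screen(n_pedigrees = 1, n_mutations_per_founder = 6,
#'                        g2_per_g1 = 6, g3_per_g2 = 8, seed = 21)
#' sc <- amm_scan(scr)
#' call_candidates(sc, scr)
#' @export
call_candidates <- function(results, screen,
                            criteria = candidate_criteria()) {
  stopifnot(inherits(criteria, "candidate_criteria"))
  check_screen_tables(screen)
  stats <- pedigree_stats(screen)
  check_count_consistency(results, stats)

  best <- results %>%
    filter(.data$flag == "ok") %>%
    mutate(model = factor(.data$model, levels = INHERITANCE_MODELS)) %>%
    group_by(.data$pedigree_id, .data$mutation_id) %>%
    arrange(.data$p_bonferroni, .data$model, .by_group = TRUE) %>%
    mutate(discordant = dplyr::n_distinct(
      .data$direction[.data$p_bonferroni < criteria$alpha &
                        .data$direction != "none"]) > 1) %>%
    dplyr::slice(1) %>%
    ungroup() %>%
    mutate(best_model = as.character(.data$model))

  trace <- best %>%
    left_join(stats$pedigrees, by = "pedigree_id") %>%
    left_join(stats$zygosity, by = c("pedigree_id", "mutation_id")) %>%
    left_join(select(screen$mutations, "id", "gene"),
              by = c(mutation_id = "id")) %>%
    mutate(
      crit_pedigree_size = .data$n_g3_female >= criteria$min_g3_per_pedigree,
      crit_hom_var = .data$hom_var_screened >= criteria$min_hom_var_screened,
      crit_hom_ref = .data$hom_ref_screened >= criteria$min_hom_ref_screened,
      crit_p = .data$p_bonferroni < criteria$alpha & !.data$discordant,
      called = .data$crit_pedigree_size & .data$crit_hom_var &
        .data$crit_hom_ref & .data$crit_p,
      direction = dplyr::case_when(
        .data$direction == "accelerate" ~ "accelerate",
        .data$direction == "suppress" ~ "delay",
        TRUE ~ "none")) %>%
    select("pedigree_id", "mutation_id", "gene", "best_model", "p_raw",
           "p_bonferroni", "direction", "n_ref", "n_het", "n_var",
           "n_g3_female", "hom_var_screened", "hom_ref_screened",
           dplyr::starts_with("crit_"), "called", "discordant")

  calls <- trace %>%
    filter(.data$called, .data$direction != "none") %>%
    select(-"called", -"discordant")
  attr(calls, "trace") <- trace
  calls
}

pedigree_stats <- function(screen) {
  frame <- scan_frame(screen)
  peds <- screen$pedigree %>%
    group_by(.data$pedigree_id) %>%
    summarise(n_g3_female = sum(.data$generation == "G3" & .data$sex == "F"),
              .groups = "drop")
  zyg <- lapply(screen$mutations$id, function(mid) {
    ped <- screen$mutations$pedigree_id[match(mid, screen$mutations$id)]
    calls <- frame[[mid]][frame$pedigree_id == ped]
    tibble(pedigree_id = ped, mutation_id = mid,
           hom_var_screened = sum(calls == "VAR", na.rm = TRUE),
           hom_ref_screened = sum(calls == "REF", na.rm = TRUE),
           n_screened = sum(!is.na(calls)))
  })
  list(pedigrees = peds, zygosity = bind_rows(zyg),
       n_screened_total = nrow(frame))
}

check_count_consistency <- function(results, stats) {
  chk <- results %>%
    left_join(stats$zygosity, by = c("pedigree_id", "mutation_id"))
  bad <- with(chk, n_ref + n_het + n_var > n_screened)
  if (any(bad, na.rm = TRUE)) {
    abort("zygosity counts exceed the number of screened mice.",
          class = "ammscreen_validation_error")
  }
  invisible(TRUE)
}

#' Classify a modifier's phenotypic direction
#'
#' Combines the nonparametric and the model-based reading of an effect:
#' the affected (dose > 0) genotype class is compared with the reference
#' class on Kaplan-Meier restricted-mean onset-free time, and the verdict
#' is cross-checked against the sign of the fitted dose effect. A mutation
#' accelerates onset when the affected class sits on the lower survival
#' curve and the fitted hazard effect is positive; it delays onset in the
#' mirrored case. Disagreement between the two readings, or
#' indistinguishable curves, yields no direction and a concordance flag
#' for manual review.
#'
#' @param phenotypes Phenotype tibble (`onset_week`, `event`).
#' @param dose Numeric dose vector aligned with `phenotypes` (`NA` dropped).
#' @param beta Fitted log hazard ratio per unit dose from the scan.
#' @return List with `direction` (`"accelerate"`, `"delay"` or `"none"`)
#'   and `concordant` (logical).
#' @export
classify_direction <- function(phenotypes, dose, beta) {
  check_phenotype_records(phenotypes)
  keep <- !is.na(dose)
  ph <- phenotypes[keep, , drop = FALSE]
  dose <- dose[keep]
  if (length(unique(dose > 0)) < 2) {
    stop_bad_arg("need both an affected (dose > 0) and a reference class.")
  }
  rmst_aff <- km_rmst(ph[dose > 0, , drop = FALSE])
  rmst_ref <- km_rmst(ph[dose == 0, , drop = FALSE])
  km_dir <- if (rmst_aff < rmst_ref) "accelerate"
            else if (rmst_aff > rmst_ref) "delay"
            else "none"
  fit_dir <- if (is.na(beta) || beta == 0) "none"
             else if (beta > 0) "accelerate" else "delay"
  if (km_dir != "none" && km_dir == fit_dir) {
    list(direction = km_dir, concordant = TRUE)
  } else {
    list(direction = "none", concordant = FALSE)
  }
}

# restricted mean onset-free time: area under the KM curve to the horizon
km_rmst <- function(records, horizon = 40) {
  km <- km_estimate(records)
  times <- c(0, km$time[km$time <= horizon], horizon)
  surv <- c(1, km$survival[km$time <= horizon])
  sum(diff(times) * surv)
}
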