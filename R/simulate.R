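#' Simulate the breeding scheme of a modifier screen
#'
#' Generates one or more pedigrees following the backcross design of an
#' ENU modifier screen: a mutagenised G0 male is outcrossed to wild-type
#' females; each G1 son inherits a private half-sample of induced mutations
#' and founds one pedigree; G1 x wild-type crosses produce G2 daughters;
#' each G2 daughter is backcrossed to her G1 sire to produce G3 daughters,
#' in which mutations can become homozygous. The G1 founder is heterozygous
#' at every mutation attributed to his pedigree; each G2 female carries each
#' mutation heterozygously with probability 1/2; G3 genotypes follow
#' Mendelian transmission from the recorded G2 dam and G1 sire. Screened
#' mice (G2 and G3 females) are the rows of the genotype table.
#'
#' @param n_g1_founders Number of G1 founder males (= number of pedigrees).
#' @param n_mutations_per_founder Mutations attributed to each founder;
#'   either a single count or a vector of length `n_g1_founders`.
#' @param g2_per_g1 G2 daughters per founder (scalar or vector).
#' @param g3_per_g2 G3 daughters per G2 dam (scalar or vector over founders).
#' @param seed Integer seed; the simulation is fully reproducible given the
#'   seed and the counts.
#' @param missing_rate Probability that any screened genotype call is lost
#'   (set to `NA`), applied independently per cell. Default 0.
#'
#' @return A list of class `amm_screen` (without phenotypes) with elements
#'   `pedigree`, `mutations`, `genotypes` and `params`. `pedigree` is a
#'   tibble with columns `mouse_id`, `pedigree_id`, `generation`, `sex`,
#'   `dam_id`, `sire_id`; `mutations` has `id`, `chrom`, `pos`, `gene`,
#'   `ref_allele`, `alt_allele`, `damage_class`, `pedigree_id`; `genotypes`
#'   is a wide tibble (`mouse_id` plus one `REF`/`HET`/`VAR`/`NA` column per
#'   mutation; loci of other pedigrees are `NA` since each pedigree is only
#'   genotyped at its own founder's mutations).
#' @examples
#' sim <- simulate_pedigree(1, 42, 6, 8, seed = 7)
#' dplyr::count(sim$pedigree, generation)
#' @export
simulate_pedigree <- function(n_g1_founders, n_mutations_per_founder,
                              g2_per_g1, g3_per_g2, seed,
                              missing_rate = 0) {
  assert_count(n_g1_founders, "n_g1_founders")
  n_mut <- rep(assert_count(n_mutations_per_founder,
                            "n_mutations_per_founder"),
               length.out = n_g1_founders)
  n_g2 <- rep(assert_count(g2_per_g1, "g2_per_g1"),
              length.out = n_g1_founders)
  n_g3 <- rep(assert_count(g3_per_g2, "g3_per_g2"),
              length.out = n_g1_founders)
  if (!is.numeric(missing_rate) || missing_rate < 0 || missing_rate >= 1) {
    stop_bad_arg("`missing_rate` must lie in [0, 1).")
  }
  set.seed(as.integer(seed))
  sims <- lapply(seq_len(n_g1_founders), function(i) {
    sim_one_pedigree(sprintf("PED%02d", i), n_mut[i], n_g2[i], n_g3[i])
  })
  pedigree <- bind_rows(lapply(sims, `[[`, "pedigree"))
  mutations <- bind_rows(lapply(sims, `[[`, "mutations"))
  genotypes <- bind_rows(lapply(sims, `[[`, "genotypes"))
  # mice of one pedigree are untyped at other pedigrees' loci, hence NA
  genotypes <- genotypes[, c("mouse_id", mutations$id)]
  if (missing_rate > 0) {
    for (m in mutations$id) {
      drop <- runif(nrow(genotypes)) < missing_rate
      genotypes[[m]][drop] <- NA_character_
    }
  }
  out <- list(pedigree = pedigree, mutations = mutations,
              genotypes = genotypes, phenotypes = NULL,
              params = list(n_g1_founders = n_g1_founders,
                            n_mutations_per_founder = n_mut,
                            g2_per_g1 = n_g2, g3_per_g2 = n_g3,
                            missing_rate = missing_rate,
                            seed = as.integer(seed)))
  class(out) <- "amm_screen"
  out
}

sim_one_pedigree <- function(ped_id, n_mut, n_g2, n_g3) {
  mutations <- sim_mutation_table(ped_id, n_mut)
  g0 <- sprintf("%s_G0", ped_id)
  g1 <- sprintf("%s_G1", ped_id)
  wt0 <- sprintf("%s_WTD0", ped_id)   # dam of G1
  wt1 <- sprintf("%s_WTD1", ped_id)   # dam of the G2 females
  g2_ids <- sprintf("%s_G2_%03d", ped_id, seq_len(n_g2))
  g3_ids <- unlist(lapply(seq_len(n_g2), function(d) {
    sprintf("%s_G3_%03d_%02d", ped_id, d, seq_len(n_g3))
  }))
  pedigree <- bind_rows(
    tibble(mouse_id = c(g0, wt0, wt1), generation = c("G0", "WT", "WT"),
           sex = c("M", "F", "F"), dam_id = NA_character_,
           sire_id = NA_character_),
    tibble(mouse_id = g1, generation = "G1", sex = "M",
           dam_id = wt0, sire_id = g0),
    tibble(mouse_id = g2_ids, generation = "G2", sex = "F",
           dam_id = wt1, sire_id = g1),
    tibble(mouse_id = g3_ids, generation = "G3", sex = "F",
           dam_id = rep(g2_ids, each = n_g3), sire_id = g1)
  )
  pedigree$pedigree_id <- ped_id
  pedigree <- pedigree[, c("mouse_id", "pedigree_id", "generation", "sex",
                           "dam_id", "sire_id")]

  # allele counts (0/1/2 mutant alleles); G1 sire is HET everywhere
  g2_alleles <- matrix(rbinom(n_g2 * n_mut, 1, 0.5), nrow = n_g2)
  dam_of_g3 <- rep(seq_len(n_g2), each = n_g3)
  n_g3_tot <- n_g2 * n_g3
  from_dam <- rbinom(n_g3_tot * n_mut, 1, 0.5) *
    g2_alleles[dam_of_g3, , drop = FALSE]
  from_sire <- matrix(rbinom(n_g3_tot * n_mut, 1, 0.5), nrow = n_g3_tot)
  g3_alleles <- from_dam + from_sire

  calls <- rbind(g2_alleles, g3_alleles)
  geno <- as_tibble(setNames(
    lapply(seq_len(n_mut), function(j) GENO_LEVELS[calls[, j] + 1L]),
    mutations$id))
  geno <- dplyr::bind_cols(tibble(mouse_id = c(g2_ids, g3_ids)), geno)
  list(pedigree = pedigree, mutations = mutations, genotypes = geno)
}

sim_mutation_table <- function(ped_id, n_mut) {
  bases <- c("A", "C", "G", "T")
  chrom <- sample.int(19, n_mut, replace = TRUE,
                      prob = MOUSE_AUTOSOME_LENGTHS)
  ref <- sample(bases, n_mut, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
  pos <- vapply(chrom, function(cc)
    sample.int(MOUSE_AUTOSOME_LENGTHS[cc], 1), integer(1))
  tibble(
    id = sprintf("%s_M%02d", ped_id, seq_len(n_mut)),
    chrom = as.character(chrom),
    pos = pos,
    gene = sprintf("%s_gene%02d", tolower(ped_id), seq_len(n_mut)),
    ref_allele = ref,
    alt_allele = unname(alt),
    damage_class = sample(DAMAGE_CLASSES, n_mut, replace = TRUE,
                          prob = c(0.35, 0.25, 0.3, 0.1)),
    pedigree_id = ped_id
  )
}

#' Simulate censored onset phenotypes for screened females
#'
#' Draws an onset age for every screened (G2 or G3) female from a Weibull
#' proportional-hazards model. The per-mouse hazard is the baseline hazard
#' times `hazard_multiplier^dose` over all planted effects, where the dose is
#' determined by the mouse's genotype under the effect's inheritance model
#' (recessive: 1 iff homozygous mutant; dominant: 1 for any carrier;
#' additive: 0/0.5/1). Monitoring is weekly, so continuous onset times are
#' rounded up to the next whole week; mice without onset by week 40 are
#' right-censored at 40. An optional dam-level log-normal frailty induces
#' litter clustering among G3 sisters.
#'
#' @param pedigree,genotypes Tibbles as produced by [simulate_pedigree()].
#' @param effects Effects table built with [effect_spec()], or `NULL` for a
#'   null screen.
#' @param baseline_incidence Cumulative event fraction by week 40 for an
#'   unaffected genotype (default 0.8, the female incidence the screen's
#'   high-incidence line shows).
#' @param baseline_median_onset Median onset week among affected unaffected-
#'   genotype females (default 22).
#' @param seed Integer seed.
#' @param dam_frailty_var Variance of the dam-level log-frailty
#'   (default 0 = independent mice).
#' @param horizon Censoring horizon in weeks (default 40).
#' @return Tibble with `mouse_id`, `onset_week`, `event` (logical).
#'   Missing genotype calls at effect loci contribute dose 0.
#' @examples
#' sim <- simulate_pedigree(1, 10, 4, 6, seed = 1)
#' ph <- simulate_phenotypes(sim$pedigree, sim$genotypes, NULL, seed = 2)
#' mean(ph$event)
#' @export
simulate_phenotypes <- function(pedigree, genotypes, effects = NULL,
                                baseline_incidence = 0.8,
                                baseline_median_onset = 22,
                                seed = 1L, dam_frailty_var = 0,
                                horizon = 40) {
  effects <- validate_effects(effects, setdiff(names(genotypes), "mouse_id"))
  base <- weibull_baseline(baseline_incidence, baseline_median_onset, horizon)
  set.seed(as.integer(seed))

  screened <- pedigree %>%
    filter(.data$sex == "F", .data$generation %in% c("G2", "G3")) %>%
    filter(.data$mouse_id %in% genotypes$mouse_id)
  geno <- genotypes[match(screened$mouse_id, genotypes$mouse_id), ,
                    drop = FALSE]

  log_mult <- rep(0, nrow(screened))
  zero_mult <- rep(FALSE, nrow(screened))
  if (nrow(effects)) {
    for (k in seq_len(nrow(effects))) {
      dose <- encode(effects$model[k], geno[[effects$mutation_id[k]]])
      dose[is.na(dose)] <- 0
      m <- effects$hazard_multiplier[k]
      if (m == 0) {
        zero_mult <- zero_mult | dose > 0
      } else {
        log_mult <- log_mult + dose * log(m)
      }
    }
  }
  frailty <- rep(0, nrow(screened))
  if (dam_frailty_var > 0) {
    # one shared log-frailty per G3 litter (dam cluster); G2 mice independent
    cl <- ifelse(screened$generation == "G3", screened$dam_id,
                 screened$mouse_id)
    u <- rnorm(length(unique(cl)), sd = sqrt(dam_frailty_var))
    frailty <- u[match(cl, unique(cl))]
  }
  mult <- exp(log_mult + frailty)
  mult[zero_mult] <- 0
  t_cont <- ifelse(mult == 0, Inf,
                   base$scale * (rexp(nrow(screened)) / mult)^(1 / base$shape))
  event <- t_cont <= horizon
  tibble(mouse_id = screened$mouse_id,
         onset_week = ifelse(event, pmax(1, ceiling(t_cont)), horizon),
         event = event)
}

#' Simulate a complete modifier screen
#'
#' Convenience wrapper chaining [simulate_pedigree()] and
#' [simulate_phenotypes()] into a ready-to-analyse screen object.
#'
#' @inheritParams simulate_pedigree
#' @inheritParams simulate_phenotypes
#' @param n_pedigrees Number of pedigrees (G1 founders).
#' @return An `amm_screen` list: `pedigree`, `mutations`, `genotypes`,
#'   `phenotypes`, `params`.
#' @examples
#' scr <- simulate_screen(n_pedigrees = 1, n_mutations_per_founder = 12,
#'                        g2_per_g1 = 4, g3_per_g2 = 6, seed = 11)
#' scr
#' @export
simulate_screen <- function(n_pedigrees = 14, n_mutations_per_founder = 42,
                            g2_per_g1 = 6, g3_per_g2 = 8, effects = NULL,
                            baseline_incidence = 0.8,
                            baseline_median_onset = 22,
                            missing_rate = 0, dam_frailty_var = 0,
                            seed = 1L, horizon = 40) {
  seed <- as.integer(seed)
  sim <- simulate_pedigree(n_pedigrees, n_mutations_per_founder,
                           g2_per_g1, g3_per_g2, seed = seed,
                           missing_rate = missing_rate)
  sim$phenotypes <- simulate_phenotypes(
    sim$pedigree, sim$genotypes, effects,
    baseline_incidence = baseline_incidence,
    baseline_median_onset = baseline_median_onset,
    seed = seed + 1L, dam_frailty_var = dam_frailty_var, horizon = horizon)
  sim$params <- c(sim$params,
                  list(baseline_incidence = baseline_incidence,
                       baseline_median_onset = baseline_median_onset,
                       dam_frailty_var = dam_frailty_var, horizon = horizon,
                       effects = effects))
  sim
}

#' @export
print.amm_screen <- function(x, ...) {
  n_screened <- if (is.null(x$phenotypes)) 0L else nrow(x$phenotypes)
  cat(sprintf(
    "<amm_screen> %d pedigree(s), %d mutations, %d mice (%d phenotyped)\n",
    length(unique(x$pedigree$pedigree_id)), nrow(x$mutations),
    nrow(x$pedigree), n_screened))
  invisible(x)
}
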