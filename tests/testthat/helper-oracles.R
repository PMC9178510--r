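# Independent oracles used across the test files. These re-derive the
# quantities under test by brute force, in a different parameterisation or
# by enumeration/permutation, and deliberately share no code with the
# package implementation.

# Brute-force maximum likelihood for the right-censored Weibull regression,
# written in accelerated-failure-time form (location mu + b * dose on
# log-time, Gumbel error with scale s) and maximised by iterative
# grid refinement. Equivalent to the package's proportional-hazards
# parameterisation, so the likelihood-ratio statistics must agree.
grid_weibull_lrt <- function(time, event, dose, rounds = 5, pts = 15) {
  ll_aft <- function(mu, logs, b = 0) {
    s <- exp(logs)
    z <- (log(time) - mu - b * dose) / s
    sum((z - logs)[event]) - sum(exp(z))
  }
  max_grid <- function(centers, widths, with_dose) {
    best <- -Inf
    best_par <- centers
    for (r in seq_len(rounds)) {
      g1 <- seq(centers[1] - widths[1], centers[1] + widths[1],
                length.out = pts)
      g2 <- seq(centers[2] - widths[2], centers[2] + widths[2],
                length.out = pts)
      g3 <- if (with_dose)
        seq(centers[3] - widths[3], centers[3] + widths[3],
            length.out = pts) else 0
      for (mu in g1) for (logs in g2) for (b in g3) {
        v <- ll_aft(mu, logs, b)
        if (is.finite(v) && v > best) {
          best <- v
          best_par <- c(mu, logs, b)
        }
      }
      centers <- best_par
      widths <- widths * (2.5 / pts)  # shrink around the incumbent
    }
    best
  }
  start <- c(mean(log(time)), 0, 0)
  l0 <- max_grid(start, c(3, 2, 0), with_dose = FALSE)
  l1 <- max_grid(start, c(3, 2, 4), with_dose = TRUE)
  max(0, 2 * (l1 - l0))
}

# Hand-rolled logrank chi-square (tied-data hypergeometric form),
# independent of survival::survdiff.
logrank_chisq_manual <- function(time, event, group) {
  stopifnot(length(unique(group)) == 2)
  g1 <- group == unique(group)[1]
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(time[event]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    d <- sum(event & time == t)
    d1 <- sum(event & time == t & g1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Permutation p-value for the logrank statistic: shuffle group labels,
# recompute the manual chi-square, take the upper-tail frequency.
logrank_permutation_p <- function(time, event, group, n_perm = 10000,
                                  seed = 1) {
  set.seed(seed)
  obs <- logrank_chisq_manual(time, event, group)
  perm <- replicate(n_perm, {
    logrank_chisq_manual(time, event, sample(group))
  })
  mean(perm >= obs - 1e-12)
}

binom_bounds99 <- function(n, p) qbinom(c(0.005, 0.995), n, p)

# Small fully hand-specified screen built from explicit genotype calls:
# one pedigree, G2 dams all heterozygous so any call pattern is Mendelian-
# consistent. `calls` is a named list mutation_id -> character vector over
# the G3 mice; phenotypes are filled deterministically unless supplied.
# `onset`/`event`, when given, cover the dam followed by the G3 mice
# (length n + 1), or just the G3 mice when the dam is unphenotyped.
make_screen_from_calls <- function(calls, onset = NULL, event = NULL,
                                   phenotype_dam = TRUE) {
  n <- length(calls[[1]])
  stopifnot(all(lengths(calls) == n))
  g3 <- sprintf("T_G3_%03d", seq_len(n))
  dam <- "T_G2_001"
  ped <- tibble::tibble(
    mouse_id = c("T_G0", "T_WTD0", "T_WTD1", "T_G1", dam, g3),
    pedigree_id = "TPED",
    generation = c("G0", "WT", "WT", "G1", "G2", rep("G3", n)),
    sex = c("M", "F", "F", "M", "F", rep("F", n)),
    dam_id = c(NA, NA, NA, "T_WTD0", "T_WTD1", rep(dam, n)),
    sire_id = c(NA, NA, NA, "T_G0", "T_G1", rep("T_G1", n)))
  muts <- tibble::tibble(
    id = names(calls), chrom = "1",
    pos = seq(1e6, by = 1e6, length.out = length(calls)),
    gene = paste0("gene_", names(calls)),
    ref_allele = "A", alt_allele = "G",
    damage_class = "probably_damaging", pedigree_id = "TPED")
  geno <- tibble::as_tibble(c(list(mouse_id = c(dam, g3)),
                              lapply(calls, function(x) c("HET", x))))
  ph_ids <- if (phenotype_dam) c(dam, g3) else g3
  if (is.null(onset)) onset <- rep(c(12, 20, 28, 40),
                                   length.out = length(ph_ids))
  if (is.null(event)) event <- onset < 40
  ph <- tibble::tibble(mouse_id = ph_ids,
                       onset_week = onset, event = event)
  structure(list(pedigree = ped, mutations = muts, genotypes = geno,
                 phenotypes = ph, params = list(seed = 0L)),
            class = "amm_screen")
}
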