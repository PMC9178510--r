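test_that("breeding-scheme structure matches the backcross design", {
  sim <- simulate_pedigree(2, 10, 4, 6, seed = 1)
  ped <- sim$pedigree
  g3 <- dplyr::filter(ped, generation == "G3")
  g2 <- dplyr::filter(ped, generation == "G2")
  # every G3 mouse has a G2 dam and the G1 founder as sire
  expect_true(all(g3$dam_id %in% g2$mouse_id))
  g1 <- dplyr::filter(ped, generation == "G1")
  expect_true(all(g3$sire_id %in% g1$mouse_id))
  expect_true(all(g2$sire_id %in% g1$mouse_id))
  # genotype matrix covers exactly the screened (G2 + G3 female) mice
  expect_setequal(sim$genotypes$mouse_id, c(g2$mouse_id, g3$mouse_id))
  # mutations are private to their pedigree: other pedigrees untyped
  other <- sim$genotypes[[sim$mutations$id[1]]][
    !sim$genotypes$mouse_id %in%
      ped$mouse_id[ped$pedigree_id == "PED01"]]
  expect_true(all(is.na(other)))
  expect_error(simulate_pedigree(1, 0, 4, 6, seed = 1),
               class = "ammscreen_argument_error")
  expect_error(simulate_pedigree(0, 10, 4, 6, seed = 1),
               class = "ammscreen_argument_error")
})

test_that("simulated transmission is Mendelian-consistent", {
  sim <- simulate_pedigree(3, 8, 5, 6, seed = 42)
  expect_silent(validate_screen(c(sim[1:3], list(
    phenotypes = tibble::tibble(mouse_id = character(),
                                onset_week = numeric(),
                                event = logical())))))
  # directly: no G3 mouse is VAR where its dam is REF
  ped <- sim$pedigree
  geno <- sim$genotypes
  g3 <- ped[ped$generation == "G3", ]
  for (m in sim$mutations$id) {
    calls <- setNames(geno[[m]], geno$mouse_id)
    var_kids <- intersect(g3$mouse_id[!is.na(calls[g3$mouse_id]) &
                                        calls[g3$mouse_id] == "VAR"],
                          names(calls))
    dams <- g3$dam_id[match(var_kids, g3$mouse_id)]
    dams <- dams[dams %in% names(calls)]
    expect_false(any(calls[dams] == "REF", na.rm = TRUE))
  }
})

test_that("G3 homozygous-mutant fraction matches the cross enumeration", {
  # dam HET w.p. 1/2 x maternal transmission 1/2 x paternal 1/2 = 1/8
  sim <- simulate_pedigree(1, 42, 6, 8, seed = 7)
  g3 <- sim$pedigree$mouse_id[sim$pedigree$generation == "G3"]
  gm <- as.matrix(sim$genotypes[sim$genotypes$mouse_id %in% g3, -1])
  n_var <- sum(gm == "VAR")
  bounds <- binom_bounds99(length(gm), 1 / 8)
  expect_gte(n_var, bounds[1])
  expect_lte(n_var, bounds[2])
})

test_that("G3 genotype-class frequencies match enumeration at n >= 500", {
  # independent dams (one G3 each): REF:HET:VAR = 3/8 : 1/2 : 1/8
  sim <- simulate_pedigree(1, 5, 600, 1, seed = 11)
  g3 <- sim$pedigree$mouse_id[sim$pedigree$generation == "G3"]
  gm <- as.matrix(sim$genotypes[sim$genotypes$mouse_id %in% g3, -1])
  expected <- c(REF = 3 / 8, HET = 1 / 2, VAR = 1 / 8)
  for (m in colnames(gm)[1:2]) {
    counts <- table(factor(gm[, m], levels = names(expected)))
    for (cls in names(expected)) {
      b <- binom_bounds99(length(g3), expected[[cls]])
      expect_gte(counts[[cls]], b[1])
      expect_lte(counts[[cls]], b[2])
    }
  }
})

test_that("paper-scale configuration yields 594 mutations, mean 42.4", {
  n_mut <- c(rep(42, 8), rep(43, 6))
  sim <- simulate_pedigree(14, n_mut, 2, 2, seed = 3)
  expect_identical(nrow(sim$mutations), 594L)
  per_ped <- dplyr::count(sim$mutations, pedigree_id)
  expect_equal(round(mean(per_ped$n), 1), 42.4)
})

test_that("null phenotypes reach the configured cumulative incidence", {
  sim <- simulate_pedigree(1, 2, 40, 10, seed = 5)
  ph <- simulate_phenotypes(sim$pedigree, sim$genotypes, NULL,
                            baseline_incidence = 0.8, seed = 6)
  n <- nrow(ph)
  expect_equal(n, 40 + 400)
  expect_lt(abs(mean(ph$event) - 0.8), 3 * sqrt(0.8 * 0.2 / n))
  # censoring rule: censored exactly at 40, events within (0, 40]
  expect_true(all(ph$onset_week[!ph$event] == 40))
  expect_true(all(ph$onset_week >= 1 & ph$onset_week <= 40))
  expect_true(all(ph$onset_week == ceiling(ph$onset_week)))
})

test_that("null onset distribution is exchangeable across genotype classes", {
  sim <- simulate_pedigree(1, 1, 150, 4, seed = 8)
  ph <- simulate_phenotypes(sim$pedigree, sim$genotypes, NULL, seed = 9)
  calls <- sim$genotypes[[2]][match(ph$mouse_id, sim$genotypes$mouse_id)]
  ks <- suppressWarnings(
    ks.test(ph$onset_week[calls == "REF"], ph$onset_week[calls == "VAR"]))
  expect_gt(ks$p.value, 0.01)
})

test_that("a zero-hazard recessive suppressor censors every homozygote", {
  sim <- simulate_pedigree(1, 6, 8, 10, seed = 13)
  eff <- effect_spec(sim$mutations$id[3], "recessive", 0)
  ph <- simulate_phenotypes(sim$pedigree, sim$genotypes, eff, seed = 14)
  calls <- sim$genotypes[[sim$mutations$id[3]]][
    match(ph$mouse_id, sim$genotypes$mouse_id)]
  expect_true(all(!ph$event[calls == "VAR"]))
  expect_true(all(ph$onset_week[calls == "VAR"] == 40))
})

test_that("a dominant accelerator shifts carrier onset to the analytic median", {
  sim <- simulate_pedigree(1, 1, 120, 6, seed = 15)
  mid <- sim$mutations$id[1]
  eff <- effect_spec(mid, "dominant", 4)
  ph <- simulate_phenotypes(sim$pedigree, sim$genotypes, eff,
                            baseline_incidence = 0.8,
                            baseline_median_onset = 22, seed = 16)
  calls <- sim$genotypes[[mid]][match(ph$mouse_id, sim$genotypes$mouse_id)]
  carrier <- calls %in% c("HET", "VAR")
  # closed-form continuous median under hazard multiplier M:
  # t_med = scale * (log(2) / M)^(1/shape), then weekly ceiling
  base <- weibull_baseline(0.8, 22)
  t_med <- base$scale * (log(2) / 4)^(1 / base$shape)
  obs <- median(ph$onset_week[carrier])
  expect_lte(abs(obs - ceiling(t_med)), 1)
  expect_lt(median(ph$onset_week[carrier]), median(ph$onset_week[!carrier]))
})

test_that("effects referencing unknown mutations are rejected", {
  sim <- simulate_pedigree(1, 3, 4, 4, seed = 17)
  eff <- effect_spec("NOSUCH", "recessive", 2)
  expect_error(simulate_phenotypes(sim$pedigree, sim$genotypes, eff,
                                   seed = 18),
               class = "ammscreen_argument_error")
  expect_error(effect_spec("x", "recessive", -1),
               class = "ammscreen_argument_error")
  expect_error(effect_spec("x", "recessive", 2, direction = "suppress"),
               class = "ammscreen_argument_error")
})

test_that("dam frailty induces litter clustering of onset times", {
  sim <- simulate_pedigree(1, 1, 40, 10, seed = 19)
  ph0 <- simulate_phenotypes(sim$pedigree, sim$genotypes, NULL, seed = 20,
                             dam_frailty_var = 0)
  ph1 <- simulate_phenotypes(sim$pedigree, sim$genotypes, NULL, seed = 20,
                             dam_frailty_var = 1.5)
  dam <- sim$pedigree$dam_id[match(ph1$mouse_id, sim$pedigree$mouse_id)]
  gen <- sim$pedigree$generation[match(ph1$mouse_id,
                                       sim$pedigree$mouse_id)]
  icc <- function(ph) {
    d <- data.frame(w = ph$onset_week, dam = dam)[gen == "G3", ]
    a <- anova(lm(w ~ dam, data = d))
    a$`Sum Sq`[1] / sum(a$`Sum Sq`)
  }
  expect_gt(icc(ph1), icc(ph0))
})
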