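test_that("genotype encodings follow the inheritance-model definitions", {
  calls <- c("REF", "HET", "VAR")
  expect_equal(encode("recessive", calls), c(0, 0, 1))
  expect_equal(encode("additive", calls), c(0, 0.5, 1))
  expect_equal(encode("dominant", calls), c(0, 1, 1))
  expect_equal(encode("recessive", c("HET", NA)), c(0, NA))
  expect_error(encode("recessive", c("REF", "HOM")),
               class = "ammscreen_argument_error")
})

test_that("LRT matches survreg's Weibull likelihood ratio", {
  scr <- simulate_screen(1, 3, 6, 8, seed = 101)
  ph <- scr$phenotypes
  for (mid in scr$mutations$id) {
    dose <- encode("additive",
                   scr$genotypes[[mid]][match(ph$mouse_id,
                                              scr$genotypes$mouse_id)])
    fit <- lrt_association(ph, dose)
    s1 <- survival::survreg(
      survival::Surv(ph$onset_week, ph$event) ~ dose, dist = "weibull")
    s0 <- survival::survreg(
      survival::Surv(ph$onset_week, ph$event) ~ 1, dist = "weibull")
    expect_equal(fit$lrt_stat,
                 as.numeric(2 * (logLik(s1) - logLik(s0))),
                 tolerance = 1e-5)
    expect_equal(fit$beta, unname(-coef(s1)[2] / s1$scale),
                 tolerance = 1e-4)
  }
})

test_that("LRT statistic matches the brute-force grid-search oracle", {
  # ten-mouse toys, both with and without censoring
  toys <- list(
    list(time = c(6, 9, 11, 14, 17, 22, 25, 30, 34, 38),
         event = rep(TRUE, 10),
         dose = c(1, 1, 1, 0, 0, 1, 0, 0, 0, 0)),
    list(time = c(8, 12, 15, 18, 24, 29, 33, 40, 40, 40),
         event = c(rep(TRUE, 7), rep(FALSE, 3)),
         dose = c(1, 0.5, 1, 0, 0.5, 0, 0, 0.5, 0, 0)))
  for (toy in toys) {
    fit <- lrt_association(
      tibble::tibble(onset_week = toy$time, event = toy$event), toy$dose)
    oracle <- grid_weibull_lrt(toy$time, toy$event, toy$dose)
    expect_equal(fit$lrt_stat, oracle, tolerance = 1e-4)
  }
})

test_that("LRT is invariant to affine rescaling of the dose", {
  scr <- simulate_screen(1, 1, 6, 8, seed = 103)
  ph <- scr$phenotypes
  dose <- encode("additive",
                 scr$genotypes[[2]][match(ph$mouse_id,
                                          scr$genotypes$mouse_id)])
  f1 <- lrt_association(ph, dose)
  f2 <- lrt_association(ph, 2 * dose + 1)
  expect_equal(f1$lrt_stat, f2$lrt_stat, tolerance = 1e-6)
  expect_equal(f1$beta, 2 * f2$beta, tolerance = 1e-4)
})

test_that("shuffled-dose null p-values are uniform", {
  scr <- simulate_screen(1, 1, 6, 9, seed = 2)
  ph <- scr$phenotypes
  dose <- encode("additive",
                 scr$genotypes[[2]][match(ph$mouse_id,
                                          scr$genotypes$mouse_id)])
  set.seed(104)
  ps <- replicate(300, lrt_association(ph, sample(dose))$p_raw)
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("degenerate inputs yield the not-testable marker, not a p-value", {
  ph <- tibble::tibble(onset_week = c(10, 20, 30, 40),
                       event = c(TRUE, TRUE, TRUE, FALSE))
  fit <- lrt_association(ph, rep(1, 4))       # constant dose
  expect_identical(fit$flag, "not_testable")
  expect_true(is.na(fit$p_raw))
  fit <- lrt_association(ph[1:3, ], c(0, 1, 1))  # n < 4
  expect_identical(fit$flag, "not_testable")
  allcens <- tibble::tibble(onset_week = rep(40, 6), event = FALSE)
  expect_identical(lrt_association(allcens, c(0, 0, 0, 1, 1, 1))$flag,
                   "not_testable")
})

test_that("missing doses are dropped together with their phenotype rows", {
  scr <- simulate_screen(1, 1, 6, 8, seed = 105)
  ph <- scr$phenotypes
  dose <- encode("recessive",
                 scr$genotypes[[2]][match(ph$mouse_id,
                                          scr$genotypes$mouse_id)])
  dose[1:5] <- NA
  fit <- lrt_association(ph, dose)
  fit2 <- lrt_association(ph[-(1:5), ], dose[-(1:5)])
  expect_equal(fit$lrt_stat, fit2$lrt_stat)
  expect_identical(fit$n, nrow(ph) - 5L)
})

test_that("dam-frailty variant detects a planted effect and stays calibrated", {
  sim <- simulate_pedigree(1, 2, 12, 8, seed = 106)
  mid <- sim$mutations$id[1]
  eff <- effect_spec(mid, "recessive", 6)
  ph <- simulate_phenotypes(sim$pedigree, sim$genotypes, eff, seed = 107,
                            dam_frailty_var = 0.3)
  ped <- sim$pedigree
  dam <- ifelse(ped$generation[match(ph$mouse_id, ped$mouse_id)] == "G3",
                ped$dam_id[match(ph$mouse_id, ped$mouse_id)], ph$mouse_id)
  dose <- encode("recessive",
                 sim$genotypes[[mid]][match(ph$mouse_id,
                                            sim$genotypes$mouse_id)])
  fit <- lrt_association(ph, dose, cluster = dam)
  expect_identical(fit$flag, "ok")
  expect_true(fit$mixed)
  expect_lt(fit$p_raw, 0.05)
  expect_gt(fit$beta, 0)
  # null locus under the same clustering stays non-significant
  dose0 <- encode("recessive",
                  sim$genotypes[[sim$mutations$id[2]]][
                    match(ph$mouse_id, sim$genotypes$mouse_id)])
  fit0 <- lrt_association(ph, dose0, cluster = dam)
  expect_identical(fit0$flag, "ok")
  expect_gt(fit0$p_raw, 0.001)
})

test_that("tidy and glance summarise a fit", {
  ph <- tibble::tibble(onset_week = c(8, 12, 15, 22, 40, 40),
                       event = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  fit <- lrt_association(ph, c(1, 1, 0, 0, 0, 1))
  td <- generics::tidy(fit)
  expect_identical(td$term, "dose")
  expect_equal(td$statistic, fit$lrt_stat)
  gl <- generics::glance(fit)
  expect_identical(gl$flag, "ok")
  expect_identical(gl$n, 6L)
})
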