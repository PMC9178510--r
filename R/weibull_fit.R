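# Weibull proportional-hazards likelihood for right-censored onset weeks.
#
# Parameterisation: cumulative hazard H(t | x) = (t/lambda)^k * exp(beta x),
# with par = (a, b, beta) = (log lambda, log shape, log hazard ratio).
# The dose covariate x is the numeric genotype encoding (0/0.5/1).

weibull_ph_loglik <- function(par, time, event, dose = NULL) {
  a <- par[1]; k <- exp(par[2])
  eta <- if (is.null(dose)) 0 else par[3] * dose
  lt <- log(time)
  H <- exp(k * (lt - a) + eta)
  ll <- sum((par[2] + k * (lt - a) - lt + eta)[event]) - sum(H)
  if (!is.finite(ll)) -1e300 else ll
}

weibull_ph_grad <- function(par, time, event, dose = NULL) {
  a <- par[1]; k <- exp(par[2])
  eta <- if (is.null(dose)) 0 else par[3] * dose
  lt <- log(time)
  H <- exp(k * (lt - a) + eta)
  d <- sum(event)
  g_a <- k * (sum(H) - d)
  g_b <- k * (sum((lt - a)[event]) - sum(H * (lt - a))) + d
  g <- if (is.null(dose)) c(g_a, g_b)
       else c(g_a, g_b, sum(dose[event]) - sum(H * dose))
  ifelse(is.finite(g), g, 0)
}

# Marginal log-likelihood with a shared N(0, sigma^2) log-frailty per
# cluster, integrated out by Gauss-Hermite quadrature.
# par = (a, b, [beta,] log sigma); dose NULL drops the beta slot.
weibull_frailty_loglik <- function(par, time, event, dose, cluster, gh) {
  has_dose <- !is.null(dose)
  a <- par[1]; k <- exp(par[2])
  beta <- if (has_dose) par[3] else 0
  sigma <- exp(par[length(par)])
  eta <- if (has_dose) beta * dose else rep(0, length(time))
  lt <- log(time)
  base_event <- (par[2] + k * (lt - a) - lt + eta) * event
  logH <- k * (lt - a) + eta
  u <- sqrt(2) * sigma * gh$x          # frailty values at the nodes
  total <- 0
  for (cl in split(seq_along(time), cluster)) {
    # log integrand at each node for this cluster
    li <- vapply(u, function(uu) {
      sum(base_event[cl]) + sum(event[cl]) * uu - sum(exp(logH[cl] + uu))
    }, numeric(1))
    mx <- max(li)
    total <- total + mx + log(sum(gh$w * exp(li - mx)) / sqrt(pi))
  }
  total
}

#' Fit a Weibull proportional-hazards onset model
#'
#' Maximum-likelihood fit of a Weibull time-to-onset model with cumulative
#' hazard \eqn{H(t \mid x) = (t/\lambda)^k e^{\beta x}} under right
#' censoring, used as the building block of the linkage scan. With
#' `cluster` supplied, a shared normal random intercept on the log hazard
#' (dam-level frailty) is integrated out by Gauss-Hermite quadrature and
#' estimated alongside the fixed parameters.
#'
#' @param time Positive onset/censoring weeks.
#' @param event Logical event indicator (FALSE = censored).
#' @param dose Optional numeric genotype dose covariate; omit for the null
#'   (intercept-only) model.
#' @param cluster Optional cluster labels (e.g. dam ids) switching on the
#'   frailty variant.
#' @param gh_nodes Number of Gauss-Hermite nodes for the frailty integral.
#' @return List with `loglik`, `par` (named), `beta` (NA for null fits),
#'   `converged`.
#' @keywords internal
fit_weibull_ph <- function(time, event, dose = NULL, cluster = NULL,
                           gh_nodes = 20) {
  stopifnot(length(time) == length(event))
  event <- as.logical(event)
  a0 <- log(stats::median(time) + 1)
  if (is.null(cluster)) {
    par0 <- if (is.null(dose)) c(a0, 0) else c(a0, 0, 0)
    # Restart BFGS until it either reports convergence or the likelihood
    # stops improving. The plateau case matters: under complete separation
    # (e.g. every homozygous mutant censored) the likelihood is monotone in
    # beta and its supremum is only approached, so the usual convergence
    # code never fires even though the LRT is determined to full accuracy.
    run <- function(p) optim(p, fn = weibull_ph_loglik,
                             gr = weibull_ph_grad,
                             time = time, event = event, dose = dose,
                             method = "BFGS",
                             control = list(fnscale = -1, maxit = 500,
                                            reltol = 1e-14))
    fit <- run(par0)
    plateau <- FALSE
    for (i in 1:10) {
      if (fit$convergence == 0) break
      refit <- run(fit$par)
      plateau <- is.finite(refit$value) &&
        abs(refit$value - fit$value) < 1e-6
      fit <- refit
      if (plateau) break
    }
    beta <- if (is.null(dose)) NA_real_ else fit$par[3]
    nm <- if (is.null(dose)) c("log_scale", "log_shape")
          else c("log_scale", "log_shape", "beta")
    list(loglik = fit$value, par = setNames(fit$par, nm), beta = beta,
         converged = (fit$convergence == 0 || plateau) &&
           is.finite(fit$value))
  } else {
    gh <- pracma::gaussHermite(gh_nodes)
    # anchor at the fixed-effect MLE: the frailty likelihood approaches it
    # as sigma -> 0, so that solution is always available as a fallback
    anchor <- fit_weibull_ph(time, event, dose = dose, cluster = NULL)
    starts <- list(c(anchor$par, log(0.3)), c(anchor$par, -4))
    run <- function(p) optim(p, fn = weibull_frailty_loglik,
                             time = time, event = event, dose = dose,
                             cluster = cluster, gh = gh, method = "BFGS",
                             control = list(fnscale = -1, maxit = 500,
                                            reltol = 1e-12))
    fit <- NULL
    for (p0 in starts) {
      cand <- tryCatch(run(p0), error = function(e) NULL)
      if (!is.null(cand) && is.finite(cand$value) &&
          (is.null(fit) || cand$value > fit$value)) fit <- cand
    }
    if (is.null(fit)) {
      return(list(loglik = NA_real_, par = NULL, beta = NA_real_,
                  converged = FALSE))
    }
    plateau <- FALSE
    for (i in 1:6) {
      if (fit$convergence == 0) break
      refit <- run(fit$par)
      plateau <- is.finite(refit$value) &&
        abs(refit$value - fit$value) < 1e-6
      if (refit$value >= fit$value) fit <- refit
      if (plateau) break
    }
    beta <- if (is.null(dose)) NA_real_ else fit$par[3]
    nm <- if (is.null(dose)) c("log_scale", "log_shape", "log_frailty_sd")
          else c("log_scale", "log_shape", "beta", "log_frailty_sd")
    list(loglik = fit$value, par = setNames(fit$par, nm), beta = beta,
         converged = (fit$convergence == 0 || plateau) &&
           is.finite(fit$value))
  }
}

#' Likelihood-ratio test of genotype dose against censored onset age
#'
#' Tests whether a numeric genotype dose (the recessive/additive/dominant
#' encoding of zygosity) shifts the onset hazard, by comparing Weibull
#' proportional-hazards fits with and without the dose covariate. The
#' statistic is twice the log-likelihood difference. Its p-value is taken
#' from an F(1, d) reference with d = events minus the number of estimated
#' parameters, the usual finite-sample calibration of regression tests:
#' pedigree-sized scans carry a few dozen events, where the chi-squared
#' tail is anti-conservative at scan-wide (Bonferroni) thresholds, and the
#' F reference restores family-wise error control; as the event count
#' grows it converges to the chi-squared reference. When `cluster` is
#' supplied (dam ids), a shared frailty term is included in both the null
#' and the alternative fit, giving the mixed-model variant.
#'
#' @param phenotypes Tibble with `onset_week` and `event` (and optionally
#'   `mouse_id`), one row per mouse, aligned with `dose`.
#' @param dose Numeric dose vector from [encode()]; `NA` doses and their
#'   phenotype rows are dropped.
#' @param cluster Optional cluster labels aligned with `phenotypes`.
#' @return An object of class `amm_lrt`: a list with `lrt_stat`, `p_raw`,
#'   `beta` (log hazard ratio per unit dose), `loglik_null`, `loglik_alt`,
#'   `n`, `flag` (`"ok"`, `"not_testable"` or `"no_convergence"`) and
#'   `mixed`. A constant dose or a degenerate phenotype (no events) yields
#'   `flag = "not_testable"` with `NA` statistics rather than a p-value.
#' @examples
#' ph <- tibble::tibble(onset_week = c(8, 12, 15, 22, 40, 40),
#'                      event = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
#' lrt_association(ph, dose = c(1, 1, 0, 0, 0, 1))
#' @export
lrt_association <- function(phenotypes, dose, cluster = NULL) {
  check_phenotype_records(phenotypes)
  if (length(dose) != nrow(phenotypes)) {
    stop_bad_arg("`dose` must align with `phenotypes` rows.")
  }
  keep <- !is.na(dose)
  time <- phenotypes$onset_week[keep]
  event <- as.logical(phenotypes$event)[keep]
  dose <- dose[keep]
  cluster <- if (!is.null(cluster)) as.character(cluster)[keep]
  out <- structure(
    list(lrt_stat = NA_real_, p_raw = NA_real_, beta = NA_real_,
         loglik_null = NA_real_, loglik_alt = NA_real_,
         n = length(time), flag = "not_testable", mixed = !is.null(cluster)),
    class = "amm_lrt")
  if (length(time) < 4 || length(unique(dose)) < 2 || !any(event)) {
    return(out)
  }
  null_fit <- fit_weibull_ph(time, event, dose = NULL, cluster = cluster)
  alt_fit <- fit_weibull_ph(time, event, dose = dose, cluster = cluster)
  if (!null_fit$converged || !alt_fit$converged) {
    out$flag <- "no_convergence"
    return(out)
  }
  lrt <- max(0, 2 * (alt_fit$loglik - null_fit$loglik))
  out$lrt_stat <- lrt
  out$p_raw <- lrt_pvalue(lrt, sum(event), mixed = !is.null(cluster))
  out$beta <- alt_fit$beta
  out$loglik_null <- null_fit$loglik
  out$loglik_alt <- alt_fit$loglik
  out$flag <- "ok"
  out
}

# F(1, events - #parameters) reference for the likelihood ratio; the
# alternative fit has 3 parameters (scale, shape, dose effect), 4 with the
# frailty variance.
lrt_pvalue <- function(lrt, n_events, mixed = FALSE) {
  df2 <- max(1, n_events - if (mixed) 4 else 3)
  stats::pf(lrt, 1, df2, lower.tail = FALSE)
}

#' @export
print.amm_lrt <- function(x, ...) {
  cat(sprintf("<amm_lrt%s> n = %d, flag = %s\n",
              if (x$mixed) " (dam frailty)" else "", x$n, x$flag))
  if (x$flag == "ok") {
    cat(sprintf("  LRT = %.4f, p = %.3g, log HR per dose = %.3f\n",
                x$lrt_stat, x$p_raw, x$beta))
  }
  invisible(x)
}

#' Tidy a dose-association fit
#'
#' @param x An `amm_lrt` object from [lrt_association()].
#' @param ... Unused.
#' @return One-row tibble with `term`, `estimate` (log hazard ratio),
#'   `statistic` (LRT) and `p.value`.
#' @export
tidy.amm_lrt <- function(x, ...) {
  tibble(term = "dose", estimate = x$beta, statistic = x$lrt_stat,
         p.value = x$p_raw)
}

#' Summarise a dose-association fit
#'
#' @inheritParams tidy.amm_lrt
#' @return One-row tibble with the log-likelihoods, sample size, flag and
#'   whether the frailty (mixed) variant was used.
#' @export
glance.amm_lrt <- function(x, ...) {
  tibble(logLik_null = x$loglik_null, logLik_alt = x$loglik_alt,
         n = x$n, flag = x$flag, mixed = x$mixed)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
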