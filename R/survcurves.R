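#' Kaplan-Meier estimate of cumulative onset
#'
#' Product-limit estimator of the onset-free survival function over weekly,
#' heavily tied data. Mice without onset by the monitoring horizon are
#' right-censored and contribute to risk sets only.
#'
#' @param records Tibble with columns `onset_week` and `event` (logical or
#'   0/1), one row per mouse; a `mouse_id` column is allowed and ignored.
#' @return A tibble (one row per distinct observed week) with columns
#'   `time`, `n_risk`, `n_event`, `n_censor`, `survival`. The estimate
#'   starts at 1 and is non-increasing.
#' @examples
#' km_estimate(tibble::tibble(onset_week = c(10, 20, 40),
#'                            event = c(TRUE, TRUE, FALSE)))
#' @export
km_estimate <- function(records) {
  check_phenotype_records(records)
  fit <- survival::survfit(
    survival::Surv(records$onset_week, as.integer(records$event)) ~ 1)
  tibble(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
         n_censor = fit$n.censor, survival = fit$surv)
}

#' Logrank (Mantel-Cox) comparison of two onset curves
#'
#' Standard Mantel-Cox test on the pooled event weeks, using the tied-data
#' hypergeometric variance; the two-sided p-value is taken from a
#' chi-squared distribution on 1 degree of freedom.
#'
#' @param records_a,records_b Phenotype tibbles (`onset_week`, `event`) for
#'   the two groups; both must be non-empty.
#' @return A list with `chisq` and `p`.
#' @examples
#' a <- tibble::tibble(onset_week = c(5, 6), event = TRUE)
#' b <- tibble::tibble(onset_week = c(40, 40), event = FALSE)
#' logrank_test(a, b)
#' @export
logrank_test <- function(records_a, records_b) {
  check_phenotype_records(records_a)
  check_phenotype_records(records_b)
  grp <- c(rep("A", nrow(records_a)), rep("B", nrow(records_b)))
  time <- c(records_a$onset_week, records_b$onset_week)
  ev <- as.integer(c(records_a$event, records_b$event))
  sd <- survival::survdiff(survival::Surv(time, ev) ~ grp)
  list(chisq = unname(sd$chisq),
       p = unname(pchisq(sd$chisq, df = 1, lower.tail = FALSE)))
}

check_phenotype_records <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop_bad_arg("phenotype records must be a non-empty data frame.")
  }
  if (!all(c("onset_week", "event") %in% names(records))) {
    stop_bad_arg("phenotype records need `onset_week` and `event` columns.")
  }
  if (any(records$onset_week <= 0) || any(is.na(records$onset_week))) {
    stop_bad_arg("`onset_week` must be positive and non-missing.")
  }
  invisible(records)
}
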