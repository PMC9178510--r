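#' Specify a phenotype-modifying effect for simulation
#'
#' An effect attaches a proportional-hazards multiplier to one simulated
#' mutation under an explicit inheritance model. A mouse whose genotype
#' fully expresses the effect (e.g. homozygous mutant under a recessive
#' model) has its baseline onset hazard multiplied by `hazard_multiplier`;
#' under the additive model a heterozygote receives the square root of the
#' multiplier (dose 0.5).
#'
#' @param mutation_id Id of the mutation carrying the effect.
#' @param model Inheritance model: `"recessive"`, `"additive"` or `"dominant"`.
#' @param hazard_multiplier Positive hazard ratio for a fully expressing
#'   genotype. Values > 1 accelerate onset, values < 1 suppress or delay it,
#'   1 is a null effect and 0 abolishes onset entirely.
#' @param direction Optional `"accelerate"` or `"suppress"`; inferred from the
#'   multiplier when omitted, and validated against it when given.
#'
#' @return A one-row tibble with columns `mutation_id`, `model`, `direction`,
#'   `hazard_multiplier`. Rows can be stacked with [dplyr::bind_rows()] to
#'   plant several effects in one screen.
#' @examples
#' effect_spec("PED01_M01", "recessive", hazard_multiplier = 0.05)
#' @export
effect_spec <- function(mutation_id, model, hazard_multiplier,
                        direction = NULL) {
  model <- match.arg(model, INHERITANCE_MODELS)
  if (!is.numeric(hazard_multiplier) || length(hazard_multiplier) != 1 ||
      is.na(hazard_multiplier) || hazard_multiplier < 0) {
    stop_bad_arg("`hazard_multiplier` must be a single non-negative number.")
  }
  inferred <- if (hazard_multiplier > 1) "accelerate"
              else if (hazard_multiplier < 1) "suppress"
              else "none"
  if (is.null(direction)) {
    direction <- inferred
  } else {
    direction <- match.arg(direction, c("accelerate", "suppress"))
    if (inferred != "none" && direction != inferred) {
      stop_bad_arg(sprintf(
        "direction `%s` is inconsistent with hazard_multiplier = %g.",
        direction, hazard_multiplier))
    }
  }
  tibble(mutation_id = as.character(mutation_id), model = model,
         direction = direction, hazard_multiplier = hazard_multiplier)
}

validate_effects <- function(effects, mutation_ids) {
  if (is.null(effects)) {
    return(tibble(mutation_id = character(), model = character(),
                  direction = character(), hazard_multiplier = numeric()))
  }
  stopifnot(is.data.frame(effects))
  needed <- c("mutation_id", "model", "hazard_multiplier")
  missing_cols <- setdiff(needed, names(effects))
  if (length(missing_cols)) {
    stop_bad_arg(paste0("effects table lacks column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  unknown <- setdiff(effects$mutation_id, mutation_ids)
  if (length(unknown)) {
    stop_bad_arg(paste0("effects reference unknown mutation id(s): ",
                        paste(unknown, collapse = ", ")))
  }
  if (any(!effects$model %in% INHERITANCE_MODELS)) {
    stop_bad_arg("effects contain an unknown inheritance model.")
  }
  invisible(effects)
}

#' Weibull baseline from cumulative incidence and median onset
#'
#' Converts the two quantities a screen reports — cumulative incidence by the
#' end of monitoring and the median onset age among affected animals — into
#' the shape and scale of the Weibull time-to-event law used by the
#' simulator. With incidence \eqn{F(H) = c} at horizon \eqn{H} weeks and
#' median-among-affected \eqn{m} (so \eqn{F(m) = c/2}), the Weibull
#' \eqn{F(t) = 1 - \exp\{-(t/\lambda)^k\}} is solved in closed form.
#'
#' @param incidence Cumulative event fraction by `horizon` (in (0,1)).
#' @param median_onset Median onset week among animals with an event by
#'   `horizon`; must lie in (0, `horizon`).
#' @param horizon Monitoring horizon in weeks (default 40).
#' @return A list with elements `shape` and `scale`.
#' @examples
#' weibull_baseline(0.8, 22)
#' @export
weibull_baseline <- function(incidence, median_onset, horizon = 40) {
  if (!is.numeric(incidence) || incidence <= 0 || incidence >= 1) {
    stop_bad_arg("`incidence` must lie strictly between 0 and 1.")
  }
  if (!is.numeric(median_onset) || median_onset <= 0 ||
      median_onset >= horizon) {
    stop_bad_arg("`median_onset` must lie strictly between 0 and `horizon`.")
  }
  h_full <- -log(1 - incidence)        # cumulative hazard at horizon
  h_half <- -log(1 - incidence / 2)    # cumulative hazard at the median
  shape <- log(h_full / h_half) / log(horizon / median_onset)
  scale <- horizon / h_full^(1 / shape)
  list(shape = shape, scale = scale)
}
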