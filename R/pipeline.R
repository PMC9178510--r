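#' Build a screen configuration
#'
#' Assembles (and schema-checks) the configuration driving
#' [run_pipeline()]: simulation sizes, baseline phenotype parameters,
#' planted effects, analysis settings and calling criteria. Unknown keys
#' are rejected so typos fail loudly.
#'
#' @param ... Named overrides of the defaults (see
#'   `names(screen_config())`). `effects` takes an [effect_spec()] table;
#'   `criteria` a [candidate_criteria()] object.
#' @return A list of class `screen_config`.
#' @examples
#' cfg <- screen_config(n_pedigrees = 2, seed = 42)
#' @export
screen_config <- function(...) {
  defaults <- list(
    n_pedigrees = 14, n_mutations_per_founder = 42, g2_per_g1 = 6,
    g3_per_g2 = 8, baseline_incidence = 0.8, baseline_median_onset = 22,
    missing_rate = 0, dam_frailty_var = 0, horizon = 40,
    effects = NULL, models = INHERITANCE_MODELS, mixed = FALSE,
    criteria = candidate_criteria(), total_autosomal_genes = 20000,
    seed = 1L)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop_bad_arg(paste0("unknown configuration key(s): ",
                        paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(defaults, overrides, keep.null = TRUE)
  structure(cfg, class = "screen_config")
}

#' Read a screen configuration from YAML
#'
#' @param path YAML file whose top-level keys match [screen_config()]
#'   arguments; `effects` may be given as a list of
#'   mutation_id/model/hazard_multiplier mappings and `criteria` as a
#'   mapping of threshold names.
#' @return A `screen_config` object.
#' @export
read_screen_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$effects)) {
    raw$effects <- bind_rows(lapply(raw$effects, function(e)
      effect_spec(e$mutation_id, e$model, e$hazard_multiplier)))
  }
  if (!is.null(raw$criteria)) {
    raw$criteria <- do.call(candidate_criteria, raw$criteria)
  }
  do.call(screen_config, raw)
}

#' Run the full screen pipeline
#'
#' Simulates (or loads) a screen, scans it, calls candidates, estimates
#' genome saturation and the per-direction genomic footprints, and returns
#' everything as one bundle. With `out_dir` set, the screen tables, scan
#' results, candidate table, a machine-readable `summary.json`, the echoed
#' configuration and a run log are written there; a rerun with the same
#' configuration and seed reproduces the summary byte for byte.
#'
#' @param config A [screen_config()] object or the path of a YAML file for
#'   [read_screen_config()].
#' @param screen Optional pre-existing `amm_screen`; when supplied the
#'   simulation stage is skipped and the analysis settings of `config`
#'   are applied to it.
#' @param out_dir Optional output directory.
#' @return A list of class `amm_report`: `screen`, `results`, `manhattan`,
#'   `candidates`, `saturation`, `footprints`, `summary`, `log`.
#' @examples
#' rep <- run_pipeline(screen_config(n_pedigrees = 1,
#'                                   n_mutations_per_founder = 6,
#'                                   g2_per_g1 = 4, g3_per_g2 = 6,
#'                                   seed = 9))
#' rep$summary$n_candidates
#' @export
run_pipeline <- function(config, screen = NULL, out_dir = NULL) {
  if (is.character(config)) config <- read_screen_config(config)
  stopifnot(inherits(config, "screen_config"))
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    invisible(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage `%s` failed: %s", name,
                    conditionMessage(e)),
            class = "ammscreen_pipeline_error")
    })
  }
  if (is.null(screen)) {
    screen <- stage("simulate", simulate_screen(
      n_pedigrees = config$n_pedigrees,
      n_mutations_per_founder = config$n_mutations_per_founder,
      g2_per_g1 = config$g2_per_g1, g3_per_g2 = config$g3_per_g2,
      effects = config$effects,
      baseline_incidence = config$baseline_incidence,
      baseline_median_onset = config$baseline_median_onset,
      missing_rate = config$missing_rate,
      dam_frailty_var = config$dam_frailty_var,
      seed = config$seed, horizon = config$horizon))
    say("simulate: %d pedigrees, %d mutations, %d phenotyped mice (seed %d)",
        length(unique(screen$pedigree$pedigree_id)), nrow(screen$mutations),
        nrow(screen$phenotypes), config$seed)
  } else {
    say("input: pre-built screen with %d phenotyped mice",
        nrow(screen$phenotypes))
  }
  results <- stage("scan", amm_scan(screen, models = config$models,
                                    mixed = config$mixed))
  for (ped in unique(results$pedigree_id)) {
    sub <- results[results$pedigree_id == ped, ]
    say("scan: %s tested %d mutations x %d models, %d flagged",
        ped, length(unique(sub$mutation_id)), length(config$models),
        sum(sub$flag != "ok"))
  }
  mh <- stage("scan", manhattan_table(results, screen$mutations))
  candidates <- stage("call",
                      call_candidates(results, screen, config$criteria))
  say("call: %d candidate(s)", nrow(candidates))
  sat <- stage("saturation",
               screen_saturation(screen, config$total_autosomal_genes))
  footprints <- if (sat$saturation > 0) {
    bind_rows(
      mutate(genomic_footprint(
        sum(candidates$direction == "accelerate"), sat$saturation),
        class = "accelerate"),
      mutate(genomic_footprint(
        sum(candidates$direction == "delay"), sat$saturation),
        class = "delay"))
  } else {
    say("saturation: zero saturation, footprints skipped")
    NULL
  }
  summary <- list(
    seed = config$seed,
    n_pedigrees = length(unique(screen$pedigree$pedigree_id)),
    n_mutations = nrow(screen$mutations),
    n_phenotyped = nrow(screen$phenotypes),
    n_tests = nrow(results),
    n_flagged = sum(results$flag != "ok"),
    n_candidates = nrow(candidates),
    candidates = candidates %>%
      select("mutation_id", "gene", "best_model", "p_bonferroni",
             "direction") %>%
      as.data.frame(),
    saturation = sat$saturation,
    footprint_accelerate =
      if (is.null(footprints)) NA else footprints$footprint_rounded[1],
    footprint_delay =
      if (is.null(footprints)) NA else footprints$footprint_rounded[2])
  out <- structure(list(screen = screen, results = results, manhattan = mh,
                        candidates = candidates, saturation = sat,
                        footprints = footprints, summary = summary,
                        log = log_lines),
                   class = "amm_report")
  if (!is.null(out_dir)) {
    stage("report", {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_screen(screen, file.path(out_dir, "screen"))
      readr::write_tsv(results, file.path(out_dir, "results.tsv"))
      readr::write_tsv(candidates, file.path(out_dir, "candidates.tsv"))
      jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      cfg_echo <- unclass(config)
      cfg_echo$criteria <- unclass(cfg_echo$criteria)
      cfg_echo$effects <- if (!is.null(cfg_echo$effects))
        lapply(seq_len(nrow(cfg_echo$effects)),
               function(i) as.list(cfg_echo$effects[i, ]))
      yaml::write_yaml(cfg_echo, file.path(out_dir, "config.yaml"))
      writeLines(log_lines, file.path(out_dir, "run.log"))
    })
  }
  out
}

#' @export
print.amm_report <- function(x, ...) {
  cat("<amm_report>\n")
  cat(sprintf("  %d pedigrees, %d mutations, %d phenotyped mice\n",
              x$summary$n_pedigrees, x$summary$n_mutations,
              x$summary$n_phenotyped))
  cat(sprintf("  %d tests (%d flagged), %d candidate call(s)\n",
              x$summary$n_tests, x$summary$n_flagged,
              x$summary$n_candidates))
  cat(sprintf("  saturation %.4g; footprint accelerate %s / delay %s\n",
              x$summary$saturation,
              format(x$summary$footprint_accelerate),
              format(x$summary$footprint_delay)))
  invisible(x)
}
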