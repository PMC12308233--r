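#' Read a pipeline run configuration
#'
#' A single YAML file drives the whole pipeline. Top-level keys: `mode`
#' (`"simulate"` or `"ingest"`), `out_dir`, `seed`, `alpha`, `margin_db`,
#' `scenario` (overrides for [scenario_config()] fields in simulate mode),
#' `recorder` (fields for [recorder_spec()]) and `metadata_csv` (site
#' metadata, ingest mode). Command-level arguments override config values;
#' all analysis defaults (bands, FFT sizes, overlaps, diel windows, alpha,
#' the 3 dB margin) are the package defaults.
#'
#' @param path YAML file path.
#' @param seed optional seed override.
#' @return A `reefpam_config` list.
#' @export
read_run_config <- function(path, seed = NULL) {
  cfg <- yaml::read_yaml(path)
  cfg$mode <- cfg$mode %||% "simulate"
  cfg$alpha <- cfg$alpha %||% 0.05
  cfg$margin_db <- cfg$margin_db %||% 3
  cfg$seed <- as.integer(seed %||% cfg$seed %||% 1L)
  cfg$out_dir <- cfg$out_dir %||% "reefpam_out"
  cfg$config_hash <- fnv1a32(paste(readLines(path), collapse = "\n"))
  class(cfg) <- "reefpam_config"
  cfg
}

config_scenario <- function(config) {
  args <- config$scenario %||% list()
  if (!is.null(args$group_offsets)) {
    args$group_offsets <- dplyr::bind_rows(lapply(args$group_offsets, as_tibble))
  }
  if (!is.null(args$sites)) args$sites <- dplyr::bind_rows(lapply(args$sites, as_tibble))
  if (!is.null(args$years)) args$years <- unlist(args$years)
  if (!is.null(args$year_start_dates)) args$year_start_dates <- unlist(args$year_start_dates)
  args$seed <- config$seed
  do.call(scenario_config, args)
}

provenance <- function(config, extra = list()) {
  c(list(package = "reefpam",
         version = as.character(utils::packageVersion("reefpam")),
         config_hash = config$config_hash %||% NA_character_,
         seed = config$seed,
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    extra)
}

#' Pipeline commands: simulate, features, stats
#'
#' `pipeline_simulate()` writes a synthetic WAV corpus plus ground-truth,
#' survey and recorder tables and a provenance JSON under
#' `<out_dir>/corpus`. `pipeline_features()` scans that corpus (or any
#' corpus laid out the same way), extracts the per-cell feature table and
#' writes `features.csv`. `pipeline_stats()` runs the statistical layer
#' (mixed ANCOVAs per band/period/response, 3 dB effect calls, survey
#' ANOVAs, CCA) and writes `report.json` plus CCA score CSVs.
#'
#' @param config a `reefpam_config` from [read_run_config()].
#' @param force overwrite a non-empty corpus directory?
#' @return `pipeline_simulate()`: the [simulate_campaign()] result;
#'   `pipeline_features()`: the feature tibble; `pipeline_stats()`: the
#'   report list. All invisibly write their files under `config$out_dir`.
#' @export
pipeline_simulate <- function(config, force = FALSE) {
  corpus_dir <- file.path(config$out_dir, "corpus")
  if (dir.exists(corpus_dir) && length(list.files(corpus_dir)) && !force) {
    abort(sprintf("output dir %s is not empty (use force = TRUE)", corpus_dir))
  }
  dir.create(corpus_dir, recursive = TRUE, showWarnings = FALSE)
  scenario <- config_scenario(config)
  res <- simulate_campaign(scenario, corpus_dir,
                           survey_effect = config$survey_effect)
  write.csv(res$ground_truth, file.path(config$out_dir, "ground_truth.csv"),
            row.names = FALSE)
  write.csv(res$survey, file.path(config$out_dir, "survey.csv"),
            row.names = FALSE)
  rec <- lapply(res$recorders, unclass)
  yaml::write_yaml(rec, file.path(config$out_dir, "recorders.yaml"))
  jsonlite::write_json(
    provenance(config, list(scenario_hash = scenario_hash(scenario),
                            n_files = nrow(res$inventory))),
    file.path(config$out_dir, "provenance.json"), auto_unbox = TRUE)
  invisible(res)
}

#' @rdname pipeline_simulate
#' @export
pipeline_features <- function(config) {
  corpus_dir <- file.path(config$out_dir, "corpus")
  if (config$mode == "simulate") {
    scenario <- config_scenario(config)
    metadata <- dplyr::rename(scenario$sites, site = "site_id")
    specs <- scenario_recorders(scenario)
  } else {
    metadata <- as_tibble(read.csv(config$metadata_csv))
    rec <- config$recorder
    specs <- recorder_spec(rec$sensitivity_db, rec$gain_db %||% 0,
                           rec$adc_fullscale_volts %||% 1,
                           rec$native_rate %||% 44100)
  }
  inv <- scan_corpus(corpus_dir, metadata)
  if (nrow(inv) == 0) abort("no parseable audio in corpus")
  features <- aggregate_features(inv, specs)
  write_feature_table(features, file.path(config$out_dir, "features.csv"))
  invisible(features)
}

#' @rdname pipeline_simulate
#' @export
pipeline_stats <- function(config) {
  features <- read_feature_table(file.path(config$out_dir, "features.csv"))
  survey_path <- file.path(config$out_dir, "survey.csv")
  survey <- if (file.exists(survey_path)) as_tibble(read.csv(survey_path)) else NULL
  report <- run_stats(features, survey, alpha = config$alpha,
                      margin_db = config$margin_db, config = config)
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(report$cca_scores)) {
    write.csv(report$cca_scores, file.path(config$out_dir, "cca_scores.csv"),
              row.names = FALSE)
  }
  invisible(report)
}

#' Statistical report for a feature table
#'
#' Runs the full statistical layer on a feature table: a mixed ANCOVA per
#' band x diel period x response (peak level and peak frequency), a 3 dB
#' effect call for every level response, survey ANOVAs (abundance, richness,
#' coral and algae cover) and a CCA of the fish community constrained by
#' benthic and acoustic features. Every p-value in the report is accompanied
#' by the corresponding dB difference and verdict. With fewer than two
#' random-factor levels the ANCOVA is skipped with an explicit message.
#'
#' @param features a feature table.
#' @param survey optional survey table.
#' @param alpha significance level.
#' @param margin_db instrument error margin in dB.
#' @param config optional `reefpam_config` for provenance.
#' @return A nested report list (JSON-ready).
#' @export
run_stats <- function(features, survey = NULL, alpha = 0.05, margin_db = 3,
                      config = NULL) {
  multi_year <- length(unique(features$year)) > 1
  group_col <- if (multi_year) "year" else "protection"
  group_term <- group_col
  ancovas <- list()
  effect_calls <- list()
  for (band in unique(features$band)) {
    for (period in unique(features$period)) {
      sub <- features[features$band == band & features$period == period, ]
      for (response in c("psd_fpeak_db", "gamma_fpeak_hz")) {
        key <- paste(band, period, response, sep = ".")
        if (length(unique(sub$location)) < 2) {
          message(sprintf("skipping ANCOVA %s: fewer than 2 locations", key))
          next
        }
        fx <- if (multi_year) c("year", "protection") else "protection"
        fit <- tryCatch(
          fit_ancova(sub, response, fixed = fx,
                     interaction = multi_year, covariate = "moon_phase"),
          error = function(e) {
            message(sprintf("skipping ANCOVA %s: %s", key, conditionMessage(e)))
            NULL
          })
        if (is.null(fit)) next
        ancovas[[key]] <- list(band = band, period = period,
                               response = response,
                               terms = fit$terms,
                               group_means = fit$group_means,
                               singular = fit$singular)
        if (response == "psd_fpeak_db") {
          diffs <- summarize_group_differences(sub, response, group_col)
          p <- fit$terms$p.value[fit$terms$term == group_term]
          call <- apply_3db_rule(diffs$diff_db[1], p, margin = margin_db,
                                 alpha = alpha)
          effect_calls[[key]] <- c(list(band = band, period = period,
                                        response = response,
                                        group = group_col),
                                   as.list(call),
                                   list(delta_audit_a = diffs$delta_a_db[1],
                                        delta_audit_b = diffs$delta_b_db[1]))
        }
      }
    }
  }

  survey_tests <- NULL
  cca_part <- NULL
  cca_scores <- NULL
  if (!is.null(survey)) {
    survey_tests <- lapply(c("abundance", "richness", "coral_pct", "algae_pct"),
                           function(m) {
      fit <- fit_survey_anova(survey, m)
      list(metric = m, chisq = fit$terms$chisq[1], df = fit$terms$df[1],
           p.value = fit$terms$p.value[1])
    })
    comm <- survey_community(survey)
    cons <- cca_constraints(features, survey)
    shared <- intersect(rownames(comm), rownames(cons))
    if (length(shared) >= 3 && ncol(cons) >= 1) {
      cc <- run_cca(comm[shared, , drop = FALSE],
                    cons[shared, , drop = FALSE])
      cca_part <- list(
        eig_constrained = cc$eig_constrained,
        eig_unconstrained = cc$eig_unconstrained,
        total_inertia = cc$total_inertia,
        prop_constrained = cc$prop_constrained
      )
      cca_scores <- as.data.frame(cc$site_scores)
      cca_scores$site <- rownames(cc$site_scores)
    }
  }

  report <- list(
    provenance = if (!is.null(config)) provenance(config) else
      list(package = "reefpam",
           version = as.character(utils::packageVersion("reefpam"))),
    alpha = alpha, margin_db = margin_db,
    n_feature_rows = nrow(features),
    ancova = unname(ancovas),
    effect_calls = unname(effect_calls),
    survey_anova = survey_tests,
    cca = cca_part,
    cca_scores = cca_scores
  )
  validate_report(report)
  report
}

# site-level CCA constraints: per-period acoustic features (LF band) plus
# coral/algae cover
cca_constraints <- function(features, survey) {
  lf <- features[features$band == "LF", ]
  ac <- lf |>
    dplyr::group_by(.data$site, .data$period) |>
    dplyr::summarise(psd = mean(.data$psd_fpeak_db),
                     gamma = mean(.data$gamma_fpeak_hz), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "period", values_from = c("psd", "gamma"))
  sv <- survey |>
    dplyr::group_by(.data$site) |>
    dplyr::summarise(coral_pct = mean(.data$coral_pct),
                     algae_pct = mean(.data$algae_pct), .groups = "drop")
  z <- dplyr::inner_join(ac, sv, by = "site")
  m <- as.matrix(z[, setdiff(names(z), "site")])
  rownames(m) <- z$site
  m
}

#' Structural validation of a statistics report
#'
#' Checks a report produced by [run_stats()] against the shipped schema
#' (`system.file("schema", "report-schema.json", package = "reefpam")`):
#' required top-level fields, required fields per ANCOVA entry and per
#' effect call, and that every effect call carries a dB difference, a
#' p-value and a verdict.
#'
#' @param report a report list.
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_report <- function(report) {
  schema_path <- system.file("schema", "report-schema.json", package = "reefpam")
  schema <- jsonlite::read_json(schema_path)
  for (f in unlist(schema$required)) {
    if (is.null(report[[f]])) abort(sprintf("report missing field '%s'", f))
  }
  for (ec in report$effect_calls) {
    for (f in unlist(schema$effect_call_required)) {
      if (is.null(ec[[f]])) abort(sprintf("effect call missing '%s'", f))
    }
  }
  for (an in report$ancova) {
    for (f in unlist(schema$ancova_required)) {
      if (is.null(an[[f]])) abort(sprintf("ancova entry missing '%s'", f))
    }
  }
  invisible(TRUE)
}
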