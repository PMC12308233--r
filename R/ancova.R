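#' Mixed-effects ANCOVA with type-II Wald chi-square tests
#'
#' Fits a linear mixed model of an acoustic response (e.g. `psd_fpeak_db`)
#' with crossed fixed factors (default `year * protection`), a continuous
#' covariate (default `moon_phase`), and a random intercept per `location`,
#' by restricted maximum likelihood (REML). Each fixed term is then tested
#' with a type-II Wald chi-square: every term is tested after all other
#' terms of equal or lower order, with interactions respected. Significance
#' is assessed at `alpha = 0.05` downstream; level differences must
#' additionally clear the instrument 3 dB margin (see [apply_3db_rule()]).
#'
#' A singular fit (location variance estimated at the boundary, zero) is
#' reported with a warning but results are still returned; the fixed-effect
#' tests then coincide with their ordinary-least-squares counterparts.
#'
#' @param data a feature table (or any data frame with the model columns).
#' @param response name of the numeric response column.
#' @param fixed character vector of fixed factor names.
#' @param interaction include the interaction of the fixed factors?
#' @param covariate name of the continuous covariate, or `NULL`.
#' @param random name of the random-intercept grouping factor; at least two
#'   levels are required.
#' @return A `reefpam_ancova` object: `terms` (tibble of term, chisq, df,
#'   p.value), `group_means`, variance components, the fitted
#'   [lme4::lmer()] model, and `singular`.
#' @seealso [fit_survey_anova()], [apply_3db_rule()], [tidy()], [glance()]
#' @export
fit_ancova <- function(data, response, fixed = c("year", "protection"),
                       interaction = TRUE, covariate = "moon_phase",
                       random = "location") {
  data <- as.data.frame(data)
  if (!response %in% names(data)) abort(sprintf("no column '%s'", response))
  if (!is.numeric(data[[response]])) abort("response column must be numeric")
  for (f in fixed) {
    data[[f]] <- factor(data[[f]])
    if (nlevels(data[[f]]) < 2) abort(sprintf("factor '%s' needs >= 2 levels", f))
  }
  if (length(unique(data[[random]])) < 2) {
    abort(sprintf("random factor '%s' needs >= 2 levels", random))
  }
  fixed_part <- paste(fixed, collapse = if (interaction) " * " else " + ")
  if (!is.null(covariate)) {
    # drop a covariate that is aliased with the factors (e.g. a single
    # recording date per year makes moon phase redundant)
    x0 <- stats::model.matrix(stats::as.formula(paste("~", fixed_part)), data)
    x1 <- stats::model.matrix(
      stats::as.formula(paste("~", fixed_part, "+", covariate)), data)
    if (qr(x1)$rank == qr(x0)$rank) {
      warn(sprintf("covariate '%s' is aliased with the design; dropped", covariate))
    } else {
      fixed_part <- paste(fixed_part, "+", covariate)
    }
  }
  fml <- stats::as.formula(
    paste0("`", response, "` ~ ", fixed_part, " + (1 | ", random, ")")
  )
  fit <- lme4::lmer(fml, data = data, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  singular <- lme4::isSingular(fit)
  if (singular) {
    warn("singular fit: random-effect variance estimated at the boundary (0)")
  }
  an <- tryCatch(
    car::Anova(fit, type = 2, test.statistic = "Chisq"),
    error = function(e) {
      warn(paste0("mixed-model Wald test failed (", conditionMessage(e),
                  "); falling back to ordinary least squares"))
      ols <- stats::lm(stats::as.formula(paste0("`", response, "` ~ ", fixed_part)),
                       data = data)
      af <- tryCatch(car::Anova(ols, type = 2),
                     error = function(e2) {
                       abort(paste0("degenerate fit for '", response, "': ",
                                    conditionMessage(e2)))
                     })
      # Anova.lm reports F; convert to the equivalent Wald chi-square
      out <- data.frame(Chisq = af[["Df"]] * af[["F value"]], Df = af[["Df"]],
                        row.names = rownames(af))
      out[["Pr(>Chisq)"]] <- stats::pchisq(out$Chisq, out$Df, lower.tail = FALSE)
      out
    })
  keep <- rownames(an) != "Residuals" & !is.na(an[["Chisq"]])
  terms <- tibble(
    term = rownames(an)[keep],
    chisq = an[["Chisq"]][keep],
    df = an[["Df"]][keep],
    p.value = an[["Pr(>Chisq)"]][keep]
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  random_var <- vc$vcov[vc$grp == random][1]
  resid_var <- vc$vcov[vc$grp == "Residual"][1]
  gm <- lapply(fixed, function(f) {
    stats::aggregate(data[[response]], list(level = data[[f]]), mean) |>
      setNames(c("level", "mean")) |>
      dplyr::mutate(factor = f, .before = 1) |>
      as_tibble()
  })
  structure(
    list(terms = terms, group_means = dplyr::bind_rows(gm),
         random_var = random_var, resid_var = resid_var,
         response = response, n = nrow(data), model = fit,
         singular = singular),
    class = "reefpam_ancova"
  )
}

#' Mixed-model comparison of survey metrics between protection groups
#'
#' One-factor mixed-model analysis of variance of a survey metric (fish
#' abundance, species richness, or a benthic cover percentage) between
#' protection groups, with location as a random factor — the same type-II
#' Wald chi-square contract as [fit_ancova()].
#'
#' @param survey a survey table (e.g. from [simulate_survey()]).
#' @param metric metric column name; `"coral"` and `"algae"` are accepted as
#'   aliases for `coral_pct` / `algae_pct`.
#' @param random random-intercept grouping factor.
#' @return A `reefpam_ancova` object.
#' @export
fit_survey_anova <- function(survey, metric, random = "location") {
  metric <- switch(metric, coral = "coral_pct", algae = "algae_pct", metric)
  if (!metric %in% names(survey)) abort(sprintf("metric '%s' not found", metric))
  fit_ancova(survey, metric, fixed = "protection", interaction = FALSE,
             covariate = NULL, random = random)
}

#' @export
print.reefpam_ancova <- function(x, ...) {
  cat(sprintf("<reefpam_ancova> %s, n = %d%s\n", x$response, x$n,
              if (x$singular) " (singular fit)" else ""))
  print(as.data.frame(x$terms), row.names = FALSE)
  invisible(x)
}

#' @rdname fit_ancova
#' @param x a `reefpam_ancova` object.
#' @param ... unused.
#' @export
tidy.reefpam_ancova <- function(x, ...) x$terms

#' @rdname fit_ancova
#' @export
glance.reefpam_ancova <- function(x, ...) {
  tibble(response = x$response, n = x$n, random_var = x$random_var,
         resid_var = x$resid_var, singular = x$singular)
}

#' The 3 dB instrument-error significance rule
#'
#' When two recording systems are compared, level differences smaller than
#' the systems' own error margin cannot be attributed to the environment:
#' a difference counts as significant only when the statistical test rejects
#' (`p < alpha`) *and* the absolute difference exceeds the margin
#' (default |3| dB). Both conditions are necessary; the rule is monotone in
#' |difference| and in p.
#'
#' @param difference_db group difference(s) in dB.
#' @param p p-value(s) from the corresponding test.
#' @param margin error margin in dB (> 0; default 3).
#' @param alpha significance level (default 0.05).
#' @return A tibble: `difference_db`, `p`, `margin`, `alpha`, `verdict`
#'   (`"significant"` / `"non-significant"`).
#' @examples
#' apply_3db_rule(c(4.07, 2.88, 3.41), c(1e-5, 0.01, 0.01))
#' @export
apply_3db_rule <- function(difference_db, p, margin = 3, alpha = 0.05) {
  if (any(margin <= 0)) abort("`margin` must be positive")
  verdict <- ifelse(p < alpha & abs(difference_db) > margin,
                    "significant", "non-significant")
  tibble(difference_db = difference_db, p = p, margin = margin, alpha = alpha,
         verdict = verdict)
}

#' Group mean differences in dB with averaging audit
#'
#' Arithmetic means of a dB response per group cell (the reporting
#' convention for PSD peak levels), the difference between the two group
#' levels (second level minus first, in the factor's level order), and the
#' dB-versus-linear averaging audit [average_db_audit()] for each cell.
#' With a `within` grouping (typically site), per-scope differences are
#' reported alongside the overall one.
#'
#' @param data a feature table.
#' @param response numeric dB response column name.
#' @param group two-level grouping column name (e.g. `year` or
#'   `protection`).
#' @param within optional column name for per-scope breakdown (e.g.
#'   `"site"`).
#' @return A tibble with one row per scope: `scope`, the two level means,
#'   `diff_db`, and the per-cell audits `delta_a_db`, `delta_b_db`. Scopes
#'   where either cell is empty are omitted with a log message.
#' @export
summarize_group_differences <- function(data, response, group, within = NULL) {
  lv <- levels(factor(data[[group]]))
  if (length(lv) != 2) abort("`group` must have exactly two levels")
  one_scope <- function(d, scope) {
    a <- d[[response]][d[[group]] == lv[1]]
    b <- d[[response]][d[[group]] == lv[2]]
    if (!length(a) || !length(b)) {
      message(sprintf("omitting scope '%s': empty group cell", scope))
      return(NULL)
    }
    tibble(scope = scope, level_a = lv[1], level_b = lv[2],
           mean_a_db = mean(a), mean_b_db = mean(b),
           diff_db = mean(b) - mean(a),
           delta_a_db = average_db_audit(a), delta_b_db = average_db_audit(b),
           n_a = length(a), n_b = length(b))
  }
  out <- list(one_scope(data, "overall"))
  if (!is.null(within)) {
    for (s in sort(unique(data[[within]]))) {
      out[[length(out) + 1L]] <- one_scope(data[data[[within]] == s, ], s)
    }
  }
  dplyr::bind_rows(out)
}
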