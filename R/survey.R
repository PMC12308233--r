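# benthic categories of the point-intercept survey and their default mean
# covers (%); scleractinians are the hard-coral fraction
.benthic_base <- c(
  sand = 15, rubble = 10, dead_coral = 10, pavement = 15,
  asparagopsis = 3, halimeda = 4, turbinaria = 3, other_macroalgae = 10,
  millepora = 2, scleractinian = 28
)
.algae_cats <- c("asparagopsis", "halimeda", "turbinaria", "other_macroalgae")

#' Simulate a site survey table
#'
#' Generates fish counts and benthic cover for every scenario site, one row
#' per transect. Species abundances are lognormal-Poisson (a fixed
#' species-level log-abundance profile, per-site lognormal heterogeneity,
#' Poisson counts per transect); a positive `richness` effect adds that many
#' MPA-only species to the pool. Benthic cover per transect is drawn from a
#' Dirichlet distribution over the ten point-intercept categories and scaled
#' to 100%; a named `cover` offset (e.g. `c(coral = 10)`) raises that
#' category for MPA sites by the stated percentage while rescaling the
#' remaining categories so rows still sum to 100 (so the expected MPA-nMPA
#' difference equals the offset). Offsets that would drive a category below
#' zero are clipped at zero and the row renormalized, with a warning.
#' `"coral"` is an alias for the scleractinian category and `"algae"` for
#' other macroalgae.
#'
#' @param scenario a [scenario_config()] (site design and seed).
#' @param effect `NULL` or a list with `richness` (extra MPA-only species)
#'   and/or `cover` (named vector of cover offsets in percentage points).
#' @param n_species size of the shared species pool.
#' @param n_transects transects per site.
#' @return A tibble, one row per site x transect: metadata, one count column
#'   per species (`sp01`, ...), `richness` (species with count > 0),
#'   `cover_*` percentages plus `coral_pct` (scleractinian + millepora),
#'   `algae_pct` (all algae categories) and `abundance` (total count).
#' @export
simulate_survey <- function(scenario, effect = NULL, n_species = 30,
                            n_transects = 3) {
  effect <- effect %||% list()
  richness_extra <- effect$richness %||% 0
  cover_off <- effect$cover %||% numeric()
  names(cover_off) <- sub("^coral$", "scleractinian",
                          sub("^algae$", "other_macroalgae", names(cover_off)))
  bad <- setdiff(names(cover_off), names(.benthic_base))
  if (length(bad)) abort(paste0("unknown benthic category: ", bad[1]))

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(derive_seed(scenario$seed, "survey"))
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))

  n_total <- n_species + richness_extra
  sp_names <- sprintf("sp%02d", seq_len(n_total))
  base_log <- rnorm(n_total, log(5), 1)
  if (richness_extra > 0) {
    base_log[(n_species + 1):n_total] <- log(3) # MPA-only additions
  }
  sites <- scenario$sites
  rows <- list()
  clipped_any <- FALSE
  for (i in seq_len(nrow(sites))) {
    is_mpa <- sites$protection[i] == "MPA"
    site_eps <- rnorm(n_total, 0, 0.5)
    lambda <- exp(base_log + site_eps)
    if (richness_extra > 0 && !is_mpa) lambda[(n_species + 1):n_total] <- 0
    for (tr in seq_len(n_transects)) {
      counts <- rpois(n_total, lambda)
      # benthic cover: Dirichlet draw scaled to 100
      g <- rgamma(length(.benthic_base), shape = .benthic_base / 2, rate = 1)
      cover <- 100 * g / sum(g)
      names(cover) <- names(.benthic_base)
      if (is_mpa && length(cover_off)) {
        for (cat in names(cover_off)) {
          new_val <- cover[cat] + cover_off[cat]
          if (new_val < 0) { new_val <- 0; clipped_any <- TRUE }
          others <- setdiff(names(cover), cat)
          rest <- sum(cover[others])
          if (rest > 0) cover[others] <- cover[others] * (100 - new_val) / rest
          cover[cat] <- new_val
        }
      }
      row <- c(
        list(site = sites$site_id[i], protection = sites$protection[i],
             location = sites$location[i], transect = tr),
        as.list(setNames(counts, sp_names)),
        list(richness = sum(counts > 0), abundance = sum(counts)),
        as.list(setNames(cover, paste0("cover_", names(cover)))),
        list(coral_pct = unname(cover["scleractinian"] + cover["millepora"]),
             algae_pct = unname(sum(cover[.algae_cats])))
      )
      rows[[length(rows) + 1L]] <- as_tibble(row)
    }
  }
  if (clipped_any) warn("cover offset drove a category below 0%; clipped and renormalized")
  dplyr::bind_rows(rows)
}

#' Community matrix from a survey table
#'
#' Aggregates transect counts to one row per site and returns the sites x
#' species abundance matrix used by [run_cca()]. Species absent from every
#' site are dropped.
#'
#' @param survey a table from [simulate_survey()] (or with the same layout).
#' @return A numeric matrix with site row names and species column names.
#' @export
survey_community <- function(survey) {
  sp_cols <- grep("^sp[0-9]+$", names(survey), value = TRUE)
  agg <- survey |>
    dplyr::group_by(.data$site) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(sp_cols), sum), .groups = "drop")
  m <- as.matrix(agg[, sp_cols])
  rownames(m) <- agg$site
  m[, colSums(m) > 0, drop = FALSE]
}
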