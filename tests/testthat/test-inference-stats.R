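# table generator for ANCOVA simulations: 8 sites in 4 MPA/nMPA couplets,
# n_days replicates per site and year, optional fixed effects in dB
sim_feature_table <- function(n_days = 14, years = "2021", noise_sd = 2,
                              loc_sd = 1, protection_effect = 0,
                              year_effect = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sites <- default_sites()
  loc_eff <- stats::setNames(rnorm(4, 0, loc_sd), unique(sites$location))
  grid <- expand.grid(site = sites$site_id, day = seq_len(n_days),
                      year = years, stringsAsFactors = FALSE)
  grid <- dplyr::left_join(grid, dplyr::rename(sites, site = "site_id"),
                           by = "site")
  grid$date <- as.Date(ifelse(grid$year == "2015", "2015-02-01", "2021-02-01")) +
    grid$day
  grid$moon_phase <- moon_phase(grid$date)
  grid$psd_fpeak_db <- 60 + loc_eff[grid$location] +
    protection_effect * (grid$protection == "MPA") +
    year_effect * (grid$year == "2021") +
    rnorm(nrow(grid), 0, noise_sd)
  tibble::as_tibble(grid)
}

test_that("mixed ANCOVA reports type-II Wald chi-square per fixed term", {
  tbl <- sim_feature_table(years = c("2015", "2021"), year_effect = 6, seed = 1)
  fit <- fit_ancova(tbl, "psd_fpeak_db")
  expect_s3_class(fit, "reefpam_ancova")
  expect_setequal(fit$terms$term,
                  c("year", "protection", "year:protection", "moon_phase"))
  expect_true(all(fit$terms$chisq >= 0))
  expect_true(all(fit$terms$df >= 1))
  expect_true(all(fit$terms$p.value >= 0 & fit$terms$p.value <= 1))
  expect_lt(fit$terms$p.value[fit$terms$term == "year"], 0.001)
  td <- tidy(fit)
  expect_identical(td, fit$terms)
  gl <- glance(fit)
  expect_equal(gl$n, nrow(tbl))
})

test_that("with zero location variance the Wald tests match an OLS ANCOVA", {
  tbl <- sim_feature_table(loc_sd = 0, protection_effect = 1, seed = 2)
  fit <- suppressWarnings(fit_ancova(tbl, "psd_fpeak_db", fixed = "protection",
                                     interaction = FALSE))
  ols <- stats::lm(psd_fpeak_db ~ protection + moon_phase, data = tbl)
  oan <- car::Anova(ols, type = 2)
  for (term in c("protection", "moon_phase")) {
    got <- fit$terms$chisq[fit$terms$term == term]
    want <- oan[term, "Df"] * oan[term, "F value"] # Wald chi-square of the OLS fit
    expect_equal(got, want, tolerance = 1e-3)
  }
})

test_that("injected year effects are detected with overwhelming power", {
  for (i in 1:20) {
    tbl <- sim_feature_table(years = c("2015", "2021"), year_effect = 6,
                             noise_sd = 2, seed = 100 + i)
    fit <- fit_ancova(tbl, "psd_fpeak_db")
    expect_lt(fit$terms$p.value[fit$terms$term == "year"], 0.001)
  }
})

test_that("survey ANOVA handles aliases, absent metrics and degenerate input", {
  sc <- tiny_scenario(n_sites = 8, seed = 31)
  sv <- simulate_survey(sc, effect = list(richness = 10), n_transects = 3)
  fit <- fit_survey_anova(sv, "richness")
  expect_lt(fit$terms$p.value[1], 0.01)
  expect_equal(suppressWarnings(fit_survey_anova(sv, "coral"))$response, "coral_pct")
  expect_error(fit_survey_anova(sv, "no_such_metric"), "not found")

  # two identical groups: no protection signal at all
  half <- sv[sv$protection == "MPA", ]
  clone <- half
  clone$protection <- "nMPA"
  fit0 <- suppressWarnings(fit_survey_anova(dplyr::bind_rows(half, clone),
                                            "richness"))
  expect_lt(fit0$terms$chisq[1], 1e-10)
})

test_that("the 3 dB rule reproduces the published verdicts", {
  calls <- apply_3db_rule(c(4.07, 2.88, 3.41), c(1e-5, 0.01, 0.01))
  expect_equal(calls$verdict,
               c("significant", "non-significant", "significant"))
  # p above alpha blocks the call regardless of the dB difference
  expect_equal(apply_3db_rule(10, 0.2)$verdict, "non-significant")
  # negative differences use the absolute margin
  expect_equal(apply_3db_rule(-4.5, 0.001)$verdict, "significant")
  expect_error(apply_3db_rule(4, 0.01, margin = 0), "positive")
})

test_that("the 3 dB rule is monotone in |difference| and in p", {
  set.seed(8)
  for (i in 1:200) {
    d <- runif(1, 0, 6); p <- runif(1, 0, 0.1)
    v1 <- apply_3db_rule(d, p)$verdict
    v2 <- apply_3db_rule(d + runif(1, 0, 3), p)$verdict
    v3 <- apply_3db_rule(d, p * runif(1))$verdict
    if (v1 == "significant") {
      expect_equal(v2, "significant")
      expect_equal(v3, "significant")
    }
  }
})

test_that("CCA matches the generalized-eigenproblem oracle on random fixtures", {
  cases <- list(c(5, 4, 2, 101), c(6, 8, 3, 102), c(8, 10, 4, 103),
                c(7, 6, 2, 104))
  for (cs in cases) {
    m <- random_community(cs[1], cs[2], cs[4])
    set.seed(cs[4] + 1)
    z <- matrix(rnorm(cs[1] * cs[3]), cs[1], cs[3])
    got <- run_cca(m, z)
    want <- oracle_cca(m, z)
    expect_equal(got$total_inertia, want$total_inertia, tolerance = 1e-8)
    expect_equal(got$eig_constrained, want$eig_constrained, tolerance = 1e-8)
    expect_true(all(diff(got$eig_constrained) <= 1e-12)) # non-increasing
    expect_true(all(got$eig_constrained >= 0 & got$eig_constrained <= 1))
    expect_lte(length(got$eig_constrained), cs[3])
    expect_equal(got$total_inertia,
                 sum(got$eig_constrained) + sum(got$eig_unconstrained),
                 tolerance = 1e-8)
  }
})

test_that("a group split that fully determines composition recovers the CA axis", {
  # taxon profiles constant within each of two site groups: the indicator
  # constraint captures all structure, so the first constrained eigenvalue
  # equals the first eigenvalue of the unconstrained correspondence analysis
  m <- rbind(matrix(rep(c(30, 20, 10, 1), each = 3), 3, byrow = FALSE),
             matrix(rep(c(1, 2, 15, 25), each = 3), 3, byrow = FALSE))
  ind <- matrix(rep(c(1, 0), each = 3), ncol = 1)
  got <- run_cca(m, ind)
  ca <- oracle_cca(m, diag(6)) # saturated constraints = plain CA
  expect_equal(got$eig_constrained[1], ca$eig_constrained[1], tolerance = 1e-8)
})

test_that("saturated constraints recover the total inertia", {
  m <- random_community(6, 5, 7)
  ind <- stats::model.matrix(~ 0 + factor(1:6))
  got <- suppressWarnings(run_cca(m, ind))
  expect_equal(sum(got$eig_constrained), got$total_inertia, tolerance = 1e-8)
  expect_equal(got$prop_constrained, 1, tolerance = 1e-8)
})

test_that("structure-free constraints explain less than the first CA axis", {
  m <- random_community(8, 6, 9)
  full_ca <- oracle_cca(m, diag(8)) # saturated: unconstrained solution
  set.seed(10)
  z <- matrix(rnorm(8), ncol = 1)
  got <- suppressWarnings(run_cca(m, z))
  expect_lt(got$prop_constrained,
            full_ca$eig_constrained[1] / full_ca$total_inertia)
})

test_that("degenerate community input is cleaned with warnings", {
  m <- random_community(5, 4, 11)
  m[2, ] <- 0
  expect_warning(got <- run_cca(m, matrix(rnorm(5), 5, 1)[, , drop = FALSE]),
                 "site row")
  m2 <- random_community(5, 4, 12)
  m2[, 3] <- 0
  expect_warning(run_cca(m2, matrix(rnorm(5), 5)), "taxon")
  expect_error(run_cca(-m, matrix(rnorm(5), 5)), "non-negative")
})

test_that("site order permutation leaves statistics unchanged", {
  tbl <- sim_feature_table(years = c("2015", "2021"), year_effect = 4, seed = 13)
  fit1 <- fit_ancova(tbl, "psd_fpeak_db")
  perm <- sample(nrow(tbl))
  fit2 <- fit_ancova(tbl[perm, ], "psd_fpeak_db")
  expect_equal(fit1$terms$chisq, fit2$terms$chisq, tolerance = 1e-8)

  m <- random_community(6, 5, 14)
  z <- matrix(rnorm(12), 6, 2)
  a <- run_cca(m, z)
  p <- c(3, 1, 6, 2, 5, 4)
  b <- run_cca(m[p, ], z[p, ])
  expect_equal(a$eig_constrained, b$eig_constrained, tolerance = 1e-10)
})

test_that("group difference summaries report means, diffs and audits", {
  tbl <- tibble::tibble(
    year = rep(c("2015", "2021"), each = 6),
    site = rep(c("A", "B", "C"), 4),
    psd_fpeak_db = rep(c(60, 64), each = 6))
  out <- summarize_group_differences(tbl, "psd_fpeak_db", "year",
                                     within = "site")
  expect_equal(nrow(out), 4) # overall + 3 sites
  expect_true(all(out$diff_db == 4))
  expect_true(all(out$delta_a_db == 0 & out$delta_b_db == 0))

  set.seed(15)
  tbl$psd_fpeak_db <- tbl$psd_fpeak_db + rnorm(12)
  out2 <- summarize_group_differences(tbl, "psd_fpeak_db", "year")
  expect_gte(out2$delta_a_db, 0)
  expect_gte(out2$delta_b_db, 0)

  # empty cell is omitted with a log entry
  tbl3 <- tbl[!(tbl$site == "C" & tbl$year == "2021"), ]
  expect_message(
    out3 <- summarize_group_differences(tbl3, "psd_fpeak_db", "year",
                                        within = "site"),
    "omitting")
  expect_equal(nrow(out3), 3)
})

test_that("singular random effects fall back with a warning but return", {
  tbl <- sim_feature_table(loc_sd = 0, seed = 16)
  expect_warning(fit <- fit_ancova(tbl, "psd_fpeak_db", fixed = "protection",
                                   interaction = FALSE), "singular")
  expect_true(fit$singular)
  expect_true(is.finite(fit$terms$chisq[1]))
})
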