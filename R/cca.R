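#' Canonical correspondence analysis of community composition
#'
#' Relates a sites x taxa abundance table to site-level explanatory
#' features (benthic cover percentages and acoustic features) by canonical
#' correspondence analysis in the classical ter Braak formulation: the
#' community table is chi-square standardized, the constraints are
#' regressed onto it under site weights (row sums), and the fitted values
#' are decomposed by singular values. The computation is delegated to
#' [vegan::cca()], the same engine used throughout community ecology; this
#' wrapper adds input hygiene and a tidy result container.
#'
#' CCA operates on row profiles, so counts and relative abundances per site
#' give identical results. All-zero site rows or taxon columns are dropped
#' with a warning; constraint columns that are aliased (rank-deficient
#' after centering) are dropped by the engine with a warning.
#'
#' @param community sites x taxa matrix or data frame of non-negative
#'   counts or relative abundances.
#' @param constraints sites x features data frame or matrix (numeric).
#' @return A `reefpam_cca` object: `eig_constrained`, `eig_unconstrained`,
#'   `total_inertia`, `prop_constrained`, `site_scores` (weighted-average
#'   scores), `species_scores`, `biplot_scores` and the underlying vegan
#'   model (`engine`).
#' @seealso [tidy()], [autoplot()], [cca_ellipses()]
#' @export
run_cca <- function(community, constraints) {
  x <- as.matrix(community)
  z <- as.data.frame(constraints)
  if (any(x < 0)) abort("community abundances must be non-negative")
  keep_r <- rowSums(x) > 0
  keep_c <- colSums(x) > 0
  if (!all(keep_r)) {
    warn(sprintf("dropping %d all-zero site row(s)", sum(!keep_r)))
    x <- x[keep_r, , drop = FALSE]
    z <- z[keep_r, , drop = FALSE]
  }
  if (!all(keep_c)) {
    warn(sprintf("dropping %d all-zero taxon column(s)", sum(!keep_c)))
    x <- x[, keep_c, drop = FALSE]
  }
  mod <- suppressWarnings(vegan::cca(X = x, Y = as.matrix(z)))
  if (!is.null(mod$CCA$alias)) {
    warn(paste0("dropped aliased constraint(s): ",
                paste(mod$CCA$alias, collapse = ", ")))
  }
  eig_c <- as.numeric(mod$CCA$eig)
  eig_u <- as.numeric(mod$CA$eig)
  total <- mod$tot.chi
  n_axes <- length(eig_c)
  structure(
    list(
      eig_constrained = eig_c,
      eig_unconstrained = eig_u,
      total_inertia = total,
      prop_constrained = sum(eig_c) / total,
      site_scores = vegan::scores(mod, display = "wa",
                                  choices = seq_len(max(n_axes, 1))),
      species_scores = vegan::scores(mod, display = "sp",
                                     choices = seq_len(max(n_axes, 1))),
      biplot_scores = mod$CCA$biplot,
      engine = mod
    ),
    class = "reefpam_cca"
  )
}

#' @export
print.reefpam_cca <- function(x, ...) {
  cat(sprintf(
    "<reefpam_cca> total inertia %.4f, %d constrained axes (%.1f%% of inertia)\n",
    x$total_inertia, length(x$eig_constrained), 100 * x$prop_constrained))
  cat("constrained eigenvalues:", signif(x$eig_constrained, 4), "\n")
  invisible(x)
}

#' @rdname run_cca
#' @param x a `reefpam_cca` object.
#' @param ... unused.
#' @export
tidy.reefpam_cca <- function(x, ...) {
  tibble(
    axis = c(paste0("CCA", seq_along(x$eig_constrained)),
             paste0("CA", seq_along(x$eig_unconstrained))),
    eigenvalue = c(x$eig_constrained, x$eig_unconstrained),
    proportion = c(x$eig_constrained, x$eig_unconstrained) / x$total_inertia,
    constrained = rep(c(TRUE, FALSE),
                      c(length(x$eig_constrained), length(x$eig_unconstrained)))
  )
}

#' @rdname run_cca
#' @export
glance.reefpam_cca <- function(x, ...) {
  tibble(total_inertia = x$total_inertia,
         inertia_constrained = sum(x$eig_constrained),
         prop_constrained = x$prop_constrained,
         n_constrained_axes = length(x$eig_constrained))
}

#' 95% ordination ellipses per group
#'
#' Bivariate normal 95% ellipse parameters (center and covariance of the
#' first two site-score axes) per grouping level, exportable as CSV for
#' ordination plots.
#'
#' @param cca_res a `reefpam_cca` object.
#' @param groups vector of group labels, one per (kept) site.
#' @return A tibble: `group`, `center1`, `center2`, `var1`, `var2`, `cov12`,
#'   `n`.
#' @export
cca_ellipses <- function(cca_res, groups) {
  s <- cca_res$site_scores
  if (nrow(s) != length(groups)) abort("`groups` must match the site rows")
  if (ncol(s) < 2) abort("need at least two ordination axes")
  purrr::map_dfr(split(seq_len(nrow(s)), groups), function(i) {
    m <- s[i, 1:2, drop = FALSE]
    v <- stats::cov(m)
    tibble(center1 = mean(m[, 1]), center2 = mean(m[, 2]),
           var1 = v[1, 1], var2 = v[2, 2], cov12 = v[1, 2], n = length(i))
  }, .id = "group")
}
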