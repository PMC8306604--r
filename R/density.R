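# Equal-clade-mass aggregation of GEC TMRCA samples into density/CDF curves,
# percentiles, and the clade-size vs TMRCA regressions.

#' Aggregate per-region TMRCA density with equal mass per clade
#'
#' Each clade's TMRCA samples get their own Gaussian kernel density estimate
#' (Silverman's rule-of-thumb bandwidth, `stats::bw.nrd0`), evaluated on a
#' shared grid from 0 to 1.1 x the oldest sample, truncated at age 0 and
#' renormalised to unit mass; the aggregate is the unweighted mean of the
#' per-clade curves, so every clade contributes mass 1/(number of clades)
#' regardless of how many posterior trees it appeared in. Clades with fewer
#' than three samples (or zero sample spread) fall back to a floor bandwidth.
#'
#' @param gecs a `gec_set` from [extract_gecs()].
#' @param region region code to aggregate.
#' @param n_grid number of grid points.
#' @param floor_bw floor bandwidth in years.
#' @return object of class `gec_density`: list with `region`, `time` (yBP,
#'   ascending), `pdf`, `cdf`, `components` (grid x clade matrix of unit-mass
#'   per-clade curves), `bandwidths`, `clade_ids`.
#' @export
aggregate_density <- function(gecs, region, n_grid = 512, floor_bw = 100) {
  stopifnot(inherits(gecs, "gec_set"))
  ids <- gecs$clades$clade_id[gecs$clades$region == region]
  if (!length(ids)) stop("no clades for region ", region)
  samples <- gecs$tmrca[ids]
  if (any(lengths(samples) < 1L)) stop("clade without TMRCA samples")
  grid <- seq(0, 1.1 * max(unlist(samples)), length.out = n_grid)
  bws <- numeric(length(ids))
  comp <- matrix(0, n_grid, length(ids), dimnames = list(NULL, ids))
  for (j in seq_along(ids)) {
    x <- samples[[j]]
    bw <- if (length(x) >= 3L) tryCatch(bw.nrd0(x), error = function(e) 0) else 0
    if (!is.finite(bw) || bw <= 0) bw <- floor_bw
    bws[j] <- bw
    d <- rowMeans(outer(grid, x, function(g, xi) dnorm(g, xi, bw)))
    mass <- trapz(grid, d)
    if (mass <= 0) stop("degenerate density for clade ", ids[j])
    comp[, j] <- d / mass
  }
  pdf <- rowMeans(comp)
  cdf <- cumtrapz(grid, pdf)
  cdf <- pmin(cdf / max(cdf), 1)
  structure(list(region = region, time = grid, pdf = pdf, cdf = cdf,
                 components = comp, bandwidths = setNames(bws, ids),
                 clade_ids = ids),
            class = "gec_density")
}

#' TMRCA percentile from an aggregate density
#'
#' Time `t` such that the equal-clade-weighted CDF at `t` equals `q`, by
#' linear interpolation on the grid.
#'
#' @param curve a `gec_density` from [aggregate_density()].
#' @param q percentile fraction(s) in (0, 1).
#' @return yBP value(s), one per `q`.
#' @export
tmrca_percentile <- function(curve, q) {
  stopifnot(inherits(curve, "gec_density"))
  if (any(q <= 0 | q >= 1)) stop("q must be in (0, 1)")
  vapply(q, function(qi) {
    approx(curve$cdf, curve$time, xout = qi, ties = "ordered", rule = 2)$y
  }, 0)
}

#' Clade size vs median TMRCA regressions
#'
#' Per-region ordinary least squares of median TMRCA on clade size, linear
#' and quadratic.
#'
#' @param gecs a `gec_set`.
#' @param regions region codes to fit (default: all with >= 3 clades).
#' @return class `size_age_regression`: per-region list with `linear` and
#'   `quadratic` coefficient vectors, residual sums of squares, and `n`.
#' @export
size_age_regression <- function(gecs, regions = NULL) {
  stopifnot(inherits(gecs, "gec_set"))
  cl <- gecs$clades
  if (is.null(regions)) {
    tab <- table(cl$region)
    regions <- names(tab)[tab >= 3L]
    if (!length(regions)) stop("no region has >= 3 clades")
  }
  out <- lapply(regions, function(r) {
    d <- cl[cl$region == r, ]
    if (nrow(d) < 3L) stop("region ", r, " has fewer clades (", nrow(d),
                           ") than quadratic fit parameters")
    lin <- lm(median_tmrca ~ size, data = d)
    quad <- lm(median_tmrca ~ size + I(size^2), data = d)
    list(linear = coef(lin), quadratic = coef(quad),
         rss_linear = sum(resid(lin)^2), rss_quadratic = sum(resid(quad)^2),
         n = nrow(d))
  })
  names(out) <- regions
  structure(out, class = "size_age_regression")
}

#' @export
print.gec_density <- function(x, ...) {
  cat(sprintf("Aggregate TMRCA density, region %s: %d clades, grid 0..%.0f yBP\n",
              x$region, length(x$clade_ids), max(x$time)))
  cat(sprintf("  integral %.4f; median %.0f yBP; 90th percentile %.0f yBP\n",
              trapz(x$time, x$pdf),
              tmrca_percentile(x, 0.5), tmrca_percentile(x, 0.9)))
  invisible(x)
}
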