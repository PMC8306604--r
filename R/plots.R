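# Base-graphics plot methods for the main result objects.

#' Plot an aggregate TMRCA density or CDF
#'
#' @param x a `gec_density`.
#' @param what `"pdf"` or `"cdf"`.
#' @param ... passed to `plot.default`.
#' @export
plot.gec_density <- function(x, what = c("pdf", "cdf"), ...) {
  what <- match.arg(what)
  y <- x[[what]]
  plot.default(x$time / 1000, y, type = "l",
               xlab = "TMRCA (ka BP)",
               ylab = if (what == "pdf") "density" else "cumulative probability",
               main = paste("Aggregate TMRCA", toupper(what), "-", x$region), ...)
  if (what == "cdf") abline(h = c(0.5, 0.9), lty = 3, col = "grey50")
  invisible(x)
}

#' Plot per-clade TMRCA distributions of a GEC set
#'
#' One density ridge per clade, grouped by region, in the style of
#' per-clade TMRCA summaries (vertical tick at each clade's median).
#'
#' @param x a `gec_set`.
#' @param floor_bw floor bandwidth (years) for clades with few samples.
#' @param ... unused.
#' @export
plot.gec_set <- function(x, floor_bw = 100, ...) {
  cl <- x$clades
  if (!nrow(cl)) {
    warning("empty GEC set")
    return(invisible(x))
  }
  xmax <- 1.1 * max(unlist(x$tmrca))
  grid <- seq(0, xmax, length.out = 256)
  cols <- setNames(hcl.colors(length(unique(cl$region)), "Dark 3"),
                   sort(unique(cl$region)))
  plot.default(NA, xlim = c(0, xmax / 1000), ylim = c(0, nrow(cl) + 1),
               xlab = "TMRCA (ka BP)", ylab = "clade", yaxt = "n",
               main = "Per-clade TMRCA distributions")
  axis(2, at = seq_len(nrow(cl)), labels = cl$clade_id, las = 2, cex.axis = 0.6)
  for (i in seq_len(nrow(cl))) {
    s <- x$tmrca[[cl$clade_id[i]]]
    bw <- if (length(s) >= 3) bw.nrd0(s) else 0
    if (!is.finite(bw) || bw <= 0) bw <- floor_bw
    d <- rowMeans(outer(grid, s, function(g, xi) dnorm(g, xi, bw)))
    d <- 0.9 * d / max(d)
    polygon(grid / 1000, i + d, col = paste0(cols[cl$region[i]], "55"),
            border = cols[cl$region[i]])
    lines(rep(cl$median_tmrca[i] / 1000, 2), c(i, i + 0.9),
          col = cols[cl$region[i]])
  }
  legend("topright", legend = names(cols), fill = cols, bty = "n")
  invisible(x)
}

#' Plot corrected migration-rate curves through time
#'
#' Observed-minus-expected transition counts per interval, one line per
#' ordered region pair with any events.
#'
#' @param x a `corrected_rates`.
#' @param ... unused.
#' @export
plot.corrected_rates <- function(x, ...) {
  r <- x$rates
  active <- names(which(tapply(r$observed, r$pair, sum) > 0))
  if (!length(active)) {
    warning("no transitions mapped")
    return(invisible(x))
  }
  cols <- setNames(hcl.colors(length(active), "Dark 3"), active)
  ylim <- range(r$corrected[r$pair %in% active])
  plot.default(NA, xlim = range(r$start + x$interval / 2) / 1000, ylim = ylim,
               xlab = "time (ka BP)", ylab = "observed - expected transitions",
               main = sprintf("Corrected migration rates (%d yr intervals)",
                              x$interval))
  abline(h = 0, lty = 3)
  for (p in active) {
    d <- r[r$pair == p, ]
    lines((d$start + x$interval / 2) / 1000, d$corrected, col = cols[p], lwd = 2)
  }
  legend("topright", legend = active, col = cols, lwd = 2, bty = "n", cex = 0.8)
  invisible(x)
}
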