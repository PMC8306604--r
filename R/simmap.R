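# Stochastic character mapping of region transitions on a dated tree, the
# branch-length profile through time, and the observed-minus-expected
# correction of transition counts per time interval.

# Sample joint node states given tip states: root from prior x root partials,
# then each child from P_edge[parent, ] x child partials, preorder.
# Returns an n x n_node integer matrix.
sample_node_states <- function(pp, P, prior, n) {
  tr <- pp$tree
  k <- length(pp$states)
  n_all <- pp$n_tip + tr$Nnode
  states <- matrix(NA_integer_, n, n_all)
  w0 <- prior * pp$partials[pp$root, ]
  if (sum(w0) <= 0) stop("tip configuration has zero likelihood under Q and root prior")
  states[, pp$root] <- sample.int(k, n, replace = TRUE, prob = w0)
  for (e in rev(seq_len(nrow(tr$edge)))) {   # preorder: parents before children
    p <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
    W <- P[[e]] * rep(pp$partials[ch, ], each = k)   # W[i, j] oc P(i->j) L_ch(j)
    sp <- states[, p]
    for (i in seq_len(k)) {
      sel <- which(sp == i)
      if (!length(sel)) next
      wi <- W[i, ]
      if (sum(wi) <= 0) {
        stop("impossible branch under Q: edge to node ", ch,
             " from parent state ", pp$states[i])
      }
      states[sel, ch] <- sample.int(k, length(sel), replace = TRUE, prob = wi)
    }
  }
  states
}

# Endpoint-conditioned CTMC path on one branch by uniformization.
# Returns times (from the older endpoint, in (0, t)) and the state after each
# real jump; the dominated jump count N is sampled from its exact conditional
# distribution, then the jump chain is filled in backward and virtual jumps
# dropped.
sample_path_uniformized <- function(a, b, t, Om, R, Rpow, Pab, min_one = FALSE,
                                    n_cap = 10000L) {
  if (Om <= 0) return(list(time = numeric(0), to = integer(0)))
  mu <- Om * t
  u <- runif(1L)
  if (min_one) {
    # condition on at least one dominated jump (used with the pre-screen,
    # which has already decided N > 0)
    p0 <- if (a == b) dpois(0, mu) / Pab else 0
    u <- p0 + u * (1 - p0)
  }
  acc <- 0
  n_jump <- -1L
  nmax <- max(20L, ceiling(mu + 12 * sqrt(mu) + 20))
  for (m in 0:min(nmax, n_cap)) {
    Rm <- Rpow$get(m)
    acc <- acc + dpois(m, mu) * Rm[a, b] / Pab
    if (u <= acc) { n_jump <- m; break }
  }
  if (n_jump < 0L) n_jump <- nmax    # vanishing tail; cap
  if (n_jump == 0L) return(list(time = numeric(0), to = integer(0)))
  s <- integer(n_jump + 1L)
  s[1L] <- a
  s[n_jump + 1L] <- b
  if (n_jump > 1L) {
    for (j in 2:n_jump) {
      w <- R[s[j - 1L], ] * Rpow$get(n_jump + 1L - j)[, b]
      s[j] <- sample.int(length(w), 1L, prob = w)
    }
  }
  tms <- sort(runif(n_jump)) * t
  real <- which(s[-1L] != s[-(n_jump + 1L)])
  list(time = tms[real], to = s[real + 1L])
}

# Cache of powers of the uniformized transition kernel R.
make_rpow <- function(R) {
  pows <- list(diag(nrow(R)))
  get <- function(m) {
    while (length(pows) < m + 1L) {
      pows[[length(pows) + 1L]] <<- pows[[length(pows)]] %*% R
    }
    pows[[m + 1L]]
  }
  list(get = get)
}

#' Stochastic mapping realisations of region transitions
#'
#' Simulates joint histories of the region character on a dated tree,
#' conditional on the tip regions, a generator `Q` and a root prior: node
#' states are drawn from their joint conditional distribution, then each
#' branch's transition path is drawn conditioned on its endpoint states by
#' uniformization (exact for small state spaces). A state transition is the
#' model's analogue of a migration event between two regions.
#'
#' @inheritParams log_likelihood
#' @param n number of realisations.
#' @param tip_ages optional named tip ages (yBP).
#' @param seed optional integer seed.
#' @return class `mapping_set`: list with `node_states` (n x nodes integer
#'   matrix), `events` (list of n data.frames: `branch` (child node id),
#'   `age` yBP, `from`, `to`), `tree` (postorder), `states`, `ages`, `Q`,
#'   `n`.
#' @export
simulate_mappings <- function(tree, regions, Q, root_prior = "equal", n = 1000,
                              tip_ages = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pp <- ctmc_partials(tree, regions, Q)
  tr <- pp$tree
  k <- length(pp$states)
  ages <- suppressWarnings(node_ages(tr, tip_ages))
  P <- edge_pmats(Q, tr$edge.length)
  Lr <- pp$partials[pp$root, ]
  prior <- resolve_root_prior(root_prior, pp$states, Lr)
  states <- sample_node_states(pp, P, prior, n)

  Om <- max(-diag(Q))
  events <- vector("list", n)
  if (Om <= 0) {
    for (i in seq_len(n)) events[[i]] <- empty_events()
  } else {
    R <- diag(k) + Q / Om
    Rpow <- make_rpow(R)
    ne <- nrow(tr$edge)
    # probability of zero dominated jumps given equal endpoints, per edge:
    # cheap pre-screen so most (a == b) branches skip the path sampler
    p0 <- matrix(0, ne, k)
    for (e in seq_len(ne)) {
      for (i in seq_len(k)) {
        if (P[[e]][i, i] > 0) {
          p0[e, i] <- exp(-Om * tr$edge.length[e]) / P[[e]][i, i]
        }
      }
    }
    parent_age <- ages[tr$edge[, 1L]]
    for (i in seq_len(n)) {
      ev_branch <- integer(0); ev_age <- numeric(0)
      ev_from <- integer(0); ev_to <- integer(0)
      for (e in seq_len(ne)) {
        a <- states[i, tr$edge[e, 1L]]
        b <- states[i, tr$edge[e, 2L]]
        screened <- a == b && p0[e, a] > 0
        if (screened && runif(1L) <= p0[e, a]) next
        path <- sample_path_uniformized(a, b, tr$edge.length[e], Om, R, Rpow,
                                        P[[e]][a, b], min_one = screened)
        m <- length(path$to)
        if (m) {
          ev_branch <- c(ev_branch, rep.int(tr$edge[e, 2L], m))
          ev_age <- c(ev_age, parent_age[e] - path$time)
          ev_from <- c(ev_from, c(a, path$to[-m]))
          ev_to <- c(ev_to, path$to)
        }
      }
      events[[i]] <- data.frame(branch = ev_branch, age = ev_age,
                                from = pp$states[ev_from],
                                to = pp$states[ev_to],
                                stringsAsFactors = FALSE)
    }
  }
  structure(list(node_states = states, events = events, tree = tr,
                 states = pp$states, ages = ages, Q = Q, n = n,
                 root_prior = root_prior),
            class = "mapping_set")
}

empty_events <- function() {
  data.frame(branch = integer(0), age = numeric(0),
             from = character(0), to = character(0), stringsAsFactors = FALSE)
}

#' Total branch length per time interval
#'
#' Divides the tree into successive non-overlapping intervals of `interval`
#' years from the tips (age 0) to the root and sums the branch length
#' overlapping each interval; each branch contributes to every interval it
#' spans, by the overlapping length. Interval totals sum to the total tree
#' length.
#'
#' @param tree rooted dated `phylo`.
#' @param interval interval width in years (> 0).
#' @param tip_ages optional named tip ages (yBP).
#' @return class `branch_profile`: data.frame with `start`, `end`, `length`;
#'   attributes `interval` and `total`.
#' @export
branch_length_profile <- function(tree, interval = 1000, tip_ages = NULL) {
  if (interval <= 0) stop("interval must be positive")
  ages <- suppressWarnings(node_ages(tree, tip_ages))
  ap <- ages[tree$edge[, 1L]]
  ac <- ages[tree$edge[, 2L]]
  nb <- max(1L, ceiling((max(ages) - 1e-12) / interval))
  starts <- (seq_len(nb) - 1L) * interval
  len <- vapply(starts, function(s) {
    sum(pmax(0, pmin(ap, s + interval) - pmax(ac, s)))
  }, 0)
  out <- data.frame(start = starts, end = starts + interval, length = len)
  attr(out, "interval") <- interval
  attr(out, "total") <- sum(tree$edge.length)
  class(out) <- c("branch_profile", "data.frame")
  out
}

#' Expected transition counts per interval
#'
#' Distributes a total transition count over time intervals in proportion to
#' the branch length each interval contains — the count expected if
#' transitions occurred at a constant rate per lineage per year.
#'
#' @param total total number of transitions (>= 0).
#' @param profile a `branch_profile`.
#' @return numeric vector of per-interval expectations; sums to `total`.
#' @export
expected_counts <- function(total, profile) {
  if (total < 0) stop("total must be >= 0")
  if (!nrow(profile)) stop("empty branch-length profile")
  total * profile$length / sum(profile$length)
}

#' Observed, expected and corrected migration rates through time
#'
#' For each ordered region pair: the observed series is the mean number of
#' mapped transitions per `interval`-year bin across realisations; the
#' expected series redistributes that pair's total in proportion to the
#' branch-length profile; the corrected series is observed minus expected
#' (its interval sum is zero by construction). Events on an interval
#' boundary belong to the older interval. A finer histogram of mean counts
#' (default 500-year bins) is reported alongside.
#'
#' @param maps a `mapping_set` from [simulate_mappings()].
#' @param interval correction interval width in years.
#' @param reporting_bin histogram bin width in years.
#' @param profile optional precomputed `branch_profile` (must use
#'   `interval`).
#' @param tip_ages optional named tip ages.
#' @return class `corrected_rates`: list with `rates` (data.frame: `pair`,
#'   `start`, `observed`, `expected`, `corrected`), `histogram` (data.frame:
#'   `pair`, `start`, `mean_count`), `profile`, `interval`, `reporting_bin`,
#'   `n`.
#' @export
corrected_rates <- function(maps, interval = 1000, reporting_bin = 500,
                            profile = NULL, tip_ages = NULL) {
  stopifnot(inherits(maps, "mapping_set"))
  if (is.null(profile)) {
    profile <- branch_length_profile(maps$tree, interval, tip_ages)
  }
  stopifnot(attr(profile, "interval") == interval)
  nb <- nrow(profile)
  pairs <- ordered_pairs(maps$states)
  n <- maps$n

  ev <- do.call(rbind, lapply(seq_len(n), function(i) {
    e <- maps$events[[i]]
    if (nrow(e)) cbind(e, realisation = i) else NULL
  }))
  bin_counts <- function(width, nbins) {
    counts <- array(0, dim = c(nrow(pairs), nbins, n))
    if (!is.null(ev) && nrow(ev)) {
      pr <- match(paste0(ev$from, "->", ev$to), pairs$label)
      bi <- pmin(nbins, floor(ev$age / width) + 1L)
      for (r in seq_len(nrow(ev))) {
        counts[pr[r], bi[r], ev$realisation[r]] <-
          counts[pr[r], bi[r], ev$realisation[r]] + 1
      }
    }
    counts
  }

  cc <- bin_counts(interval, nb)
  observed <- apply(cc, c(1L, 2L), mean)
  lenprop <- profile$length / sum(profile$length)
  rates <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(p) {
    obs <- observed[p, ]
    exp_k <- sum(obs) * lenprop
    data.frame(pair = pairs$label[p], start = profile$start,
               observed = obs, expected = exp_k,
               corrected = obs - exp_k, stringsAsFactors = FALSE)
  }))
  # per-realisation corrected values, for Monte-Carlo standard errors
  corr_se <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(p) {
    ci <- cc[p, , , drop = FALSE]
    dim(ci) <- c(nb, n)
    tot_i <- colSums(ci)
    dev <- ci - outer(lenprop, tot_i)
    data.frame(pair = pairs$label[p], start = profile$start,
               se = apply(dev, 1L, sd) / sqrt(n), stringsAsFactors = FALSE)
  }))
  rates$se <- corr_se$se

  nb2 <- max(1L, ceiling((max(maps$ages) - 1e-12) / reporting_bin))
  c2 <- bin_counts(reporting_bin, nb2)
  m2 <- apply(c2, c(1L, 2L), mean)
  histogram <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(p) {
    data.frame(pair = pairs$label[p],
               start = (seq_len(nb2) - 1L) * reporting_bin,
               mean_count = m2[p, ], stringsAsFactors = FALSE)
  }))
  structure(list(rates = rates, histogram = histogram, profile = profile,
                 interval = interval, reporting_bin = reporting_bin, n = n),
            class = "corrected_rates")
}

#' @export
print.mapping_set <- function(x, ...) {
  nev <- vapply(x$events, nrow, 0L)
  cat(sprintf("Stochastic mapping: %d realisations on %d-tip tree; mean %.2f transition(s) per realisation\n",
              x$n, length(x$tree$tip.label), mean(nev)))
  invisible(x)
}

#' @export
print.corrected_rates <- function(x, ...) {
  cat(sprintf("Corrected migration rates: %d-year intervals (histogram %d-year), %d realisations\n",
              x$interval, x$reporting_bin, x$n))
  tot <- tapply(x$rates$observed, x$rates$pair, sum)
  cat("Mean transitions per realisation by pair:\n")
  print(round(tot, 3))
  invisible(x)
}
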