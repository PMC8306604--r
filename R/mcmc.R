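# Bayesian fitting of migration models: adaptive random-walk MCMC on log
# rates, stepping-stone marginal likelihoods, and log10 Bayes factors.

# Rate prior. Default: independent exponentials with mean 1/(root age), a
# proper, scale-aware prior (one expected transition per lineage path from
# root to tip is the natural unit). A point-mass prior is supported as a
# degenerate case (it turns the marginal likelihood into a plain likelihood).
resolve_rate_prior <- function(prior, root_age, n_par) {
  if (is.null(prior)) prior <- list(type = "exp", rate = root_age)
  stopifnot(is.list(prior), prior$type %in% c("exp", "point"))
  if (prior$type == "exp") {
    stopifnot(prior$rate > 0)
    prior$log_density <- function(r) sum(dexp(r, rate = prior$rate, log = TRUE))
    prior$sample <- function() rexp(n_par, rate = prior$rate)
    prior$mean <- 1 / prior$rate
  } else {
    stopifnot(length(prior$value) == n_par, all(prior$value > 0))
  }
  prior
}

mcmc_prepare <- function(tree, regions, model, root_prior, prior, tip_ages = NULL) {
  stopifnot(inherits(model, "migration_model"))
  if (model$n_par < 1L) stop("model has no free parameters")
  tr <- reorder(tree, "postorder")
  check_regions_total(regions, tr$tip.label)
  tipst <- match(unname(regions[tr$tip.label]), model$states)
  if (anyNA(tipst)) stop("tip regions outside the model's state space")
  n_tip <- length(tr$tip.label)
  root_age <- max(suppressWarnings(node_ages(tr, tip_ages)))
  prior <- resolve_rate_prior(prior, root_age, model$n_par)
  loglik <- function(rates) {
    Q <- make_Q(model, rates)
    res <- ctmc_partials_cpp(tr$edge, tr$edge.length, n_tip, n_tip + tr$Nnode,
                             tipst, Q)
    Lr <- res$partials[n_tip + 1L, ]
    if (sum(Lr) <= 0) return(-Inf)
    pri <- resolve_root_prior(root_prior, model$states, Lr)
    v <- sum(pri * Lr)
    if (v <= 0) return(-Inf)
    log(v) + res$logscale[n_tip + 1L]
  }
  list(tree = tr, tipst = tipst, n_tip = n_tip, root_age = root_age,
       prior = prior, loglik = loglik)
}

# One adaptive Metropolis-within-Gibbs sweep chain over theta = log(rates).
# Adaptation (Robbins-Monro toward `target`) runs only while `adapt_until`.
run_rw_chain <- function(loglik, log_prior, theta0, n_sweep, adapt_until,
                         lstep0 = NULL, power = 1, target = 0.44,
                         record = TRUE) {
  p <- length(theta0)
  theta <- theta0
  lstep <- if (is.null(lstep0)) rep(0, p) else lstep0
  lp <- log_prior(theta)
  ll <- loglik(exp(theta))
  out_theta <- if (record) matrix(NA_real_, n_sweep, p) else NULL
  out_ll <- if (record) numeric(n_sweep) else NULL
  n_acc <- 0L
  for (it in seq_len(n_sweep)) {
    for (j in seq_len(p)) {
      th2 <- theta
      th2[j] <- theta[j] + rnorm(1L, 0, exp(lstep[j]))
      lp2 <- log_prior(th2)
      ll2 <- loglik(exp(th2))
      a <- (lp2 + power * ll2) - (lp + power * ll)
      acc_prob <- if (is.nan(a)) 0 else min(1, exp(a))
      if (runif(1L) < acc_prob) {
        theta <- th2; lp <- lp2; ll <- ll2
        n_acc <- n_acc + 1L
      }
      if (it <= adapt_until) {
        gam <- min(0.5, 5 / sqrt(it))
        lstep[j] <- lstep[j] + gam * (acc_prob - target)
      }
    }
    if (record) {
      out_theta[it, ] <- theta
      out_ll[it] <- ll
    }
  }
  list(theta = out_theta, ll = out_ll, last_theta = theta, lstep = lstep,
       accept = n_acc / (n_sweep * p))
}

#' Fit a migration model by MCMC
#'
#' Adaptive log-scale random-walk Metropolis over the model's rate
#' parameters, under independent exponential rate priors (mean 1/root age by
#' default). The ancestral root-state posterior is the marginal root
#' reconstruction averaged over (a thinned subset of) the posterior rate
#' samples. Non-convergence (minimum effective sample size below
#' `ess_warn`) raises a warning; the result is still returned.
#'
#' @param tree rooted `phylo`, branch lengths in years.
#' @param regions named character vector tip -> region.
#' @param model a `migration_model`.
#' @param root_prior root prior (see [log_likelihood()]).
#' @param n_iter post-burn-in MCMC sweeps (one update per parameter per
#'   sweep).
#' @param burnin adaptation/burn-in sweeps.
#' @param thin keep every `thin`-th sweep.
#' @param prior rate prior: `NULL` for the default exponential, or
#'   `list(type = "exp", rate = <lambda>)`.
#' @param tip_ages optional named tip ages (yBP).
#' @param seed optional integer seed (reproducible chains).
#' @param ess_warn effective-sample-size warning threshold.
#' @return class `migration_fit`: list with `samples` (thinned rate matrix),
#'   `median`, `mean`, `root_posterior`, `log10_ml = NA` (see
#'   [stepping_stone()]), `ess`, `accept`, `settings`.
#' @export
fit_mcmc <- function(tree, regions, model, root_prior = "equal",
                     n_iter = 10000, burnin = max(200, n_iter %/% 5),
                     thin = 10, prior = NULL, tip_ages = NULL, seed = NULL,
                     ess_warn = 100) {
  if (!is.null(seed)) set.seed(seed)
  prep <- mcmc_prepare(tree, regions, model, root_prior, prior, tip_ages)
  if (prep$prior$type == "point") stop("point-mass prior cannot be sampled")
  log_prior <- function(theta) prep$prior$log_density(exp(theta)) + sum(theta)
  theta0 <- rep(log(prep$prior$mean), model$n_par)
  ch <- run_rw_chain(prep$loglik, log_prior, theta0,
                     n_sweep = burnin + n_iter, adapt_until = burnin)
  keep <- seq(burnin + 1L, burnin + n_iter, by = thin)
  samples <- exp(ch$theta[keep, , drop = FALSE])
  colnames(samples) <- model$par_names
  ll_keep <- ch$ll[keep]
  ess_vals <- apply(log(samples), 2L, ess)
  if (min(ess_vals) < ess_warn) {
    warning(sprintf("possible non-convergence: min ESS %.0f < %d",
                    min(ess_vals), ess_warn))
  }
  # root state posterior averaged over <= 200 posterior draws
  sub <- samples[unique(round(seq(1L, nrow(samples),
                                  length.out = min(200L, nrow(samples))))), ,
                 drop = FALSE]
  root_post <- rowMeans(apply(sub, 1L, function(r) {
    Q <- make_Q(model, r)
    res <- ctmc_partials_cpp(prep$tree$edge, prep$tree$edge.length, prep$n_tip,
                             prep$n_tip + prep$tree$Nnode, prep$tipst, Q)
    Lr <- res$partials[prep$n_tip + 1L, ]
    pri <- resolve_root_prior(root_prior, model$states, Lr)
    w <- pri * Lr
    w / sum(w)
  }))
  names(root_post) <- model$states
  med <- apply(samples, 2L, median)
  structure(list(model = model, samples = samples, loglik_samples = ll_keep,
                 median = med, mean = colMeans(samples),
                 Q_median = make_Q(model, med),
                 root_posterior = root_post, root_prior = root_prior,
                 ess = ess_vals, accept = ch$accept,
                 settings = list(n_iter = n_iter, burnin = burnin, thin = thin,
                                 prior = prep$prior[c("type", "rate")],
                                 seed = seed, root_age = prep$root_age)),
            class = "migration_fit")
}

#' Stepping-stone marginal likelihood
#'
#' Estimates the (natural-log) marginal likelihood by power-posterior
#' stepping-stone sampling along temperatures `beta_k = (k/K)^(1/alpha)`
#' (quantiles of Beta(alpha, 1); `alpha = 0.4` places stones densely near the
#' prior, where the integrand varies fastest). The prior stone (`beta = 0`)
#' is sampled exactly; each subsequent stone continues a short adaptive MCMC
#' chain from its predecessor. With a point-mass prior the marginal reduces
#' to the likelihood at that point (degenerate case, useful for checks).
#'
#' @inheritParams fit_mcmc
#' @param stones number of stepping stones K.
#' @param iter_per_stone MCMC sweeps per stone (a leading fraction
#'   `burnin_frac` is discarded within each stone).
#' @param burnin_frac within-stone burn-in fraction.
#' @param alpha Beta-quantile schedule parameter.
#' @return class `stepping_stone`: list with `log_ml` (natural log),
#'   `log10_ml`, `se_log` / `se_log10` (Monte-Carlo standard errors,
#'   autocorrelation-adjusted), `betas`, `settings`.
#' @export
stepping_stone <- function(tree, regions, model, root_prior = "equal",
                           stones = 250, iter_per_stone = 10000,
                           burnin_frac = 0.2, alpha = 0.4, prior = NULL,
                           tip_ages = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  prep <- mcmc_prepare(tree, regions, model, root_prior, prior, tip_ages)
  if (prep$prior$type == "point") {
    ll <- prep$loglik(prep$prior$value)
    return(structure(list(log_ml = ll, log10_ml = ll / log(10),
                          se_log = 0, se_log10 = 0, betas = c(0, 1),
                          settings = list(prior = "point")),
                     class = "stepping_stone"))
  }
  stopifnot(stones >= 2L, iter_per_stone >= 10L)
  betas <- ((0:stones) / stones)^(1 / alpha)
  log_prior <- function(theta) prep$prior$log_density(exp(theta)) + sum(theta)
  nb <- max(1L, round(burnin_frac * iter_per_stone))

  log_rk <- numeric(stones)
  var_rk <- numeric(stones)
  theta <- rep(log(prep$prior$mean), model$n_par)
  lstep <- rep(0, model$n_par)
  for (k in seq_len(stones)) {
    b <- betas[k]
    db <- betas[k + 1L] - b
    if (b == 0) {
      ll <- vapply(seq_len(iter_per_stone),
                   function(i) prep$loglik(prep$prior$sample()), 0)
      theta <- log(prep$prior$sample())
    } else {
      ch <- run_rw_chain(prep$loglik, log_prior, theta,
                         n_sweep = iter_per_stone, adapt_until = nb,
                         lstep0 = lstep, power = b)
      ll <- ch$ll[(nb + 1L):iter_per_stone]
      theta <- ch$last_theta
      lstep <- ch$lstep
    }
    w <- db * ll
    m <- max(w)
    if (!is.finite(m)) {   # all samples impossible: marginal is -Inf
      log_rk[k] <- -Inf
      next
    }
    a <- exp(w - m)
    log_rk[k] <- m + log(mean(a))
    n_eff <- ess(a)
    var_rk[k] <- var(a) / (n_eff * mean(a)^2)
  }
  log_ml <- sum(log_rk)
  se <- sqrt(sum(var_rk))
  structure(list(log_ml = log_ml, log10_ml = log_ml / log(10),
                 se_log = se, se_log10 = se / log(10), betas = betas,
                 log_ratios = log_rk,
                 settings = list(stones = stones,
                                 iter_per_stone = iter_per_stone,
                                 alpha = alpha, seed = seed,
                                 prior = prep$prior[c("type", "rate")])),
            class = "stepping_stone")
}

#' Log10 Bayes factor between two models
#'
#' `BF = 2 x (log10 L_j - log10 L_k)` with `j` the model of higher marginal
#' likelihood. Interpretation bands: `BF <= 2` weak (no real evidence),
#' `2 < BF < 5` strong, `BF >= 5` very strong evidence for the higher-scoring
#' model.
#'
#' @param ml_a,ml_b log10 marginal likelihoods (bare numbers or
#'   `stepping_stone` objects).
#' @param labels model labels for reporting.
#' @return class `bayes_factor_report`: list with `bf`, `category`,
#'   `better`, `log10_ml`.
#' @export
bayes_factor <- function(ml_a, ml_b, labels = c("A", "B")) {
  get <- function(x) if (inherits(x, "stepping_stone")) x$log10_ml else x
  la <- get(ml_a); lb <- get(ml_b)
  bf <- 2 * abs(la - lb)
  category <- if (bf <= 2) "weak" else if (bf < 5) "strong" else "very strong"
  structure(list(bf = bf, category = category,
                 better = labels[which.max(c(la, lb))],
                 log10_ml = setNames(c(la, lb), labels)),
            class = "bayes_factor_report")
}

#' @export
print.migration_fit <- function(x, ...) {
  cat(sprintf("Migration model fit '%s' (%d parameter(s), %d samples)\n",
              x$model$name, x$model$n_par, nrow(x$samples)))
  print(data.frame(parameter = x$model$par_names,
                   median = x$median, mean = x$mean,
                   ess = round(x$ess), row.names = NULL))
  cat("Root state posterior:",
      paste(sprintf("%s=%.3f", names(x$root_posterior), x$root_posterior),
            collapse = " "), "\n")
  invisible(x)
}

#' @export
print.stepping_stone <- function(x, ...) {
  cat(sprintf("Stepping-stone marginal likelihood: log10 ML = %.4f (SE %.4f)\n",
              x$log10_ml, x$se_log10))
  invisible(x)
}

#' @export
print.bayes_factor_report <- function(x, ...) {
  cat(sprintf("BF = %.3f (%s evidence; favours %s)\n",
              x$bf, x$category, x$better))
  invisible(x)
}
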