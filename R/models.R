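# Constrained 3-state (general k-state) migration rate-matrix models on a
# tree: constraint DSL, generator construction, pruning likelihood, and
# marginal ancestral-state reconstruction.

#' Ordered state pairs of a region state space
#'
#' @param states ordered region codes.
#' @return data.frame with `from`, `to`, `label` (`"FROM->TO"`), one row per
#'   ordered pair i != j, ordered by `from` then `to`.
#' @export
ordered_pairs <- function(states = c("AUS", "PAP", "WLC")) {
  k <- length(states)
  from <- rep(states, each = k)
  to <- rep(states, k)
  keep <- from != to
  data.frame(from = from[keep], to = to[keep],
             label = paste0(from[keep], "->", to[keep]),
             stringsAsFactors = FALSE)
}

#' Build a constrained migration rate-matrix model
#'
#' Each ordered pair of regions is `"free"` (its own rate parameter),
#' `"zero"` (migration prohibited) or `"tie:<group>"` (shares one parameter
#' with every pair in the same tie group). The parameter count is the number
#' of free pairs plus the number of tie groups.
#'
#' @param constraint named character vector over pair labels (`"FROM->TO"`);
#'   pairs not named default to `"free"`.
#' @param name model name.
#' @param states ordered region codes.
#' @return class `migration_model`: list with `name`, `states`, `pairs`,
#'   `constraint`, `par_names`, `par_index` (0 for zero pairs), `n_par`.
#' @export
build_model <- function(constraint = character(0), name = "custom",
                        states = c("AUS", "PAP", "WLC")) {
  if (length(states) < 2L || anyDuplicated(states)) {
    stop("states must be >= 2 unique codes")
  }
  pairs <- ordered_pairs(states)
  full <- setNames(rep("free", nrow(pairs)), pairs$label)
  if (length(constraint)) {
    bad <- setdiff(names(constraint), pairs$label)
    if (length(bad)) stop("unknown pair label(s): ", paste(bad, collapse = ", "))
    full[names(constraint)] <- constraint
  }
  ok <- full == "free" | full == "zero" | grepl("^tie:.+", full)
  if (!all(ok)) stop("constraint values must be 'free', 'zero' or 'tie:<group>'")
  if (all(full == "zero")) stop("all-zero constraint: no migration possible")

  par_names <- character(0)
  par_index <- integer(nrow(pairs))
  tie_par <- character(0)
  for (i in seq_len(nrow(pairs))) {
    v <- full[i]
    if (v == "zero") {
      par_index[i] <- 0L
    } else if (v == "free") {
      par_names <- c(par_names, pairs$label[i])
      par_index[i] <- length(par_names)
    } else {
      g <- sub("^tie:", "", v)
      if (g %in% names(tie_par)) {
        par_index[i] <- match(tie_par[[g]], par_names)
      } else {
        par_names <- c(par_names, paste0("tie:", g))
        tie_par[g] <- paste0("tie:", g)
        par_index[i] <- length(par_names)
      }
    }
  }
  structure(list(name = name, states = states, pairs = pairs,
                 constraint = full, par_names = par_names,
                 par_index = par_index, n_par = length(par_names)),
            class = "migration_model")
}

#' Preset migration models
#'
#' The five models discussed in the source analyses of this package's model
#' space: `"all"` — saturated, six independent rates; `"null"` — one shared
#' rate for all ordered pairs; `"m4"` — only WLC->AUS, WLC->PAP and PAP->WLC
#' allowed, each with its own rate (3 parameters); `"m9"` — as m4 but with
#' the two New Guinea–Wallacea rates tied (2 parameters); `"m12"` —
#' bidirectional AUS<->PAP and PAP<->WLC movement, no direct
#' Wallacea–Australia exchange (4 parameters).
#'
#' @param name preset name.
#' @param states ordered region codes (presets assume the default three).
#' @return a `migration_model`.
#' @export
migration_model <- function(name = c("all", "null", "m4", "m9", "m12"),
                            states = c("AUS", "PAP", "WLC")) {
  name <- match.arg(name)
  spec <- switch(name,
    all = character(0),
    null = setNames(rep("tie:global", 6L), ordered_pairs(states)$label),
    m4 = c("AUS->PAP" = "zero", "AUS->WLC" = "zero", "PAP->AUS" = "zero",
           "PAP->WLC" = "free", "WLC->AUS" = "free", "WLC->PAP" = "free"),
    m9 = c("AUS->PAP" = "zero", "AUS->WLC" = "zero", "PAP->AUS" = "zero",
           "PAP->WLC" = "tie:PW", "WLC->AUS" = "free", "WLC->PAP" = "tie:PW"),
    m12 = c("AUS->PAP" = "free", "AUS->WLC" = "zero", "PAP->AUS" = "free",
            "PAP->WLC" = "free", "WLC->AUS" = "zero", "WLC->PAP" = "free"))
  build_model(spec, name = name, states = states)
}

#' Generator matrix from model parameters
#'
#' @param model a `migration_model`.
#' @param rates numeric vector of length `model$n_par` (>= 0), transitions
#'   per lineage per year.
#' @return k x k generator `Q` with `dimnames` set to the states; rows sum
#'   to zero.
#' @export
make_Q <- function(model, rates) {
  stopifnot(inherits(model, "migration_model"))
  if (length(rates) != model$n_par) {
    stop("expected ", model$n_par, " rate parameter(s), got ", length(rates))
  }
  if (any(rates < 0)) stop("rates must be >= 0")
  k <- length(model$states)
  Q <- matrix(0, k, k, dimnames = list(model$states, model$states))
  for (i in seq_len(nrow(model$pairs))) {
    if (model$par_index[i] > 0L) {
      Q[model$pairs$from[i], model$pairs$to[i]] <- rates[model$par_index[i]]
    }
  }
  diag(Q) <- -rowSums(Q)
  Q
}

validate_Q <- function(Q) {
  if (!is.matrix(Q) || nrow(Q) != ncol(Q)) stop("Q must be square")
  if (is.null(rownames(Q))) stop("Q must carry state names as dimnames")
  off <- Q; diag(off) <- 0
  if (any(off < 0)) stop("off-diagonal rates must be >= 0")
  if (max(abs(rowSums(Q))) > 1e-8 * (1 + max(abs(Q)))) {
    stop("Q rows must sum to zero")
  }
  invisible(TRUE)
}

# Up-pass partial likelihoods; shared by likelihood, ASR and mapping code.
# Returns the postorder tree alongside so callers reuse the same edge order.
ctmc_partials <- function(tree, regions, Q) {
  validate_Q(Q)
  states <- rownames(Q)
  tr <- reorder(tree, "postorder")
  check_regions_total(regions, tr$tip.label)
  tipst <- match(unname(regions[tr$tip.label]), states)
  if (anyNA(tipst)) {
    stop("tip region(s) outside Q's state space: ",
         paste(unique(regions[tr$tip.label][is.na(tipst)]), collapse = ", "))
  }
  n_tip <- length(tr$tip.label)
  res <- ctmc_partials_cpp(tr$edge, tr$edge.length, n_tip, n_tip + tr$Nnode,
                           tipst, Q)
  list(partials = res$partials, logscale = res$logscale, tree = tr,
       states = states, n_tip = n_tip, root = n_tip + 1L)
}

# Per-edge transition matrices as an R list, same order as tree$edge rows.
edge_pmats <- function(Q, lens) {
  cube <- ctmc_edge_pmats_cpp(Q, lens)
  lapply(seq_along(lens), function(e) cube[, , e])
}

resolve_root_prior <- function(root_prior, states, root_partial = NULL) {
  k <- length(states)
  if (is.numeric(root_prior)) {
    stopifnot(length(root_prior) == k, all(root_prior >= 0), sum(root_prior) > 0)
    return(root_prior / sum(root_prior))
  }
  if (!is.character(root_prior) || length(root_prior) != 1L) {
    stop("root_prior must be 'equal', 'empirical', 'fixed:<STATE>' or a numeric vector")
  }
  if (root_prior == "equal") return(rep(1 / k, k))
  if (root_prior == "empirical") {
    if (is.null(root_partial) || sum(root_partial) <= 0) {
      stop("empirical root prior undefined: zero root likelihood")
    }
    return(root_partial / sum(root_partial))
  }
  if (grepl("^fixed:", root_prior)) {
    s <- sub("^fixed:", "", root_prior)
    i <- match(s, states)
    if (is.na(i)) stop("fixed root state '", s, "' not in state space")
    pri <- rep(0, k); pri[i] <- 1
    return(pri)
  }
  stop("unknown root prior: ", root_prior)
}

#' Pruning log-likelihood of tip regions under a migration generator
#'
#' Felsenstein pruning with per-branch transition matrices `exp(Q t)`
#' (branch lengths in years, rates per year). The root is handled by the
#' chosen prior: `"equal"` (uniform over states), `"empirical"` (the
#' normalised root conditional likelihoods), `"fixed:<STATE>"`, or an
#' explicit probability vector.
#'
#' @param tree rooted `phylo` with branch lengths in years.
#' @param regions named character vector tip -> region.
#' @param Q generator matrix with state dimnames (see [make_Q()]).
#' @param root_prior root state prior (see above).
#' @return the natural-log likelihood (`-Inf` when the data are impossible
#'   under `Q`).
#' @export
log_likelihood <- function(tree, regions, Q, root_prior = "equal") {
  pp <- ctmc_partials(tree, regions, Q)
  Lr <- pp$partials[pp$root, ]
  if (sum(Lr) <= 0) return(-Inf)
  pri <- resolve_root_prior(root_prior, pp$states, Lr)
  v <- sum(pri * Lr)
  if (v <= 0) return(-Inf)
  log(v) + pp$logscale[pp$root]
}

#' Marginal ancestral-state reconstruction
#'
#' Posterior probability of each region at every node given the tip regions,
#' the generator and the root prior, by the standard up-down (inside-outside)
#' pass.
#'
#' @inheritParams log_likelihood
#' @return matrix (nodes x states, ape node order) of marginal posteriors;
#'   rows sum to 1.
#' @export
asr_marginal <- function(tree, regions, Q, root_prior = "equal") {
  pp <- ctmc_partials(tree, regions, Q)
  tr <- pp$tree
  k <- length(pp$states)
  n_all <- pp$n_tip + tr$Nnode
  Lr <- pp$partials[pp$root, ]
  if (sum(Lr) <= 0) stop("tip configuration impossible under Q")
  pri <- resolve_root_prior(root_prior, pp$states, Lr)
  P <- edge_pmats(Q, tr$edge.length)

  # m_e = P_e %*% L_child, the child's message to its parent, per edge
  msg <- lapply(seq_len(nrow(tr$edge)), function(e) {
    as.vector(P[[e]] %*% pp$partials[tr$edge[e, 2L], ])
  })
  D <- matrix(0, n_all, k)
  D[pp$root, ] <- pri
  # preorder over edges: parents before children
  pre <- rev(seq_len(nrow(tr$edge)))
  child_edges <- split(seq_len(nrow(tr$edge)), tr$edge[, 1L])
  for (e in pre) {
    p <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
    dt <- D[p, ]
    for (s in child_edges[[as.character(p)]]) {
      if (s != e) dt <- dt * msg[[s]]
    }
    v <- as.vector(dt %*% P[[e]])
    sv <- sum(v)
    D[ch, ] <- if (sv > 0) v / sv else v
  }
  post <- D * pp$partials
  sw <- rowSums(post)
  if (any(sw <= 0)) stop("zero posterior mass at some node (impossible data under Q)")
  post <- post / sw
  dimnames(post) <- list(c(tr$tip.label,
                           as.character((pp$n_tip + 1L):n_all)), pp$states)
  post
}

#' @export
print.migration_model <- function(x, ...) {
  cat(sprintf("Migration model '%s' on {%s}: %d parameter(s)\n",
              x$name, paste(x$states, collapse = ", "), x$n_par))
  lab <- ifelse(x$par_index == 0L, "0", x$par_names[pmax(x$par_index, 1L)])
  cat(paste(sprintf("  %s : %s", x$pairs$label, lab), collapse = "\n"), "\n")
  invisible(x)
}
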