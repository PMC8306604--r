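# Synthetic ground-truth data: dated trees, region histories evolved under a
# known generator, and emulated posterior tree sets (branch-length jitter
# plus occasional rooted NNI moves), so every downstream stage can be tested
# against recorded truth.

#' Simulate a rooted, dated tree
#'
#' Coalescent trees come from `ape::rcoal` (branch lengths in units of Ne
#' generations) scaled by `Ne x gen_time` to years; birth-death trees from
#' `ape::rphylo` with per-year rates. Both are ultrametric with the requested
#' number of tips.
#'
#' @param n_tips number of tips (>= 3).
#' @param model `"coalescent"` or `"birth-death"`.
#' @param Ne effective (female, for matrilines) population size, in
#'   individuals; coalescent only.
#' @param gen_time generation time in years; coalescent only.
#' @param birth,death per-lineage per-year rates; birth-death only.
#' @param seed optional integer seed.
#' @param retries birth-death redraw cap for degenerate draws.
#' @return a `phylo` with branch lengths in years.
#' @export
simulate_tree <- function(n_tips, model = c("coalescent", "birth-death"),
                          Ne = 1000, gen_time = 28, birth = 2e-4, death = 0,
                          seed = NULL, retries = 10) {
  model <- match.arg(model)
  if (n_tips < 3L) stop("n_tips must be >= 3")
  if (!is.null(seed)) set.seed(seed)
  if (model == "coalescent") {
    tr <- ape::rcoal(n_tips)
    tr$edge.length <- tr$edge.length * Ne * gen_time
    return(tr)
  }
  for (i in seq_len(retries)) {
    tr <- tryCatch(ape::rphylo(n_tips, birth, death), error = function(e) NULL)
    if (!is.null(tr)) return(tr)
  }
  stop("birth-death simulation failed after ", retries, " attempts")
}

#' Evolve a region character down a tree under a known generator
#'
#' Forward continuous-time Markov simulation from the root toward the tips,
#' recording every transition (the ground truth for migration-event timing).
#'
#' @param tree rooted dated `phylo`.
#' @param Q generator with state dimnames.
#' @param root_state state code at the root.
#' @param tip_ages optional named tip ages.
#' @param seed optional integer seed.
#' @return list with `regions` (named tip -> state), `node_states` (named by
#'   node), `events` (data.frame: `branch` = child node id, `age` yBP,
#'   `from`, `to`).
#' @export
evolve_trait <- function(tree, Q, root_state, tip_ages = NULL, seed = NULL) {
  validate_Q(Q)
  if (!is.null(seed)) set.seed(seed)
  states <- rownames(Q)
  ri <- match(root_state, states)
  if (is.na(ri)) stop("root_state not in Q's state space")
  tr <- reorder(tree, "cladewise")   # parents before children
  n_tip <- length(tr$tip.label)
  n_all <- n_tip + tr$Nnode
  ages <- suppressWarnings(node_ages(tr, tip_ages))
  node_state <- integer(n_all)
  node_state[n_tip + 1L] <- ri
  ev_branch <- integer(0); ev_age <- numeric(0)
  ev_from <- integer(0); ev_to <- integer(0)
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
    len <- tr$edge.length[e]
    s <- node_state[p]
    tcur <- 0
    repeat {
      rate <- -Q[s, s]
      if (rate <= 0) break
      w <- rexp(1L, rate)
      if (tcur + w > len) break
      tcur <- tcur + w
      probs <- Q[s, ]; probs[s] <- 0
      j <- sample.int(length(states), 1L, prob = probs)
      ev_branch <- c(ev_branch, ch)
      ev_age <- c(ev_age, ages[p] - tcur)
      ev_from <- c(ev_from, s)
      ev_to <- c(ev_to, j)
      s <- j
    }
    node_state[ch] <- s
  }
  list(
    regions = setNames(states[node_state[seq_len(n_tip)]], tr$tip.label),
    node_states = setNames(states[node_state],
                           c(tr$tip.label, as.character((n_tip + 1L):n_all))),
    events = data.frame(branch = ev_branch, age = ev_age,
                        from = states[ev_from], to = states[ev_to],
                        stringsAsFactors = FALSE)
  )
}

# Redate a tree after branch-length perturbation: tips keep their ages;
# each internal node's age is the mean over children of (child age + new
# branch length), clamped to stay strictly above its children.
redate_from_lengths <- function(tree, new_len, tip_ages_vec) {
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  po <- reorder(tree, "postorder")
  perm <- match(paste(po$edge[, 1L], po$edge[, 2L]),
                paste(tree$edge[, 1L], tree$edge[, 2L]))
  len_po <- new_len[perm]
  ages <- numeric(n_all)
  ages[seq_len(n_tip)] <- tip_ages_vec
  eps <- 1e-9 * max(1, max(tip_ages_vec), max(new_len))
  # parents ordered by their last postorder appearance: every child's own
  # subtree (hence its age) is complete by then
  ord <- rev(unique(rev(po$edge[, 1L])))
  for (p in ord) {
    rows <- which(po$edge[, 1L] == p)
    ch <- po$edge[rows, 2L]
    ages[p] <- max(mean(ages[ch] + len_po[rows]), max(ages[ch]) + eps)
  }
  tree$edge.length <- unname(ages[tree$edge[, 1L]] - ages[tree$edge[, 2L]])
  tree
}

# One random rooted nearest-neighbour interchange, preserving node ages
# (the moved node's age is adjusted only when the swap makes it invalid).
rooted_nni <- function(tree) {
  ages <- suppressWarnings(node_ages(tree))
  edge <- tree$edge
  n_tip <- length(tree$tip.label)
  cand <- which(edge[, 2L] > n_tip)
  if (!length(cand)) return(tree)
  e <- if (length(cand) == 1L) cand else sample(cand, 1L)
  u <- edge[e, 1L]; v <- edge[e, 2L]
  ch_v <- edge[edge[, 1L] == v, 2L]
  ch_u <- setdiff(edge[edge[, 1L] == u, 2L], v)
  if (!length(ch_u) || !length(ch_v)) return(tree)
  s <- if (length(ch_u) == 1L) ch_u else sample(ch_u, 1L)
  cc <- if (length(ch_v) == 1L) ch_v else sample(ch_v, 1L)
  row_s <- which(edge[, 1L] == u & edge[, 2L] == s)
  row_c <- which(edge[, 1L] == v & edge[, 2L] == cc)
  edge[row_s, 1L] <- v
  edge[row_c, 1L] <- u
  new_ch_v <- c(setdiff(ch_v, cc), s)
  lo <- max(ages[new_ch_v]); hi <- ages[u]
  if (!(ages[v] > lo && ages[v] < hi)) ages[v] <- (lo + hi) / 2
  tree$edge <- edge
  tree$edge.length <- unname(ages[tree$edge[, 1L]] - ages[tree$edge[, 2L]])
  attr(tree, "order") <- NULL   # edge order changed: force a true reorder
  reorder(tree, "cladewise")
}

#' Emulate a posterior tree set around a known tree
#'
#' Each emulated sample is a copy of the input tree with multiplicative
#' lognormal branch-length jitter (mean-one on the natural scale), re-dated
#' so the tips keep their ages, and — with probability `nni_prob` — one
#' random rooted nearest-neighbour interchange. This mimics the topological
#' and node-age uncertainty of a Bayesian posterior at controllable support
#' levels; it is not a substitute for actual posterior inference.
#'
#' @param tree the true dated `phylo`.
#' @param n_trees number of emulated samples.
#' @param jitter_sd lognormal sigma of the branch-length jitter (>= 0).
#' @param nni_prob per-tree probability of one NNI move.
#' @param tip_ages optional named tip ages.
#' @param seed optional integer seed.
#' @return a `multiPhylo` with `tip_universe` attribute.
#' @export
emulate_posterior <- function(tree, n_trees = 100, jitter_sd = 0.05,
                              nni_prob = 0.1, tip_ages = NULL, seed = NULL) {
  if (jitter_sd < 0 || nni_prob < 0 || nni_prob > 1) {
    stop("invalid jitter/NNI parameters")
  }
  if (!is.null(seed)) set.seed(seed)
  n_tip <- length(tree$tip.label)
  ta <- suppressWarnings(node_ages(tree, tip_ages))[seq_len(n_tip)]
  out <- vector("list", n_trees)
  for (i in seq_len(n_trees)) {
    tr <- tree
    if (jitter_sd > 0) {
      f <- rlnorm(nrow(tr$edge), -jitter_sd^2 / 2, jitter_sd)
      tr <- redate_from_lengths(tr, tr$edge.length * f, ta)
    }
    if (runif(1L) < nni_prob) tr <- rooted_nni(tr)
    out[[i]] <- tr
  }
  class(out) <- "multiPhylo"
  attr(out, "tip_universe") <- sort(tree$tip.label)
  out
}

#' Generate a complete synthetic dataset with known truth
#'
#' Convenience wrapper: simulates a dated tree, evolves the region character
#' under a known generator, and emulates a posterior tree set around the
#' true tree. All truth values (true tree, node states, transition events)
#' are returned alongside the inputs a real analysis would see.
#'
#' @inheritParams simulate_tree
#' @inheritParams emulate_posterior
#' @param Q true generator (with state dimnames).
#' @param root_state true root state.
#' @param n_trees emulated posterior size.
#' @param seed optional integer seed governing all stages.
#' @return class `synthetic_dataset`: list with `tree`, `regions`,
#'   `node_states`, `events`, `trees` (emulated posterior), `Q`,
#'   `root_state`, `config`.
#' @export
synthetic_dataset <- function(n_tips = 50, Q, root_state = "WLC",
                              n_trees = 100, jitter_sd = 0.05, nni_prob = 0.1,
                              model = "coalescent", Ne = 1000, gen_time = 28,
                              birth = 2e-4, death = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tree <- simulate_tree(n_tips, model, Ne = Ne, gen_time = gen_time,
                        birth = birth, death = death)
  truth <- evolve_trait(tree, Q, root_state)
  trees <- emulate_posterior(tree, n_trees, jitter_sd, nni_prob)
  structure(list(tree = tree, regions = truth$regions,
                 node_states = truth$node_states, events = truth$events,
                 trees = trees, Q = Q, root_state = root_state,
                 config = list(n_tips = n_tips, n_trees = n_trees,
                               jitter_sd = jitter_sd, nni_prob = nni_prob,
                               model = model, Ne = Ne, gen_time = gen_time,
                               birth = birth, death = death, seed = seed)),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("Synthetic dataset: %d tips, %d emulated posterior trees, root %s\n",
              length(x$tree$tip.label), length(x$trees), x$root_state))
  print(table(x$regions))
  cat(nrow(x$events), "true transition event(s)\n")
  invisible(x)
}
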