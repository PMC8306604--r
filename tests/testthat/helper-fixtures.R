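# Shared fixtures: small trees, state spaces, generator matrices.

STATES <- c("AUS", "PAP", "WLC")

# symmetric equal-rates generator (the null model's Q)
sym_Q <- function(r, states = STATES) {
  k <- length(states)
  Q <- matrix(r, k, k, dimnames = list(states, states))
  diag(Q) <- -(k - 1) * r
  Q
}

# random valid generator with off-diagonal rates uniform on (0, scale)
rand_Q <- function(scale = 1e-4, states = STATES) {
  k <- length(states)
  Q <- matrix(runif(k * k, 0, scale), k, k, dimnames = list(states, states))
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

# random dated tree (years), coalescent shape
rand_tree <- function(n, depth_scale = 10000) {
  tr <- ape::rcoal(n)
  tr$edge.length <- tr$edge.length * depth_scale
  tr
}

# random total region labelling
rand_regions <- function(tree, states = STATES) {
  setNames(sample(states, length(tree$tip.label), replace = TRUE),
           tree$tip.label)
}

# star tree: one root, n equal branches of length len
star_tree <- function(n, len) {
  ape::read.tree(text = paste0("(", paste0("t", seq_len(n), ":", len,
                                           collapse = ","), ");"))
}

read_one_tree <- function(text) ape::read.tree(text = text)

# closed-form k=3 symmetric transition probability
sym_P_same <- function(r, t) 1 / 3 + 2 / 3 * exp(-3 * r * t)
sym_P_diff <- function(r, t) 1 / 3 - 1 / 3 * exp(-3 * r * t)

# hand-built gec_set for density tests
fake_gecs <- function(samples, regions, sizes = NULL) {
  ids <- names(samples)
  if (is.null(sizes)) sizes <- rep(2L, length(ids))
  clades <- data.frame(clade_id = ids, region = regions, size = sizes,
                       support = 1, median_tmrca = vapply(samples, median, 0),
                       stringsAsFactors = FALSE)
  clades$tips <- I(lapply(seq_along(ids), function(i) {
    paste0(ids[i], "_tip", seq_len(sizes[i]))
  }))
  structure(list(clades = clades, tmrca = samples, n_trees = 1L,
                 support_threshold = 0.5), class = "gec_set")
}
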