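# Independent oracles, kept deliberately separate from the implementation:
# phangorn traversals for clade structure, ape::branching.times for ages,
# Matrix::expm for transition matrices, full state enumeration for the
# likelihood, and a rejection sampler for endpoint-conditioned paths.

# All region-pure clades (>= 2 tips) of one tree, via phangorn::Descendants.
oracle_pure_clades <- function(tree, regions) {
  n_tip <- length(tree$tip.label)
  out <- list()
  for (nd in (n_tip + 1L):(n_tip + tree$Nnode)) {
    tips <- tree$tip.label[phangorn::Descendants(tree, nd, "tips")[[1L]]]
    regs <- unique(regions[tips])
    if (length(regs) == 1L) {
      out[[length(out) + 1L]] <- list(tips = sort(tips), region = unname(regs))
    }
  }
  out
}

# Largest pure clade containing each tip, by walking rootward from the tip
# while the subtree above stays region-pure.
oracle_largest_gecs <- function(tree, regions) {
  n_tip <- length(tree$tip.label)
  found <- character(0)
  out <- list()
  for (tip in seq_len(n_tip)) {
    node <- tip
    best <- NULL
    anc <- phangorn::Ancestors(tree, tip, "all")
    for (a in anc) {
      tips <- tree$tip.label[phangorn::Descendants(tree, a, "tips")[[1L]]]
      if (length(unique(regions[tips])) == 1L) best <- a else break
    }
    if (!is.null(best)) {
      tips <- sort(tree$tip.label[phangorn::Descendants(tree, best, "tips")[[1L]]])
      key <- paste(tips, collapse = "|")
      if (!key %in% found) {
        found <- c(found, key)
        out[[length(out) + 1L]] <- list(tips = tips,
                                        region = unname(regions[tips[1L]]))
      }
    }
  }
  out
}

# internal-node ages of an ultrametric tree (independent of node_ages)
oracle_ages <- function(tree) ape::branching.times(tree)

# Brute-force GEC extraction over a tree set: candidates from the rootward
# walk, support/TMRCAs by per-tree monophyly + MRCA, then the documented
# disjointness rule.
oracle_extract_gecs <- function(trees, regions, thr = 0.5) {
  n <- length(trees)
  cand <- list()
  for (tr in trees) {
    for (cl in oracle_largest_gecs(tr, regions)) {
      key <- paste(cl$tips, collapse = "|")
      if (is.null(cand[[key]])) cand[[key]] <- cl
    }
  }
  if (!length(cand)) return(empty_named_list())
  res <- list()
  for (key in names(cand)) {
    tips <- cand[[key]]$tips
    sam <- numeric(0)
    for (tr in trees) {
      if (ape::is.monophyletic(tr, tips)) {
        bt <- oracle_ages(tr)
        mrca <- if (length(tips) == length(tr$tip.label)) {
          length(tr$tip.label) + 1L
        } else {
          ape::getMRCA(tr, tips)
        }
        sam <- c(sam, unname(bt[as.character(mrca)]))
      }
    }
    if (length(sam) / n > thr) {
      res[[key]] <- list(tips = tips, region = cand[[key]]$region,
                         support = length(sam) / n, tmrca = sam,
                         median = stats::median(sam), size = length(tips))
    }
  }
  if (!length(res)) return(empty_named_list())
  sup <- vapply(res, `[[`, 0, "support")
  siz <- vapply(res, `[[`, 0, "size")
  med <- vapply(res, `[[`, 0, "median")
  ord <- order(-sup, -siz, -med, names(res))
  taken <- character(0)
  keep <- list()
  for (i in ord) {
    tips <- res[[i]]$tips
    if (!any(tips %in% taken)) {
      keep[[names(res)[i]]] <- res[[i]]
      taken <- c(taken, tips)
    }
  }
  keep
}

empty_named_list <- function() structure(list(), names = character(0))

# gec_set -> comparable canonical list
gec_set_canonical <- function(g) {
  if (!nrow(g$clades)) return(empty_named_list())
  out <- list()
  for (i in seq_len(nrow(g$clades))) {
    tips <- sort(g$clades$tips[[i]])
    key <- paste(tips, collapse = "|")
    out[[key]] <- list(tips = tips, region = g$clades$region[i],
                       support = g$clades$support[i],
                       n_samples = length(g$tmrca[[g$clades$clade_id[i]]]),
                       median = g$clades$median_tmrca[i])
  }
  out[order(names(out))]
}

# Conditional likelihood of the tip states given each root state, by full
# enumeration over internal-node assignments (trees <= ~6 tips).
enum_root_likelihood <- function(tree, regions, Q) {
  states <- rownames(Q)
  k <- length(states)
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  tipst <- match(unname(regions[tree$tip.label]), states)
  P <- lapply(tree$edge.length, function(t) {
    as.matrix(Matrix::expm(Q * t))
  })
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n_int)))
  root_col <- 1L   # node n_tip + 1 is column 1 of the grid
  Lr <- numeric(k)
  for (g in seq_len(nrow(grid))) {
    assign_int <- grid[g, ]
    state_of <- function(nd) if (nd <= n_tip) tipst[nd] else assign_int[nd - n_tip]
    lk <- 1
    for (e in seq_len(nrow(tree$edge))) {
      lk <- lk * P[[e]][state_of(tree$edge[e, 1L]), state_of(tree$edge[e, 2L])]
    }
    Lr[assign_int[root_col]] <- Lr[assign_int[root_col]] + lk
  }
  setNames(Lr, states)
}

enum_loglik <- function(tree, regions, Q, root_prior = "equal") {
  Lr <- enum_root_likelihood(tree, regions, Q)
  states <- rownames(Q)
  pri <- if (identical(root_prior, "equal")) {
    rep(1 / length(states), length(states))
  } else if (identical(root_prior, "empirical")) {
    if (sum(Lr) <= 0) return(-Inf)
    Lr / sum(Lr)
  } else if (is.character(root_prior) && grepl("^fixed:", root_prior)) {
    as.numeric(states == sub("^fixed:", "", root_prior))
  } else root_prior
  v <- sum(pri * Lr)
  if (v <= 0) -Inf else log(v)
}

# Forward (unconditioned) CTMC path on one branch; used by the rejection
# oracle for endpoint-conditioned event counts.
forward_path <- function(a, t, Q) {
  states <- seq_len(nrow(Q))
  s <- a
  tcur <- 0
  n_ev <- 0L
  repeat {
    rate <- -Q[s, s]
    if (rate <= 0) break
    w <- rexp(1L, rate)
    if (tcur + w > t) break
    tcur <- tcur + w
    probs <- Q[s, ]; probs[s] <- 0
    s <- sample(states, 1L, prob = probs)
    n_ev <- n_ev + 1L
  }
  list(end = s, n = n_ev)
}

rejection_event_counts <- function(a, b, t, Q, n_accept) {
  counts <- integer(0)
  while (length(counts) < n_accept) {
    p <- forward_path(a, t, Q)
    if (p$end == b) counts <- c(counts, p$n)
  }
  counts
}
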