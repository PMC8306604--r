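# Geographically exclusive clade (GEC) extraction from posterior tree sets.
#
# A GEC is a monophyletic group of >= 2 samples all drawn from one region.
# Candidate clades are, per posterior tree, the *largest* region-pure clade
# containing each sample; a candidate is retained when it is monophyletic in
# more than `support_threshold` of the posterior trees, and its TMRCA sample
# in each such tree is the age of its MRCA there.

# Region of each node's descendant tip set (NA when mixed), plus maximality.
node_purity <- function(tree, regions) {
  check_regions_total(regions, tree$tip.label)
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  desc <- clade_tip_sets(tree)
  regcode <- unname(regions[tree$tip.label])
  node_region <- rep(NA_character_, n_all)
  for (nd in seq_len(n_all)) {
    u <- unique(regcode[desc[[nd]]])
    if (length(u) == 1L) node_region[nd] <- u
  }
  list(desc = desc, region = node_region, parent = node_parents(tree),
       n_tip = n_tip, n_all = n_all)
}

#' All geographically exclusive clades of one tree
#'
#' Every monophyletic subtree with at least two tips whose tips all share one
#' region, including nested ones.
#'
#' @param tree a rooted `phylo`.
#' @param regions named character vector tip -> region (total on the tips).
#' @return data.frame with columns `key` (canonical clade key, see
#'   [clade_key()]), `region`, `size`.
#' @export
exclusive_clades <- function(tree, regions) {
  np <- node_purity(tree, regions)
  ints <- (np$n_tip + 1L):np$n_all
  pure <- ints[!is.na(np$region[ints])]
  data.frame(
    key = vapply(pure, function(nd) clade_key(tree$tip.label[np$desc[[nd]]]), ""),
    region = np$region[pure],
    size = vapply(pure, function(nd) length(np$desc[[nd]]), 0L),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Largest geographically exclusive clade containing each sample
#'
#' For each tip, the maximal region-pure clade containing it in this tree;
#' tips in no pure clade of size >= 2 are discarded. The returned clades are
#' pairwise disjoint by construction.
#'
#' @inheritParams exclusive_clades
#' @return data.frame as in [exclusive_clades()], maximal clades only.
#' @export
largest_gec_per_sample <- function(tree, regions) {
  np <- node_purity(tree, regions)
  ints <- (np$n_tip + 1L):np$n_all
  maximal <- ints[!is.na(np$region[ints]) &
                    (is.na(np$parent[ints]) | is.na(np$region[np$parent[ints]]))]
  data.frame(
    key = vapply(maximal, function(nd) clade_key(tree$tip.label[np$desc[[nd]]]), ""),
    region = np$region[maximal],
    size = vapply(maximal, function(nd) length(np$desc[[nd]]), 0L),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Posterior support of a clade across a tree set
#'
#' Fraction of trees in which the given tip set is monophyletic (the MRCA's
#' descendant tip set equals the set exactly).
#'
#' @param tips character vector of tip labels (>= 2).
#' @param trees a `multiPhylo`.
#' @return a fraction in `[0, 1]`.
#' @export
clade_support <- function(tips, trees) {
  if (inherits(trees, "phylo")) trees <- c(trees)
  universe <- trees[[1L]]$tip.label
  out <- setdiff(tips, universe)
  if (length(out)) stop("tips not in tree set: ", paste(out, collapse = ", "))
  key <- clade_key(tips)
  mean(vapply(trees, function(tr) key %in% clade_keys(tr), TRUE))
}

#' Extract well-supported GECs and their TMRCA posterior samples
#'
#' Candidate clades are the union over posterior trees of
#' [largest_gec_per_sample()]; a candidate is retained when monophyletic in
#' strictly more than `support_threshold` of the trees. Its TMRCA samples are
#' the MRCA ages in exactly those trees, so the number of samples equals
#' support x number of trees. Retained clades are made pairwise tip-disjoint:
#' on overlap the clade with higher support wins, ties broken by larger size,
#' then older median TMRCA, then lexicographic key (only reachable at
#' threshold exactly 0.5, where two conflicting clades can both pass).
#'
#' @param trees a `multiPhylo` sharing one tip universe.
#' @param regions named character vector tip -> region.
#' @param support_threshold retention threshold in `[0.5, 1)`; clades must
#'   exceed it strictly (the strict majority rule).
#' @param tip_ages optional named tip ages (yBP).
#' @return an object of class `gec_set`: list with `clades` (data.frame:
#'   `clade_id`, `region`, `size`, `support`, `median_tmrca`, `tips`),
#'   `tmrca` (named list of per-clade TMRCA sample vectors), `n_trees`,
#'   `support_threshold`.
#' @export
extract_gecs <- function(trees, regions, support_threshold = 0.5, tip_ages = NULL) {
  if (inherits(trees, "phylo")) trees <- c(trees)
  if (length(trees) < 1L) stop("empty tree set")
  if (support_threshold < 0.5 || support_threshold >= 1) {
    stop("support_threshold must be in [0.5, 1)")
  }
  check_regions_total(regions, trees[[1L]]$tip.label)
  n <- length(trees)

  per_tree <- lapply(trees, function(tr) {
    np <- node_purity(tr, regions)
    ints <- (np$n_tip + 1L):np$n_all
    ages <- suppressWarnings(node_ages(tr, tip_ages))
    keys <- vapply(ints, function(nd) clade_key(tr$tip.label[np$desc[[nd]]]), "")
    maximal <- !is.na(np$region[ints]) &
      (is.na(np$parent[ints]) | is.na(np$region[np$parent[ints]]))
    list(keys = keys, ages = unname(ages[ints]), region = np$region[ints],
         maximal = maximal)
  })

  cand_key <- unique(unlist(lapply(per_tree, function(x) x$keys[x$maximal]),
                            use.names = FALSE))
  if (!length(cand_key)) {
    return(empty_gec_set(n, support_threshold))
  }
  first <- match(cand_key, unlist(lapply(per_tree, `[[`, "keys"), use.names = FALSE))
  all_region <- unlist(lapply(per_tree, `[[`, "region"), use.names = FALSE)
  cand_region <- all_region[first]

  # collect MRCA ages in every tree where the candidate is monophyletic
  idx_acc <- integer(0)
  age_acc <- numeric(0)
  for (t in seq_len(n)) {
    m <- match(per_tree[[t]]$keys, cand_key)
    hit <- !is.na(m)
    idx_acc <- c(idx_acc, m[hit])
    age_acc <- c(age_acc, per_tree[[t]]$ages[hit])
  }
  tmrca <- split(age_acc, factor(idx_acc, levels = seq_along(cand_key)))
  support <- lengths(tmrca) / n

  keep <- support > support_threshold
  if (!any(keep)) return(empty_gec_set(n, support_threshold))
  cand_key <- cand_key[keep]
  cand_region <- cand_region[keep]
  tmrca <- tmrca[keep]
  support <- support[keep]
  size <- lengths(lapply(cand_key, clade_tips))
  med <- vapply(tmrca, median, 0)

  # deterministic disjointness resolution
  ord <- order(-support, -size, -med, cand_key)
  taken <- character(0)
  sel <- logical(length(ord))
  for (i in ord) {
    tips_i <- clade_tips(cand_key[i])
    if (!any(tips_i %in% taken)) {
      sel[i] <- TRUE
      taken <- c(taken, tips_i)
    }
  }
  cand_key <- cand_key[sel]
  cand_region <- cand_region[sel]
  tmrca <- tmrca[sel]
  support <- unname(support[sel])
  size <- size[sel]
  med <- unname(med[sel])

  o <- order(cand_region, -size, -med)
  cand_key <- cand_key[o]; cand_region <- cand_region[o]
  tmrca <- tmrca[o]; support <- support[o]; size <- size[o]; med <- med[o]
  ids <- character(length(cand_region))
  for (r in unique(cand_region)) {
    ix <- which(cand_region == r)
    ids[ix] <- sprintf("%s_%02d", r, seq_along(ix))
  }
  names(tmrca) <- ids

  clades <- data.frame(clade_id = ids, region = cand_region, size = size,
                       support = support, median_tmrca = med,
                       stringsAsFactors = FALSE, row.names = NULL)
  clades$tips <- I(lapply(cand_key, clade_tips))
  structure(list(clades = clades, tmrca = tmrca, n_trees = n,
                 support_threshold = support_threshold),
            class = "gec_set")
}

empty_gec_set <- function(n, support_threshold) {
  clades <- data.frame(clade_id = character(0), region = character(0),
                       size = integer(0), support = numeric(0),
                       median_tmrca = numeric(0), stringsAsFactors = FALSE)
  clades$tips <- I(list())
  structure(list(clades = clades, tmrca = setNames(list(), character(0)),
                 n_trees = n, support_threshold = support_threshold),
            class = "gec_set")
}

#' @export
print.gec_set <- function(x, ...) {
  cat("GEC set:", nrow(x$clades), "clades from", x$n_trees,
      sprintf("posterior trees (support > %.2f)\n", x$support_threshold))
  if (nrow(x$clades)) {
    df <- x$clades
    df$tips <- vapply(df$tips, function(t) paste(t, collapse = ","), "")
    print(df, ...)
  }
  invisible(x)
}
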