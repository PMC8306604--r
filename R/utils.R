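# Shared internal helpers: clade keys, traversal bookkeeping, quadrature.

.key_sep <- "\x1f"

#' Canonical clade key from tip labels
#'
#' A clade is identified across trees by its tip-label set; the key is the
#' sorted labels joined with a non-printing separator, so set equality
#' becomes string equality.
#'
#' @param tips character vector of tip labels (length >= 1).
#' @return a single string.
#' @seealso [clade_tips()] for the inverse.
#' @export
clade_key <- function(tips) paste(sort(tips), collapse = .key_sep)

#' Tip labels from a canonical clade key
#' @param key a key produced by [clade_key()].
#' @return character vector of tip labels.
#' @export
clade_tips <- function(key) strsplit(key, .key_sep, fixed = TRUE)[[1]]

# Descendant-tip index sets for every node (tips and internal), by a single
# postorder sweep. Returns a list indexed by ape node id.
clade_tip_sets <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  po <- reorder(tree, "postorder")
  desc <- vector("list", n_all)
  for (i in seq_len(n_tip)) desc[[i]] <- i
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1L]
    ch <- po$edge[e, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  desc
}

# Keys of all internal-node clades of a tree, named by node id.
clade_keys <- function(tree) {
  n_tip <- length(tree$tip.label)
  desc <- clade_tip_sets(tree)
  ints <- (n_tip + 1L):(n_tip + tree$Nnode)
  out <- vapply(ints, function(nd) clade_key(tree$tip.label[desc[[nd]]]), "")
  names(out) <- as.character(ints)
  out
}

# Parent node id for every node (NA at the root).
node_parents <- function(tree) {
  n_all <- length(tree$tip.label) + tree$Nnode
  par <- rep(NA_integer_, n_all)
  par[tree$edge[, 2L]] <- tree$edge[, 1L]
  par
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1L) + tail(y, -1L)) / 2)

cumtrapz <- function(x, y) {
  c(0, cumsum(diff(x) * (head(y, -1L) + tail(y, -1L)) / 2))
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Effective sample size from the initial positive sequence of autocorrelations.
ess <- function(x) {
  n <- length(x)
  if (n < 10 || var(x) == 0) return(n)
  rho <- acf(x, lag.max = min(n - 1L, 200L), plot = FALSE)$acf[-1L]
  s <- 0
  for (r in rho) {
    if (r < 0) break
    s <- s + r
  }
  n / (1 + 2 * s)
}

check_regions_total <- function(regions, tips) {
  miss <- setdiff(tips, names(regions))
  if (length(miss)) {
    stop("no region assigned for tip(s): ", paste(head(miss, 5L), collapse = ", "),
         if (length(miss) > 5L) ", ..." else "")
  }
  invisible(TRUE)
}
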