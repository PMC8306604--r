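# Reading/writing posterior tree sets, node ages, MCC consensus, tables.

# Remove bracketed NEXUS/BEAST comments such as [&rate=...], including nested
# brackets, before handing the text to ape's parsers.
strip_nexus_comments <- function(txt) {
  while (any(grepl("\\[[^][]*\\]", txt))) txt <- gsub("\\[[^][]*\\]", "", txt)
  txt
}

#' Read a posterior set of rooted, time-calibrated trees
#'
#' Reads Newick or NEXUS (BEAST dialect: `translate` blocks are resolved,
#' bracketed `[&...]` metadata comments are discarded). All trees must be
#' rooted, share the same tip-label set, and have non-negative numeric branch
#' lengths (in years).
#'
#' @param path path to the tree file.
#' @param format `"auto"` (detect from a leading `#NEXUS`), `"nexus"` or
#'   `"newick"`.
#' @param burnin number of leading trees to discard; a value in `[0, 1)` is
#'   interpreted as a fraction of the file. Default 0: input is assumed to be
#'   post-burn-in already.
#' @return a `multiPhylo` with attributes `tip_universe` (sorted tip labels)
#'   and `source` (file and tree count).
#' @export
read_tree_set <- function(path, format = c("auto", "nexus", "newick"), burnin = 0) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (format == "auto") {
    format <- if (grepl("^\\s*#NEXUS", txt, ignore.case = TRUE)) "nexus" else "newick"
  }
  txt <- strip_nexus_comments(txt)
  if (format == "nexus") {
    tf <- tempfile(fileext = ".nex")
    on.exit(unlink(tf), add = TRUE)
    writeLines(txt, tf)
    trees <- ape::read.nexus(tf)
  } else {
    trees <- ape::read.tree(text = txt)
  }
  if (is.null(trees)) stop("no trees could be parsed from ", path)
  if (inherits(trees, "phylo")) trees <- c(trees)
  n0 <- length(trees)
  if (burnin > 0) {
    drop <- if (burnin < 1) floor(burnin * n0) else as.integer(burnin)
    if (drop >= n0) stop("burn-in discards all ", n0, " trees")
    trees <- trees[(drop + 1L):n0]
    class(trees) <- "multiPhylo"
  }
  validate_tree_set(trees, path)
  attr(trees, "tip_universe") <- sort(trees[[1L]]$tip.label)
  attr(trees, "source") <- list(file = path, count = length(trees))
  trees
}

validate_tree_set <- function(trees, label = "tree set") {
  if (length(trees) < 1L) stop(label, ": empty tree set")
  universe <- sort(trees[[1L]]$tip.label)
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    if (anyDuplicated(tr$tip.label)) {
      stop(label, ": duplicate tip label in tree ", i)
    }
    if (!ape::is.rooted(tr)) stop(label, ": tree ", i, " is not rooted")
    if (is.null(tr$edge.length)) stop(label, ": tree ", i, " has no branch lengths")
    if (anyNA(tr$edge.length) || !is.numeric(tr$edge.length)) {
      stop(label, ": non-numeric branch length in tree ", i)
    }
    if (any(tr$edge.length < 0)) stop(label, ": negative branch length in tree ", i)
    if (!identical(sort(tr$tip.label), universe)) {
      stop(label, ": tree ", i, " has a different tip set from tree 1")
    }
  }
  invisible(TRUE)
}

#' Write a set of trees to Newick or NEXUS
#'
#' The NEXUS writer emits a `translate` table (tips written as integers), the
#' dialect [read_tree_set()] consumes. Branch lengths are written with enough
#' digits to round-trip.
#'
#' @param trees a `multiPhylo` (or single `phylo`).
#' @param path output file path.
#' @param format `"nexus"` or `"newick"`.
#' @param digits significant digits for branch lengths (15 keeps year-scale
#'   lengths bit-faithful to well below 1e-9).
#' @export
write_tree_set <- function(trees, path, format = c("nexus", "newick"), digits = 15) {
  format <- match.arg(format)
  if (inherits(trees, "phylo")) trees <- c(trees)
  if (format == "newick") {
    writeLines(ape::write.tree(trees, digits = digits), path)
    return(invisible(path))
  }
  labels <- trees[[1L]]$tip.label
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(c("#NEXUS", "", "BEGIN TREES;", "\tTRANSLATE"), con)
  writeLines(paste0("\t\t", seq_along(labels), " ", labels,
                    ifelse(seq_along(labels) < length(labels), ",", ";")), con)
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    tr$tip.label <- as.character(match(tr$tip.label, labels))
    writeLines(sprintf("\tTREE tree_%d = [&R] %s", i,
                       ape::write.tree(tr, digits = digits)), con)
  }
  writeLines("END;", con)
  invisible(path)
}

#' Node ages in years before present
#'
#' Ages are measured up from the youngest tip (age 0); dated tips are offset
#' by their own age. For a clock tree with dated tips, every tip satisfies
#' `depth(tip) + tip_age(tip) = root age`; departures beyond `tol` (relative
#' to the root age) raise a warning, or an error when `clock = TRUE`.
#'
#' @param tree a rooted `phylo` with branch lengths in years.
#' @param tip_ages optional named numeric vector of tip ages (yBP); tips not
#'   named are at age 0.
#' @param clock if `TRUE`, inconsistent root-to-tip path lengths are an error
#'   rather than a warning.
#' @param tol relative tolerance for the clock check.
#' @return numeric vector of ages indexed by ape node id (tips first), named
#'   by tip label / node id.
#' @export
node_ages <- function(tree, tip_ages = NULL, clock = FALSE, tol = 1e-6) {
  n_tip <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  ta <- rep(0, n_tip)
  if (!is.null(tip_ages)) {
    if (is.null(names(tip_ages))) stop("tip_ages must be a named vector")
    idx <- match(names(tip_ages), tree$tip.label)
    if (anyNA(idx)) stop("tip_ages names not in tree: ",
                         paste(names(tip_ages)[is.na(idx)], collapse = ", "))
    ta[idx] <- tip_ages
  }
  root_candidates <- depth[seq_len(n_tip)] + ta
  root_age <- max(root_candidates)
  spread <- diff(range(root_candidates))
  if (root_age > 0 && spread > tol * root_age) {
    msg <- sprintf("root-to-tip path lengths inconsistent (spread %.3g of root age %.3g)",
                   spread, root_age)
    if (clock) stop(msg) else warning(msg)
  }
  ages <- root_age - depth
  names(ages) <- c(tree$tip.label,
                   as.character((n_tip + 1L):(n_tip + tree$Nnode)))
  ages
}

#' Maximum clade credibility consensus with common-ancestor heights
#'
#' Selects the posterior sample tree maximising the product of its clades'
#' posterior frequencies (summed in log space), then replaces each internal
#' node's age by the mean, over all posterior trees, of the age of the most
#' recent common ancestor of that node's tip set — whether or not the clade
#' is monophyletic in a given tree. Branch lengths are re-derived from the
#' mean ages. Ties in clade credibility keep the earliest tree in file order
#' (a message is emitted).
#'
#' @param trees a `multiPhylo` sharing one tip universe.
#' @param tip_ages optional named tip ages (yBP), see [node_ages()].
#' @return the MCC `phylo`, with attribute `log_clade_credibility`.
#' @export
mcc_consensus <- function(trees, tip_ages = NULL) {
  if (inherits(trees, "phylo")) trees <- c(trees)
  if (length(trees) < 1L) stop("empty tree set")
  n <- length(trees)
  keysets <- lapply(trees, clade_keys)
  freq <- table(unlist(lapply(keysets, unique), use.names = FALSE))
  logcred <- vapply(keysets, function(k) sum(log(as.numeric(freq[k]) / n)), 0)
  best <- which.max(logcred)
  if (sum(abs(logcred - logcred[best]) < 1e-12) > 1L) {
    message("MCC tie between trees; keeping the earliest in file order")
  }
  tr <- trees[[best]]
  n_tip <- length(tr$tip.label)
  ages_list <- lapply(trees, function(t) suppressWarnings(node_ages(t, tip_ages)))
  keymaps <- lapply(seq_len(n), function(i) {
    k <- keysets[[i]]
    setNames(ages_list[[i]][as.integer(names(k))], k)
  })
  desc <- clade_tip_sets(tr)
  ints <- (n_tip + 1L):(n_tip + tr$Nnode)
  mean_age <- numeric(length(ints))
  for (j in seq_along(ints)) {
    tipvec <- tr$tip.label[desc[[ints[j]]]]
    key <- clade_key(tipvec)
    a <- vapply(seq_len(n), function(i) {
      hit <- keymaps[[i]][key]
      if (!is.na(hit)) return(unname(hit))
      mrca <- ape::getMRCA(trees[[i]], tipvec)
      unname(ages_list[[i]][mrca])
    }, 0)
    mean_age[j] <- mean(a)
  }
  ages <- c(suppressWarnings(node_ages(tr, tip_ages))[seq_len(n_tip)], # tip ages kept
            setNames(mean_age, as.character(ints)))
  tr$edge.length <- unname(ages[tr$edge[, 1L]] - ages[tr$edge[, 2L]])
  attr(tr, "log_clade_credibility") <- logcred[best]
  tr
}

#' Read a tip-to-region table
#'
#' Expects a TSV with two columns, tip label and region code; a header row is
#' optional and `#` comment lines are skipped. Duplicate rows are accepted if
#' consistent; conflicting duplicates, missing regions, and codes outside the
#' declared state space are errors.
#'
#' @param path TSV path.
#' @param states allowed region codes (default `AUS`, `PAP`, `WLC`).
#' @return named character vector tip label -> region, with attribute
#'   `states`.
#' @export
read_region_map <- function(path, states = c("AUS", "PAP", "WLC")) {
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE, strip.white = TRUE,
                   colClasses = "character")
  if (ncol(df) < 2L) stop("expected two tab-separated columns in ", path)
  df <- df[, 1:2]
  names(df) <- c("tip_label", "region")
  if (nrow(df) &&
      (tolower(df$tip_label[1L]) %in% c("tip", "tip_label", "label", "sample") ||
       tolower(df$region[1L]) %in% c("region", "state"))) {
    df <- df[-1L, , drop = FALSE]
  }
  if (!nrow(df)) stop("no data rows in ", path)
  if (any(is.na(df$region) | df$region == "")) {
    stop("missing region for tip(s): ",
         paste(df$tip_label[is.na(df$region) | df$region == ""], collapse = ", "))
  }
  bad <- setdiff(unique(df$region), states)
  if (length(bad)) {
    stop("unknown region code(s): ", paste(bad, collapse = ", "),
         " (declared states: ", paste(states, collapse = ", "), ")")
  }
  split_reg <- split(df$region, df$tip_label)
  conflict <- names(split_reg)[vapply(split_reg, function(x) length(unique(x)) > 1L, TRUE)]
  if (length(conflict)) {
    stop("conflicting region for tip(s): ", paste(conflict, collapse = ", "))
  }
  out <- vapply(split_reg, `[[`, "", 1L)
  attr(out, "states") <- states
  out
}

#' Tabulate category frequencies within a stratum
#'
#' Counts and percentages (to 0.1%) of a categorical tip attribute (e.g.
#' haplogroup or region) within a subset of tips.
#'
#' @param categories named character vector tip -> category.
#' @param stratum tip labels to tabulate over (default: all).
#' @return data.frame with columns `category`, `n`, `percent`, sorted by
#'   decreasing count.
#' @export
tabulate_frequencies <- function(categories, stratum = names(categories)) {
  if (length(stratum) == 0L) stop("empty stratum")
  miss <- setdiff(stratum, names(categories))
  if (length(miss)) stop("stratum tips without category: ", paste(miss, collapse = ", "))
  x <- categories[stratum]
  tab <- sort(table(x), decreasing = TRUE)
  data.frame(category = names(tab),
             n = as.integer(tab),
             percent = round(100 * as.integer(tab) / length(x), 1L),
             stringsAsFactors = FALSE, row.names = NULL)
}
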