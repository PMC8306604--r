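test_that("newick and translated NEXUS parse to the same tree", {
  nwk <- tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):2,C:3);", nwk)
  ts <- read_tree_set(nwk)
  expect_length(ts, 1L)
  expect_identical(attr(ts, "tip_universe"), c("A", "B", "C"))

  nex <- tempfile(fileext = ".nex")
  writeLines(c("#NEXUS", "BEGIN TREES;", "  TRANSLATE",
               "    1 A,", "    2 B,", "    3 C;",
               "  TREE t1 = [&R] ((1:1[&rate=0.1],2:1):2[&height=2],3:3);",
               "END;"), nex)
  ts2 <- read_tree_set(nex)
  expect_identical(sort(phylogec:::clade_keys(ts2[[1L]])),
                   sort(phylogec:::clade_keys(ts[[1L]])))
  expect_equal(sort(ts2[[1L]]$edge.length), sort(ts[[1L]]$edge.length))
})

test_that("invalid tree sets are rejected", {
  f <- tempfile()
  writeLines("((A:1,B:-1):2,C:3);", f)
  expect_error(read_tree_set(f), "negative")
  writeLines(c("((A:1,B:1):2,C:3);", "((A:1,B:1):2,D:3);"), f)
  expect_error(read_tree_set(f), "different tip set")
  writeLines("(A:1,B:1,C:1,D:2);", f)  # basal polytomy: unrooted by convention
  expect_error(read_tree_set(f), "not rooted")
})

test_that("burn-in discards leading trees", {
  f <- tempfile()
  writeLines(rep("((A:1,B:1):2,C:3);", 10), f)
  expect_length(read_tree_set(f, burnin = 0.3), 7L)
  expect_length(read_tree_set(f, burnin = 4), 6L)
  expect_error(read_tree_set(f, burnin = 10), "discards all")
})

test_that("tree sets round-trip through both formats", {
  set.seed(101)
  tree <- simulate_tree(12, Ne = 1, gen_time = 5000)
  trees <- emulate_posterior(tree, n_trees = 100, jitter_sd = 0.1,
                             nni_prob = 0.3)
  for (fmt in c("nexus", "newick")) {
    f <- tempfile()
    write_tree_set(trees, f, fmt)
    back <- read_tree_set(f)
    expect_length(back, 100L)
    for (i in c(1L, 37L, 100L)) {
      expect_identical(sort(unname(phylogec:::clade_keys(back[[i]]))),
                       sort(unname(phylogec:::clade_keys(trees[[i]]))))
      expect_equal(sort(back[[i]]$edge.length), sort(trees[[i]]$edge.length),
                   tolerance = 1e-9)
    }
  }
})

test_that("node ages follow the yBP convention, including dated tips", {
  tr <- read_one_tree("((A:1,B:1):2,C:3);")
  a <- node_ages(tr)
  expect_equal(unname(a[c("A", "B", "C")]), c(0, 0, 0))
  expect_equal(unname(a["5"]), 1)   # MRCA(A,B)
  expect_equal(unname(a["4"]), 3)   # root

  # ancient tip D sampled 1250 yBP, attached with consistent lengths
  tr2 <- read_one_tree("((A:1000,B:1000):2000,(C:2000,D:750):1000);")
  a2 <- node_ages(tr2, tip_ages = c(D = 1250))
  expect_equal(unname(a2["D"]), 1250)
  expect_equal(unname(a2["5"]), 3000)  # root
  expect_equal(unname(a2["7"]), 2000)  # MRCA(C,D)

  # generator bookkeeping: ages agree with ape::branching.times
  set.seed(7)
  tr3 <- simulate_tree(15, Ne = 100, gen_time = 30)
  expect_equal(unname(node_ages(tr3)[as.integer(names(oracle_ages(tr3)))]),
               unname(oracle_ages(tr3)), tolerance = 1e-9)
})

test_that("clock violations warn by default and error when required", {
  tr <- read_one_tree("((A:1,B:2):2,C:3);")
  expect_warning(node_ages(tr), "inconsistent")
  expect_error(node_ages(tr, clock = TRUE), "inconsistent")
})

test_that("MCC consensus is the identity on a point-mass posterior", {
  tr <- read_one_tree("((A:1000,B:1000):2000,C:3000);")
  trees <- c(tr, tr, tr, tr, tr, tr, tr, tr, tr, tr)
  m <- mcc_consensus(trees)
  expect_identical(sort(unname(phylogec:::clade_keys(m))),
                   sort(unname(phylogec:::clade_keys(tr))))
  expect_equal(sort(m$edge.length), sort(tr$edge.length), tolerance = 1e-12)
})

test_that("MCC picks the majority topology", {
  t1 <- read_one_tree("((A:1,B:1):2,(C:2,D:2):1);")
  t2 <- read_one_tree("((A:1,C:1):2,(B:2,D:2):1);")
  trees <- c(t1, t1, t1, t1, t1, t1, t1, t1, t2, t2)
  m <- mcc_consensus(trees)
  expect_true(clade_key(c("A", "B")) %in% phylogec:::clade_keys(m))
})

test_that("MCC node ages equal per-clade mean MRCA ages (brute-force oracle)", {
  set.seed(31)
  tree <- simulate_tree(10, Ne = 1, gen_time = 8000)
  trees <- emulate_posterior(tree, n_trees = 60, jitter_sd = 0.08, nni_prob = 0)
  m <- mcc_consensus(trees)
  am <- node_ages(m)
  n_tip <- 10L
  for (nd in (n_tip + 1L):(n_tip + m$Nnode)) {
    tips <- m$tip.label[phangorn::Descendants(m, nd, "tips")[[1L]]]
    mean_oracle <- mean(vapply(trees, function(tr) {
      mrca <- if (length(tips) == n_tip) n_tip + 1L else ape::getMRCA(tr, tips)
      unname(oracle_ages(tr)[as.character(mrca)])
    }, 0))
    expect_equal(unname(am[as.character(nd)]), mean_oracle, tolerance = 1e-9)
  }
})

test_that("region maps are read and validated", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("# sampling regions", "tip_label\tregion",
               "A\tWLC", "B\tWLC", "C\tPAP", "A\tWLC"), f)
  m <- read_region_map(f)
  expect_length(m, 3L)
  expect_identical(unname(m[c("A", "B", "C")]), c("WLC", "WLC", "PAP"))

  writeLines(c("A\tWLC", "A\tPAP"), f)
  expect_error(read_region_map(f), "conflicting")
  writeLines(c("A\tXYZ"), f)
  expect_error(read_region_map(f), "XYZ")
  expect_silent(read_region_map(f, states = c("XYZ", "ABC")))
  writeLines(c("A\t"), f)
  expect_error(read_region_map(f))
})

test_that("frequency tables count and percentage correctly", {
  # 120 tips, 69 in haplogroup Q -> 57.5%
  cats <- setNames(c(rep("Q", 69), rep("P", 27), rep("M73", 3), rep("other", 21)),
                   paste0("s", 1:120))
  tab <- tabulate_frequencies(cats)
  expect_identical(tab$n[tab$category == "Q"], 69L)
  expect_identical(tab$percent[tab$category == "Q"], 57.5)
  expect_identical(tab$percent[tab$category == "P"], 22.5)

  one <- tabulate_frequencies(setNames(rep("Q", 7), paste0("x", 1:7)))
  expect_identical(one$percent, 100)

  set.seed(5)
  r <- setNames(sample(STATES, 1000, TRUE), paste0("t", 1:1000))
  tab3 <- tabulate_frequencies(r)
  expect_equal(sum(tab3$percent), 100, tolerance = 0.1)
  expect_identical(sum(tab3$n), 1000L)
  expect_error(tabulate_frequencies(r, character(0)), "empty stratum")
})

test_that("the bundled synthetic example loads and yields regional clades", {
  nex <- system.file("extdata", "synthetic_posterior.nex", package = "phylogec")
  tsv <- system.file("extdata", "synthetic_regions.tsv", package = "phylogec")
  trees <- read_tree_set(nex)
  regions <- read_region_map(tsv)
  expect_length(trees, 30L)
  expect_setequal(names(regions), attr(trees, "tip_universe"))
  expect_identical(unname(regions["Aru1"]), "WLC")
  g <- extract_gecs(trees, regions)
  expect_true(all(g$clades$support > 0.5))
  expect_true(all(g$clades$size >= 2))
})
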