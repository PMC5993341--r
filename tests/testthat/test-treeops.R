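# Tree assembly, pruning, incomplete sampling, statistics, Newick I/O and
# shift reports.

test_that("assembly maps point-mass traces to the expected shapes", {
  sym <- sim_age(5, fig_sym_cfg())$tree
  expect_identical(sum(sym$nodes$is_tip), 4L)
  expect_identical(sum(!sym$nodes$is_tip), 3L)
  expect_equal(sym$stem_length, 2)
  expect_true(all(sym$nodes$extant[sym$nodes$is_tip]))
  asym <- sim_age(5, fig_asym_cfg())$tree
  expect_identical(sum(asym$nodes$is_tip & asym$nodes$extant), 1L)
  expect_identical(sum(asym$nodes$is_tip & !asym$nodes$extant), 2L)
  expect_equal(sort(asym$nodes$time[!asym$nodes$is_tip]), c(2, 4))
  # node times equal the sum of edge lengths from the origin
  for (tr in list(sym, asym)) {
    expect_equal(node_depths(tr), tr$nodes$time, tolerance = 1e-9)
  }
})

test_that("assembly rejects inconsistent lineage records", {
  lin <- lin_3tip()
  lin$parent[4] <- 99L
  expect_error(assemble_tree(lin), class = "bhtree_bad_lineages")
  lin2 <- lin_3tip()[-1, ]
  attr(lin2, "horizon") <- 3
  expect_error(assemble_tree(lin2), class = "bhtree_bad_lineages")
})

test_that("pruning drops extinct history, preserves extant tips, yields ultrametry", {
  set.seed(61)
  res <- sim_age(6, crbd_cfg(0.9, 0.4))
  while (is.null(res$tree) || tree_stats(res$tree)$extant_tips < 2 ||
         tree_stats(res$tree)$total_tips == tree_stats(res$tree)$extant_tips) {
    res <- sim_age(6, crbd_cfg(0.9, 0.4))
  }
  full <- tree_stats(res$tree)
  pr <- prune_extinct(res$tree)
  expect_identical(pr$status, "completed")
  st <- tree_stats(pr$tree)
  expect_identical(st$extant_tips, full$extant_tips)
  expect_identical(st$total_tips, st$extant_tips)
  expect_lt(st$total_branch_length, full$total_branch_length)
  # ultrametric to 1e-9 relative tolerance, via recomputed depths
  d <- node_depths(pr$tree)[pr$tree$nodes$is_tip]
  expect_lt(diff(range(d)), 1e-9 * max(d))
  # internal nodes strictly binary after suppression
  nkid <- table(factor(pr$tree$nodes$parent, levels = pr$tree$nodes$id))
  expect_true(all(nkid[!pr$tree$nodes$is_tip] == 2L))
  # labels survive pruning
  expect_true(all(pr$tree$nodes$label[pr$tree$nodes$is_tip] %in%
                  res$tree$nodes$label))
})

test_that("pruning a no-extinction tree is the identity on its node set", {
  set.seed(63)
  res <- sim_taxa(12, yule_cfg(0.5))
  pr <- prune_extinct(res$tree)
  expect_identical(pr$status, "completed")
  expect_equal(pr$tree$nodes, res$tree$nodes)
})

test_that("pruning reports extinct and single-survivor statuses", {
  asym <- sim_age(5, fig_asym_cfg())$tree
  pr <- prune_extinct(asym)
  expect_identical(pr$status, "single_survivor")
  expect_null(pr$tree)
  # complete = FALSE propagates the status through simulation results
  res <- sim_age(5, fig_asym_cfg(complete = FALSE))
  expect_identical(res$status, "single_survivor")
  expect_null(res$tree)
})

test_that("uniform tip sampling is exchangeable across tip subsets", {
  set.seed(65)
  tr <- tree_4tip()
  expect_identical(sample_tips(tr, 1, "uniform"), tr) # frac = 1 identity
  pairs <- replicate(3000, {
    s <- sample_tips(tr, 0.5, "uniform")
    paste(sort(s$nodes$label[s$nodes$is_tip]), collapse = ",")
  })
  expect_identical(length(unique(pairs)), 6L)
  expect_gt(stats::chisq.test(table(pairs))$p.value, 0.01)
  s <- sample_tips(tr, 0.5, "uniform")
  expect_identical(tree_stats(s)$extant_tips, 2L)
})

test_that("proportional sampling follows successive pendant-length-weighted draws", {
  # exact enumeration oracle for 2 successive weighted draws without
  # replacement from pendant weights (2, 1, 1):
  #   P({t1,t2}) = P({t1,t3}) = 5/12, P({t2,t3}) = 1/6
  w <- c(2, 1, 1)
  p_set <- c(0, 0, 0) # sets {1,2}, {1,3}, {2,3}
  set_id <- function(a, b) c("1,2" = 1, "1,3" = 2, "2,3" = 3)[paste(sort(c(a, b)), collapse = ",")]
  for (first in 1:3) {
    rest <- setdiff(1:3, first)
    for (second in rest) {
      p <- (w[first] / sum(w)) * (w[second] / sum(w[rest]))
      i <- set_id(first, second)
      p_set[i] <- p_set[i] + p
    }
  }
  expect_equal(p_set, c(5 / 12, 5 / 12, 1 / 6))
  set.seed(67)
  tr <- tree_3tip() # pendant lengths t1: 2, t2: 1, t3: 1
  pend <- tr$nodes$length[tr$nodes$is_tip]
  expect_equal(sort(pend, decreasing = TRUE), c(2, 1, 1))
  sets <- replicate(5000, {
    s <- sample_tips(tr, 2 / 3, "proportional")
    paste(sort(s$nodes$label[s$nodes$is_tip]), collapse = ",")
  })
  tab <- table(factor(sets, c("t1,t2", "t1,t3", "t2,t3")))
  expect_gt(stats::chisq.test(tab, p = p_set)$p.value, 0.01)
})

test_that("sampling guards its preconditions", {
  tr <- tree_4tip()
  expect_error(sample_tips(tr, 0.2, "uniform"), class = "bhtree_bad_sampling")
  cmpl <- sim_age(5, fig_asym_cfg())$tree # has extinct tips
  expect_error(sample_tips(cmpl, 0.5, "uniform"), class = "bhtree_bad_sampling")
})

test_that("end-to-end incomplete sampling keeps round(N * frac) tips", {
  set.seed(69)
  cfg <- yule_cfg(0.5, complete = FALSE, frac = 0.5)
  res <- sim_taxa(20, cfg)
  expect_identical(tree_stats(res$tree)$extant_tips, 10L)
})

test_that("tree statistics match the point-mass traces", {
  st <- tree_stats(sim_age(5, fig_sym_cfg())$tree)
  expect_identical(st$extant_tips, 4L)
  expect_equal(st$oldest_branching_time, 2)
  expect_equal(st$stem_age, 5)
  expect_equal(st$total_branch_length, 2 + 2 * 2 + 4 * 1)
  expect_equal(st$ltt, data.frame(time = c(0, 2, 4), count = c(1, 2, 4)))
  stb <- tree_stats(sim_age(5, fig_asym_cfg())$tree)
  expect_identical(stb$total_tips, 3L)
  expect_identical(stb$extant_tips, 1L)
  expect_equal(stb$ltt$count, c(1, 2, 1, 2, 1))
})

test_that("Newick output round-trips through an independent parser", {
  set.seed(71)
  for (cfg in list(fig_sym_cfg(), crbd_cfg(0.9, 0.3),
                   crbd_cfg(0.9, 0.3, symmetric = FALSE))) {
    tr <- sim_age(4, cfg)$tree
    if (is.null(tr)) next
    back <- read_newick(write_newick(tr))
    expect_identical(sum(back$nodes$is_tip), sum(tr$nodes$is_tip))
    expect_setequal(back$nodes$label[back$nodes$is_tip],
                    tr$nodes$label[tr$nodes$is_tip])
    expect_equal(back$stem_length, tr$stem_length, tolerance = 1e-9)
    if (sum(tr$nodes$is_tip) >= 2) {
      p1 <- as.phylo(tr); p2 <- as.phylo(back)
      expect_true(ape::all.equal.phylo(p1, p2, use.edge.length = FALSE))
      expect_equal(sort(ape::node.depth.edgelength(p1)),
                   sort(ape::node.depth.edgelength(p2)), tolerance = 1e-9)
    }
  }
})

test_that("one-tip trees serialize with an explicit stem", {
  tr <- sim_age(3, sim_config("const(10)"))$tree
  nwk <- write_newick(tr)
  expect_identical(nwk, "(t1:0):3;")
  back <- read_newick(nwk)
  expect_equal(back$stem_length, 3)
  expect_identical(sum(back$nodes$is_tip), 1L)
})

test_that("malformed Newick raises a parse error; duplicate labels flagged", {
  expect_error(read_newick("((A,B;"), class = "bhtree_parse")
  expect_error(read_newick("(A:1,A:2):1;"), class = "bhtree_parse")
})

test_that("shift reports expose factors, flags and the four tip vectors", {
  set.seed(73)
  plain <- sim_taxa(6, yule_cfg(0.5))$tree
  rep0 <- shift_report(plain)
  expect_true(all(rep0$nodes$sp_factor == 1) && all(rep0$nodes$ext_factor == 1))
  expect_true(all(rep0$shifted.sp.living == 0L))
  expect_identical(names(rep0$shifted.sp.living),
                   plain$nodes$label[plain$nodes$is_tip & plain$nodes$extant])
  cfg <- sim_config("rexp(1)", shiftsp = list(prob = 1, strength = "const(0.5)"))
  tr <- sim_taxa(6, cfg)$tree
  rep1 <- shift_report(tr)
  # under symmetric speciation every tip lineage is a (shifted) new species
  expect_true(all(rep1$shifted.sp.living == 1L))
  expect_true(all(rep1$nodes$sp_factor[rep1$nodes$is_tip] == 0.5))
  ann <- write_annotations(tr)
  expect_identical(nrow(ann), sum(tr$nodes$is_tip))
  expect_named(ann, c("node_label", "sp_factor", "ext_factor",
                      "sp_shifted", "ext_shifted", "extant"))
})
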