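tree_of <- function(newick) genus_tree(ape::read.tree(text = newick))

test_that("single-genus cherries and mixed cherries are scored correctly", {
  both <- find_multiplied_clusters(tree_of("((A_1,A_2),(B_1,B_2));"))
  expect_equal(both$per_genus$fraction, c(1, 1))

  none <- find_multiplied_clusters(tree_of("((A_1,B_1),(A_2,B_2));"))
  expect_equal(none$per_genus$fraction, c(0, 0))
  expect_equal(nrow(none$clusters), 0L)
})

test_that("reported clusters are maximal and disjoint", {
  # nested single-genus clades: only the outermost is reported
  gt <- tree_of("(((A_1,A_2),(A_3,A_4)),(B_1,B_2));")
  s <- find_multiplied_clusters(gt)
  expect_equal(dplyr::n_distinct(s$clusters$cluster_id), 2L)
  a_cluster <- s$clusters[s$clusters$genus == "A", ]
  expect_setequal(a_cluster$leaf, c("A_1", "A_2", "A_3", "A_4"))
  expect_false(any(duplicated(s$clusters$leaf)))
  expect_equal(s$per_genus$fraction[s$per_genus$genus == "A"], 1)
})

test_that("cluster extraction equals exhaustive clade enumeration", {
  for (seed in 1:200) {
    gt <- random_genus_tree(n_leaves = sample(4:12, 1), n_genera = 3,
                            seed = seed)
    got <- find_multiplied_clusters(gt)$per_genus
    want <- oracle_multiplied_fractions(gt$tree, gt$genera)
    expect_equal(as.data.frame(got), as.data.frame(want),
                 label = sprintf("seed %d", seed))
  }
})

test_that("planted multiplied fractions are recovered exactly", {
  gt <- simulate_genus_tree(
    c(Tco = 100, Tci = 40, Cs = 30),
    c(Tco = 0.67, Tci = 0.5, Cs = 0),
    seed = 8
  )
  got <- find_multiplied_clusters(gt)$per_genus
  expect_equal(as.data.frame(got), as.data.frame(attr(gt, "truth")))

  # extremes: fully monophyletic and fully dispersed genera
  ext <- simulate_genus_tree(c(A = 6, B = 7), c(A = 1.0, B = 0.0), seed = 2)
  got_ext <- find_multiplied_clusters(ext)$per_genus
  expect_equal(got_ext$fraction[got_ext$genus == "A"], 1)
  expect_equal(got_ext$fraction[got_ext$genus == "B"], 0)

  # a planted singleton cluster is rejected as unachievable
  expect_error(simulate_genus_tree(c(A = 10, B = 10), c(A = 0.1, B = 0)),
               "singleton")
})

test_that("growing an existing cluster never decreases the genus fraction", {
  for (seed in 1:10) {
    gt <- simulate_genus_tree(c(A = 8, B = 8), c(A = 0.5, B = 0.5), seed = seed)
    before <- find_multiplied_clusters(gt)$per_genus
    f0 <- before$fraction[before$genus == "A"]
    # attach a new A leaf inside A's cluster (sister to one cluster leaf)
    cl <- find_multiplied_clusters(gt)$clusters
    target <- cl$leaf[cl$genus == "A"][1]
    tree2 <- phangorn::add.tips(ape::compute.brlen(gt$tree, 1), "A_999",
                                where = which(gt$tree$tip.label == target))
    gt2 <- genus_tree(tree2)
    after <- find_multiplied_clusters(gt2)$per_genus
    expect_gte(after$fraction[after$genus == "A"], f0)
  }
})

test_that("unrooted trees are rejected and midpoint rooting resolves them", {
  unrooted <- ape::unroot(ape::rtree(6))
  unrooted$tip.label <- sprintf("G%d_%d", rep(1:2, 3), 1:6)
  gt <- genus_tree(unrooted)
  expect_error(find_multiplied_clusters(gt), "unrooted")
  rooted <- midpoint_root(gt)
  expect_true(ape::is.rooted(rooted$tree))
  expect_s3_class(find_multiplied_clusters(rooted), "cluster_summary")
})

test_that("midpoint rooting minimizes the maximum root-to-leaf distance", {
  # 3-leaf tree with one long pendant edge: root lands on the long edge
  t3 <- ape::read.tree(text = "(A_1:1,B_1:1,C_1:10);")
  r3 <- midpoint_root(t3)
  d <- ape::dist.nodes(r3)[length(r3$tip.label) + 1L, seq_along(r3$tip.label)]
  expect_equal(max(d), 5.5)  # half the 11-unit diameter (A_1 to C_1)

  # random trees: achieved max depth equals half the tree diameter
  for (seed in 1:10) {
    tr <- withr::with_seed(seed, ape::rtree(10))
    rooted <- midpoint_root(tr)
    depth <- ape::dist.nodes(rooted)[ape::Ntip(rooted) + 1L,
                                     seq_len(ape::Ntip(rooted))]
    diameter <- max(ape::cophenetic.phylo(tr))
    expect_equal(max(depth), diameter / 2, tolerance = 1e-8)
  }

  nolen <- ape::rtree(5); nolen$edge.length <- NULL
  expect_error(midpoint_root(nolen), "branch lengths")
})

test_that("low-support nodes can be collapsed before extraction", {
  # the A-clade has support 40: below the threshold it dissolves into a
  # polytomy with B_1, destroying the cluster
  nwk <- "(((A_1,A_2)40,B_1)90,(B_2,C_1)95);"
  tr <- ape::read.tree(text = nwk)
  gt <- genus_tree(tr)
  keep <- find_multiplied_clusters(gt)
  expect_equal(sum(keep$per_genus$multiplied_leaves), 2L)
  drop <- find_multiplied_clusters(gt, collapse_below = 50)
  expect_equal(sum(drop$per_genus$multiplied_leaves), 0L)
  # threshold below every support changes nothing
  same <- find_multiplied_clusters(gt, collapse_below = 10)
  expect_equal(same$per_genus, keep$per_genus)
})

test_that("the multiplied report prints rounded integer percentages", {
  gt <- simulate_genus_tree(c(A = 6, B = 8), c(A = 2 / 3, B = 0), seed = 1)
  rep_tbl <- multiplied_report(find_multiplied_clusters(gt))
  expect_equal(rep_tbl$percent[rep_tbl$genus == "A"], 67L)  # 0.667 -> 67
  expect_equal(rep_tbl$percent[rep_tbl$genus == "B"], 0L)
  expect_named(rep_tbl, c("genus", "total", "multiplied", "percent"))
})
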