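test_that("branch profile accumulates leaf proportions up the tree", {
  tab <- matrix(c(0.5, 0.5, 0,
                  0.2, 0.3, 0.5,
                  1 / 3, 1 / 3, 1 / 3), 3, 3, byrow = TRUE,
                dimnames = list(paste0("S", 1:3), c("A", "B", "C")))
  bp <- branch_profile(tab, star_tree(c("A", "B", "C")))
  expect_equal(dim(bp$proportions), c(3, 3))
  expect_equal(sort(bp$proportions[1, ]), c(0, 0.5, 0.5))

  # caterpillar: internal branch carries the sum of its two leaf proportions
  tr <- ape::read.tree(text = "(A:1,(B:0.5,C:0.5):1);")
  bp2 <- branch_profile(tab, tr)
  child <- tr$edge[, 2]
  internal_col <- which(child > ape::Ntip(tr))
  expect_equal(unname(bp2$proportions[, internal_col]),
               unname(tab[, "B"] + tab[, "C"]))
})

test_that("branch profile agrees with naive per-branch leaf-set summation", {
  set.seed(10)
  tr <- ape::rtree(10)
  tab <- random_table(6, 10, seed = 11)
  colnames(tab) <- tr$tip.label
  bp <- branch_profile(tab, tr)
  # oracle: for each edge, sum the relative abundances of the tips below it
  tips_below <- function(tree, node) {
    if (node <= ape::Ntip(tree)) return(tree$tip.label[node])
    unlist(lapply(tree$edge[tree$edge[, 1] == node, 2], tips_below, tree = tree))
  }
  for (e in seq_len(nrow(tr$edge))) {
    leaves <- tips_below(tr, tr$edge[e, 2])
    expect_equal(bp$proportions[, e],
                 rowSums(tab[, leaves, drop = FALSE]),
                 tolerance = 1e-12)
  }
})

test_that("weighted UniFrac matches the defining formula on hand cases", {
  tab <- matrix(c(1, 0, 0,
                  0, 1, 0,
                  0.5, 0.5, 0), 3, 3, byrow = TRUE,
                dimnames = list(paste0("S", 1:3), c("A", "B", "C")))
  bp <- branch_profile(tab, star_tree(c("A", "B", "C")))
  D <- weighted_unifrac(bp, alpha = 0.5)
  expect_equal(diag(D), rep(0, 3), ignore_attr = TRUE)
  # disjoint single-OTU samples on unit star: numerator = denominator
  expect_equal(D[1, 2], 1)
  expect_equal(D, t(D))

  # identical samples at any alpha
  tab2 <- rbind(tab, S4 = tab[3, ])
  bp2 <- branch_profile(tab2, star_tree(c("A", "B", "C")))
  expect_equal(weighted_unifrac(bp2, 0.3)[3, 4], 0)
})

test_that("alpha = 0 reduces to the shared-support normalized L1 form", {
  set.seed(21)
  tr <- ape::rtree(8)
  tab <- random_table(5, 8, seed = 22)
  colnames(tab) <- tr$tip.label
  tab[1, 1:4] <- 0; tab <- tab / rowSums(tab)   # introduce zeros
  bp <- branch_profile(tab, tr)
  D <- weighted_unifrac(bp, alpha = 0)
  P <- bp$proportions; b <- bp$lengths
  for (i in 1:4) for (j in (i + 1):5) {
    keep <- P[i, ] + P[j, ] > 0
    expect_equal(D[i, j],
                 sum(b[keep] * abs(P[i, keep] - P[j, keep])) / sum(b[keep]),
                 tolerance = 1e-12)
  }
})

test_that("unweighted UniFrac uses presence/absence over total tree length", {
  tab <- matrix(c(1, 0, 0,
                  0, 1, 0,
                  0.5, 0.5, 0), 3, 3, byrow = TRUE,
                dimnames = list(paste0("S", 1:3), c("A", "B", "C")))
  bp <- branch_profile(tab, star_tree(c("A", "B", "C")))
  D <- unweighted_unifrac(bp)
  expect_equal(D[1, 2], 2 / 3)  # two mismatching unit branches of three

  # identical presence patterns at different abundances
  tab2 <- matrix(c(0.9, 0.1, 0,
                   0.1, 0.9, 0,
                   0.5, 0.5, 0), 3, 3, byrow = TRUE,
                 dimnames = dimnames(tab))
  bp2 <- branch_profile(tab2, star_tree(c("A", "B", "C")))
  expect_equal(unweighted_unifrac(bp2)[1, 2], 0)

  # presence is strict positivity, no threshold
  tab3 <- matrix(c(1 - 1e-300, 1e-300, 0,
                   1, 0, 0,
                   0, 0, 1), 3, 3, byrow = TRUE, dimnames = dimnames(tab))
  bp3 <- branch_profile(tab3, star_tree(c("A", "B", "C")))
  expect_equal(unweighted_unifrac(bp3)[1, 2], 1 / 3)
})

test_that("unweighted UniFrac is invariant to positive abundance rescaling", {
  set.seed(31)
  tr <- ape::rtree(12)
  tab <- random_table(6, 12, seed = 32)
  colnames(tab) <- tr$tip.label
  tab[tab < 0.05] <- 0
  tab <- tab / rowSums(tab)
  D1 <- unweighted_unifrac(branch_profile(tab, tr))
  # rescale rows by random positive factors, renormalize: presence unchanged
  tab2 <- tab * matrix(runif(length(tab), 0.5, 2), nrow(tab))
  tab2 <- tab2 / rowSums(tab2)
  D2 <- unweighted_unifrac(branch_profile(tab2, tr))
  expect_equal(D1, D2, tolerance = 1e-12)
})

test_that("Bray-Curtis matches hand values and the half-L1 oracle", {
  tab <- matrix(c(1, 0, 0,
                  0, 1, 0,
                  0.5, 0.5, 0,
                  0.25, 0.25, 0.5), 4, 3, byrow = TRUE,
                dimnames = list(paste0("S", 1:4), c("A", "B", "C")))
  D <- bray_curtis(tab)
  expect_equal(D[1, 2], 1)   # disjoint support
  expect_equal(D[3, 4], 0.5) # hand evaluation
  expect_equal(diag(D), rep(0, 4), ignore_attr = TRUE)

  tab2 <- random_table(7, 15, seed = 41)
  D2 <- bray_curtis(tab2)
  L1 <- as.matrix(dist(tab2, method = "manhattan"))
  expect_equal(D2, L1 / 2, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("all three metrics give symmetric [0,1] matrices with zero diagonal", {
  set.seed(51)
  tr <- ape::rcoal(20)
  tab <- random_table(8, 20, seed = 52)
  colnames(tab) <- tr$tip.label
  tab[tab < 0.03] <- 0
  tab <- tab / rowSums(tab)
  prof <- branch_profile(tab, tr)
  for (D in list(weighted_unifrac(prof), unweighted_unifrac(prof),
                 bray_curtis(tab))) {
    expect_equal(D, t(D))
    expect_equal(diag(D), rep(0, 8), ignore_attr = TRUE)
    expect_true(all(D >= 0 & D <= 1 + 1e-12))
    expect_true(all(is.finite(D)))
  }
})
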