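GRASS_TREE <- paste0(
  "(((maize,sorghum),rice),(Brachypodium,(barley,wheat)[&age=10-15])",
  "[&age=32-39])[&age=45-60];")

test_that("presence matrix counts planted loci per species", {
  set.seed(71)
  m1 <- random_rna(21); m2 <- random_rna(22)
  gA <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
              collapse = "")
  gB <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
              collapse = "")
  for (at in c(200, 900, 1600)) substr(gA, at, at + 20) <- as_dna(m1)
  mirnas <- seq_set(c("m1", "m2"), c(m1, m2), "rna")
  genomes <- list(A = seq_set("A_c1", gA, "dna"),
                  B = seq_set("B_c1", gB, "dna"))
  pm <- build_presence_matrix(mirnas, genomes)
  expect_equal(pm["m1", ], c(A = 3L, B = 0L))
  expect_equal(pm["m2", ], c(A = 0L, B = 0L))
})

test_that("single-clade presence puts the origin at the clade MRCA", {
  tr <- annotated_tree_from_string(GRASS_TREE)
  pres <- c(maize = 0, sorghum = 0, rice = 0, Brachypodium = 1,
            barley = 1, wheat = 1)
  bd <- dollo_reconstruct(pres, tr)
  expect_equal(bd$origin,
               ape::getMRCA(tr$phylo, c("Brachypodium", "barley", "wheat")))
  expect_equal(bd$n_losses, 0)
  expect_equal(unname(bd$origin_age), c(32, 39))
})

test_that("presence everywhere is a single root birth; one leaf is a tip", {
  tr <- annotated_tree_from_string(GRASS_TREE)
  all_pres <- setNames(rep(1, 6), tr$phylo$tip.label)
  bd <- dollo_reconstruct(all_pres, tr)
  expect_equal(bd$origin, ape::Ntip(tr$phylo) + 1)   # root
  expect_equal(bd$n_losses, 0)
  one <- setNames(c(1, rep(0, 5)), tr$phylo$tip.label)
  bd1 <- dollo_reconstruct(one, tr)
  expect_equal(bd1$origin, 1L)
  expect_equal(bd1$n_losses, 0)
  expect_error(dollo_reconstruct(setNames(rep(0, 6), tr$phylo$tip.label),
                                 tr), "all-absent")
})

test_that("losses are the maximal absent subtrees under the origin", {
  tr <- annotated_tree_from_string(GRASS_TREE)
  pres <- c(maize = 1, sorghum = 1, rice = 1, Brachypodium = 1,
            barley = 0, wheat = 0)
  bd <- dollo_reconstruct(pres, tr)
  expect_equal(bd$n_losses, 1)
  expect_setequal(bd$loss_clades[[1]], c("barley", "wheat"))
})

test_that("dollo matches brute-force minimal single-gain placement", {
  set.seed(72)
  for (rep in 1:40) {
    nt <- sample(6:8, 1)
    phy <- ape::rtree(nt)
    pres <- setNames(sample(c(TRUE, FALSE), nt, replace = TRUE),
                     phy$tip.label)
    if (!any(pres)) pres[sample(nt, 1)] <- TRUE
    bd <- dollo_reconstruct(pres, phy)
    oracle <- oracle_dollo(phy, pres)
    expect_equal(bd$n_losses, oracle$losses)
    expect_equal(bd$origin, oracle$gain)
  }
})

test_that("poisson distance follows its closed form", {
  expect_equal(poisson_distance(0.1), -log(0.9), tolerance = 1e-12)
  expect_equal(poisson_distance(0), 0)
  expect_error(poisson_distance(1), "lie in")
  p <- seq(0.01, 0.95, by = 0.01)
  expect_true(all(poisson_distance(p) >= p))   # correction only stretches
})

test_that("pairwise deletion drops gapped columns", {
  aln <- c(a = "ARND-QEG", b = "ARNDCQEG", c = "ARKD-QEG")
  out <- poisson_nj(aln)
  expect_equal(out$distances["a", "b"], 0)       # gap column excluded
  expect_equal(out$distances["a", "c"], -log(1 - 1 / 7))
  expect_error(poisson_nj(c(a = "AAAA", b = "CCCC", c = "AAAA")), ">= 1")
})

test_that("three-taxon NJ solves the closed-form branch lengths", {
  D <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- nj_tree(D)
  bl <- setNames(tree$edge.length[match(1:3, tree$edge[, 2])],
                 tree$tip.label)
  expect_equal(bl[["A"]], 1)
  expect_equal(bl[["B"]], 1)
  expect_equal(bl[["C"]], 2)
})

test_that("NJ exactly recovers additive trees", {
  set.seed(73)
  for (rep in 1:10) {
    true <- ape::rtree(6)
    true$edge.length <- runif(nrow(true$edge), 0.2, 1.5)
    D <- ape::cophenetic.phylo(true)
    got <- nj_tree(D)
    expect_equal(ape::dist.topo(ape::unroot(true), got)[1], 0)
    Dh <- ape::cophenetic.phylo(got)[rownames(D), colnames(D)]
    expect_lt(max(abs(Dh - D)), 1e-9)
  }
})

test_that("NJ on ultrametric matrices returns non-negative branches", {
  set.seed(74)
  for (rep in 1:5) {
    true <- ape::rcoal(7)
    got <- nj_tree(ape::cophenetic.phylo(true))
    expect_true(all(got$edge.length >= 0))
  }
})

test_that("identical sequences give zero distance", {
  aln <- c(x = "MKVLLA", y = "MKVLLA", z = "MKVLIA")
  out <- poisson_nj(aln)
  expect_equal(out$distances["x", "y"], 0)
})

test_that("network overlaps equal brute-force set intersections", {
  sites <- data.frame(
    mirna_id = c("X", "X", "Y", "Y", "Z"),
    transcript_id = c("a", "b", "b", "c", "q"), stringsAsFactors = FALSE)
  net <- network_and_overlaps(sites)
  expect_equal(net$overlaps$shared[net$overlaps$members == "X+Y"], 1)
  expect_equal(net$overlaps$shared[net$overlaps$members == "X+Z"], 0)
  expect_equal(net$overlaps$shared[net$overlaps$members == "X+Y+Z"], 0)

  set.seed(75)
  ids <- paste0("m", 1:5)
  sets <- lapply(ids, function(i) sample(letters, sample(3:10, 1)))
  names(sets) <- ids
  df <- do.call(rbind, lapply(ids, function(i)
    data.frame(mirna_id = i, transcript_id = sets[[i]],
               stringsAsFactors = FALSE)))
  net <- network_and_overlaps(df)
  for (r in seq_len(nrow(net$overlaps))) {
    members <- strsplit(net$overlaps$members[r], "+", fixed = TRUE)[[1]]
    expect_equal(net$overlaps$shared[r],
                 length(Reduce(intersect, sets[members])))
  }
})
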