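test_that("species tree simulation is Yule-shaped and reproducible", {
  st <- simulate_species_tree(4, seed = 1)
  expect_true(ape::is.rooted(st) && ape::is.binary(st))
  # n = 4: 3 internal nodes, 2 internal edges
  expect_equal(st$Nnode, 3L)
  expect_equal(sum(st$edge[, 2] > 4), 2L)
  expect_identical(ape::write.tree(simulate_species_tree(9, seed = 3)),
                   ape::write.tree(simulate_species_tree(9, seed = 3)))
  big <- simulate_species_tree(101, seed = 2)
  expect_equal(big$Nnode, 100L)
  expect_error(simulate_species_tree(3), "at least 4")
})

test_that("degenerate rates reproduce the species tree exactly", {
  st <- simulate_species_tree(10, seed = 11)
  f <- simulate_gene_family(st, dup_rate = 0, loss_rate = 0, seed = 12)
  expect_equal(sort(unname(f$species)), sort(st$tip.label))
  expect_true(all(node_tags(f) == "speciation"))
  r <- relabel_to_species(disco_decompose(f)$trees[[1]])
  expect_equal(rf_distance(r$tree, st)$rf, 0)
})

test_that("loss-only families equal the species tree restricted to survivors", {
  st <- simulate_species_tree(16, seed = 21)
  set.seed(22)
  for (i in 1:10) {
    f <- simulate_gene_family(st, dup_rate = 0, loss_rate = 0.25)
    sp <- unname(f$species)
    expect_false(any(duplicated(sp)))      # single copy
    expect_true(all(node_tags(f) == "speciation"))
    restricted <- ape::keep.tip(st, sp)
    r <- relabel_to_species(f)
    expect_equal(rf_distance(r$tree, restricted)$rf, 0)
  }
})

test_that("duplication-only families keep every species", {
  st <- simulate_species_tree(8, seed = 31)
  set.seed(32)
  for (i in 1:10) {
    f <- simulate_gene_family(st, dup_rate = 0.4, loss_rate = 0)
    expect_setequal(unique(unname(f$species)), st$tip.label)
    expect_gte(length(f$tree$tip.label), 8)
  }
})

test_that("simulation records are reproducible and orthology-consistent", {
  st <- simulate_species_tree(8, seed = 41)
  r1 <- simulate_families(st, 5, dup_rate = 0.3, loss_rate = 0.15, seed = 42)
  r2 <- simulate_families(st, 5, dup_rate = 0.3, loss_rate = 0.15, seed = 42)
  expect_identical(lapply(r1$families, function(f) ape::write.tree(f$tree)),
                   lapply(r2$families, function(f) ape::write.tree(f$tree)))
  # under dup_rate = 0 every pair is a true ortholog
  r0 <- simulate_families(st, 3, dup_rate = 0, loss_rate = 0.2, seed = 43)
  for (i in seq_along(r0$families)) {
    n <- length(r0$families[[i]]$tree$tip.label)
    expect_equal(length(r0$truth[[i]]$calls), choose(n, 2))
  }
  # truth = pairs whose MRCA event is a speciation
  f <- r1$families[[1]]
  expect_identical(r1$truth[[1]]$calls,
                   predicted_orthology_tagged(f)$calls)
})

test_that("NNI perturbation moves trees by the expected RF steps", {
  set.seed(51)
  phy <- ape::rtree(12, tip.label = sprintf("s%02d_1", 1:12))
  x <- gene_family_tree(phy)
  p0 <- perturb_nni(x, 0)
  expect_equal(attr(p0, "nrf"), 0)
  expect_equal(ape::write.tree(p0$tree), ape::write.tree(phy))
  for (i in 1:10) {
    p1 <- perturb_nni(x, 1, seed = i)
    expect_equal(rf_distance(phy, p1$tree)$rf, 2)
  }
  # mean displacement grows with the move count
  mean_nrf <- function(k) mean(vapply(1:25, function(s)
    attr(perturb_nni(x, k, seed = s), "nrf"), numeric(1)))
  expect_lt(mean_nrf(1), mean_nrf(8))
  # calibration finds a move count reaching a target level
  trees <- replicate(5, {
    t <- ape::rtree(16, tip.label = sprintf("s%02d_1", 1:16))
    gene_family_tree(t)
  }, simplify = FALSE)
  k <- calibrate_nni(trees, target_nrf = 0.2, seed = 5)
  expect_gte(attr(k, "achieved_nrf"), 0.2)
})

test_that("clade-based deletion restricts affected families to one clade", {
  st <- simulate_species_tree(12, seed = 61)
  rec <- simulate_families(st, 20, dup_rate = 0.25, loss_rate = 0.1,
                           seed = 62)
  # affected_fraction = 0 is the identity
  id <- clade_based_missing(rec$families, st, affected_fraction = 0,
                            seed = 63)
  expect_equal(length(id$families), 20)
  expect_identical(lapply(id$families, function(f) f$tree$tip.label),
                   lapply(rec$families, function(f) f$tree$tip.label))
  # min_clade_fraction near 1: only the root clade qualifies, families
  # keep their species
  root_only <- clade_based_missing(rec$families, st, affected_fraction = 1,
                                   min_clade_fraction = 0.99, seed = 64)
  expect_identical(lapply(root_only$families, function(f) f$tree$tip.label),
                   lapply(rec$families, function(f) f$tree$tip.label))
  expect_true(all(root_only$removed_fraction == 0))
  # affected families retain only species of one species-tree clade
  cm <- clade_based_missing(rec$families, st, affected_fraction = 1,
                            min_clade_fraction = 0.2, seed = 65)
  clades <- lapply(seq_len(12 + st$Nnode), function(v)
    tryCatch(ape::extract.clade(st, v)$tip.label,
             error = function(e) st$tip.label[v]))
  for (f in cm$families) {
    sp <- unique(unname(f$species))
    expect_true(any(vapply(clades, function(cl) all(sp %in% cl),
                           logical(1))))
  }
})
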