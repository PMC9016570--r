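test_that("RF distances match enumeration-derived values", {
  t1 <- ape::read.tree(text = "((a,b),(c,(d,e)));")
  expect_equal(rf_distance(t1, t1), list(rf = 0L, nrf = 0))

  # n = 5 with disjoint nontrivial bipartition sets: maximal distance
  t2 <- ape::read.tree(text = "((a,c),(e,(b,d)));")
  expect_equal(bipartition_set(t1), c("a,b", "a,b,c"))    # {ab|cde},{de|abc}
  expect_equal(bipartition_set(t2), c("a,c", "a,c,e"))    # {ac|bde},{bd|ace}
  expect_equal(rf_distance(t1, t2), list(rf = 4L, nrf = 1))

  # one NNI move on n = 6 (swap c with (e,f)) changes one bipartition
  s1 <- ape::read.tree(text = "(a,(b,(c,(d,(e,f)))));")
  s2 <- ape::read.tree(text = "(a,(b,(d,(c,(e,f)))));")
  expect_equal(rf_distance(s1, s2), list(rf = 2L, nrf = 2 / 6))

  # symmetry and triangle-like bound
  set.seed(5)
  trees <- replicate(3, ape::rtree(12, tip.label = paste0("t", 1:12)),
                     simplify = FALSE)
  ab <- rf_distance(trees[[1]], trees[[2]])$rf
  ba <- rf_distance(trees[[2]], trees[[1]])$rf
  ac <- rf_distance(trees[[1]], trees[[3]])$rf
  bc <- rf_distance(trees[[2]], trees[[3]])$rf
  expect_equal(ab, ba)
  expect_lte(ac, ab + bc)

  # mismatched leafsets are reported with the differing labels
  t3 <- ape::read.tree(text = "((a,b),(c,(d,x)));")
  expect_error(rf_distance(t1, t3), "e.*x|x.*e")
})

test_that("decomposition orthology calls pairs within output trees only", {
  x <- read_gene_trees(text = "(((a_1,b_1),c_1),((a_2,b_2),c_2));")[[1]]
  tg <- tag_rooted(x)
  d <- disco_decompose(tg)
  pd <- predicted_orthology_decomposition(d)
  expect_equal(length(pd$calls), 6)       # two triplets, 3 pairs each
  expect_equal(pd$universe, choose(6, 2))

  # singleton trees produce no calls
  pair <- read_gene_trees(text = "(a_1,a_2);")[[1]]
  dp <- disco_decompose(tag_rooted(pair))
  expect_length(predicted_orthology_decomposition(dp)$calls, 0)

  # one tree with all copies of distinct species: all pairs called
  sc <- read_gene_trees(text = "((a_1,b_1),(c_1,d_1));")[[1]]
  ds <- disco_decompose(tag_rooted(sc))
  expect_equal(length(predicted_orthology_decomposition(ds)$calls),
               choose(4, 2))
})

test_that("tagged-tree orthology follows speciation LCAs and contains
           decomposition calls", {
  sc <- read_gene_trees(text = "((a_1,b_1),(c_1,d_1));")[[1]]
  expect_equal(length(predicted_orthology_tagged(tag_rooted(sc))$calls),
               choose(4, 2))
  pair <- read_gene_trees(text = "(a_1,a_2);")[[1]]
  expect_length(predicted_orthology_tagged(tag_rooted(pair))$calls, 0)

  set.seed(21)
  for (i in 1:20) {
    x <- rand_mul_tree(sample(5:30, 1), 5)
    tg <- tag_rooted(x)
    pt <- predicted_orthology_tagged(tg)
    pd <- predicted_orthology_decomposition(disco_decompose(tg))
    expect_true(all(pd$calls %in% pt$calls))
  }
})

test_that("precision and recall handle agreement and empty calls", {
  labs <- c("a_1", "a_2", "b_1", "c_1")
  truth <- pair_calls(rbind(c("a_1", "b_1"), c("a_1", "c_1"),
                            c("b_1", "c_1")), labs)
  expect_equal(unname(c(precision_recall(truth, truth))), c(1, 1))

  empty <- pair_calls(matrix(character(0), 0, 2), labs)
  pr <- precision_recall(empty, truth)
  expect_equal(unname(c(pr)), c(1, 0))  # zero-denominator convention

  pred <- pair_calls(rbind(c("a_1", "b_1"), c("a_2", "b_1")), labs)
  pr2 <- precision_recall(pred, truth)
  expect_equal(unname(c(pr2)), c(1 / 2, 1 / 3))
  cnt <- attr(pr2, "counts")
  expect_equal(sum(cnt), choose(4, 2))

  other <- pair_calls(matrix(character(0), 0, 2), c("x_1", "y_1"))
  expect_error(precision_recall(pred, other), "universe")
})

test_that("batch accuracy reports pooled and macro aggregations", {
  labs1 <- c("a_1", "b_1"); labs2 <- c("c_1", "c_2", "d_1")
  p1 <- pair_calls(rbind(c("a_1", "b_1")), labs1)
  t1 <- p1
  p2 <- pair_calls(matrix(character(0), 0, 2), labs2)
  t2 <- pair_calls(rbind(c("c_1", "d_1"), c("c_2", "d_1")), labs2)
  acc <- orthology_accuracy(list(p1, p2), list(t1, t2))
  expect_equal(acc$precision_pooled, 1)
  expect_equal(acc$recall_pooled, 1 / 3)
  expect_equal(acc$precision_macro, 1)
  expect_equal(acc$recall_macro, 1 / 2)
})

test_that("per-family summary tables carry the published statistics' columns", {
  st <- simulate_species_tree(10, seed = 8)
  rec <- simulate_families(st, 8, dup_rate = 0.3, loss_rate = 0.15, seed = 9)
  tab <- decomposition_summary(rec$families, method = "DISCO",
                               min_species = 4)
  expect_true(all(c("family_id", "n_leaves", "n_species", "n_duplications",
                    "n_output_trees", "max_size", "mean_size", "coverage")
                  %in% names(tab)))
  expect_true(all(tab$coverage >= 0 & tab$coverage <= 1))
  tab_mi <- decomposition_summary(rec$families, method = "MI")
  expect_equal(nrow(tab), nrow(tab_mi))
})
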