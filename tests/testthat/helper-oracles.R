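# Test fixtures are generated in code, and independent oracles recompute
# expected values by direct recursion/enumeration, separate from the
# package's own code paths.

# random multicopy gene family tree: random binary topology, leaves drawn
# from n_species species with replacement, labels "sp<k>_<copy>"
rand_mul_tree <- function(n_leaves, n_species, family_id = "fam1") {
  phy <- ape::rtree(n_leaves)
  sp <- sample.int(n_species, n_leaves, replace = TRUE)
  copy <- stats::ave(sp, sp, FUN = seq_along)
  phy$tip.label <- sprintf("sp%02d_%d", sp, copy)
  gene_family_tree(phy, family_id = family_id)
}

# independent duplication/loss scorer: for every edge of the unrooted
# tree, recompute the rooted score by direct recursion on an adjacency
# list (no rerooting, no package tagging engine)
oracle_edge_scores <- function(x) {
  phy <- x$tree
  if (ape::is.rooted(phy)) phy <- ape::unroot(phy)
  species <- x$species
  n <- length(phy$tip.label)
  n_all <- n + phy$Nnode
  adj <- vector("list", n_all)
  for (k in seq_len(nrow(phy$edge))) {
    a <- phy$edge[k, 1L]; b <- phy$edge[k, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  sub <- function(v, parent) {
    nb <- setdiff(adj[[v]], parent)
    if (length(nb) == 0L)
      return(list(set = species[[phy$tip.label[v]]], d = 0L, l = 0L))
    a <- sub(nb[1L], v); b <- sub(nb[2L], v)
    U <- union(a$set, b$set)
    dup <- length(intersect(a$set, b$set)) > 0L
    loss <- if (dup) (length(a$set) < length(U)) + (length(b$set) < length(U))
            else 0L
    list(set = U, d = a$d + b$d + dup, l = a$l + b$l + loss)
  }
  vapply(seq_len(nrow(phy$edge)), function(k) {
    u <- phy$edge[k, 1L]; v <- phy$edge[k, 2L]
    a <- sub(v, u); b <- sub(u, v)
    U <- union(a$set, b$set)
    dup <- length(intersect(a$set, b$set)) > 0L
    loss <- if (dup) (length(a$set) < length(U)) + (length(b$set) < length(U))
            else 0L
    as.integer(a$d + b$d + dup + a$l + b$l + loss)
  }, integer(1))
}

# unordered nontrivial bipartition set of an unrooted tree, as canonical
# strings (for round-trip identity checks)
bipartition_set <- function(phy) {
  if (ape::is.rooted(phy) && length(phy$tip.label) > 2L)
    phy <- ape::unroot(phy)
  labs <- sort(phy$tip.label)
  pp <- ape::prop.part(phy)
  keys <- vapply(pp, function(idx) {
    side <- sort(attr(pp, "labels")[idx])
    other <- setdiff(labs, side)
    if (length(side) < 2L || length(other) < 2L) return(NA_character_)
    min(paste(side, collapse = ","), paste(other, collapse = ","))
  }, character(1))
  sort(unique(keys[!is.na(keys)]))
}

# caption-consistent worked example: 11 species a..k, two duplication
# vertices; the lower one has two 4-species children (tie), the upper one
# 6 vs 7 species after the first split
fig_example_tree <- function() {
  txt <- paste0("((((a_1,(b_1,(c_1,d_1))),(a_2,(b_2,(c_2,e_1)))),",
                "(f_1,g_1)),(d_2,(e_2,(f_2,(h_1,(i_1,(j_1,k_1)))))));")
  read_gene_trees(text = txt)[[1]]
}

n_distinct_species <- function(t) length(unique(t$species))
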