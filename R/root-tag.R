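# Rooting and tagging: score every possible root edge by the number of
# duplication (+ inferred loss) events it implies, root on the minimum-score
# edge, and tag each internal vertex as a duplication iff the species sets
# of its two children intersect (equivalently, iff it is the LCA of two
# copies of the same species).

# Tag a rooted binary phylo given a label->species map.
# Loss convention (no reference species tree is available): at each
# duplication vertex with child species sets A and B, one loss is charged
# for each child missing a species present under the vertex, i.e.
# [A != A union B] + [B != A union B]. Speciation vertices charge nothing.
.tag_engine <- function(phy, species) {
  n <- length(phy$tip.label)
  if (!.is_binary_rooted(phy))
    stop("tree must be rooted and binary; resolve polytomies first ",
         "(resolve_polytomies) and/or root it (best_root)")
  ch <- .children(phy)
  sets <- vector("list", n + phy$Nnode)
  for (i in seq_len(n)) sets[[i]] <- species[[phy$tip.label[i]]]
  tags <- character(phy$Nnode)
  dups <- 0L; losses <- 0L
  for (v in .postorder_nodes(phy)) {
    kids <- ch[[v]]
    A <- sets[[kids[1L]]]; B <- sets[[kids[2L]]]
    U <- unique(c(A, B))
    sets[[v]] <- U
    if (length(A) + length(B) > length(U)) {   # sets intersect
      tags[v - n] <- "duplication"
      dups <- dups + 1L
      losses <- losses + (length(A) < length(U)) + (length(B) < length(U))
    } else {
      tags[v - n] <- "speciation"
    }
  }
  list(tags = tags, duplications = dups, losses = losses)
}

.new_tagged_tree <- function(x, phy, eng, root_edge = NULL) {
  structure(
    list(tree = phy, species = x$species, labels = x$labels,
         family_id = x$family_id, tags = eng$tags,
         score = c(duplications = eng$duplications, losses = eng$losses),
         root_edge = root_edge),
    class = c("tagged_tree", "gene_family_tree"))
}

#' Tag the internal vertices of a rooted gene family tree
#'
#' Labels every internal vertex as `"duplication"` when the species sets of
#' its two child subtrees intersect (the vertex is then the least common
#' ancestor of two copies of some species) and as `"speciation"` otherwise.
#' Retagging a tagged tree is a no-op.
#'
#' @param x a rooted, binary [gene_family_tree] (or `tagged_tree`).
#' @return an object of class `tagged_tree`: the input plus `tags`
#'   (character vector over internal nodes, index `node - Ntip`) and
#'   `score = c(duplications, losses)`. Losses are counted as one per
#'   duplication child missing a species present under the duplication
#'   vertex.
#' @export
tag_rooted <- function(x) {
  stopifnot(inherits(x, "gene_family_tree"))
  eng <- .tag_engine(x$tree, x$species)
  .new_tagged_tree(x, x$tree, eng,
                   root_edge = if (inherits(x, "tagged_tree")) x$root_edge)
}

#' Duplication and loss score of a rooting
#'
#' @param x a rooted, binary [gene_family_tree].
#' @return integer vector `c(duplications, losses)`; the rooting score is
#'   their sum.
#' @export
score_rooting <- function(x) {
  stopifnot(inherits(x, "gene_family_tree"))
  eng <- .tag_engine(x$tree, x$species)
  c(duplications = eng$duplications, losses = eng$losses)
}

# deterministic enumeration of candidate root edges: order by the
# lexicographically smaller of the two sorted leaf-label strings of the
# split an edge induces
.edge_order <- function(phy, below) {
  n <- length(phy$tip.label)
  keys <- character(nrow(phy$edge))
  labs <- phy$tip.label
  for (k in seq_len(nrow(phy$edge))) {
    side <- labs[below[[phy$edge[k, 2L]]]]
    other <- setdiff(labs, side)
    keys[k] <- min(.label_key(side), .label_key(other))
  }
  order(keys)
}

#' Root a gene family tree by duplication/loss parsimony
#'
#' Every edge of the unrooted tree is tried as a root position; each
#' candidate rooting is tagged and scored (duplications + losses), and the
#' tree is rooted on a minimum-score edge. Ties are broken by a canonical
#' deterministic edge order derived from sorted leaf labels, so results are
#' reproducible across platforms. The root is inserted as a degree-2 vertex
#' subdividing the chosen edge.
#'
#' @param x an unrooted, binary [gene_family_tree] with at least 3 leaves.
#'   A rooted input is unrooted first.
#' @return a `tagged_tree` rooted on the minimum-score edge; `root_edge`
#'   holds the leaf labels on the smaller side of the chosen edge.
#' @export
best_root <- function(x) {
  stopifnot(inherits(x, "gene_family_tree"))
  phy <- x$tree
  if (length(phy$tip.label) < 3L)
    stop("best_root requires at least 3 leaves")
  if (ape::is.rooted(phy)) phy <- ape::unroot(phy)
  if (!ape::is.binary(phy))
    stop("tree must be binary; resolve polytomies first")
  had_lengths <- !is.null(phy$edge.length)
  if (!had_lengths) phy$edge.length <- rep(1, nrow(phy$edge))
  below <- .tips_below(phy)
  ord <- .edge_order(phy, below)
  best <- NULL; best_score <- Inf; best_side <- NULL
  for (k in ord) {
    v <- phy$edge[k, 2L]
    len <- phy$edge.length[k]
    rooted <- phytools::reroot(phy, v, position = len / 2)
    eng <- .tag_engine(rooted, x$species)
    total <- eng$duplications + eng$losses
    if (total < best_score) {
      best_score <- total
      best <- list(phy = rooted, eng = eng)
      side <- phy$tip.label[below[[v]]]
      other <- setdiff(phy$tip.label, side)
      best_side <- if (length(side) <= length(other)) side else other
    }
  }
  if (!had_lengths) best$phy$edge.length <- NULL
  .new_tagged_tree(x, best$phy, best$eng, root_edge = sort(best_side))
}

#' Tags of the internal vertices
#' @param x a `tagged_tree`.
#' @return character vector of `"speciation"`/`"duplication"`, one per
#'   internal node (index `node - Ntip`).
#' @export
node_tags <- function(x) {
  stopifnot(inherits(x, "tagged_tree"))
  x$tags
}

#' @export
print.tagged_tree <- function(x, ...) {
  n <- length(x$tree$tip.label)
  cat("Tagged gene family tree '", x$family_id, "': ", n, " gene copies, ",
      length(unique(x$species)), " species; ",
      x$score[["duplications"]], " duplication vertices, ",
      x$score[["losses"]], " inferred losses\n", sep = "")
  invisible(x)
}
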