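# DISCO decomposition: walk the tagged tree bottom-up; at every vertex that
# was tagged as a duplication, detach the child subtree currently holding
# fewer distinct species, then continue. Detached subtrees plus the residual
# tree form a leaf-disjoint, single-copy cover of the input leafset.

.new_single_copy_tree <- function(x, tip_idx, provenance, index) {
  labs <- x$tree$tip.label[tip_idx]
  phy <- .induced_tree(x$tree, labs)
  structure(
    list(tree = phy,
         species = x$species[phy$tip.label],
         labels = x$labels[phy$tip.label],
         family_id = x$family_id,
         provenance = provenance,
         index = index),
    class = c("single_copy_tree", "gene_family_tree"))
}

#' Decompose a tagged gene family tree into single-copy trees
#'
#' Visits the internal vertices in postorder (children before parents). At
#' each vertex whose original tag is `"duplication"`, the current number of
#' distinct species in each child subtree is computed (reflecting earlier
#' detachments below); the child with fewer species is detached, the
#' resulting degree-2 vertex suppressed, and the detached subtree appended
#' to the output. Ties on species count are broken toward fewer leaves,
#' then toward the canonical right child (the child whose sorted leaf-label
#' multiset is lexicographically larger). The residual tree is appended
#' last. Tags are computed once on the input and never recomputed after
#' splits; species counts are.
#'
#' For a binary input the output always contains exactly
#' `n_duplications + 1` trees, their leafsets are pairwise disjoint, their
#' union is the input leafset (coverage 1), and every output tree contains
#' at most one leaf per species.
#'
#' @param x a `tagged_tree` (see [best_root()] / [tag_rooted()]).
#' @return an object of class `disco_decomposition`: list with `trees`
#'   (list of `single_copy_tree`), `n_duplications`, `coverage`,
#'   `max_size` and `mean_size` (distinct-species counts over output
#'   trees), `n_leaves` (input leaf count), `method`, `family_id`, and
#'   `original_labels` (the uniquified input leafset).
#' @export
disco_decompose <- function(x) {
  if (!inherits(x, "tagged_tree"))
    stop("input must be a tagged_tree; run best_root() or tag_rooted() first")
  phy <- x$tree
  n <- length(phy$tip.label)
  tags <- x$tags
  if (length(tags) != phy$Nnode || any(!nzchar(tags)))
    stop("tree has untagged internal vertices")
  ch <- .children(phy)
  below <- .tips_below(phy)
  detached <- logical(n)
  outs <- list()
  for (v in .postorder_nodes(phy)) {
    if (tags[v - n] != "duplication") next
    kids <- ch[[v]]
    cur <- lapply(kids, function(k) {
      tips <- below[[k]]
      tips[!detached[tips]]
    })
    nsp <- vapply(cur, function(t) length(unique(x$species[phy$tip.label[t]])),
                  integer(1))
    nlv <- lengths(cur)
    # decide which child to detach: fewer species, then fewer leaves,
    # then the canonical right child
    pick <- if (nsp[1L] != nsp[2L]) which.min(nsp)
            else if (nlv[1L] != nlv[2L]) which.min(nlv)
            else {
              k1 <- .label_key(phy$tip.label[cur[[1L]]])
              k2 <- .label_key(phy$tip.label[cur[[2L]]])
              if (k1 <= k2) 2L else 1L   # detach the canonical right child
            }
    tips <- cur[[pick]]
    outs[[length(outs) + 1L]] <-
      .new_single_copy_tree(x, tips, provenance = paste0("node", v),
                            index = length(outs) + 1L)
    detached[tips] <- TRUE
  }
  outs[[length(outs) + 1L]] <-
    .new_single_copy_tree(x, which(!detached), provenance = "residual",
                          index = length(outs) + 1L)
  .new_decomposition(outs, n_duplications = sum(tags == "duplication"),
                     n_leaves = n, family_id = x$family_id,
                     original_labels = phy$tip.label, method = "DISCO")
}

.new_decomposition <- function(trees, n_duplications, n_leaves, family_id,
                               original_labels, method,
                               discarded_labels = character(0)) {
  sizes <- vapply(trees, function(t) length(unique(t$species)), integer(1))
  retained <- sum(vapply(trees, function(t) length(t$tree$tip.label),
                         integer(1)))
  structure(
    list(trees = trees,
         n_duplications = n_duplications,
         coverage = retained / n_leaves,
         max_size = if (length(sizes)) max(sizes) else 0L,
         mean_size = if (length(sizes)) mean(sizes) else NaN,
         n_leaves = n_leaves,
         family_id = family_id,
         original_labels = original_labels,
         discarded_labels = discarded_labels,
         method = method),
    class = "disco_decomposition")
}

#' Filter a decomposition by species count
#'
#' Keeps output trees with at least `min_species` distinct species.
#' Coverage is recomputed against the original family leafset, so filtering
#' lowers coverage. With summary methods the convention is
#' `min_species = 4` (trees with 3 or fewer leaves are discarded); in
#' concatenation mode nothing is filtered (`min_species = 1`).
#'
#' @param d a `disco_decomposition`.
#' @param min_species minimum number of distinct species (>= 1).
#' @return a filtered `disco_decomposition` (possibly with zero trees).
#' @export
filter_by_size <- function(d, min_species = 4L) {
  stopifnot(inherits(d, "disco_decomposition"), min_species >= 1L)
  keep <- vapply(d$trees, function(t) length(unique(t$species)) >= min_species,
                 logical(1))
  dropped <- unlist(lapply(d$trees[!keep],
                           function(t) t$tree$tip.label), use.names = FALSE)
  .new_decomposition(d$trees[keep], n_duplications = d$n_duplications,
                     n_leaves = d$n_leaves, family_id = d$family_id,
                     original_labels = d$original_labels, method = d$method,
                     discarded_labels = c(d$discarded_labels, dropped))
}

#' Relabel a single-copy tree to species labels
#'
#' Replaces each gene-copy leaf label by its species identifier, producing
#' a tree directly comparable to (a restriction of) a species tree. Only
#' valid on single-copy trees, where the result has unique labels.
#'
#' @param t a `single_copy_tree` (or any single-copy [gene_family_tree]).
#' @return a `gene_family_tree` whose leaf labels are species identifiers.
#' @export
relabel_to_species <- function(t) {
  stopifnot(inherits(t, "gene_family_tree"))
  sp <- t$species[t$tree$tip.label]
  if (anyDuplicated(sp))
    stop("tree is not single-copy: species ",
         paste(unique(sp[duplicated(sp)]), collapse = ", "),
         " appear more than once")
  t$tree$tip.label <- unname(sp)
  t$species <- setNames(unname(sp), unname(sp))
  t$labels <- setNames(unname(sp), unname(sp))
  t
}

#' @export
print.disco_decomposition <- function(x, ...) {
  cat(x$method, " decomposition of '", x$family_id, "': ",
      length(x$trees), " single-copy trees from ", x$n_leaves,
      " leaves (", x$n_duplications, " duplications)\n",
      "coverage ", round(x$coverage, 3),
      ", max size ", x$max_size,
      ", mean size ", round(x$mean_size, 2), " species\n", sep = "")
  invisible(x)
}

#' @export
summary.disco_decomposition <- function(object, ...) {
  sizes <- vapply(object$trees, function(t) length(unique(t$species)),
                  integer(1))
  out <- list(method = object$method, family_id = object$family_id,
              n_trees = length(object$trees), sizes = sizes,
              n_duplications = object$n_duplications,
              coverage = object$coverage)
  class(out) <- "summary.disco_decomposition"
  out
}

#' @export
print.summary.disco_decomposition <- function(x, ...) {
  cat(x$method, " decomposition of '", x$family_id, "'\n", sep = "")
  cat("  trees:        ", x$n_trees, "\n")
  cat("  duplications: ", x$n_duplications, "\n")
  cat("  coverage:     ", round(x$coverage, 4), "\n")
  cat("  sizes:        ", paste(x$sizes, collapse = " "), "\n")
  invisible(x)
}
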