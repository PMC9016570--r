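# MI baseline: iteratively cut out a maximally inclusive subtree — a
# subtree (one side of some edge, or the whole remaining tree) containing
# no two copies of the same species — of maximum species count, until no
# candidate with at least `min_species` species remains. Remaining
# fragments are discarded but still count against coverage.

# candidate leafsets of the current tree: both sides of every edge, plus
# the whole leafset
.mi_candidates <- function(phy) {
  labs <- phy$tip.label
  if (length(labs) == 1L) return(list(labs))
  if (length(labs) == 2L)
    return(list(labs, labs[1L], labs[2L]))
  below <- .tips_below(phy)
  sides <- lapply(seq_len(nrow(phy$edge)), function(k)
    labs[below[[phy$edge[k, 2L]]]])
  cands <- c(sides, lapply(sides, function(s) setdiff(labs, s)), list(labs))
  cands[lengths(cands) > 0L]
}

#' MI decomposition of a gene family tree
#'
#' The maximum-inclusive-subtree strategy: repeatedly find, over all ways
#' of cutting one edge of the current unrooted tree (and the whole tree
#' itself), a duplicate-species-free subtree with the largest number of
#' species, extract it, and continue on the remainder. Extraction stops
#' when no duplicate-free subtree with at least `min_species` species is
#' left; the final remainder is discarded but still counts against
#' coverage. No rooting or tagging is involved.
#'
#' Ties on species count are broken toward more leaves, then by a
#' canonical order on sorted leaf labels.
#'
#' @param x a [gene_family_tree] with at least 3 leaves (rooted inputs are
#'   treated as unrooted).
#' @param min_species minimum distinct-species count of an extracted tree.
#' @return a `disco_decomposition` with `method = "MI"`; coverage is
#'   extracted leaves over original leaves.
#' @export
mi_decompose <- function(x, min_species = 4L) {
  stopifnot(inherits(x, "gene_family_tree"), min_species >= 1L)
  phy0 <- x$tree
  n <- length(phy0$tip.label)
  if (n < 3L) stop("mi_decompose requires at least 3 leaves")
  remaining <- phy0$tip.label
  outs <- list()
  repeat {
    if (length(remaining) == 0L) break
    cur <- .induced_tree(phy0, remaining)
    cands <- .mi_candidates(cur)
    ok <- vapply(cands, function(s) {
      sp <- x$species[s]
      !anyDuplicated(sp) && length(sp) >= min_species
    }, logical(1))
    cands <- cands[ok]
    if (length(cands) == 0L) break                 # remainder discarded
    nsp <- vapply(cands, function(s) length(unique(x$species[s])), integer(1))
    top <- which(nsp == max(nsp))
    if (length(top) > 1L) {
      nlv <- lengths(cands[top])
      top <- top[nlv == max(nlv)]
      if (length(top) > 1L) {
        keys <- vapply(cands[top], .label_key, character(1))
        top <- top[order(keys)]
      }
    }
    sel <- cands[[top[1L]]]
    outs[[length(outs) + 1L]] <-
      .new_single_copy_tree(x, match(sel, phy0$tip.label),
                            provenance = "mi", index = length(outs) + 1L)
    remaining <- setdiff(remaining, sel)
  }
  .new_decomposition(outs, n_duplications = NA_integer_, n_leaves = n,
                     family_id = x$family_id,
                     original_labels = phy0$tip.label, method = "MI",
                     discarded_labels = remaining)
}
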