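# Internal tree helpers shared across modules. All algorithms in this
# package are purely topological: branch lengths are carried through I/O but
# never consulted.

# children of every node, as a list indexed by node number
.children <- function(phy) {
  n_all <- length(phy$tip.label) + phy$Nnode
  ch <- vector("list", n_all)
  for (k in seq_len(nrow(phy$edge))) {
    p <- phy$edge[k, 1L]
    ch[[p]] <- c(ch[[p]], phy$edge[k, 2L])
  }
  ch
}

# internal nodes in postorder (children before parents)
.postorder_nodes <- function(phy) {
  po <- ape::reorder.phylo(phy, "postorder")
  unique(po$edge[, 1L])
}

# tip indices below every node (tips map to themselves)
.tips_below <- function(phy) {
  n <- length(phy$tip.label)
  below <- vector("list", n + phy$Nnode)
  for (i in seq_len(n)) below[[i]] <- i
  po <- ape::reorder.phylo(phy, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1L]
    below[[p]] <- c(below[[p]], below[[po$edge[k, 2L]]])
  }
  below
}

# deterministic sort key for a set of labels
.label_key <- function(labels) paste(sort(labels), collapse = "\r")

# run code under a temporary RNG seed; NULL seed = use the current stream
.with_seed <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

# induced subtree on a set of tip labels, handling the 1-tip degenerate case
# (ape::keep.tip requires >= 2 tips)
.induced_tree <- function(phy, tip_labels) {
  if (length(tip_labels) == 0L) stop("cannot induce a tree on zero tips")
  if (length(tip_labels) == 1L) {
    return(structure(
      list(edge = matrix(c(2L, 1L), 1L, 2L), tip.label = tip_labels,
           Nnode = 1L),
      class = "phylo"))
  }
  ape::keep.tip(phy, tip_labels)
}

.is_binary_rooted <- function(phy) {
  ape::is.rooted(phy) && ape::is.binary(phy)
}

# unordered pair keys for orthology bookkeeping
.pair_keys <- function(a, b) {
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  paste(a, b, sep = "\r")
}

# all unordered pairs among labels, as keys
.all_pair_keys <- function(labels) {
  n <- length(labels)
  if (n < 2L) return(character(0))
  idx <- utils::combn(n, 2L)
  .pair_keys(labels[idx[1L, ]], labels[idx[2L, ]])
}
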