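#' Construct a gene family tree
#'
#' A gene family tree is a (possibly multifurcating, possibly multicopy)
#' tree whose leaves are gene copies. Several leaves may belong to the same
#' species; the species of each leaf is either extracted from its label
#' (see [extract_species()]) or supplied directly. Leaf labels that repeat
#' within one family are uniquified internally by appending `#k` (k-th
#' occurrence in parse order); the original label is retained for species
#' extraction and sequence lookup.
#'
#' @param phy a `phylo` object (rooted or unrooted).
#' @param species optional character vector of species identifiers, one per
#'   tip in `phy$tip.label` order. If `NULL`, species are extracted from the
#'   tip labels.
#' @param family_id identifier for the gene family.
#' @param delimiter field delimiter inside gene-copy labels.
#' @param field 1-based index of the delimiter-separated field holding the
#'   species identifier.
#' @param label_is_species if `TRUE`, each whole leaf label is its species.
#' @param allow_repeats accept repeated leaf labels (uniquified internally).
#'   With `allow_repeats = FALSE` repeated labels raise an error.
#' @return an object of class `gene_family_tree`: a list with elements
#'   `tree` (`phylo`, tips relabeled uniquely), `species` (named character
#'   vector, uniquified label -> species), `labels` (uniquified label ->
#'   original label) and `family_id`.
#' @export
gene_family_tree <- function(phy, species = NULL, family_id = "fam1",
                             delimiter = "_", field = 1L,
                             label_is_species = FALSE,
                             allow_repeats = TRUE) {
  stopifnot(inherits(phy, "phylo"))
  orig <- phy$tip.label
  if (anyDuplicated(orig)) {
    if (!allow_repeats)
      stop("repeated leaf labels (", paste(unique(orig[duplicated(orig)]),
           collapse = ", "), ") in family '", family_id,
           "'; set allow_repeats = TRUE to uniquify them")
    uniq <- orig
    for (lab in unique(orig[duplicated(orig)])) {
      at <- which(orig == lab)
      uniq[at] <- paste0(lab, "#", seq_along(at))
    }
    phy$tip.label <- uniq
  }
  if (is.null(species)) {
    species <- if (label_is_species) orig
               else extract_species(orig, delimiter = delimiter, field = field)
  }
  stopifnot(length(species) == length(orig))
  if (any(is.na(species) | !nzchar(species)))
    stop("empty species identifier for leaf '",
         orig[which(is.na(species) | !nzchar(species))[1L]], "'")
  structure(
    list(tree = phy,
         species = setNames(as.character(species), phy$tip.label),
         labels = setNames(orig, phy$tip.label),
         family_id = family_id),
    class = "gene_family_tree")
}

#' Read gene family trees from Newick text or file
#'
#' Reads one or more semicolon-terminated Newick trees (one file may hold
#' many families). Branch lengths and quoted labels are accepted; branch
#' lengths are retained in the `phylo` object but ignored by every
#' algorithm in this package.
#'
#' @param file path to a Newick file, or `NULL` when `text` is given.
#' @param text Newick string(s), alternative to `file`.
#' @param allow_repeats accept repeated leaf labels within a tree.
#' @param family_ids optional character vector of family identifiers, one
#'   per tree; defaults to `fam1`, `fam2`, ...
#' @inheritParams gene_family_tree
#' @return a list of [gene_family_tree] objects.
#' @export
read_gene_trees <- function(file = NULL, text = NULL, delimiter = "_",
                            field = 1L, label_is_species = FALSE,
                            allow_repeats = TRUE, family_ids = NULL) {
  trees <- tryCatch(
    if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(file),
    error = function(e) stop("malformed Newick input: ", conditionMessage(e)))
  if (is.null(trees)) stop("malformed Newick input: no tree could be parsed")
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (is.null(family_ids)) family_ids <- paste0("fam", seq_along(trees))
  stopifnot(length(family_ids) == length(trees))
  mapply(function(phy, fid)
           gene_family_tree(phy, family_id = fid, delimiter = delimiter,
                            field = field,
                            label_is_species = label_is_species,
                            allow_repeats = allow_repeats),
         trees, family_ids, SIMPLIFY = FALSE)
}

#' Extract species identifiers from gene-copy labels
#'
#' Returns the `field`-th delimiter-separated field of each label
#' (1-based). Labels not containing the delimiter are returned whole, so
#' pre-mapped species labels pass through unchanged.
#'
#' @param labels character vector of gene-copy labels.
#' @param delimiter nonempty delimiter string (fixed, not a regex).
#' @param field 1-based field index.
#' @return character vector of species identifiers.
#' @examples
#' extract_species("GeneX_speciesA_3", field = 2)  # "speciesA"
#' extract_species("a1")                            # "a1"
#' @export
extract_species <- function(labels, delimiter = "_", field = 1L) {
  if (!nzchar(delimiter)) stop("delimiter must be nonempty")
  parts <- strsplit(labels, delimiter, fixed = TRUE)
  vapply(seq_along(labels), function(i) {
    p <- parts[[i]]
    if (length(p) == 1L) return(labels[i])  # delimiter absent: whole label
    if (field < 1L || field > length(p))
      stop("field ", field, " out of range for label '", labels[i], "'")
    p[[field]]
  }, character(1))
}

#' Write trees to Newick
#'
#' Serializes [gene_family_tree] objects (or bare `phylo` trees, or the
#' trees of a decomposition) to Newick, one tree per line. By default the
#' internally uniquified labels are replaced by the original input labels.
#'
#' @param x a `gene_family_tree`, `phylo`, `disco_decomposition`, or a list
#'   of these.
#' @param file output path, or `NULL` to return the Newick strings.
#' @param original_labels write original (possibly repeated) leaf labels
#'   instead of the uniquified internal ones.
#' @param unroot write trees unrooted (degree-2 root suppressed), the form
#'   consumed by summary methods. Trees with fewer than 3 leaves are
#'   written as-is.
#' @return invisibly (or visibly when `file = NULL`) a character vector of
#'   Newick strings.
#' @export
write_gene_trees <- function(x, file = NULL, original_labels = TRUE,
                             unroot = FALSE) {
  xs <- if (inherits(x, c("gene_family_tree", "phylo"))) list(x)
        else if (inherits(x, "disco_decomposition")) x$trees
        else x
  lines <- vapply(xs, function(t) {
    phy <- if (inherits(t, "gene_family_tree")) t$tree else t
    if (original_labels && inherits(t, "gene_family_tree"))
      phy$tip.label <- unname(t$labels[phy$tip.label])
    if (unroot && length(phy$tip.label) > 2L && ape::is.rooted(phy))
      phy <- ape::unroot(phy)
    ape::write.tree(phy)
  }, character(1))
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(lines)
}

#' Randomly resolve polytomies
#'
#' Multifurcations are resolved into a random binary refinement (inserted
#' edges have zero length); the rooting and tagging step requires binary
#' trees. The input's bipartitions are always a subset of the output's, and
#' a given seed reproduces the same resolution.
#'
#' @param x a [gene_family_tree] or `phylo`.
#' @param seed integer seed for reproducible resolution; `NULL` uses the
#'   current RNG stream.
#' @return object of the same class as `x`, fully binary.
#' @export
resolve_polytomies <- function(x, seed = NULL) {
  phy <- if (inherits(x, "gene_family_tree")) x$tree else x
  if (ape::is.binary(phy)) return(x)
  res <- .with_seed(seed, ape::multi2di(phy, random = TRUE))
  if (inherits(x, "gene_family_tree")) { x$tree <- res; x } else res
}

#' Species of each leaf of a gene family tree
#' @param x a [gene_family_tree].
#' @return named character vector (uniquified leaf label -> species).
#' @export
species_map <- function(x) {
  stopifnot(inherits(x, "gene_family_tree"))
  x$species
}

#' @export
print.gene_family_tree <- function(x, ...) {
  n <- length(x$tree$tip.label)
  ns <- length(unique(x$species))
  cat("Gene family tree '", x$family_id, "': ", n, " gene copies, ",
      ns, " species", if (!ape::is.binary(x$tree)) " (multifurcating)",
      "\n", sep = "")
  invisible(x)
}
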