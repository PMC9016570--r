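# CA-DISCO supermatrix construction: carve each family's alignment along
# its decomposition, relabel rows to species, and concatenate all pieces
# into one gap-filled species x sites matrix with named partitions.

#' Read a FASTA alignment as a named character vector
#'
#' Sequences are uppercased; ambiguity codes and alignment gaps (`-`) pass
#' through untouched. Works for nucleotide or amino-acid data.
#'
#' @param file FASTA path.
#' @return named character vector (label -> sequence).
#' @export
read_fasta_alignment <- function(file) {
  s <- Biostrings::readBStringSet(file)
  setNames(toupper(as.character(s)), names(s))
}

#' Split a family alignment along a decomposition
#'
#' Produces one sub-alignment per output tree, rows keyed by species.
#' Sequences are looked up by the original (input) leaf labels of the
#' family.
#'
#' @param aln named character vector of aligned sequences (gene-copy label
#'   -> sequence), all of one length.
#' @param d a `disco_decomposition` of the same family.
#' @return named list of sub-alignments (named character vectors keyed by
#'   species); list names are `<family_id>_<k>`.
#' @export
split_alignment <- function(aln, d) {
  stopifnot(inherits(d, "disco_decomposition"))
  if (length(unique(nchar(aln))) > 1L)
    stop("alignment rows have unequal lengths")
  subs <- lapply(d$trees, function(t) {
    labs <- unname(t$labels[t$tree$tip.label])
    sp <- unname(t$species[t$tree$tip.label])
    missing <- labs[!(labs %in% names(aln))]
    if (length(missing))
      stop("no sequence for leaf '", missing[1L], "' in family '",
           d$family_id, "'")
    if (anyDuplicated(sp))
      stop("tree is not single-copy; cannot key rows by species")
    setNames(aln[labs], sp)
  })
  setNames(subs, paste0(d$family_id, "_", seq_along(subs)))
}

#' Build a concatenation supermatrix
#'
#' Rows are the sorted union of species over all sub-alignments; columns
#' are the sub-alignments concatenated in the given (family, tree-index)
#' order. A species absent from a sub-alignment is filled with gap
#' characters across its columns. Gappiness counts both fill gaps and
#' alignment-internal gaps.
#'
#' @param subalns named list of species-keyed sub-alignments, e.g. the
#'   concatenation of [split_alignment()] results over all families.
#' @param gap gap character.
#' @return object of class `supermatrix`: list with `sequences` (named
#'   character vector, species -> concatenated row), `partitions`
#'   (data.frame: name, start, end; 1-based inclusive), `gappiness`.
#' @export
build_supermatrix <- function(subalns, gap = "-") {
  stopifnot(length(subalns) >= 1L)
  if (is.null(names(subalns)) || any(!nzchar(names(subalns))))
    stop("sub-alignments must be named (family/partition names)")
  for (nm in names(subalns)) {
    sa <- subalns[[nm]]
    if (anyDuplicated(names(sa)))
      stop("duplicate species within sub-alignment '", nm,
           "' (violates single-copy)")
    if (length(unique(nchar(sa))) > 1L)
      stop("unequal row lengths in sub-alignment '", nm, "'")
  }
  species <- sort(unique(unlist(lapply(subalns, names), use.names = FALSE)))
  widths <- vapply(subalns, function(sa) nchar(sa[[1L]]), integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  rows <- vapply(species, function(sp) {
    paste(vapply(seq_along(subalns), function(i) {
      sa <- subalns[[i]]
      if (sp %in% names(sa)) sa[[sp]]
      else strrep(gap, widths[[i]])
    }, character(1)), collapse = "")
  }, character(1))
  total <- sum(widths) * length(species)
  n_gaps <- sum(vapply(rows, function(r)
    lengths(regmatches(r, gregexpr(gap, r, fixed = TRUE))), integer(1)))
  structure(
    list(sequences = rows,
         partitions = data.frame(name = names(subalns),
                                 start = starts, end = ends,
                                 row.names = NULL),
         gappiness = n_gaps / total,
         gap = gap),
    class = "supermatrix")
}

#' Write a supermatrix and its partition file
#'
#' The matrix is written as FASTA (and optionally relaxed PHYLIP); the
#' partition file uses RAxML-style lines `DNA, name = start-end`.
#'
#' @param sm a `supermatrix`.
#' @param fasta output FASTA path (`NULL` to skip).
#' @param partitions output partition-file path (`NULL` to skip).
#' @param phylip optional relaxed-PHYLIP output path.
#' @param datatype datatype token for the partition lines.
#' @return invisibly, the paths written.
#' @export
write_supermatrix <- function(sm, fasta = NULL, partitions = NULL,
                              phylip = NULL, datatype = "DNA") {
  stopifnot(inherits(sm, "supermatrix"))
  written <- character(0)
  if (!is.null(fasta)) {
    writeLines(paste0(">", names(sm$sequences), "\n", sm$sequences), fasta)
    written <- c(written, fasta)
  }
  if (!is.null(phylip)) {
    writeLines(c(paste(length(sm$sequences), nchar(sm$sequences[[1L]])),
                 paste(names(sm$sequences), sm$sequences)), phylip)
    written <- c(written, phylip)
  }
  if (!is.null(partitions)) {
    writeLines(sprintf("%s, %s = %d-%d", datatype, sm$partitions$name,
                       sm$partitions$start, sm$partitions$end), partitions)
    written <- c(written, partitions)
  }
  invisible(written)
}

#' @export
print.supermatrix <- function(x, ...) {
  cat("Supermatrix: ", length(x$sequences), " species x ",
      nchar(x$sequences[[1L]]), " sites in ", nrow(x$partitions),
      " partitions; gappiness ", round(x$gappiness, 4), "\n", sep = "")
  invisible(x)
}

#' CA-DISCO: decompose families and build their supermatrix
#'
#' Convenience wrapper over the full concatenation pipeline: each family
#' tree is resolved, rooted+tagged, decomposed (unfiltered by default, so
#' every input sequence lands in exactly one partition), its alignment
#' split and relabeled to species, and everything concatenated.
#'
#' @param trees list of [gene_family_tree]s.
#' @param alignments list of alignments (named character vectors), matched
#'   to `trees` by position.
#' @param min_species size filter on decomposition trees (default 1: keep
#'   everything).
#' @param seed seed for polytomy resolution.
#' @param gap gap character.
#' @return a `supermatrix`.
#' @export
ca_disco <- function(trees, alignments, min_species = 1L, seed = NULL,
                     gap = "-") {
  stopifnot(length(trees) == length(alignments))
  subs <- list()
  for (i in seq_along(trees)) {
    x <- resolve_polytomies(trees[[i]], seed = seed)
    d <- disco_decompose(best_root(x))
    if (min_species > 1L) d <- filter_by_size(d, min_species)
    subs <- c(subs, split_alignment(alignments[[i]], d))
  }
  build_supermatrix(subs, gap = gap)
}
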