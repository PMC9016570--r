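# Evaluation statistics: coverage/size summaries of decompositions,
# normalized Robinson-Foulds distances (normalization constant 2n - 6), and
# orthology precision/recall against simulator truth.

#' Coverage and size statistics of a decomposition
#'
#' Coverage is the proportion of the original gene family tree's leaves
#' contained in the decomposition's output trees; sizes are counted in
#' distinct species per output tree.
#'
#' @param d a `disco_decomposition`.
#' @return list with `coverage`, `max_size`, `mean_size`, `n_trees`.
#' @export
coverage_stats <- function(d) {
  stopifnot(inherits(d, "disco_decomposition"))
  list(coverage = d$coverage, max_size = d$max_size,
       mean_size = d$mean_size, n_trees = length(d$trees))
}

#' Per-family decomposition summary table
#'
#' Applies rooting+tagging and DISCO decomposition (and optionally the MI
#' baseline) to a list of gene family trees and tabulates per-family
#' statistics. Families with fewer than `min_family_species` distinct
#' species are excluded from the table.
#'
#' @param trees list of [gene_family_tree] objects.
#' @param method `"DISCO"` or `"MI"`.
#' @param min_species size filter applied to output trees (species count).
#' @param min_family_species exclude families with fewer distinct species.
#' @param seed seed for random polytomy resolution, if any is needed.
#' @return data.frame with columns family_id, n_leaves, n_species,
#'   n_duplications, n_output_trees, max_size, mean_size, coverage.
#' @export
decomposition_summary <- function(trees, method = c("DISCO", "MI"),
                                  min_species = 4L,
                                  min_family_species = 4L, seed = NULL) {
  method <- match.arg(method)
  rows <- lapply(trees, function(x) {
    if (length(unique(x$species)) < min_family_species) return(NULL)
    x <- resolve_polytomies(x, seed = seed)
    d <- if (method == "DISCO") {
      dd <- disco_decompose(best_root(x))
      if (min_species > 1L) filter_by_size(dd, min_species) else dd
    } else {
      mi_decompose(x, min_species = min_species)
    }
    data.frame(family_id = x$family_id,
               n_leaves = length(x$tree$tip.label),
               n_species = length(unique(x$species)),
               n_duplications = d$n_duplications,
               n_output_trees = length(d$trees),
               max_size = d$max_size,
               mean_size = d$mean_size,
               coverage = d$coverage)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Robinson-Foulds distance between two trees
#'
#' The symmetric difference of the nontrivial bipartition sets, normalized
#' by `2n - 6` (the maximum for two binary trees on `n` shared leaves).
#' Multicopy trees are compared via their uniquified per-copy leaf labels.
#'
#' @param t1,t2 [gene_family_tree] or `phylo` objects on the same leafset.
#' @param normalized also return `nrf = rf / (2n - 6)`; requires `n >= 4`.
#' @return list with `rf` (integer) and `nrf` (fraction, `NULL` when
#'   `normalized = FALSE`).
#' @export
rf_distance <- function(t1, t2, normalized = TRUE) {
  p1 <- if (inherits(t1, "gene_family_tree")) t1$tree else t1
  p2 <- if (inherits(t2, "gene_family_tree")) t2$tree else t2
  l1 <- sort(p1$tip.label); l2 <- sort(p2$tip.label)
  if (!identical(l1, l2)) {
    diff <- c(setdiff(l1, l2), setdiff(l2, l1))
    stop("trees do not share a leafset; differing labels: ",
         paste(diff, collapse = ", "))
  }
  n <- length(l1)
  if (n > 3L) {
    rf <- as.integer(phangorn::RF.dist(ape::unroot(p1), ape::unroot(p2),
                                       check.labels = TRUE))
  } else rf <- 0L  # at most 3 leaves: a single unrooted topology exists
  if (!normalized) return(list(rf = rf, nrf = NULL))
  if (n < 4L) stop("normalized RF requires at least 4 leaves")
  list(rf = rf, nrf = rf / (2 * n - 6))
}

#' Orthology call sets
#'
#' A set of unordered gene-copy pairs called orthologous, within a fixed
#' universe of all pairs of a family's gene copies.
#'
#' @param calls character vector of pair keys (see [pair_calls()]).
#' @param labels the family's gene-copy labels (defines the universe).
#' @return object of class `orthology_calls`: list with `calls`, `labels`,
#'   `universe` (number of pairs).
#' @keywords internal
new_orthology_calls <- function(calls, labels) {
  structure(list(calls = unique(calls), labels = sort(labels),
                 universe = choose(length(labels), 2)),
            class = "orthology_calls")
}

#' Build orthology calls from an explicit pair list
#'
#' @param pairs two-column matrix or data.frame of gene-copy labels.
#' @param labels all gene-copy labels of the family.
#' @return an `orthology_calls` object.
#' @export
pair_calls <- function(pairs, labels) {
  pairs <- as.matrix(pairs)
  keys <- if (nrow(pairs)) .pair_keys(pairs[, 1L], pairs[, 2L])
          else character(0)
  new_orthology_calls(keys, labels)
}

#' Orthology predicted by a decomposition
#'
#' Two gene copies are called orthologous iff they lie in the same output
#' tree; pairs split across trees (or discarded by filtering) are called
#' paralogous. The pair universe is all pairs of the original family's
#' copies.
#'
#' @param d a `disco_decomposition`.
#' @return an `orthology_calls` object.
#' @export
predicted_orthology_decomposition <- function(d) {
  stopifnot(inherits(d, "disco_decomposition"))
  calls <- unlist(lapply(d$trees, function(t)
    .all_pair_keys(t$tree$tip.label)), use.names = FALSE)
  new_orthology_calls(calls, d$original_labels)
}

#' Orthology predicted by a tagged tree
#'
#' Two gene copies are called orthologous iff their least common ancestor
#' is tagged as a speciation.
#'
#' @param x a `tagged_tree`.
#' @return an `orthology_calls` object.
#' @export
predicted_orthology_tagged <- function(x) {
  stopifnot(inherits(x, "tagged_tree"))
  phy <- x$tree
  labs <- phy$tip.label
  n <- length(labs)
  if (n < 2L) return(new_orthology_calls(character(0), labs))
  m <- ape::mrca(phy)
  idx <- utils::combn(n, 2L)
  anc <- m[cbind(idx[1L, ], idx[2L, ])]
  ok <- x$tags[anc - n] == "speciation"
  new_orthology_calls(.pair_keys(labs[idx[1L, ok]], labs[idx[2L, ok]]), labs)
}

#' Precision and recall of orthology calls
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)` over the shared
#' pair universe. A zero denominator (no predicted calls, or no true
#' pairs) yields 1 by convention, so batch summaries stay finite.
#'
#' @param pred,truth `orthology_calls` over the same universe.
#' @return named numeric vector `c(precision, recall)` with attribute
#'   `counts = c(TP, FP, FN, TN)`.
#' @export
precision_recall <- function(pred, truth) {
  stopifnot(inherits(pred, "orthology_calls"),
            inherits(truth, "orthology_calls"))
  if (!identical(pred$labels, truth$labels))
    stop("orthology call sets are over different pair universes")
  tp <- length(intersect(pred$calls, truth$calls))
  fp <- length(setdiff(pred$calls, truth$calls))
  fn <- length(setdiff(truth$calls, pred$calls))
  tn <- pred$universe - tp - fp - fn
  res <- c(precision = if (tp + fp == 0L) 1 else tp / (tp + fp),
           recall = if (tp + fn == 0L) 1 else tp / (tp + fn))
  attr(res, "counts") <- c(TP = tp, FP = fp, FN = fn, TN = tn)
  res
}

#' Batch orthology evaluation
#'
#' Pools true/false positives over families ("pooled") and also averages
#' per-family values ("macro"); the two aggregations can differ and both
#' are reported.
#'
#' @param preds,truths lists of `orthology_calls`, matched by position.
#' @return list with `precision_pooled`, `recall_pooled`,
#'   `precision_macro`, `recall_macro`, and the pooled `counts`.
#' @export
orthology_accuracy <- function(preds, truths) {
  stopifnot(length(preds) == length(truths))
  per <- mapply(function(p, t) precision_recall(p, t), preds, truths,
                SIMPLIFY = FALSE)
  counts <- Reduce(`+`, lapply(per, attr, "counts"))
  tp <- counts[["TP"]]; fp <- counts[["FP"]]; fn <- counts[["FN"]]
  list(
    precision_pooled = if (tp + fp == 0) 1 else tp / (tp + fp),
    recall_pooled = if (tp + fn == 0) 1 else tp / (tp + fn),
    precision_macro = mean(vapply(per, `[[`, numeric(1), "precision")),
    recall_macro = mean(vapply(per, `[[`, numeric(1), "recall")),
    counts = counts)
}
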