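# Gene duplication/loss simulator. A gene lineage enters the species tree
# at the root and evolves down every branch; along a branch of length t it
# experiences duplications (rate dup_rate per unit length) and losses
# (rate loss_rate). A duplication spawns an independent daughter lineage
# that continues down the remaining species tree from the duplication
# point; a loss prunes the lineage. Surviving tips become gene copies
# labeled "<species>_<copy index>", and every surviving internal vertex is
# event-labeled speciation or duplication, which defines true pairwise
# orthology (orthologs = pairs whose MRCA event is a speciation). Rates
# are per unit branch length of the species tree (free scale).

#' Simulate a species tree
#'
#' A Yule (pure-birth) tree with `n_species` tips and exponentially
#' distributed branch lengths, tips labeled `S001`, `S002`, ...
#'
#' @param n_species number of species (>= 4).
#' @param seed integer seed; identical seeds give identical trees.
#' @param birth speciation rate of the Yule process (time-scale only).
#' @return a rooted binary `phylo`.
#' @export
simulate_species_tree <- function(n_species = 101L, seed = NULL, birth = 1) {
  if (n_species < 4L) stop("need at least 4 species")
  phy <- .with_seed(seed, ape::rphylo(n_species, birth = birth, death = 0))
  phy$tip.label <- sprintf("S%03d", seq_len(n_species))
  phy
}

# recursive GDL process; returns nested list or NULL (lineage extinct)
.gdl_evolve <- function(st, ch, dup_rate, loss_rate) {
  total <- dup_rate + loss_rate
  n <- length(st$tip.label)
  elen <- setNames(st$edge.length, st$edge[, 2L])
  node_f <- function(v) {
    if (v <= n) return(list(type = "leaf", species = st$tip.label[v]))
    kids <- ch[[v]]
    a <- branch_f(kids[1L], elen[[as.character(kids[1L])]])
    b <- branch_f(kids[2L], elen[[as.character(kids[2L])]])
    if (is.null(a)) return(b)
    if (is.null(b)) return(a)
    list(type = "node", tag = "speciation", left = a, right = b)
  }
  branch_f <- function(v, t_rem) {
    repeat {
      w <- if (total > 0) rexp(1L, total) else Inf
      if (w >= t_rem) return(node_f(v))
      t_rem <- t_rem - w
      if (runif(1L) < dup_rate / total) {
        a <- branch_f(v, t_rem)
        b <- branch_f(v, t_rem)
        if (is.null(a)) { if (is.null(b)) return(NULL) else return(b) }
        if (is.null(b)) return(a)
        return(list(type = "node", tag = "duplication", left = a, right = b))
      } else return(NULL)  # loss
    }
  }
  node_f(n + 1L)
}

# serialize nested simulation result to Newick with event tags as internal
# node labels; copy indices assigned per species in serialization order
.gdl_newick <- function(sim) {
  counter <- new.env(parent = emptyenv())
  rec <- function(x) {
    if (x$type == "leaf") {
      k <- (get0(x$species, envir = counter, ifnotfound = 0L)) + 1L
      assign(x$species, k, envir = counter)
      paste0(x$species, "_", k)
    } else {
      paste0("(", rec(x$left), ",", rec(x$right), ")", x$tag)
    }
  }
  paste0(rec(sim), ";")
}

#' Simulate one gene family under gene duplication and loss
#'
#' @param st species tree (`phylo` from [simulate_species_tree()]).
#' @param dup_rate,loss_rate duplication and loss rates per unit branch
#'   length of `st` (>= 0).
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @param family_id family identifier.
#' @param min_leaves families with fewer surviving gene copies are
#'   regenerated.
#' @param max_retries cap on regenerations before erroring (suggesting a
#'   rate adjustment).
#' @return a `tagged_tree` whose tags are the true simulated events, with
#'   attribute `retries` (number of regenerations needed).
#' @export
simulate_gene_family <- function(st, dup_rate = 0.2, loss_rate = 0.2,
                                 seed = NULL, family_id = "fam1",
                                 min_leaves = 4L, max_retries = 100L) {
  stopifnot(inherits(st, "phylo"), dup_rate >= 0, loss_rate >= 0)
  if (!.is_binary_rooted(st)) stop("species tree must be rooted and binary")
  ch <- .children(st)
  .with_seed(seed, {
    for (try in 0:max_retries) {
      sim <- .gdl_evolve(st, ch, dup_rate, loss_rate)
      if (!is.null(sim) && sim$type == "node") {
        phy <- ape::read.tree(text = .gdl_newick(sim))
        if (length(phy$tip.label) >= min_leaves) {
          gft <- gene_family_tree(phy, family_id = family_id,
                                  delimiter = "_", field = 1L)
          eng_tags <- phy$node.label
          x <- .new_tagged_tree(gft, gft$tree,
                                list(tags = eng_tags,
                                     duplications = sum(eng_tags == "duplication"),
                                     losses = NA_integer_))
          attr(x, "retries") <- try
          return(x)
        }
      }
    }
    stop("no family with >= ", min_leaves, " gene copies after ",
         max_retries, " retries; adjust dup_rate/loss_rate")
  })
}

#' Simulate a batch of gene families with orthology truth
#'
#' @inheritParams simulate_gene_family
#' @param n_families number of families.
#' @param seed integer seed; the whole record is reproducible per
#'   (parameters, seed).
#' @return object of class `simulation_record`: list with `species_tree`,
#'   `families` (list of true `tagged_tree`s), `truth` (list of
#'   `orthology_calls` derived from the event labels), `dup_rate`,
#'   `loss_rate`, `seed`.
#' @export
simulate_families <- function(st, n_families = 100L, dup_rate = 0.2,
                              loss_rate = 0.2, seed = NULL,
                              min_leaves = 4L, max_retries = 100L) {
  fams <- .with_seed(seed, lapply(seq_len(n_families), function(i)
    simulate_gene_family(st, dup_rate = dup_rate, loss_rate = loss_rate,
                         family_id = paste0("fam", i),
                         min_leaves = min_leaves,
                         max_retries = max_retries)))
  structure(
    list(species_tree = st, families = fams,
         truth = lapply(fams, predicted_orthology_tagged),
         dup_rate = dup_rate, loss_rate = loss_rate, seed = seed),
    class = "simulation_record")
}

#' @export
print.simulation_record <- function(x, ...) {
  nl <- vapply(x$families, function(f) length(f$tree$tip.label), integer(1))
  cat("Simulation record: ", length(x$families), " gene families over ",
      length(x$species_tree$tip.label), " species\n",
      "rates: duplication ", x$dup_rate, ", loss ", x$loss_rate,
      "; mean leaves/family ", round(mean(nl), 1), "\n", sep = "")
  invisible(x)
}

#' Perturb a tree by random NNI moves
#'
#' A proxy for gene tree estimation error: applies `k_moves` random
#' nearest-neighbor-interchange moves. `k_moves = 0` is the identity; a
#' single move changes exactly one bipartition (RF distance 2 to the
#' input). The achieved normalized RF distance to the input is attached as
#' attribute `nrf`.
#'
#' @param x a binary [gene_family_tree] or `phylo` with >= 4 leaves.
#' @param k_moves number of NNI moves (>= 0).
#' @param seed integer seed.
#' @return same class as `x`, with attribute `nrf`.
#' @export
perturb_nni <- function(x, k_moves = 1L, seed = NULL) {
  phy <- if (inherits(x, "gene_family_tree")) x$tree else x
  stopifnot(k_moves >= 0L, length(phy$tip.label) >= 4L)
  if (!ape::is.binary(phy)) stop("perturb_nni requires a binary tree")
  out <- if (k_moves == 0L) phy
         else .with_seed(seed, phangorn::rNNI(phy, moves = k_moves, n = 1L))
  nrf <- rf_distance(phy, out)$nrf
  res <- if (inherits(x, "gene_family_tree")) {
    y <- x; y$tree <- out
    if (inherits(x, "tagged_tree")) {    # topology changed: tags are void
      y$tags <- NULL; y$score <- NULL
      class(y) <- "gene_family_tree"
      y <- structure(y[c("tree", "species", "labels", "family_id")],
                     class = "gene_family_tree")
    }
    y
  } else out
  attr(res, "nrf") <- nrf
  res
}

#' Choose an NNI move count reaching a target estimation-error level
#'
#' Monte-Carlo search: increases the move count until the mean normalized
#' RF distance over a sample of trees reaches `target_nrf`.
#'
#' @param trees list of binary [gene_family_tree]s.
#' @param target_nrf desired mean normalized RF distance in `[0, 1]`.
#' @param seed integer seed.
#' @param max_k upper bound on the move count.
#' @return the chosen move count `k` with attribute `achieved_nrf`.
#' @export
calibrate_nni <- function(trees, target_nrf, seed = NULL, max_k = 200L) {
  stopifnot(target_nrf >= 0, target_nrf <= 1)
  if (target_nrf == 0) return(structure(0L, achieved_nrf = 0))
  .with_seed(seed, {
    for (k in seq_len(max_k)) {
      nrfs <- vapply(trees, function(t)
        attr(perturb_nni(t, k_moves = k), "nrf"), numeric(1))
      if (mean(nrfs) >= target_nrf)
        return(structure(k, achieved_nrf = mean(nrfs)))
    }
    structure(max_k, achieved_nrf = NA_real_)
  })
}

#' Clade-based missing data
#'
#' Emulates genes born below the species-tree root: each family is
#' independently affected with probability `affected_fraction`; for an
#' affected family a clade with at least `min_clade_fraction` of the
#' species is drawn uniformly from the species tree's clades, and all
#' copies of species outside that clade are pruned. Families shrinking
#' below `min_leaves` gene copies are dropped.
#'
#' @param families list of [gene_family_tree]s (tags, if any, are dropped:
#'   pruning invalidates them).
#' @param st the species tree the families evolved in.
#' @param affected_fraction probability a family is affected.
#' @param min_clade_fraction minimum clade size as a fraction of species.
#' @param seed integer seed.
#' @param min_leaves families with fewer copies after pruning are dropped.
#' @return list with `families` (pruned), `n_dropped`, and
#'   `removed_fraction` (per affected family, the fraction of its species
#'   that were deleted).
#' @export
clade_based_missing <- function(families, st, affected_fraction = 0.6,
                                min_clade_fraction = 0.2, seed = NULL,
                                min_leaves = 4L) {
  stopifnot(affected_fraction >= 0, affected_fraction <= 1,
            min_clade_fraction > 0, min_clade_fraction < 1)
  nsp <- length(st$tip.label)
  below <- .tips_below(st)
  clades <- lapply(seq_len(nsp + st$Nnode), function(v)
    st$tip.label[below[[v]]])
  clades <- clades[lengths(clades) >= min_clade_fraction * nsp]
  if (length(clades) == 0L)
    stop("no clade with at least ", min_clade_fraction,
         " of the species exists")
  .with_seed(seed, {
    out <- list(); removed <- numeric(0); dropped <- 0L
    for (x in families) {
      if (runif(1L) < affected_fraction) {
        clade <- clades[[sample.int(length(clades), 1L)]]
        keep <- x$tree$tip.label[x$species[x$tree$tip.label] %in% clade]
        sp_before <- unique(x$species)
        removed <- c(removed,
                     1 - length(unique(x$species[keep])) / length(sp_before))
        if (length(keep) < min_leaves) { dropped <- dropped + 1L; next }
        phy <- .induced_tree(x$tree, keep)
        out[[length(out) + 1L]] <- structure(
          list(tree = phy, species = x$species[phy$tip.label],
               labels = x$labels[phy$tip.label], family_id = x$family_id),
          class = "gene_family_tree")
      } else {
        out[[length(out) + 1L]] <- structure(
          x[c("tree", "species", "labels", "family_id")],
          class = "gene_family_tree")
      }
    }
    list(families = out, n_dropped = dropped, removed_fraction = removed)
  })
}

#' Write a simulation record to a directory
#'
#' Emits `truth.nwk` (event-labeled true family trees), `species_tree.nwk`,
#' a JSON sidecar with rates, seed and per-family leaf/species counts, and
#' a TSV summary.
#'
#' @param record a `simulation_record`.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_simulation_record <- function(record, dir) {
  stopifnot(inherits(record, "simulation_record"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p_tree <- file.path(dir, "species_tree.nwk")
  ape::write.tree(record$species_tree, p_tree)
  p_fam <- file.path(dir, "truth.nwk")
  writeLines(vapply(record$families, function(f) ape::write.tree(f$tree),
                    character(1)), p_fam)
  tab <- data.frame(
    family_id = vapply(record$families, `[[`, character(1), "family_id"),
    n_leaves = vapply(record$families, function(f)
      length(f$tree$tip.label), integer(1)),
    n_species = vapply(record$families, function(f)
      length(unique(f$species)), integer(1)),
    n_duplications = vapply(record$families, function(f)
      f$score[["duplications"]], integer(1)))
  p_tsv <- file.path(dir, "families.tsv")
  write.table(tab, p_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  p_json <- file.path(dir, "record.json")
  jsonlite::write_json(
    list(dup_rate = record$dup_rate, loss_rate = record$loss_rate,
         seed = record$seed, n_families = length(record$families),
         mean_leaves = mean(tab$n_leaves),
         mean_species = mean(tab$n_species)),
    p_json, auto_unbox = TRUE, digits = NA)
  invisible(c(p_tree, p_fam, p_tsv, p_json))
}
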