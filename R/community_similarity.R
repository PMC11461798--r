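#' Bray-Curtis similarity between two abundance vectors
#'
#' `1 - sum(|x - y|) / sum(x + y)` over the shared taxon space.
#'
#' @param x,y non-negative numeric vectors over the same taxa (matched by
#'   name when both are named).
#' @return similarity in `[0, 1]`.
#' @export
bray_curtis_similarity <- function(x, y) {
  v <- match_vectors(x, y)
  tot <- sum(v$x + v$y)
  if (tot == 0) stop("both communities are empty")
  1 - sum(abs(v$x - v$y)) / tot
}

#' Sorensen (presence/absence) similarity
#'
#' `2 * |shared taxa| / (|taxa in x| + |taxa in y|)`.
#'
#' @inheritParams bray_curtis_similarity
#' @return similarity in `[0, 1]`.
#' @export
sorensen_similarity <- function(x, y) {
  v <- match_vectors(x, y)
  a <- v$x > 0; b <- v$y > 0
  if (!any(a) && !any(b)) stop("both communities are empty")
  2 * sum(a & b) / (sum(a) + sum(b))
}

match_vectors <- function(x, y) {
  if (!is.null(names(x)) && !is.null(names(y))) {
    taxa <- union(names(x), names(y))
    xx <- stats::setNames(numeric(length(taxa)), taxa)
    yy <- xx
    xx[names(x)] <- x; yy[names(y)] <- y
    list(x = xx, y = yy)
  } else {
    if (length(x) != length(y)) stop("unnamed vectors must have equal length")
    list(x = x, y = y)
  }
}

#' UniFrac similarity between two communities on a tree
#'
#' Unweighted UniFrac distance is the branch length unique to one
#' community's tip set divided by the branch length leading to either set;
#' weighted UniFrac moves relative-abundance mass along branches and is
#' normalized so the distance lies in `[0, 1]`
#' (`sum(b * |pA - pB|) / sum(b * (pA + pB))`, the normalization used by
#' phyloseq). Similarity is `1 - distance`. Abundances are converted to
#' within-sample relative abundances before the weighted variant.
#'
#' @param x,y named non-negative abundance vectors; names must be tips of
#'   `tree` (tips absent from a vector count as absent).
#' @param tree a `"phylo"` object.
#' @param weighted logical.
#' @return similarity in `[0, 1]`.
#' @export
unifrac_similarity <- function(x, y, tree, weighted = FALSE) {
  validate_tree(tree)
  px <- tip_vector(x, tree); py <- tip_vector(y, tree)
  if (sum(px) == 0 || sum(py) == 0) stop("empty community")
  ex <- edge_mass(tree, px / sum(px))
  ey <- edge_mass(tree, py / sum(py))
  b <- tree$edge.length
  if (weighted) {
    1 - sum(b * abs(ex - ey)) / sum(b * (ex + ey))
  } else {
    ia <- ex > 0; ib <- ey > 0
    denom <- sum(b[ia | ib])
    if (denom == 0) return(1)
    1 - sum(b[xor(ia, ib)]) / denom
  }
}

tip_vector <- function(x, tree) {
  if (is.null(names(x))) stop("abundance vectors must be named by taxon")
  unknown <- setdiff(names(x)[x > 0], tree$tip.label)
  if (length(unknown) > 0)
    stop("taxa not in tree: ", paste(unknown, collapse = ", "))
  out <- numeric(length(tree$tip.label))
  names(out) <- tree$tip.label
  out[intersect(names(x), tree$tip.label)] <-
    x[intersect(names(x), tree$tip.label)]
  out
}

# Per-edge descendant mass: edge e carries the summed tip values below its
# child node. Single postorder accumulation over the edge matrix.
edge_mass <- function(tree, tip_values) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  acc <- numeric(ntip + nnode)
  acc[seq_len(ntip)] <- tip_values
  edge <- tree$edge
  ord <- ape::reorder.phylo(tree, "postorder")$edge
  # walk child->parent in postorder so children are complete before parents
  for (k in seq_len(nrow(ord))) {
    acc[ord[k, 1]] <- acc[ord[k, 1]] + acc[ord[k, 2]]
  }
  acc[edge[, 2]]
}

#' Per-sample similarity between a full and a filtered dataset
#'
#' For every sample shared by the two datasets, computes Bray-Curtis,
#' Sorensen and weighted/unweighted UniFrac similarity between the sample's
#' abundance vector in the full dataset and in the filtered one. Vectors are
#' compared on the full dataset's taxon space (taxa removed by filtering are
#' zeros in the filtered vector) and both UniFrac variants use the FULL tree,
#' so taxa that were removed contribute their (possibly long) branches to the
#' full-side vector only. A similarity of 1 means the sample was unaffected
#' by the filtering.
#'
#' @param full,filtered `"community_dataset"` objects; `filtered`'s samples
#'   and taxa must be subsets of `full`'s.
#' @return data.frame with columns `sample`, `metric`, `similarity`,
#'   `removed_abundance_fraction` (fraction of the sample's full-dataset
#'   abundance held by taxa absent from the filtered dataset).
#' @export
compare_datasets <- function(full, filtered) {
  shared <- intersect(rownames(full$table), rownames(filtered$table))
  if (length(shared) == 0) stop("no shared samples between datasets")
  extra_taxa <- setdiff(colnames(filtered$table), colnames(full$table))
  if (length(extra_taxa) > 0)
    stop("filtered dataset has taxa absent from full dataset: ",
         paste(utils::head(extra_taxa, 5), collapse = ", "))
  removed <- setdiff(colnames(full$table), colnames(filtered$table))
  taxa <- colnames(full$table)
  metrics <- c("bray_curtis", "sorensen", "weighted_unifrac",
               "unweighted_unifrac")
  rows <- lapply(shared, function(s) {
    xf <- full$table[s, ]
    xr <- stats::setNames(numeric(length(taxa)), taxa)
    xr[colnames(filtered$table)] <- filtered$table[s, ]
    rf <- if (sum(xf) > 0) sum(xf[removed]) / sum(xf) else 0
    sims <- c(
      bray_curtis = bray_curtis_similarity(xf, xr),
      sorensen = sorensen_similarity(xf, xr),
      weighted_unifrac = unifrac_similarity(xf, xr, full$tree, weighted = TRUE),
      unweighted_unifrac = unifrac_similarity(xf, xr, full$tree, weighted = FALSE))
    data.frame(sample = s, metric = metrics,
               similarity = unname(sims[metrics]),
               removed_abundance_fraction = rf,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
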