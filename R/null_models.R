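#' Cophenetic (tip-to-tip path) distances of a tree
#'
#' Entry (i, j) is the sum of branch lengths on the path between tips i and
#' j; the matrix is symmetric with a zero diagonal and is the only
#' phylogenetic input the null models consume.
#'
#' @param tree a `"phylo"` object.
#' @return a symmetric numeric matrix with tip labels as dimnames.
#' @export
cophenetic_distances <- function(tree) {
  validate_tree(tree)
  stats::cophenetic(tree)
}

#' Mean nearest taxon distance (MNTD) of a community
#'
#' For each taxon present, the distance to its nearest co-occurring taxon is
#' found; MNTD is the (optionally abundance-weighted) mean of those minima.
#'
#' @param present_taxa character vector of taxa present (>= 2), or a named
#'   abundance vector whose positive entries define the community.
#' @param dist cophenetic distance matrix covering all `present_taxa`.
#' @param abundances optional named weights (ignored unless `weighted`).
#' @param weighted logical; weight each taxon's nearest-neighbour distance by
#'   its relative abundance.
#' @return a single number in branch-length units.
#' @export
mntd <- function(present_taxa, dist, abundances = NULL, weighted = FALSE) {
  if (is.numeric(present_taxa) && !is.null(names(present_taxa))) {
    abundances <- present_taxa
    present_taxa <- names(present_taxa)[present_taxa > 0]
    abundances <- abundances[present_taxa]
  }
  if (length(present_taxa) < 2)
    stop("MNTD is undefined for communities with fewer than 2 taxa")
  idx <- match(present_taxa, rownames(dist))
  if (anyNA(idx))
    stop("taxa absent from distance matrix: ",
         paste(present_taxa[is.na(idx)], collapse = ", "))
  mins <- row_min_offdiag(dist[idx, idx, drop = FALSE])
  if (weighted) {
    if (is.null(abundances)) stop("weighted MNTD needs abundances")
    w <- abundances[present_taxa]
    sum(mins * w) / sum(w)
  } else mean(mins)
}

# MNTD on integer row indices of a distance matrix (hot inner loop).
mntd_idx <- function(idx, dist, w = NULL) {
  mins <- row_min_offdiag(dist[idx, idx, drop = FALSE])
  if (is.null(w)) mean(mins) else sum(mins * w) / sum(w)
}

#' Beta mean nearest taxon distance (betaMNTD) between two communities
#'
#' For every taxon in community A the distance to its nearest taxon in
#' community B is found (0 if the taxon itself is present in B), and vice
#' versa; the two directional means (abundance-weighted if requested) are
#' averaged.
#'
#' @param x,y named abundance vectors; positive entries define each
#'   community.
#' @param dist cophenetic distance matrix covering both communities.
#' @param weighted logical; use within-sample relative abundances as weights.
#' @return a single number in branch-length units.
#' @export
bmntd <- function(x, y, dist, weighted = FALSE) {
  ta <- names(x)[x > 0]; tb <- names(y)[y > 0]
  if (length(ta) == 0 || length(tb) == 0)
    stop("betaMNTD is undefined for empty communities")
  ia <- match(ta, rownames(dist)); ib <- match(tb, rownames(dist))
  if (anyNA(ia) || anyNA(ib)) stop("taxa absent from distance matrix")
  bmntd_idx(ia, ib, dist,
            wa = if (weighted) x[ta] else NULL,
            wb = if (weighted) y[tb] else NULL)
}

bmntd_idx <- function(ia, ib, dist, wa = NULL, wb = NULL) {
  sub <- dist[ia, ib, drop = FALSE]
  mins_a <- sub[cbind(seq_along(ia), max.col(-sub, ties.method = "first"))]
  tsub <- t(sub)
  mins_b <- tsub[cbind(seq_along(ib), max.col(-tsub, ties.method = "first"))]
  da <- if (is.null(wa)) mean(mins_a) else sum(mins_a * wa) / sum(wa)
  db <- if (is.null(wb)) mean(mins_b) else sum(mins_b * wb) / sum(wb)
  (da + db) / 2
}

new_null_model_result <- function(metric, observed, null_values, n_null, seed,
                                  threshold = 2) {
  null_mean <- mean(null_values)
  null_sd <- stats::sd(null_values)
  degenerate <- !is.finite(null_sd) || null_sd <= 1e-12 * max(1, abs(null_mean))
  z <- if (degenerate) 0
  else if (metric == "NTI") (null_mean - observed) / null_sd
  else (observed - null_mean) / null_sd
  structure(list(metric = metric, observed = observed, null_mean = null_mean,
                 null_sd = if (degenerate) 0 else null_sd, z = z,
                 n_null = n_null, degenerate = degenerate, seed = seed,
                 threshold = threshold,
                 call = classify_assembly(z, metric, threshold, degenerate)),
            class = "null_model_result")
}

#' @export
print.null_model_result <- function(x, ...) {
  cat(sprintf("%s: observed=%.4g null=%.4g+/-%.4g z=%.3f call=%s%s\n",
              x$metric, x$observed, x$null_mean, x$null_sd, x$z, x$call,
              if (x$degenerate) " (degenerate null)" else ""))
  invisible(x)
}

#' Classify an assembly process from a standardized deviate
#'
#' Uses the conventional two-standard-deviation cut with strict inequality:
#' `|z|` exactly at the threshold is stochastic. NTI > threshold means
#' phylogenetic clustering, NTI < -threshold overdispersion; bNTI > threshold
#' heterogeneous selection, bNTI < -threshold homogeneous selection.
#'
#' @param z standardized deviate (vectorized).
#' @param metric `"NTI"` or `"bNTI"`.
#' @param threshold positive cutoff, default 2.
#' @param degenerate logical (vectorized); degenerate nulls are stochastic.
#' @return character vector of calls.
#' @export
classify_assembly <- function(z, metric = c("NTI", "bNTI"), threshold = 2,
                              degenerate = FALSE) {
  metric <- match.arg(metric)
  hi <- if (metric == "NTI") "clustered" else "heterogeneous_selection"
  lo <- if (metric == "NTI") "dispersed" else "homogeneous_selection"
  out <- ifelse(z > threshold, hi, ifelse(z < -threshold, lo, "stochastic"))
  out[degenerate | !is.finite(z)] <- "stochastic"
  out
}

#' Nearest taxon index (NTI) of one community against a tip-shuffle null
#'
#' The metacommunity is the full tip set of the dataset's tree. Each null
#' replicate permutes all tip labels of the cophenetic distance matrix
#' uniformly at random (the "taxa.labels" shuffle) and recomputes MNTD for
#' the same community. The index is
#' `z = (null_mean - observed) / null_sd`, so positive values mean the
#' community is more phylogenetically clustered than expected by chance and
#' `z > 2` is read as significant clustering.
#'
#' @param sample a sample id present in `dataset`, or a named abundance
#'   vector over the dataset's taxa.
#' @param dataset a `"community_dataset"`.
#' @param n_null number of null replicates (default 1000).
#' @param weighted abundance-weight the MNTD (default `FALSE`,
#'   presence/absence as in `picante::ses.mntd`'s default).
#' @param seed integer seed for the null stream.
#' @param threshold classification cutoff (default 2).
#' @param dist optional precomputed cophenetic matrix (tip order must match
#'   `dataset$tree`); avoids recomputation in loops.
#' @return a `"null_model_result"` with fields `observed`, `null_mean`,
#'   `null_sd`, `z`, `n_null`, `degenerate`, `seed`, `call`.
#' @export
nti <- function(sample, dataset, n_null = 1000, weighted = FALSE,
                seed = 1L, threshold = 2, dist = NULL) {
  if (is.character(sample) && length(sample) == 1) {
    if (!sample %in% rownames(dataset$table))
      stop("unknown sample: ", sample)
    sample <- dataset$table[sample, ]
  }
  dist <- dist %||% cophenetic_distances(dataset$tree)
  taxa <- names(sample)[sample > 0]
  if (length(taxa) < 2) stop("NTI needs a community with >= 2 taxa")
  idx <- match(taxa, rownames(dist))
  if (anyNA(idx)) stop("community taxa absent from metacommunity tree")
  w <- if (weighted) unname(sample[taxa]) else NULL
  observed <- mntd_idx(idx, dist, w)
  n <- nrow(dist)
  null_values <- with_seed(seed, {
    vapply(seq_len(n_null), function(r) {
      perm <- sample.int(n)
      mntd_idx(perm[idx], dist, w)
    }, numeric(1))
  })
  new_null_model_result("NTI", observed, null_values, n_null, seed, threshold)
}

#' NTI for every sample of a dataset
#'
#' Per-sample seeds are derived from the master seed by hashing the sample
#' id, so results are independent of evaluation order.
#'
#' @inheritParams nti
#' @param min_taxa samples with fewer present taxa are skipped with a warning.
#' @return a data.frame with one row per evaluated sample: `sample`,
#'   `observed`, `null_mean`, `null_sd`, `z`, `degenerate`, `call`.
#' @export
nti_all <- function(dataset, n_null = 1000, weighted = FALSE, seed = 1L,
                    threshold = 2, min_taxa = 2) {
  dist <- cophenetic_distances(dataset$tree)
  keep <- rownames(dataset$table)[richness(dataset$table) >= min_taxa]
  skipped <- setdiff(rownames(dataset$table), keep)
  if (length(skipped) > 0)
    warning("skipping samples with < ", min_taxa, " taxa: ",
            paste(skipped, collapse = ", "))
  rows <- lapply(keep, function(s) {
    r <- nti(dataset$table[s, ], dataset, n_null = n_null, weighted = weighted,
             seed = sub_seed(seed, "nti", s), threshold = threshold, dist = dist)
    data.frame(sample = s, observed = r$observed, null_mean = r$null_mean,
               null_sd = r$null_sd, z = r$z, degenerate = r$degenerate,
               call = r$call, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Beta nearest taxon index (bNTI) between two communities
#'
#' Null replicates permute all metacommunity tip labels (both communities are
#' mapped through the same permutation) and recompute betaMNTD. The index is
#' `z = (observed - null_mean) / null_sd`: `z > 2` means the two communities
#' share significantly fewer / more phylogenetically dispersed taxa than
#' expected (heterogeneous selection), `z < -2` homogeneous selection.
#'
#' @param sample_a,sample_b sample ids or named abundance vectors.
#' @param dataset a `"community_dataset"`.
#' @param n_null number of null replicates (default 1000).
#' @param weighted abundance-weight betaMNTD (default `TRUE`, the convention
#'   of the turnover literature).
#' @param seed integer seed.
#' @param threshold classification cutoff (default 2).
#' @param dist optional precomputed cophenetic matrix.
#' @return a `"null_model_result"` with metric `"bNTI"`.
#' @export
bnti <- function(sample_a, sample_b, dataset, n_null = 1000, weighted = TRUE,
                 seed = 1L, threshold = 2, dist = NULL) {
  get_vec <- function(s) {
    if (is.character(s) && length(s) == 1) {
      if (!s %in% rownames(dataset$table)) stop("unknown sample: ", s)
      dataset$table[s, ]
    } else s
  }
  x <- get_vec(sample_a); y <- get_vec(sample_b)
  dist <- dist %||% cophenetic_distances(dataset$tree)
  ta <- names(x)[x > 0]; tb <- names(y)[y > 0]
  if (length(ta) == 0 || length(tb) == 0) stop("empty community")
  ia <- match(ta, rownames(dist)); ib <- match(tb, rownames(dist))
  if (anyNA(ia) || anyNA(ib)) stop("community taxa absent from metacommunity tree")
  wa <- if (weighted) unname(x[ta]) else NULL
  wb <- if (weighted) unname(y[tb]) else NULL
  observed <- bmntd_idx(ia, ib, dist, wa, wb)
  n <- nrow(dist)
  null_values <- with_seed(seed, {
    vapply(seq_len(n_null), function(r) {
      perm <- sample.int(n)
      bmntd_idx(perm[ia], perm[ib], dist, wa, wb)
    }, numeric(1))
  })
  new_null_model_result("bNTI", observed, null_values, n_null, seed, threshold)
}

#' bNTI for all within-group sample pairs
#'
#' Samples are grouped by the interaction of one or more categorical metadata
#' variables; every unordered pair of samples within a group is evaluated and
#' between-group pairs are excluded. Per-pair seeds are derived by hashing
#' the (sorted) pair of sample ids, so the result set does not depend on
#' sample order. Groups of size 1 contribute no pairs.
#'
#' @param dataset a `"community_dataset"`.
#' @param group_by character vector of metadata variable names; `NULL` treats
#'   all samples as one group.
#' @inheritParams bnti
#' @return a data.frame with one row per pair: `sample_a`, `sample_b`,
#'   `group`, `observed`, `null_mean`, `null_sd`, `z`, `degenerate`, `call`.
#' @export
bnti_group <- function(dataset, group_by = NULL, n_null = 1000, weighted = TRUE,
                       seed = 1L, threshold = 2) {
  md <- dataset$metadata
  if (is.null(group_by)) {
    grp <- rep("all", nrow(md))
  } else {
    missing_vars <- setdiff(group_by, names(md))
    if (length(missing_vars) > 0)
      stop("unknown metadata variables: ", paste(missing_vars, collapse = ", "))
    grp <- do.call(paste, c(md[group_by], sep = "/"))
  }
  dist <- cophenetic_distances(dataset$tree)
  rows <- list()
  for (g in unique(grp)) {
    ids <- sort(md$sample_id[grp == g])
    if (length(ids) < 2) next
    for (i in seq_len(length(ids) - 1)) for (j in seq(i + 1, length(ids))) {
      a <- ids[i]; b <- ids[j]
      r <- bnti(a, b, dataset, n_null = n_null, weighted = weighted,
                seed = sub_seed(seed, "bnti", a, b), threshold = threshold,
                dist = dist)
      rows[[length(rows) + 1]] <-
        data.frame(sample_a = a, sample_b = b, group = g,
                   observed = r$observed, null_mean = r$null_mean,
                   null_sd = r$null_sd, z = r$z, degenerate = r$degenerate,
                   call = r$call, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(sample_a = character(), sample_b = character(),
                      group = character(), observed = numeric(),
                      null_mean = numeric(), null_sd = numeric(),
                      z = numeric(), degenerate = logical(),
                      call = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
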