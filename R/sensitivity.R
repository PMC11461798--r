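#' Cross-tabulate assembly conclusions before vs after a perturbation
#'
#' Counts, within each group, how often each (before, after) pair of
#' classifications occurred, with percentages relative to the group and to
#' the total, and the per-group percentage of units whose conclusion changed.
#' Percentages are reported to one decimal place.
#'
#' @param call_before,call_after character vectors of classifications for the
#'   same units, in the same order.
#' @param group optional grouping vector (e.g. sample type); default one
#'   group.
#' @return list of class `"conclusion_change_table"` with `cells`
#'   (data.frame: `group`, `call_before`, `call_after`, `n`, `pct_of_group`,
#'   `pct_of_total`) and `summary` (data.frame: `group`, `n_units`,
#'   `n_changed`, `pct_changed`).
#' @export
conclusion_change_table <- function(call_before, call_after, group = NULL) {
  stopifnot(length(call_before) == length(call_after))
  if (is.null(group)) group <- rep("all", length(call_before))
  stopifnot(length(group) == length(call_before))
  total <- length(call_before)
  df <- data.frame(group = as.character(group),
                   call_before = as.character(call_before),
                   call_after = as.character(call_after),
                   stringsAsFactors = FALSE)
  agg <- stats::aggregate(list(n = rep(1L, nrow(df))),
                          by = df[c("group", "call_before", "call_after")],
                          FUN = sum)
  gsize <- table(df$group)
  agg$pct_of_group <- round(100 * agg$n / as.integer(gsize[agg$group]), 1)
  agg$pct_of_total <- round(100 * agg$n / total, 1)
  agg <- agg[order(agg$group, -agg$n), ]
  rownames(agg) <- NULL
  changed <- df$call_before != df$call_after
  sm <- stats::aggregate(list(n_changed = changed),
                         by = df["group"], FUN = sum)
  sm$n_units <- as.integer(gsize[sm$group])
  sm$pct_changed <- round(100 * sm$n_changed / sm$n_units, 1)
  sm <- sm[, c("group", "n_units", "n_changed", "pct_changed")]
  structure(list(cells = agg, summary = sm),
            class = "conclusion_change_table")
}

#' @export
print.conclusion_change_table <- function(x, ...) {
  cat("Conclusion changes by group:\n")
  print(x$summary, row.names = FALSE)
  cat("\nCells:\n")
  print(x$cells, row.names = FALSE)
  invisible(x)
}

#' Full outlier-removal impact experiment
#'
#' Runs the complete audit protocol on one dataset: flag long-branch tips,
#' remove them, quantify per-sample compositional impact (Bray-Curtis,
#' Sorensen, weighted/unweighted UniFrac), recompute NTI (and optionally
#' bNTI) on the full and outlier-free datasets with identical per-unit
#' seeds, and tabulate how assembly conclusions changed. Because seeds are
#' shared, the per-unit deltas reflect the perturbation rather than
#' Monte-Carlo noise; with zero flagged tips all deltas are exactly 0.
#'
#' @param dataset a `"community_dataset"`.
#' @param method,threshold,max_iter passed to [audit_tree()].
#' @param n_null null replicates per unit.
#' @param weighted_nti,weighted_bnti weighting flags for the two indices.
#' @param bnti_group_by metadata variables defining within-group pairs for
#'   bNTI; `NULL` skips bNTI.
#' @param group_var metadata variable used to group the change tables
#'   (e.g. `"sample_type"`); `NULL` pools all units.
#' @param seed master seed.
#' @return list with `report` (outlier report), `removal` (per-sample removed
#'   abundance), `similarity` (from [compare_datasets()]), `nti` (list:
#'   `before`, `after`, `delta`), `bnti` (or `NULL`), and `change_tables`
#'   (per metric).
#' @export
outlier_impact <- function(dataset, method = "terminal_mad", threshold = 5,
                           max_iter = 1, n_null = 1000, weighted_nti = FALSE,
                           weighted_bnti = TRUE, bnti_group_by = NULL,
                           group_var = NULL, seed = 1L) {
  report <- audit_tree(dataset$tree, method = method, threshold = threshold,
                       max_iter = max_iter)
  flagged <- report$tip[report$flagged]
  rem <- remove_outliers(dataset, flagged)
  similarity <- if (length(flagged) > 0)
    compare_datasets(dataset, rem$dataset) else NULL

  grp_of <- function(samples) {
    if (is.null(group_var)) rep("all", length(samples))
    else dataset$metadata[[group_var]][match(samples, dataset$metadata$sample_id)]
  }

  nti_before <- nti_all(dataset, n_null = n_null, weighted = weighted_nti,
                        seed = seed)
  nti_after <- nti_all(rem$dataset, n_null = n_null, weighted = weighted_nti,
                       seed = seed)
  nd <- merge(nti_before[, c("sample", "z", "degenerate", "call")],
              nti_after[, c("sample", "z", "degenerate", "call")],
              by = "sample", suffixes = c("_before", "_after"))
  nd$delta <- nd$z_after - nd$z_before
  nd$metric <- "NTI"
  tables <- list(nti = conclusion_change_table(nd$call_before, nd$call_after,
                                               grp_of(nd$sample)))

  bn <- NULL
  if (!is.null(bnti_group_by)) {
    b_before <- bnti_group(dataset, group_by = bnti_group_by, n_null = n_null,
                           weighted = weighted_bnti, seed = seed)
    b_after <- bnti_group(rem$dataset, group_by = bnti_group_by,
                          n_null = n_null, weighted = weighted_bnti,
                          seed = seed)
    bn <- merge(b_before[, c("sample_a", "sample_b", "group", "z", "call")],
                b_after[, c("sample_a", "sample_b", "z", "call")],
                by = c("sample_a", "sample_b"),
                suffixes = c("_before", "_after"))
    bn$delta <- bn$z_after - bn$z_before
    bn$metric <- "bNTI"
    tables$bnti <- conclusion_change_table(bn$call_before, bn$call_after,
                                           bn$group)
  }

  list(report = report, removal = rem$summary, similarity = similarity,
       nti = list(before = nti_before, after = nti_after, delta = nd),
       bnti = bn, change_tables = tables)
}

#' Subset a dataset's samples, shrinking the metacommunity accordingly
#'
#' Keeps the selected samples, drops taxa that no longer occur in any kept
#' sample, and prunes those taxa from the tree — the null-model
#' metacommunity of the subset is exactly the taxa observed in the kept
#' samples.
#'
#' @param dataset a `"community_dataset"`.
#' @param keep sample ids (character), a logical vector over the dataset's
#'   samples, or a predicate `function(metadata) -> logical`.
#' @return a `"community_dataset"`; attribute `"subset"` records
#'   `dropped_samples`, `dropped_taxa` and the fraction of regional taxa
#'   lost.
#' @export
metacommunity_subset <- function(dataset, keep) {
  samples <- rownames(dataset$table)
  keep_ids <- if (is.function(keep)) {
    samples[keep(dataset$metadata)]
  } else if (is.logical(keep)) {
    stopifnot(length(keep) == length(samples))
    samples[keep]
  } else {
    unknown <- setdiff(keep, samples)
    if (length(unknown) > 0)
      stop("unknown samples: ", paste(unknown, collapse = ", "))
    intersect(samples, keep)
  }
  if (length(keep_ids) < 2)
    stop("subset must keep >= 2 samples (kept ", length(keep_ids), ")")
  tab <- dataset$table[keep_ids, , drop = FALSE]
  gone <- colnames(tab)[colSums(tab) == 0]
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  tree <- if (length(gone) > 0) ape::drop.tip(dataset$tree, gone) else dataset$tree
  md <- dataset$metadata[dataset$metadata$sample_id %in% keep_ids, , drop = FALSE]
  out <- community_dataset(tab, tree, md)
  attr(out, "subset") <- list(dropped_samples = setdiff(samples, keep_ids),
                              dropped_taxa = gone,
                              taxa_loss_fraction =
                                length(gone) / ncol(dataset$table))
  out
}

#' Metacommunity-richness impact experiment
#'
#' Evaluates NTI (and optionally bNTI) for the samples of each subset under
#' the subset's reduced metacommunity, with the same per-unit seeds as under
#' the full metacommunity, and reports deltas (subset minus full) and
#' conclusion-change tables. This is the robustness protocol of reanalysing
#' a dataset under progressively poorer regional pools.
#'
#' @param dataset the full `"community_dataset"` (reference metacommunity).
#' @param subsets named list of `keep` selections for
#'   [metacommunity_subset()].
#' @param n_null,weighted_nti,weighted_bnti,bnti_group_by,group_var,seed as
#'   in [outlier_impact()].
#' @return list with `full` (reference NTI/bNTI tables) and, per subset, a
#'   list `nti_delta`, `bnti_delta` (or `NULL`), `change_tables`,
#'   `taxa_loss_fraction`.
#' @export
richness_impact <- function(dataset, subsets, n_null = 1000,
                            weighted_nti = FALSE, weighted_bnti = TRUE,
                            bnti_group_by = NULL, group_var = NULL,
                            seed = 1L) {
  stopifnot(is.list(subsets), length(names(subsets)) == length(subsets))
  nti_full <- nti_all(dataset, n_null = n_null, weighted = weighted_nti,
                      seed = seed)
  bnti_full <- if (!is.null(bnti_group_by))
    bnti_group(dataset, group_by = bnti_group_by, n_null = n_null,
               weighted = weighted_bnti, seed = seed) else NULL
  grp_of <- function(samples) {
    if (is.null(group_var)) rep("all", length(samples))
    else dataset$metadata[[group_var]][match(samples, dataset$metadata$sample_id)]
  }
  out <- list(full = list(nti = nti_full, bnti = bnti_full), subsets = list())
  for (nm in names(subsets)) {
    ds_k <- metacommunity_subset(dataset, subsets[[nm]])
    nti_k <- nti_all(ds_k, n_null = n_null, weighted = weighted_nti,
                     seed = seed)
    nd <- merge(nti_full[, c("sample", "z", "call")],
                nti_k[, c("sample", "z", "call")],
                by = "sample", suffixes = c("_before", "_after"))
    nd$delta <- nd$z_after - nd$z_before
    nd$metric <- "NTI"
    tables <- list(nti = conclusion_change_table(nd$call_before, nd$call_after,
                                                 grp_of(nd$sample)))
    bd <- NULL
    if (!is.null(bnti_group_by)) {
      b_k <- bnti_group(ds_k, group_by = bnti_group_by, n_null = n_null,
                        weighted = weighted_bnti, seed = seed)
      bd <- merge(bnti_full[, c("sample_a", "sample_b", "group", "z", "call")],
                  b_k[, c("sample_a", "sample_b", "z", "call")],
                  by = c("sample_a", "sample_b"),
                  suffixes = c("_before", "_after"))
      bd$delta <- bd$z_after - bd$z_before
      bd$metric <- "bNTI"
      tables$bnti <- conclusion_change_table(bd$call_before, bd$call_after,
                                             bd$group)
    }
    out$subsets[[nm]] <- list(nti_delta = nd, bnti_delta = bd,
                              change_tables = tables,
                              taxa_loss_fraction =
                                attr(ds_k, "subset")$taxa_loss_fraction)
  }
  out
}
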