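#' One-hot encode categorical sample metadata
#'
#' Each categorical variable with k levels becomes k indicator columns named
#' `variable.level`; row sums within a variable's block are 1. One-hot
#' encoding is what makes an abundance-weighted mean of categorical
#' environmental variables well-defined.
#'
#' @param metadata data.frame with a `sample_id` column.
#' @param variables character vector of metadata variable names.
#' @return numeric matrix, samples as rows (named by `sample_id`).
#' @export
encode_metadata <- function(metadata, variables) {
  missing_vars <- setdiff(variables, names(metadata))
  if (length(missing_vars) > 0)
    stop("unknown metadata variables: ", paste(missing_vars, collapse = ", "))
  blocks <- lapply(variables, function(v) {
    vals <- as.character(metadata[[v]])
    levs <- sort(unique(vals))
    if (length(levs) < 2)
      stop("variable has a single level across samples: ", v)
    m <- vapply(levs, function(l) as.numeric(vals == l),
                numeric(length(vals)))
    colnames(m) <- paste(v, levs, sep = ".")
    m
  })
  out <- do.call(cbind, blocks)
  rownames(out) <- metadata$sample_id
  out
}

#' Abundance-weighted environmental optima of taxa
#'
#' The optimum of a taxon along each encoded environmental dimension is the
#' mean of that dimension over samples, weighted by the taxon's relative
#' abundance in each sample. Taxa with zero total abundance are excluded.
#'
#' @param table samples-by-taxa matrix.
#' @param encoded sample-by-dimension matrix from [encode_metadata()] (rows
#'   must cover all samples of `table`).
#' @return taxa-by-dimension numeric matrix.
#' @export
taxon_optima <- function(table, encoded) {
  miss <- setdiff(rownames(table), rownames(encoded))
  if (length(miss) > 0)
    stop("samples without encoded metadata: ", paste(miss, collapse = ", "))
  enc <- encoded[rownames(table), , drop = FALSE]
  rel <- table / rowSums(table)
  keep <- colSums(table) > 0
  rel <- rel[, keep, drop = FALSE]
  w <- t(rel) %*% enc            # taxon x dim, weighted sums
  sweep(w, 1, colSums(rel), "/") # divide by each taxon's total weight
}

#' Mantel correlogram between trait (optima) distances and phylogenetic distances
#'
#' Phylogenetic distances are divided by their maximum before binning, then
#' [vegan::mantel.correlog()] evaluates a Mantel correlation per distance
#' class with permutation tests, progressive testing, and Holm correction —
#' the construction used to test for phylogenetic signal before interpreting
#' nearest-taxon null models.
#'
#' @param optima_dist `dist` or symmetric matrix of between-taxon distances
#'   in environmental-optimum space (e.g. Euclidean on [taxon_optima()]).
#' @param phylo_dist `dist` or symmetric matrix of cophenetic distances over
#'   the same taxa, in the same order.
#' @param n_classes number of distance classes; `NULL` uses Sturges' rule on
#'   the number of taxon pairs (the vegan default).
#' @param n_perm permutations per class (default 1000).
#' @param seed integer seed for the permutation stream.
#' @return data.frame of class `"correlogram_result"`: `class_index`,
#'   `class_midpoint` (on the max-normalized phylogenetic-distance scale),
#'   `mantel_r`, `n_pairs_in_class`, `p_raw`, `p_holm` (untested classes have
#'   `NA` p-values); attributes `n_permutations` and `seed`.
#' @export
mantel_correlogram <- function(optima_dist, phylo_dist, n_classes = NULL,
                               n_perm = 1000, seed = 1L) {
  d_eco <- stats::as.dist(optima_dist)
  d_phy <- stats::as.dist(phylo_dist)
  if (length(d_eco) != length(d_phy))
    stop("distance matrices cover different numbers of taxa")
  mx <- max(d_phy)
  if (mx <= 0) stop("phylogenetic distances are all zero")
  d_phy <- d_phy / mx
  res <- with_seed(seed,
    vegan::mantel.correlog(d_eco, D.geo = d_phy,
                           n.class = if (is.null(n_classes)) 0 else n_classes,
                           nperm = n_perm, mult = "holm",
                           progressive = TRUE))
  m <- res$mantel.res
  out <- data.frame(class_index = seq_len(nrow(m)),
                    class_midpoint = m[, "class.index"],
                    mantel_r = m[, "Mantel.cor"],
                    n_pairs_in_class = as.integer(m[, "n.dist"] / 2),
                    p_raw = m[, "Pr(Mantel)"],
                    p_holm = m[, "Pr(corrected)"],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, n_permutations = n_perm, seed = seed,
            class = c("correlogram_result", "data.frame"))
}

#' Test a dataset for phylogenetic signal in environmental preference
#'
#' Computes abundance-weighted environmental optima for the given categorical
#' variables, Euclidean distances between taxon optima, and a Mantel
#' correlogram against max-normalized cophenetic distances. A phylogenetic
#' signal is declared when at least one of the shortest third of the distance
#' classes has a significantly positive Mantel correlation after Holm
#' correction — i.e. closely related taxa occupy similar environments, the
#' precondition for interpreting NTI/bNTI.
#'
#' @param dataset a `"community_dataset"` with >= 2 samples.
#' @param variables metadata variable names to encode.
#' @param n_classes,n_perm,seed passed to [mantel_correlogram()].
#' @param alpha significance level on Holm-corrected p-values (default 0.05).
#' @return list with `signal` (logical), `correlogram` (the
#'   `"correlogram_result"`), and `optima`.
#' @export
signal_check <- function(dataset, variables, n_classes = NULL, n_perm = 1000,
                         seed = 1L, alpha = 0.05) {
  if (nrow(dataset$table) < 2)
    stop("phylogenetic-signal testing needs >= 2 samples for environmental contrast")
  enc <- encode_metadata(dataset$metadata, variables)
  opt <- taxon_optima(dataset$table, enc)
  d_opt <- stats::dist(opt)
  d_phy <- stats::as.dist(cophenetic_distances(dataset$tree)[rownames(opt),
                                                             rownames(opt)])
  cg <- mantel_correlogram(d_opt, d_phy, n_classes = n_classes,
                           n_perm = n_perm, seed = seed)
  k <- ceiling(nrow(cg) / 3)
  short <- cg[seq_len(k), ]
  hit <- !is.na(short$p_holm) & short$p_holm <= alpha & short$mantel_r > 0
  list(signal = any(hit), correlogram = cg, optima = opt)
}
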