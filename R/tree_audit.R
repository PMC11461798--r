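#' Per-tip branch metrics
#'
#' For every tip, the length of its pendant (terminal) edge and its
#' root-to-tip path distance. Misclassified (non-target) sequences typically
#' stand out as tips whose terminal branch is many-fold longer than the bulk.
#'
#' @param tree a `"phylo"` object.
#' @return data.frame with columns `tip`, `terminal_length`, `root_to_tip`,
#'   ordered as `tree$tip.label`.
#' @export
branch_metrics <- function(tree) {
  validate_tree(tree)
  ntip <- length(tree$tip.label)
  tip_edge <- match(seq_len(ntip), tree$edge[, 2])
  data.frame(tip = tree$tip.label,
             terminal_length = tree$edge.length[tip_edge],
             root_to_tip = ape::node.depth.edgelength(tree)[seq_len(ntip)],
             stringsAsFactors = FALSE)
}

#' Score tips for long-branch outliers with a robust deviate
#'
#' Standardizes the chosen branch metric as
#' `score = (value - median) / (1.4826 * MAD)` and flags tips whose score
#' exceeds `threshold` (one-sided: only unusually long branches are
#' suspects). If the MAD is zero the scale falls back to the normalized
#' interquartile range (IQR / 1.349); if that is also zero all scores are 0
#' and nothing is flagged.
#'
#' @param tree a `"phylo"` object with at least 4 tips, or a data.frame from
#'   [branch_metrics()].
#' @param method `"terminal_mad"` (score the pendant edge length, default) or
#'   `"root_to_tip_mad"`.
#' @param threshold robust-score cutoff, default 5.
#' @return an `"outlier_report"`: data.frame with `tip`, `terminal_length`,
#'   `root_to_tip`, `score`, `flagged`; attributes `method` and `threshold`.
#' @export
score_outliers <- function(tree, method = c("terminal_mad", "root_to_tip_mad"),
                           threshold = 5) {
  method <- match.arg(method)
  metrics <- if (is.data.frame(tree)) tree else branch_metrics(tree)
  if (nrow(metrics) < 4)
    stop("outlier scoring needs >= 4 tips for a meaningful robust scale")
  x <- if (method == "terminal_mad") metrics$terminal_length else metrics$root_to_tip
  med <- stats::median(x)
  scale <- stats::mad(x)  # already normalized by 1.4826
  if (scale == 0) scale <- stats::IQR(x) / 1.349
  if (scale == 0) {
    metrics$score <- rep(0, nrow(metrics))
  } else {
    metrics$score <- (x - med) / scale
  }
  metrics$flagged <- metrics$score > threshold
  structure(metrics, method = method, threshold = threshold,
            class = c("outlier_report", "data.frame"))
}

#' Audit a tree for long-branch outliers, optionally iteratively
#'
#' Runs [score_outliers()]; with `max_iter > 1` the flagged tips are removed
#' and the remainder re-scored, which can unmask secondary outliers whose
#' scores were shrunk by more extreme ones. The returned report covers all
#' tips of the input tree, with flags accumulated over iterations (scores are
#' from the iteration in which each tip was last scored).
#'
#' @inheritParams score_outliers
#' @param max_iter maximum screening passes, default 1.
#' @return an `"outlier_report"`; attribute `iterations` gives the number of
#'   passes that flagged at least one tip (plus the final clean pass).
#' @export
audit_tree <- function(tree, method = c("terminal_mad", "root_to_tip_mad"),
                       threshold = 5, max_iter = 1) {
  method <- match.arg(method)
  validate_tree(tree)
  current <- tree
  report <- score_outliers(current, method, threshold)
  flagged_all <- report$tip[report$flagged]
  iter <- 1
  while (iter < max_iter && length(flagged_all) > 0 &&
         length(current$tip.label) - sum(report$flagged) >= 4) {
    current <- ape::drop.tip(current, report$tip[report$flagged])
    rescore <- score_outliers(current, method, threshold)
    newly <- rescore$tip[rescore$flagged]
    idx <- match(rescore$tip, report$tip)
    report$score[idx] <- rescore$score
    report$flagged[idx] <- rescore$flagged
    if (length(newly) == 0) break
    flagged_all <- union(flagged_all, newly)
    iter <- iter + 1
  }
  report$flagged <- report$tip %in% flagged_all
  attr(report, "iterations") <- iter
  report
}

#' Remove flagged tips from a dataset
#'
#' Prunes the flagged tips from the tree and drops the corresponding taxa
#' from the abundance table; samples are kept. The summary records, per
#' sample, the relative abundance held by the removed taxa (the quantity that
#' bounds how much compositional metrics can change).
#'
#' @param dataset a `"community_dataset"`.
#' @param flagged character vector of tip labels to remove (subset of the
#'   tree's tips).
#' @return list with `dataset` (the filtered `"community_dataset"`) and
#'   `summary` (data.frame: `sample`, `removed_abundance_fraction`,
#'   `removed_taxa_present`).
#' @export
remove_outliers <- function(dataset, flagged) {
  flagged <- unique(as.character(flagged))
  unknown <- setdiff(flagged, dataset$tree$tip.label)
  if (length(unknown) > 0)
    stop("flagged tips not in tree: ", paste(unknown, collapse = ", "))
  tab <- dataset$table
  removed <- intersect(colnames(tab), flagged)
  frac <- if (length(removed) > 0)
    rowSums(tab[, removed, drop = FALSE]) / rowSums(tab) else
    rep(0, nrow(tab))
  n_present <- if (length(removed) > 0)
    rowSums(tab[, removed, drop = FALSE] > 0) else rep(0L, nrow(tab))
  summary <- data.frame(sample = rownames(tab),
                        removed_abundance_fraction = unname(frac),
                        removed_taxa_present = unname(n_present),
                        stringsAsFactors = FALSE)
  if (length(flagged) == 0)
    return(list(dataset = dataset, summary = summary))
  emptied <- rownames(tab)[rowSums(tab[, setdiff(colnames(tab), removed),
                                       drop = FALSE]) == 0]
  if (length(emptied) > 0)
    stop("removal would empty samples: ", paste(emptied, collapse = ", "))
  new_tree <- ape::drop.tip(dataset$tree, flagged)
  new_tab <- tab[, setdiff(colnames(tab), removed), drop = FALSE]
  list(dataset = community_dataset(new_tab, new_tree, dataset$metadata),
       summary = summary)
}

#' Export the sequences of flagged tips to FASTA
#'
#' Writes the records of the flagged tips (headers preserved) so they can be
#' checked against a reference database (e.g. a nucleotide BLAST search)
#' outside the package.
#'
#' @param flagged character vector of tip labels.
#' @param sequences a named `Biostrings::XStringSet`-like object, a named
#'   character vector of sequences, or a path to a FASTA file.
#' @param path output FASTA path.
#' @return `path`, invisibly; zero flagged tips produce an empty file with a
#'   warning.
#' @export
export_suspects <- function(flagged, sequences, path) {
  flagged <- unique(as.character(flagged))
  if (is.character(sequences) && length(sequences) == 1 &&
      file.exists(sequences) && is.null(names(sequences))) {
    sequences <- Biostrings::readBStringSet(sequences)
  } else if (is.character(sequences)) {
    sequences <- Biostrings::BStringSet(sequences)
  }
  if (length(flagged) == 0) {
    warning("no flagged tips; writing empty FASTA")
    Biostrings::writeXStringSet(Biostrings::BStringSet(), path)
    return(invisible(path))
  }
  missing_seq <- setdiff(flagged, names(sequences))
  if (length(missing_seq) > 0)
    stop("no sequence record for flagged tips: ",
         paste(missing_seq, collapse = ", "))
  Biostrings::writeXStringSet(sequences[flagged], path)
  invisible(path)
}
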