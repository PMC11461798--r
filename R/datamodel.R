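#' Read a rooted phylogenetic tree from a Newick file
#'
#' Thin wrapper around [ape::read.tree()] that enforces the invariants the
#' rest of the package relies on: unique non-empty tip labels, branch lengths
#' present and non-negative (zero-length terminal branches are legal: they
#' arise when identical sequences are kept as separate taxa), and a rooted
#' topology.
#'
#' @param path path to a file containing a single Newick tree, or a Newick
#'   string passed via `text`.
#' @param text optional Newick string; when supplied `path` is ignored.
#' @return an object of class `"phylo"` (ape).
#' @export
read_newick <- function(path, text = NULL) {
  tree <- if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick input")
  if (inherits(tree, "multiPhylo")) stop("expected a single tree, got ", length(tree))
  validate_tree(tree)
  tree
}

#' Validate the tree invariants used throughout the package
#'
#' @param tree a `"phylo"` object.
#' @return the tree, invisibly; errors describe the violated invariant.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a \"phylo\" object")
  labs <- tree$tip.label
  if (any(!nzchar(labs))) stop("empty tip labels are not allowed")
  dup <- unique(labs[duplicated(labs)])
  if (length(dup) > 0)
    stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; branch lengths are required")
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0))
    stop("branch lengths must be non-negative and non-missing")
  if (all(tree$edge.length == 0))
    stop("all branch lengths are zero; at least one must be positive")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  invisible(tree)
}

#' Write a tree to Newick
#'
#' @param tree a `"phylo"` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Reroot a tree at the midpoint of its single longest branch
#'
#' A deterministic stand-in for rooting "to the longest branch": the root is
#' placed halfway along the longest edge of the tree. Ties are broken by the
#' lexicographically smallest tip label found below each candidate edge.
#'
#' @param tree a `"phylo"` object.
#' @return a rerooted `"phylo"` object.
#' @export
reroot_longest_branch <- function(tree) {
  validate_tree(tree)
  len <- tree$edge.length
  cand <- which(len == max(len))
  if (length(cand) > 1) {
    first_tip <- vapply(cand, function(e)
      min(tip_labels_below(tree, tree$edge[e, 2])), character(1))
    cand <- cand[order(first_tip)][1]
  }
  child <- tree$edge[cand, 2]
  out <- phytools::reroot(tree, node.number = child,
                          position = tree$edge.length[cand] / 2)
  validate_tree(out)
  out
}

# All tip labels descending from (and including) `node`.
tip_labels_below <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  desc <- ape::extract.clade(tree, node)$tip.label
  desc
}

#' Read a sample-by-taxon abundance table from TSV
#'
#' The file must be tab-delimited with a header row; the first column holds
#' identifiers. Counts may be raw reads or relative abundances; no internal
#' rarefaction or rescaling is applied on read.
#'
#' @param path path to the TSV file.
#' @param orientation `"samples_as_rows"` (default) or `"taxa_as_rows"`.
#' @return a numeric matrix, samples as rows, taxa as columns, with unique
#'   dimnames.
#' @export
read_community_table <- function(path,
                                 orientation = c("samples_as_rows", "taxa_as_rows")) {
  orientation <- match.arg(orientation)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  body <- df[, -1, drop = FALSE]
  non_num <- !vapply(body, is.numeric, logical(1))
  if (any(non_num))
    stop("non-numeric columns in table body: ",
         paste(names(body)[non_num], collapse = ", "))
  m <- as.matrix(body)
  rownames(m) <- ids
  if (orientation == "taxa_as_rows") m <- t(m)
  validate_community_table(m)
}

#' Validate (and return) a community table matrix
#'
#' @param m numeric matrix, samples as rows, taxa as columns.
#' @return the matrix, invisibly coerced to double.
#' @export
validate_community_table <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop("community table must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("community table must have sample (row) and taxon (column) names")
  if (anyDuplicated(rownames(m)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  if (anyDuplicated(colnames(m)))
    stop("duplicate taxon ids: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  if (anyNA(m) || any(m < 0)) stop("counts must be non-negative and non-missing")
  empty <- rownames(m)[rowSums(m) == 0]
  if (length(empty) > 0)
    stop("all-zero sample rows: ", paste(empty, collapse = ", "))
  storage.mode(m) <- "double"
  m
}

#' Write a community table as dense TSV (BIOM-convertible)
#'
#' @param m samples-by-taxa matrix.
#' @param path output path.
#' @param orientation orientation of the written file.
#' @return `path`, invisibly.
#' @export
write_community_table <- function(m, path,
                                  orientation = c("samples_as_rows", "taxa_as_rows")) {
  orientation <- match.arg(orientation)
  out <- if (orientation == "taxa_as_rows") t(m) else m
  id_name <- if (orientation == "taxa_as_rows") "taxon_id" else "sample_id"
  df <- data.frame(rownames(out), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata (categorical variables) from TSV
#'
#' @param path TSV with a `sample_id` column (or the first column taken as
#'   the sample id) and one column per categorical variable.
#' @return a data.frame with a `sample_id` character column; all other
#'   columns are character.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) names(df)[1] <- "sample_id"
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in metadata")
  for (v in setdiff(names(df), "sample_id")) df[[v]] <- as.character(df[[v]])
  df
}

#' Bundle a table, tree and metadata into a consistent dataset
#'
#' Constructs the central container used by all downstream analyses. After
#' construction the taxa of the table and the tips of the tree are in strict
#' bijection, and every sample has a metadata row.
#'
#' @param table samples-by-taxa numeric matrix.
#' @param tree `"phylo"` object whose tip labels match the table's taxa.
#' @param metadata data.frame with a `sample_id` column covering all samples;
#'   if `NULL` a minimal metadata frame is created.
#' @return an object of class `"community_dataset"` with elements `table`,
#'   `tree`, `metadata`.
#' @export
community_dataset <- function(table, tree, metadata = NULL) {
  table <- validate_community_table(table)
  validate_tree(tree)
  if (is.null(metadata))
    metadata <- data.frame(sample_id = rownames(table),
                           stringsAsFactors = FALSE)
  miss_tab <- setdiff(colnames(table), tree$tip.label)
  miss_tree <- setdiff(tree$tip.label, colnames(table))
  if (length(miss_tab) > 0 || length(miss_tree) > 0)
    stop("taxon/tip mismatch: ",
         length(miss_tab), " taxa missing from tree, ",
         length(miss_tree), " tips missing from table")
  miss_meta <- setdiff(rownames(table), metadata$sample_id)
  if (length(miss_meta) > 0)
    stop("samples without metadata: ", paste(miss_meta, collapse = ", "))
  metadata <- metadata[match(rownames(table), metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  structure(list(table = table, tree = tree, metadata = metadata),
            class = "community_dataset")
}

#' @export
print.community_dataset <- function(x, ...) {
  cat("community_dataset:", nrow(x$table), "samples x", ncol(x$table), "taxa\n")
  vars <- setdiff(names(x$metadata), "sample_id")
  if (length(vars) > 0)
    cat("metadata variables:", paste(vars, collapse = ", "), "\n")
  invisible(x)
}

#' Align a table, tree and metadata into a dataset
#'
#' Under `policy = "strict"` any taxon/tip mismatch is an error naming the
#' orphans. Under `policy = "prune"`, tree tips absent from the table are
#' dropped from the tree and table taxa absent from the tree are dropped from
#' the table; both sets are reported in the `"alignment"` attribute.
#'
#' @param table samples-by-taxa matrix.
#' @param tree `"phylo"` object.
#' @param metadata optional metadata data.frame.
#' @param policy `"strict"` or `"prune"`.
#' @return a `"community_dataset"`; attribute `"alignment"` lists
#'   `pruned_tips` and `dropped_taxa`.
#' @export
align_dataset <- function(table, tree, metadata = NULL,
                          policy = c("strict", "prune")) {
  policy <- match.arg(policy)
  table <- validate_community_table(table)
  validate_tree(tree)
  extra_taxa <- setdiff(colnames(table), tree$tip.label)
  extra_tips <- setdiff(tree$tip.label, colnames(table))
  if (policy == "strict") {
    if (length(extra_taxa) > 0 || length(extra_tips) > 0)
      stop("strict alignment failed; table-only taxa: [",
           paste(extra_taxa, collapse = ", "), "]; tree-only tips: [",
           paste(extra_tips, collapse = ", "), "]")
  } else {
    if (length(extra_tips) > 0) tree <- ape::drop.tip(tree, extra_tips)
    if (length(extra_taxa) > 0)
      table <- table[, setdiff(colnames(table), extra_taxa), drop = FALSE]
    table <- validate_community_table(table)
  }
  ds <- community_dataset(table, tree, metadata)
  attr(ds, "alignment") <- list(pruned_tips = extra_tips,
                                dropped_taxa = extra_taxa)
  ds
}

#' Taxon richness of a community table
#'
#' @param table samples-by-taxa matrix.
#' @param scope `"per_sample"` (taxa with count > 0 in each sample) or
#'   `"regional"` (taxa with count > 0 in at least one sample).
#' @return named integer vector (per sample) or a single integer (regional).
#' @export
richness <- function(table, scope = c("per_sample", "regional")) {
  scope <- match.arg(scope)
  if (scope == "per_sample") rowSums(table > 0)
  else sum(colSums(table) > 0)
}
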