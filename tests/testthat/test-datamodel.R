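test_that("newick parsing enforces tree invariants", {
  tr <- read_newick(text = "((t1:1,t2:1):1,t3:3);")
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("t1", "t2", "t3"))
  root <- length(tr$tip.label) + 1
  expect_equal(sum(tr$edge[, 1] == root), 2)  # root has two children

  expect_error(read_newick(text = "((t1:1,t2:1):1,t1:3);"), "duplicate")
  expect_error(read_newick(text = "((t1,t2),t3);"), "branch length")
  expect_error(validate_tree(structure(list(), class = "lm")), "phylo")
})

test_that("newick write/read round-trips topology and branch lengths", {
  for (s in 1:4) {
    tr <- random_tree(10 + s, seed = s)
    path <- withr::local_tempfile(fileext = ".nwk")
    write_newick(tr, path)
    tr2 <- read_newick(path)
    expect_setequal(tr2$tip.label, tr$tip.label)
    d1 <- cophenetic_distances(tr)
    d2 <- cophenetic_distances(tr2)[rownames(d1), colnames(d1)]
    expect_equal(d2, d1, tolerance = 1e-9)
  }
})

test_that("community table io validates and respects orientation", {
  m <- matrix(c(1, 0, 2, 5, 3, 0), nrow = 2,
              dimnames = list(c("sA", "sB"), c("t1", "t2", "t3")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_community_table(m, path)
  expect_equal(read_community_table(path), m)

  patht <- withr::local_tempfile(fileext = ".tsv")
  write_community_table(m, patht, orientation = "taxa_as_rows")
  expect_equal(read_community_table(patht, orientation = "taxa_as_rows"), m)

  bad <- m; bad["sA", ] <- 0
  expect_error(validate_community_table(bad), "sA")
  bad2 <- m; bad2[1, 1] <- -1
  expect_error(validate_community_table(bad2), "non-negative")
  pathx <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tt1\tt2", "sA\t1\tfoo", "sB\t2\t3"), pathx)
  expect_error(read_community_table(pathx), "non-numeric")
})

test_that("align_dataset prunes, errors strictly, and is idempotent", {
  tr <- random_tree(8, seed = 2)
  tab <- matrix(1, 3, 7,
                dimnames = list(paste0("s", 1:3), tr$tip.label[1:7]))
  expect_error(align_dataset(tab, tr, policy = "strict"), "t8")

  ds <- align_dataset(tab, tr, policy = "prune")
  expect_setequal(ds$tree$tip.label, colnames(tab))
  expect_equal(attr(ds, "alignment")$pruned_tips, "t8")

  tab2 <- cbind(tab, tX = 1)
  ds2 <- align_dataset(tab2, tr, policy = "prune")
  expect_equal(attr(ds2, "alignment")$dropped_taxa, "tX")
  ds3 <- align_dataset(ds2$table, ds2$tree, ds2$metadata, policy = "prune")
  expect_equal(ds3$table, ds2$table)
  expect_equal(ds3$tree$tip.label, ds2$tree$tip.label)

  full <- matrix(1, 2, 8, dimnames = list(c("a", "b"), tr$tip.label))
  expect_identical(align_dataset(full, tr, policy = "strict")$table, full)
})

test_that("richness definitions and monotonicity under removal", {
  m <- rbind(s1 = c(0, 5, 2), s2 = c(1, 0, 0))
  colnames(m) <- paste0("t", 1:3)
  expect_equal(unname(richness(m, "per_sample")), c(2, 1))
  expect_equal(richness(m, "regional"), 3)

  big <- tiny_dataset(n_tips = 20, n_samples = 6, seed = 3)$table
  r_all <- richness(big, "regional")
  for (drop in 1:3) {
    expect_lte(richness(big[-drop, , drop = FALSE], "regional"), r_all)
    expect_lte(richness(big[, -(1:drop), drop = FALSE], "regional"), r_all)
  }
})

test_that("rerooting splits the longest branch at its midpoint", {
  tr <- random_tree(10, seed = 5)
  long <- max(tr$edge.length)
  rr <- reroot_longest_branch(tr)
  expect_true(ape::is.rooted(rr))
  expect_setequal(rr$tip.label, tr$tip.label)
  root <- length(rr$tip.label) + 1
  root_edges <- rr$edge.length[rr$edge[, 1] == root]
  expect_equal(sum(root_edges), long, tolerance = 1e-9)
  # path lengths between tips are preserved by rerooting
  expect_equal(cophenetic_distances(rr)[tr$tip.label, tr$tip.label],
               cophenetic_distances(tr), tolerance = 1e-9)
  rr2 <- reroot_longest_branch(tr)
  expect_equal(ape::write.tree(rr2), ape::write.tree(rr))
})

test_that("community_dataset enforces the taxon/tip bijection and metadata cover", {
  tr <- random_tree(6, seed = 9)
  tab <- matrix(1, 2, 6, dimnames = list(c("s1", "s2"), tr$tip.label))
  expect_error(community_dataset(tab[, 1:5], tr), "mismatch")
  md <- data.frame(sample_id = "s1", stringsAsFactors = FALSE)
  expect_error(community_dataset(tab, tr, md), "s2")
  ds <- community_dataset(tab, tr)
  expect_equal(ds$metadata$sample_id, c("s1", "s2"))
})
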