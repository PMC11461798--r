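test_that("branch metrics are pendant lengths and root-to-tip sums", {
  bm <- branch_metrics(toy_tree())
  expect_equal(bm$terminal_length[match(c("t1", "t2", "t3"), bm$tip)],
               c(1, 1, 3))
  expect_equal(bm$root_to_tip[match(c("t1", "t2", "t3"), bm$tip)],
               c(2, 2, 3))

  ul <- with_seed(4, ape::rcoal(12))
  bmu <- branch_metrics(ul)
  expect_equal(diff(range(bmu$root_to_tip)), 0, tolerance = 1e-9)

  rt <- random_tree(9, seed = 14)
  d_bf <- bf_cophenetic(rt)
  bmr <- branch_metrics(rt)
  # root-to-tip from the oracle: distance to the root node via any tip path
  rtt <- ape::node.depth.edgelength(rt)[seq_len(9)]
  expect_equal(bmr$root_to_tip, rtt)
  pend <- rt$edge.length[match(seq_len(9), rt$edge[, 2])]
  expect_equal(bmr$terminal_length, pend)
})

test_that("robust MAD scores flag exactly the constructed outlier", {
  # bulk terminal lengths with small spread, one planted extreme tip
  n <- 100
  lens <- seq(0.008, 0.012, length.out = n)
  tips <- sprintf("b%03d", seq_len(n))
  metrics <- data.frame(tip = c(tips, "planted"),
                        terminal_length = c(lens, 0.5),
                        root_to_tip = 0, stringsAsFactors = FALSE)
  rep <- score_outliers(metrics, method = "terminal_mad", threshold = 5)
  expect_equal(rep$tip[rep$flagged], "planted")
  med <- stats::median(metrics$terminal_length)
  madn <- stats::mad(metrics$terminal_length)
  expect_equal(rep$score[rep$tip == "planted"], (0.5 - med) / madn)

  # all-equal branches: zero scale, zero scores, nothing flagged
  eq <- data.frame(tip = tips, terminal_length = 0.01, root_to_tip = 0.5)
  rep_eq <- score_outliers(eq, threshold = 5)
  expect_equal(rep_eq$score, rep(0, n))
  expect_false(any(rep_eq$flagged))

  rep_inf <- score_outliers(metrics, threshold = Inf)
  expect_false(any(rep_inf$flagged))

  expect_error(score_outliers(metrics[1:3, ]), ">= 4 tips")
})

test_that("planted outliers are recovered exactly; clean trees stay clean", {
  for (s in 1:5) {
    tr <- simulate_tree(150, seed = s)
    pl <- plant_outliers(tr, fraction = 0.012, multiplier = 10, seed = s + 40)
    rep <- score_outliers(pl$tree)
    expect_setequal(rep$tip[rep$flagged], pl$outliers)
    clean <- score_outliers(tr)
    expect_equal(sum(clean$flagged), 0)
  }
})

test_that("false-positive rate stays at or below 1% on lognormal pendant edges", {
  flagged <- 0; total <- 0
  for (s in 1:10) {
    tr <- random_tree(120, seed = 300 + s)
    pend <- match(seq_len(120), tr$edge[, 2])
    tr$edge.length[pend] <- with_seed(400 + s,
      stats::rlnorm(120, meanlog = log(0.05), sdlog = 0.5))
    rep <- score_outliers(tr)
    flagged <- flagged + sum(rep$flagged); total <- total + 120
  }
  expect_lte(flagged / total, 0.01)
})

test_that("remove_outliers prunes consistently and commutes with alignment", {
  ds <- tiny_dataset(n_tips = 15, n_samples = 4, seed = 12)
  flagged <- ds$tree$tip.label[c(2, 9)]
  before <- richness(ds$table, "regional")
  out <- remove_outliers(ds, flagged)
  expect_equal(richness(out$dataset$table, "regional"),
               before - sum(colSums(ds$table[, flagged]) > 0))
  expect_equal(ncol(out$dataset$table), 13)
  expect_equal(out$summary$removed_abundance_fraction,
               unname(rowSums(ds$table[, flagged]) / rowSums(ds$table)))

  same <- remove_outliers(ds, character(0))
  expect_identical(same$dataset$table, ds$table)
  expect_error(remove_outliers(ds, "no_such_tip"), "no_such_tip")

  # prune-then-align equals align-then-prune
  a <- align_dataset(out$dataset$table, out$dataset$tree, policy = "prune")
  b0 <- align_dataset(ds$table[, setdiff(colnames(ds$table), flagged)],
                      ds$tree, policy = "prune")
  expect_equal(a$table, b0$table)
  expect_equal(cophenetic_distances(a$tree)[colnames(a$table), colnames(a$table)],
               cophenetic_distances(b0$tree)[colnames(a$table), colnames(a$table)],
               tolerance = 1e-12)
})

test_that("iterative auditing can unmask secondary outliers", {
  # one extreme and one moderate outlier: the extreme one inflates the MAD
  n <- 60
  lens <- rep(0.01, n) + seq(0, 0.004, length.out = n)
  metrics <- data.frame(tip = sprintf("b%02d", 1:n),
                        terminal_length = lens, root_to_tip = 0)
  metrics$terminal_length[c(5, 6)] <- c(5, 0.08)
  tr <- with_seed(1, ape::rtree(n))
  tr$tip.label <- metrics$tip
  tr$edge.length[match(1:n, tr$edge[, 2])] <- metrics$terminal_length
  one <- audit_tree(tr, threshold = 5, max_iter = 1)
  two <- audit_tree(tr, threshold = 5, max_iter = 3)
  expect_true(all(one$tip[one$flagged] %in% two$tip[two$flagged]))
  expect_gte(sum(two$flagged), sum(one$flagged))
  expect_true("b05" %in% two$tip[two$flagged])
})

test_that("export_suspects writes exactly the flagged records", {
  seqs <- Biostrings::DNAStringSet(c(t1 = "ACGT", t2 = "GGCC", t3 = "ATAT",
                                     t4 = "TTAA"))
  path <- withr::local_tempfile(fileext = ".fasta")
  export_suspects(c("t2", "t4", "t1"), seqs, path)
  back <- Biostrings::readDNAStringSet(path)
  expect_setequal(names(back), c("t1", "t2", "t4"))
  expect_equal(as.character(back[["t2"]]), "GGCC")

  expect_warning(export_suspects(character(0), seqs, path), "empty")
  expect_equal(length(Biostrings::readDNAStringSet(path)), 0)
  expect_error(export_suspects(c("t1", "tZ"), seqs, path), "tZ")
})
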