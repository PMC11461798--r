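test_that("cophenetic distances equal brute-force path sums", {
  tr <- toy_tree()
  d <- cophenetic_distances(tr)
  expect_equal(d["t1", "t2"], 2)
  expect_equal(d["t1", "t3"], 5)
  expect_equal(unname(diag(d)), rep(0, 3))

  rt <- random_tree(8, seed = 11)
  expect_equal(cophenetic_distances(rt), bf_cophenetic(rt), tolerance = 1e-12)
})

test_that("mntd matches the toy example and a brute-force scan", {
  d <- cophenetic_distances(toy_tree())
  expect_equal(mntd(c("t1", "t2"), d), 2)
  # any two-taxon community: MNTD equals the pairwise distance, any weighting
  expect_equal(mntd(c("t1", "t3"), d), d["t1", "t3"])
  expect_equal(mntd(c("t1", "t3"), d, abundances = c(t1 = 9, t3 = 1),
                    weighted = TRUE), d["t1", "t3"])
  expect_error(mntd("t1", d), "fewer than 2")

  rt <- random_tree(10, seed = 21)
  drt <- cophenetic_distances(rt)
  for (s in 1:5) {
    taxa <- with_seed(s, sample(rt$tip.label, 5))
    w <- with_seed(s + 50, stats::setNames(stats::runif(5, 1, 10), taxa))
    expect_equal(mntd(taxa, drt), bf_mntd(taxa, drt))
    expect_equal(mntd(taxa, drt, abundances = w, weighted = TRUE),
                 bf_mntd(taxa, drt, w))
  }
})

test_that("mntd and bmntd agree with picante on random communities", {
  skip_if_not_installed("picante")
  rt <- random_tree(15, seed = 31)
  drt <- cophenetic_distances(rt)
  comm <- with_seed(99, {
    m <- matrix(stats::rpois(4 * 15, 1.2), 4, 15,
                dimnames = list(paste0("s", 1:4), rt$tip.label))
    m[rowSums(m > 0) < 2, 1:2] <- 1
    m
  })
  expect_equal(unname(picante::mntd(comm, drt)),
               unname(apply(comm, 1, function(x)
                 mntd(names(x)[x > 0], drt))))
  expect_equal(unname(picante::mntd(comm, drt, abundance.weighted = TRUE)),
               unname(apply(comm, 1, function(x) mntd(x, drt, weighted = TRUE))))
  # abundance-weighted betaMNTD is picante's comdistnt convention
  pc <- as.matrix(picante::comdistnt(comm, drt, abundance.weighted = TRUE))
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(bmntd(comm[i, ], comm[j, ], drt, weighted = TRUE),
                 pc[i, j])
})

test_that("bmntd identities and brute-force oracle", {
  d <- cophenetic_distances(toy_tree())
  x <- c(t1 = 1, t2 = 2, t3 = 0)
  expect_equal(bmntd(x, x, d), 0)
  expect_equal(bmntd(c(t1 = 1, t2 = 0, t3 = 0), c(t1 = 0, t2 = 0, t3 = 1), d), 5)
  expect_error(bmntd(c(t1 = 0, t2 = 0, t3 = 0), x, d), "empty")

  rt <- random_tree(12, seed = 41)
  drt <- cophenetic_distances(rt)
  for (s in 1:5) {
    va <- with_seed(s, stats::setNames(stats::rpois(12, 1), rt$tip.label))
    vb <- with_seed(s + 10, stats::setNames(stats::rpois(12, 1), rt$tip.label))
    va[1] <- va[1] + 1; vb[12] <- vb[12] + 1
    ta <- names(va)[va > 0]; tb <- names(vb)[vb > 0]
    expect_equal(bmntd(va, vb, drt), bf_bmntd(ta, tb, drt))
    expect_equal(bmntd(va, vb, drt, weighted = TRUE),
                 bf_bmntd(ta, tb, drt, va, vb))
  }
})

test_that("nti: degeneracy, scale invariance, and the exhaustive null", {
  ds <- tiny_dataset(n_tips = 8, n_samples = 3, seed = 5)
  full <- stats::setNames(rep(1, 8), ds$tree$tip.label)
  r <- nti(full, ds, n_null = 50, seed = 1)
  expect_true(r$degenerate)
  expect_identical(r$z, 0)
  expect_equal(r$call, "stochastic")

  comm <- stats::setNames(c(1, 1, 1, 0, 0, 0, 0, 2), ds$tree$tip.label)
  r1 <- nti(comm, ds, n_null = 200, seed = 3)
  scaled <- ds
  scaled$tree$edge.length <- scaled$tree$edge.length * 7
  r2 <- nti(comm, scaled, n_null = 200, seed = 3)
  expect_equal(r2$z, r1$z, tolerance = 1e-12)

  # exhaustive all-permutations oracle on a 6-tip metacommunity
  tr <- random_tree(6, seed = 61)
  dm <- cophenetic_distances(tr)
  tab <- matrix(c(1, 1, 0, 1, 0, 0), 1, 6,
                dimnames = list("s1", tr$tip.label))
  ds6 <- community_dataset(rbind(tab, s2 = 1), tr)
  idx <- which(tab[1, ] > 0)
  z_ex <- exhaustive_z(dm, idx, metric = "NTI")
  r_mc <- nti(tab[1, ], ds6, n_null = 4000, seed = 9)
  expect_lt(abs(r_mc$z - z_ex), 0.1)
})

test_that("bnti: direction, classification and the exhaustive null", {
  ds <- tiny_dataset(n_tips = 10, n_samples = 3, seed = 6)
  x <- ds$table[1, ]
  r <- bnti(x, x, ds, n_null = 100, seed = 2)
  expect_lte(r$z, 0)  # identical communities can never exceed the null

  expect_equal(classify_assembly(c(2.1, -2.5, 0.3, 2, -2), "bNTI"),
               c("heterogeneous_selection", "homogeneous_selection",
                 "stochastic", "stochastic", "stochastic"))
  expect_equal(classify_assembly(c(2.5, -3, 1), "NTI"),
               c("clustered", "dispersed", "stochastic"))

  tr <- random_tree(5, seed = 71)
  dm <- cophenetic_distances(tr)
  tab <- rbind(a = c(1, 0, 0, 0, 0), b = c(0, 0, 0, 0, 1))
  colnames(tab) <- tr$tip.label
  ds5 <- community_dataset(tab, tr)
  z_ex <- exhaustive_z(dm, 1, 5, metric = "bNTI")
  r_mc <- bnti("a", "b", ds5, n_null = 4000, weighted = FALSE, seed = 13)
  expect_lt(abs(r_mc$z - z_ex), 0.1)
})

test_that("bnti_group pairs within groups, independent of sample order", {
  ds <- tiny_dataset(n_tips = 10, n_samples = 7, seed = 8)
  ds$metadata$sample_type <- c("a", "a", "a", "a", "b", "b", "b")
  res <- bnti_group(ds, group_by = "sample_type", n_null = 30, seed = 4)
  expect_equal(nrow(res), choose(4, 2) + choose(3, 2))
  expect_true(all(res$group %in% c("a", "b")))

  perm <- c(5, 3, 7, 1, 6, 2, 4)
  ds2 <- community_dataset(ds$table[perm, ], ds$tree,
                           ds$metadata[perm, ])
  res2 <- bnti_group(ds2, group_by = "sample_type", n_null = 30, seed = 4)
  key <- function(d) d[order(d$sample_a, d$sample_b), ]
  expect_equal(key(res2), key(res), ignore_attr = TRUE)

  ds$metadata$sample_type[5:7] <- c("b", "c", "d")  # two singleton groups
  res3 <- bnti_group(ds, group_by = "sample_type", n_null = 30, seed = 4)
  expect_equal(nrow(res3), choose(4, 2))
})

test_that("z is centred near zero for uniformly random communities", {
  # reduced version of the calibration run in the acceptance suite
  tr <- random_tree(20, seed = 91)
  tab <- matrix(1, 2, 20, dimnames = list(c("s1", "s2"), tr$tip.label))
  ds <- community_dataset(tab, tr)
  dm <- cophenetic_distances(tr)
  zs <- vapply(1:150, function(i) {
    comm <- with_seed(2000 + i,
      stats::setNames(as.numeric(seq_len(20) %in% sample.int(20, 7)),
                      tr$tip.label))
    nti(comm, ds, n_null = 150, seed = 3000 + i, dist = dm)$z
  }, numeric(1))
  expect_lt(abs(mean(zs)), 0.2)
  expect_lte(mean(abs(zs) > 2), 0.1)
})
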