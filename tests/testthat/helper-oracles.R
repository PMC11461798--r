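# Independent oracles and small fixtures used across the test files.
# Everything here is deliberately naive (graph walks, exhaustive enumeration)
# and shares no code with the implementation it checks.

toy_tree <- function() read_newick(text = "((t1:1,t2:1):1,t3:3);")

random_tree <- function(n, seed) {
  tr <- with_seed(seed, ape::rtree(n))
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}

with_seed <- phylonull:::with_seed

# Brute-force tip-to-tip path sums by breadth-first search over the
# (undirected) edge graph; independent of stats::cophenetic.
bf_cophenetic <- function(tree) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  adj <- vector("list", nn)
  for (k in seq_len(nrow(tree$edge))) {
    a <- tree$edge[k, 1]; b <- tree$edge[k, 2]; w <- tree$edge.length[k]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  out <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (src in seq_len(ntip)) {
    dist <- rep(NA_real_, nn); dist[src] <- 0
    queue <- src
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (r in seq_len(NROW(adj[[v]]))) {
        u <- adj[[v]][r, 1]
        if (is.na(dist[u])) {
          dist[u] <- dist[v] + adj[[v]][r, 2]
          queue <- c(queue, u)
        }
      }
    }
    out[src, ] <- dist[seq_len(ntip)]
  }
  out
}

# Naive per-taxon nearest-neighbour scan.
bf_mntd <- function(taxa, dmat, w = NULL) {
  mins <- vapply(taxa, function(ti)
    min(dmat[ti, setdiff(taxa, ti)]), numeric(1))
  if (is.null(w)) mean(mins) else sum(mins * w[taxa]) / sum(w[taxa])
}

bf_bmntd <- function(ta, tb, dmat, wa = NULL, wb = NULL) {
  ma <- vapply(ta, function(ti) min(dmat[ti, tb, drop = FALSE]), numeric(1))
  mb <- vapply(tb, function(ti) min(dmat[ti, ta, drop = FALSE]), numeric(1))
  da <- if (is.null(wa)) mean(ma) else sum(ma * wa[ta]) / sum(wa[ta])
  db <- if (is.null(wb)) mean(mb) else sum(mb * wb[tb]) / sum(wb[tb])
  (da + db) / 2
}

# All permutations of 1..n, one per row.
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 1
  for (i in seq_len(n)) {
    for (j in seq_len(nrow(sub))) {
      row <- sub[j, ]
      row[row >= i] <- row[row >= i] + 1L
      out[r, ] <- c(i, row)
      r <- r + 1
    }
  }
  out
}

# Exhaustive z over every tip-label permutation (the null the Monte-Carlo
# engine samples from), for metacommunities small enough to enumerate.
exhaustive_z <- function(dmat, idx_a, idx_b = NULL, metric = c("NTI", "bNTI"),
                         wa = NULL, wb = NULL) {
  metric <- match.arg(metric)
  n <- nrow(dmat)
  perms <- all_perms(n)
  stat <- function(ia, ib) {
    if (metric == "NTI") phylonull:::mntd_idx(ia, dmat, wa)
    else phylonull:::bmntd_idx(ia, ib, dmat, wa, wb)
  }
  obs <- stat(idx_a, idx_b)
  nulls <- vapply(seq_len(nrow(perms)), function(r) {
    p <- perms[r, ]
    stat(p[idx_a], if (is.null(idx_b)) NULL else p[idx_b])
  }, numeric(1))
  mu <- mean(nulls); sdv <- sqrt(mean((nulls - mu)^2) * length(nulls) / (length(nulls) - 1))
  if (metric == "NTI") (mu - obs) / sdv else (obs - mu) / sdv
}

# A small hand-assembled dataset on a random tree.
tiny_dataset <- function(n_tips = 12, n_samples = 4, seed = 7) {
  tr <- random_tree(n_tips, seed)
  tab <- with_seed(seed + 1, {
    m <- matrix(stats::rpois(n_samples * n_tips, 3), n_samples, n_tips)
    dimnames(m) <- list(paste0("s", seq_len(n_samples)), tr$tip.label)
    m[rowSums(m) == 0, 1] <- 1
    m
  })
  md <- data.frame(sample_id = rownames(tab),
                   sample_type = rep(c("fish", "water"),
                                     length.out = n_samples),
                   stringsAsFactors = FALSE)
  community_dataset(tab, tr, md)
}
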