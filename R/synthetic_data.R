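#' Configuration for a synthetic community-assembly scenario
#'
#' Describes a metacommunity tree with planted long-branch outlier tips and
#' multi-sample-type community tables with either environmental-filtering or
#' neutral assembly, emulating the structure of 16S amplicon datasets in
#' which ~1% of taxa are misclassified non-target sequences with terminal
#' branches many-fold longer than the bulk, rare within samples (~0.1% mean
#' relative abundance), and in which sample types of differing richness make
#' up the regional pool.
#'
#' @param n_tips number of metacommunity taxa (>= 8).
#' @param tree_model `"birth_death"` (pure-birth, [ape::rphylo()]) or
#'   `"coalescent"` ([ape::rcoal()]).
#' @param outlier_fraction fraction of tips planted as long-branch outliers
#'   (default 0.012, in `[0, 0.5)`).
#' @param outlier_multiplier factor applied to a planted tip's terminal
#'   branch (default 10, > 1).
#' @param sample_types character vector of sample-type names.
#' @param n_samples integer vector (recycled/named by type) of samples per
#'   type; the first type is the most intensively sampled "focal host" type.
#' @param assembly_regime `"filtering"` or `"neutral"`, recycled per type.
#' @param filtering_strength niche-kernel width as a multiple of the trait
#'   standard deviation (default 0.3; smaller = stronger filtering).
#' @param optimum_spacing quantile spacing between the environmental optima
#'   of adjacent sample types (default 0.18: with three types the optima sit
#'   at the 0.32/0.50/0.68 trait quantiles). Together with
#'   `filtering_strength` this sets how many regional taxa are exclusive to
#'   one sample type, and hence how much of the regional pool is lost when
#'   the metacommunity is subset to a single type.
#' @param richness_fraction expected fraction of the metacommunity present
#'   in one sample (default 0.3); matched between regimes so that index
#'   differences reflect assembly, not richness.
#' @param mean_outlier_abundance target mean within-sample relative abundance
#'   of a present outlier taxon (default 0.001).
#' @param outlier_occupancy probability that a planted outlier occurs in any
#'   given sample (default 0.8), independent of the niche kernel:
#'   misclassified host or fungal reads are systematic trace contaminants,
#'   present across most samples rather than tracking an environmental
#'   optimum.
#' @param seed master seed; all randomness flows from it via named
#'   sub-streams.
#' @return a list of class `"scenario_config"`.
#' @export
scenario_config <- function(n_tips = 200,
                            tree_model = c("birth_death", "coalescent"),
                            outlier_fraction = 0.012,
                            outlier_multiplier = 10,
                            sample_types = c("fish", "rearing_water", "intake_water"),
                            n_samples = c(12, 5, 3),
                            assembly_regime = "filtering",
                            filtering_strength = 0.3,
                            optimum_spacing = 0.18,
                            richness_fraction = 0.3,
                            mean_outlier_abundance = 0.001,
                            outlier_occupancy = 0.8,
                            seed = 1L) {
  tree_model <- match.arg(tree_model)
  stopifnot(n_tips >= 8,
            outlier_fraction >= 0, outlier_fraction < 0.5,
            outlier_multiplier > 1 || outlier_multiplier == 1,
            filtering_strength > 0, optimum_spacing > 0, optimum_spacing < 1,
            richness_fraction > 0, richness_fraction <= 1,
            outlier_occupancy >= 0, outlier_occupancy <= 1)
  n_samples <- rep_len(n_samples, length(sample_types))
  names(n_samples) <- sample_types
  assembly_regime <- rep_len(assembly_regime, length(sample_types))
  names(assembly_regime) <- sample_types
  stopifnot(all(assembly_regime %in% c("filtering", "neutral")))
  structure(list(n_tips = n_tips, tree_model = tree_model,
                 outlier_fraction = outlier_fraction,
                 outlier_multiplier = outlier_multiplier,
                 sample_types = sample_types, n_samples = n_samples,
                 assembly_regime = assembly_regime,
                 filtering_strength = filtering_strength,
                 optimum_spacing = optimum_spacing,
                 richness_fraction = richness_fraction,
                 mean_outlier_abundance = mean_outlier_abundance,
                 outlier_occupancy = outlier_occupancy,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Simulate a metacommunity tree
#'
#' Topology and internal branch lengths come from the chosen model. By
#' default (`terminal = "marker"`) the pendant (terminal) edges are then
#' redrawn from a lognormal distribution truncated to `[0.4, 2]` times the
#' model's median pendant edge. This emulates an inferred single-marker
#' (16S) tree: within-domain terminal divergences are bounded by the
#' conservation of the marker, so the bulk of pendant edges is light-tailed
#' — the extreme pendant edges of misclassified non-target sequences are
#' exactly the violation of that bound that the tree audit screens for.
#' `terminal = "model"` keeps the raw model branch lengths (whose pendant
#' edges are approximately exponential and hence heavy-tailed relative to
#' real marker trees).
#'
#' @param n_tips number of tips (>= 8).
#' @param model `"birth_death"` (pure-birth Yule, birth rate 1) or
#'   `"coalescent"`.
#' @param seed integer seed.
#' @param terminal `"marker"` (truncated-lognormal pendant edges, default)
#'   or `"model"`.
#' @param terminal_sdlog lognormal sd of pendant edges under `"marker"`
#'   (default 0.3).
#' @return a `"phylo"` tree with tips `t1..tn` and positive branch lengths.
#' @export
simulate_tree <- function(n_tips, model = c("birth_death", "coalescent"),
                          seed = 1L, terminal = c("marker", "model"),
                          terminal_sdlog = 0.3) {
  model <- match.arg(model)
  terminal <- match.arg(terminal)
  stopifnot(n_tips >= 8)
  tree <- with_seed(seed, {
    phy <- if (model == "birth_death") ape::rphylo(n_tips, birth = 1, death = 0)
    else ape::rcoal(n_tips)
    if (terminal == "marker") {
      pend <- match(seq_len(n_tips), phy$edge[, 2])
      med <- stats::median(phy$edge.length[pend])
      draw <- stats::rlnorm(n_tips, meanlog = 0, sdlog = terminal_sdlog)
      phy$edge.length[pend] <- med * pmin(2, pmax(0.4, draw))
    }
    phy
  })
  tree$tip.label <- paste0("t", seq_len(n_tips))
  # guard against numerically zero internal branches from the simulators
  tree$edge.length <- pmax(tree$edge.length, 1e-8)
  validate_tree(tree)
  tree
}

#' Plant long-branch outlier tips on a tree
#'
#' Randomly chosen tips have their terminal branch multiplied by
#' `multiplier`, mimicking misclassified non-target sequences; the planted
#' set is returned as ground truth. The number planted is
#' `max(1, floor(fraction * n_tips))` (0 when `fraction == 0`).
#'
#' @param tree a `"phylo"` object.
#' @param fraction fraction of tips to plant.
#' @param multiplier terminal-branch factor (1 leaves the tree unchanged).
#' @param seed integer seed.
#' @return list with `tree` (modified) and `outliers` (character tips).
#' @export
plant_outliers <- function(tree, fraction = 0.012, multiplier = 10, seed = 1L) {
  validate_tree(tree)
  ntip <- length(tree$tip.label)
  n_out <- if (fraction <= 0) 0L else max(1L, floor(fraction * ntip))
  if (n_out == 0L) return(list(tree = tree, outliers = character(0)))
  picked <- with_seed(seed, sample(tree$tip.label, n_out))
  edge_idx <- match(match(picked, tree$tip.label), tree$edge[, 2])
  tree$edge.length[edge_idx] <- tree$edge.length[edge_idx] * multiplier
  list(tree = tree, outliers = sort(picked))
}

#' Evolve a continuous niche trait along a tree by Brownian motion
#'
#' Trait variance accumulates proportionally to branch length, so closely
#' related tips receive similar trait values — the niche-conservatism
#' assumption that underlies nearest-taxon null models.
#'
#' @param tree a `"phylo"` object.
#' @param seed integer seed.
#' @param sigma Brownian rate (per unit branch length), default 1.
#' @return named numeric vector of tip traits.
#' @export
evolve_niche_trait <- function(tree, seed = 1L, sigma = 1) {
  validate_tree(tree)
  with_seed(seed, ape::rTraitCont(tree, model = "BM", sigma = sigma))
}

#' Simulate community tables over a tree and niche trait
#'
#' Under the `"filtering"` regime each sample type has an environmental
#' optimum on the trait axis (optima sit at trait quantiles centred on the
#' median and spaced `optimum_spacing` apart),
#' and a taxon enters a sample with probability proportional to a Gaussian
#' kernel `exp(-(trait - optimum)^2 / (2 * sigma^2))` with
#' `sigma = filtering_strength * sd(trait)`; probabilities are scaled so the
#' expected per-sample richness is `richness_fraction * n_tips`. Under
#' `"neutral"`, every taxon enters with the same probability matched to that
#' expected richness. Abundances of included taxa are lognormal. Planted
#' outlier taxa do not follow the niche kernel: they occur in each sample
#' with probability `outlier_occupancy` (systematic trace contamination) at
#' a relative abundance of about `mean_outlier_abundance`. Every tip is
#' guaranteed to occur in at least one sample so the regional pool equals
#' the tree's tip set.
#'
#' @param tree metacommunity tree (with planted outliers, if any).
#' @param traits named tip trait vector from [evolve_niche_trait()].
#' @param config a `"scenario_config"`.
#' @param outliers character vector of planted outlier tips (may be empty).
#' @param seed integer seed.
#' @return a `"community_dataset"`; its metadata has columns `sample_id`,
#'   `sample_type`, `regime`. Attribute `"optima"` records each type's
#'   environmental optimum.
#' @export
simulate_communities <- function(tree, traits, config, outliers = character(0),
                                 seed = 1L) {
  stopifnot(inherits(config, "scenario_config"))
  taxa <- tree$tip.label
  traits <- traits[taxa]
  types <- config$sample_types
  k_types <- length(types)
  qs <- 0.5 + (seq_len(k_types) - (k_types + 1) / 2) * config$optimum_spacing
  qs <- pmin(0.98, pmax(0.02, qs))
  optima <- stats::quantile(traits, probs = qs, names = FALSE)
  names(optima) <- types
  sigma <- config$filtering_strength * stats::sd(traits)
  target <- config$richness_fraction * length(taxa)
  is_out <- taxa %in% outliers

  with_seed(seed, {
    rows <- list(); meta <- list()
    for (ty in types) {
      p <- if (config$assembly_regime[[ty]] == "filtering") {
        raw <- exp(-(traits - optima[[ty]])^2 / (2 * sigma^2))
        pmin(0.95, raw * target / sum(raw))
      } else rep(min(0.95, target / length(taxa)), length(taxa))
      for (i in seq_len(config$n_samples[[ty]])) {
        sid <- sprintf("%s_%02d", ty, i)
        for (try in 1:50) {
          present <- stats::runif(length(taxa)) < p
          if (sum(present & !is_out) >= 2) break
          if (try == 50) stop("could not draw a community with >= 2 taxa for ", sid)
        }
        present[is_out] <- stats::runif(sum(is_out)) < config$outlier_occupancy
        counts <- numeric(length(taxa))
        counts[present] <- stats::rlnorm(sum(present), meanlog = log(100),
                                         sdlog = 1)
        # outliers are rare regardless of how they entered the sample
        core_total <- sum(counts[!is_out])
        oi <- which(present & is_out)
        if (length(oi) > 0)
          counts[oi] <- config$mean_outlier_abundance * core_total *
            stats::rlnorm(length(oi), meanlog = 0, sdlog = 0.3)
        rows[[sid]] <- counts
        meta[[sid]] <- data.frame(sample_id = sid, sample_type = ty,
                                  regime = config$assembly_regime[[ty]],
                                  stringsAsFactors = FALSE)
      }
    }
    tab <- do.call(rbind, rows)
    colnames(tab) <- taxa
    # every tip must occur somewhere: seed unobserved taxa into one sample
    absent <- which(colSums(tab) == 0)
    for (j in absent) {
      s <- sample.int(nrow(tab), 1)
      tab[s, j] <- if (is_out[j])
        config$mean_outlier_abundance * sum(tab[s, !is_out]) else
        stats::rlnorm(1, meanlog = log(100), sdlog = 1)
    }
    md <- do.call(rbind, unname(meta))
    ds <- community_dataset(tab, tree, md)
    attr(ds, "optima") <- optima
    ds
  })
}

#' Generate a complete synthetic scenario
#'
#' Orchestrates tree simulation, outlier planting, Brownian niche traits and
#' community simulation, each on a named sub-stream of the master seed. The
#' niche trait is evolved on the tree *before* outlier planting, so planted
#' outliers are ecologically unremarkable (their rarity and long branch are
#' their only distinguishing features, as for real misclassified sequences).
#'
#' @param config a `"scenario_config"`.
#' @return list of class `"scenario"`: `dataset` (full, with outliers in tree
#'   and table), `truth` (list: `outliers`, `traits`, `optima`, `regimes`),
#'   `config`.
#' @export
simulate_scenario <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  base_tree <- simulate_tree(config$n_tips, config$tree_model,
                             seed = sub_seed(config$seed, "tree"))
  traits <- evolve_niche_trait(base_tree, seed = sub_seed(config$seed, "traits"))
  planted <- plant_outliers(base_tree, config$outlier_fraction,
                            config$outlier_multiplier,
                            seed = sub_seed(config$seed, "outliers"))
  ds <- simulate_communities(planted$tree, traits, config,
                             outliers = planted$outliers,
                             seed = sub_seed(config$seed, "communities"))
  structure(list(dataset = ds,
                 truth = list(outliers = planted$outliers, traits = traits,
                              optima = attr(ds, "optima"),
                              regimes = config$assembly_regime),
                 config = config),
            class = "scenario")
}
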