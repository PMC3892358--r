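# ---- synthetic trees, traits and communities --------------------------------
#
# A stated world for testing: Yule trees dated in Myr, a Brownian
# "elevation optimum" trait, and plots along a 375-3200 m gradient assembled
# under environmental filtering, limiting similarity, or neutrality.

#' Simulate an ultrametric Yule (pure-birth) tree
#'
#' Starts with two lineages at the root, waits Exp(k * lambda) between
#' successive speciation events while k lineages are alive, splits a
#' uniformly chosen lineage at each event, and cuts the tree a final
#' Exp(n_tips * lambda) after the last split. The expected height is
#' therefore (1/lambda) * sum_{k=2..n_tips} 1/k, which the test suite uses
#' as an analytic oracle.
#'
#' @param n_tips Number of tips (>= 3).
#' @param lambda Speciation rate per lineage per Myr (> 0).
#' @param seed Integer seed; the same seed reproduces the same Newick
#'   string.
#' @return A \code{dated_tree}.
#' @export
simulate_yule_tree <- function(n_tips, lambda = 1, seed = 1L) {
  stopifnot(n_tips >= 3, lambda > 0)
  set.seed(as.integer(seed %% .Machine$integer.max))
  n_internal <- n_tips - 1L
  edge <- matrix(0L, nrow = 2L * n_tips - 2L, ncol = 2)
  edge_len <- numeric(nrow(edge))
  n_edges <- 0L
  root <- n_tips + 1L
  next_internal <- root + 1L
  # active lineages: parent node and birth time
  par <- c(root, root)
  birth <- c(0, 0)
  t <- 0
  k <- 2L
  while (k < n_tips) {
    t <- t + rexp(1, k * lambda)
    i <- sample.int(k, 1)
    node <- next_internal
    next_internal <- next_internal + 1L
    n_edges <- n_edges + 1L
    edge[n_edges, ] <- c(par[i], node)
    edge_len[n_edges] <- t - birth[i]
    par[i] <- node; birth[i] <- t
    par <- c(par, node); birth <- c(birth, t)
    k <- k + 1L
  }
  t_end <- t + rexp(1, n_tips * lambda)
  for (i in seq_len(n_tips)) {
    n_edges <- n_edges + 1L
    edge[n_edges, ] <- c(par[i], i)
    edge_len[n_edges] <- t_end - birth[i]
  }
  phy <- structure(list(edge = edge, edge.length = edge_len,
                        tip.label = sprintf("s%03d", seq_len(n_tips)),
                        Nnode = n_internal),
                   class = "phylo", order = "cladewise")
  phy <- ape::reorder.phylo(phy, "cladewise")
  as_dated_tree(phy)
}

#' Evolve a continuous trait by Brownian motion along a tree
#'
#' Each branch adds a Normal(0, sigma2 * branch length) increment, so the
#' expected squared trait difference between two tips equals sigma2 times
#' their patristic distance.
#'
#' @param tree A \code{dated_tree}.
#' @param sigma2 Brownian rate (trait units squared per Myr, > 0).
#' @param root_value Trait value at the root.
#' @param seed Integer seed.
#' @return Named numeric vector of tip trait values (here: optimum
#'   elevation in metres).
#' @export
evolve_trait <- function(tree, sigma2, root_value = 0, seed = 1L) {
  stopifnot(inherits(tree, "dated_tree"), sigma2 > 0)
  set.seed(as.integer(seed %% .Machine$integer.max))
  phy <- tree$phy
  ntip <- length(phy$tip.label)
  vals <- numeric(ntip + phy$Nnode)
  vals[ntip + 1L] <- root_value
  # cladewise order guarantees parents are visited before children
  for (i in seq_len(nrow(phy$edge))) {
    vals[phy$edge[i, 2]] <- vals[phy$edge[i, 1]] +
      rnorm(1, 0, sqrt(sigma2 * phy$edge.length[i]))
  }
  setNames(vals[seq_len(ntip)], phy$tip.label)
}

#' Define a community-assembly scenario
#'
#' @param n_tips Tips of the simulated tree (default 200, the scale of a
#'   regional flora phylogeny).
#' @param lambda Yule speciation rate (default 1 /Myr).
#' @param sigma2 Brownian rate of the elevation-optimum trait (default
#'   1e5 m^2/Myr so optima spread over the full gradient on a tree of height
#'   ~5 Myr).
#' @param root_value Root optimum (default 1800 m, mid-gradient).
#' @param n_plots Number of plots (default 500).
#' @param elevation_range Gradient span in metres (default 375-3200).
#' @param mean_richness Mean plot species richness (Poisson, default 15,
#'   floored at 2).
#' @param filter_strength Environmental filtering strength (>= 0;
#'   dimensionless multiplier of the squared trait-elevation mismatch).
#' @param competition_strength Limiting-similarity strength (>= 0, Myr; a
#'   candidate is down-weighted by exp(-strength / d_min) where d_min is its
#'   patristic distance to the nearest already-selected species).
#' @param filter_scale Gaussian kernel scale s in metres (default 300).
#' @param seed Integer seed.
#' @param allow_mixed Allow both strengths positive (default FALSE).
#' @return List of class \code{assembly_scenario}.
#' @export
assembly_scenario <- function(n_tips = 200, lambda = 1, sigma2 = 1e5,
                              root_value = 1800, n_plots = 500,
                              elevation_range = c(375, 3200),
                              mean_richness = 15,
                              filter_strength = 0, competition_strength = 0,
                              filter_scale = 300, seed = 1L,
                              allow_mixed = FALSE) {
  stopifnot(n_tips >= 3, lambda > 0, sigma2 > 0, n_plots >= 1,
            mean_richness >= 2, filter_strength >= 0,
            competition_strength >= 0, filter_scale > 0,
            elevation_range[2] > elevation_range[1])
  if (!allow_mixed && filter_strength > 0 && competition_strength > 0)
    stop("at most one of filter_strength/competition_strength may be > 0 ",
         "(set allow_mixed = TRUE to override)")
  structure(list(n_tips = n_tips, lambda = lambda, sigma2 = sigma2,
                 root_value = root_value, n_plots = n_plots,
                 elevation_range = elevation_range,
                 mean_richness = mean_richness,
                 filter_strength = filter_strength,
                 competition_strength = competition_strength,
                 filter_scale = filter_scale, seed = as.integer(seed),
                 allow_mixed = allow_mixed),
            class = "assembly_scenario")
}

#' Assemble communities along the elevation gradient
#'
#' Plots sit on an even elevation grid. Per plot, richness k is Poisson
#' (floored at 2) and k species are drawn without replacement with weight
#' proportional to exp(-filter_strength * (trait - elevation)^2 / s^2);
#' under competition, species are picked sequentially and each candidate's
#' weight is additionally multiplied by exp(-competition_strength / d_min),
#' d_min its patristic distance to the closest species already in the plot.
#' With both strengths zero the draw is uniform (neutral). Covers are
#' log-normal, rescaled to sum to 100 percent per plot — assembly itself is
#' presence-based.
#'
#' @param tree A \code{dated_tree}.
#' @param traits Named optimum-elevation vector covering all tips (e.g. from
#'   \code{\link{evolve_trait}}).
#' @param scenario An \code{\link{assembly_scenario}}.
#' @return List with \code{cm} (\code{community_matrix}), \code{meta}
#'   (\code{plot_metadata}) and \code{scenario}.
#' @export
assemble_communities <- function(tree, traits, scenario) {
  stopifnot(inherits(tree, "dated_tree"),
            inherits(scenario, "assembly_scenario"))
  sp <- tip_labels(tree)
  if (!all(sp %in% names(traits))) stop("'traits' must cover all tips")
  traits <- traits[sp]
  n_sp <- length(sp)
  set.seed(.substream_seed(scenario$seed, 7))
  elev <- seq(scenario$elevation_range[1], scenario$elevation_range[2],
              length.out = scenario$n_plots)
  richness <- pmax(stats::rpois(scenario$n_plots, scenario$mean_richness), 2L)
  if (any(richness > n_sp))
    stop("plot richness exceeds the number of species (", n_sp, ")")
  D <- if (scenario$competition_strength > 0) phylo_cophenetic(tree) else NULL
  cover <- matrix(0, scenario$n_plots, n_sp,
                  dimnames = list(sprintf("p%04d", seq_len(scenario$n_plots)), sp))
  for (i in seq_len(scenario$n_plots)) {
    w <- exp(-scenario$filter_strength *
               ((traits - elev[i])^2) / scenario$filter_scale^2)
    w <- pmax(w, 1e-12)
    k <- richness[i]
    if (scenario$competition_strength == 0) {
      chosen <- sample.int(n_sp, k, prob = w)
    } else {
      chosen <- integer(0)
      avail <- seq_len(n_sp)
      for (j in seq_len(k)) {
        wj <- w[avail]
        if (length(chosen)) {
          dmin <- apply(D[avail, sp[chosen], drop = FALSE], 1, min)
          wj <- wj * exp(-scenario$competition_strength / pmax(dmin, 1e-9))
          wj <- pmax(wj, 1e-300)
        }
        pick <- avail[sample.int(length(avail), 1, prob = wj)]
        chosen <- c(chosen, pick)
        avail <- setdiff(avail, pick)
      }
    }
    cv <- rlnorm(k, meanlog = 0, sdlog = 1)
    cover[i, chosen] <- 100 * cv / sum(cv)
  }
  list(cm = community_matrix(cover),
       meta = plot_metadata(rownames(cover), elev),
       scenario = scenario)
}

#' Simulate a full synthetic dataset from a scenario
#'
#' Convenience wrapper: Yule tree, Brownian elevation-optimum trait, and
#' assembled communities, all driven by the scenario's seed.
#'
#' @param scenario An \code{\link{assembly_scenario}}.
#' @return List with \code{tree}, \code{traits}, \code{cm}, \code{meta},
#'   \code{scenario}.
#' @export
simulate_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "assembly_scenario"))
  tree <- simulate_yule_tree(scenario$n_tips, scenario$lambda,
                             seed = .substream_seed(scenario$seed, 1))
  traits <- evolve_trait(tree, scenario$sigma2, scenario$root_value,
                         seed = .substream_seed(scenario$seed, 2))
  asm <- assemble_communities(tree, traits, scenario)
  list(tree = tree, traits = traits, cm = asm$cm, meta = asm$meta,
       scenario = scenario)
}
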