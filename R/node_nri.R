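# ---- node-restricted net relatedness index ----------------------------------
#
# NRI = -(MPD_obs - mean(MPD_null)) / SD(MPD_null), evaluated per community,
# with the null pool restricted to the tips descending from a focal internal
# node. Positive NRI = phylogenetic clustering, negative = overdispersion.

#' Mean pairwise phylogenetic distance
#'
#' @param species Character vector of >= 2 species.
#' @param dist Patristic distance matrix containing them.
#' @param abundance Optional named abundances; when given, pairs are
#'   weighted by the product of the two species' abundances
#'   (abundance-weighted MPD). Default NULL = presence-based, the standard
#'   for NRI.
#' @return Mean of d(i, j) over all unordered pairs (Myr).
#' @export
mpd <- function(species, dist, abundance = NULL) {
  species <- as.character(species)
  if (length(species) < 2) stop("MPD needs at least 2 species")
  miss <- setdiff(species, rownames(dist))
  if (length(miss)) stop("species not in distance matrix: ",
                         paste(miss, collapse = ", "))
  d <- dist[species, species]
  if (is.null(abundance))
    return(sum(d) / (length(species) * (length(species) - 1)))
  a <- as.numeric(abundance[species])
  if (anyNA(a) || any(a <= 0)) stop("positive abundance required for all species")
  w <- outer(a, a)
  diag(w) <- 0
  sum(w * d) / sum(w)
}

# deterministic substream seed in [1, 2^31-2]; doubles stay exact here
.substream_seed <- function(seed, a, b = 0) {
  s <- (as.numeric(seed) %% 2147483647) * 1009 + a * 8191 + b * 131
  as.integer(s %% 2147483646) + 1L
}

# n_null richness-k null communities from `pool` (indices into dist rows),
# sampled without replacement with probability proportional to prevalence;
# returns the vector of null MPD values
.null_mpd_draws <- function(pool, k, dist, w, n_null) {
  D <- dist[pool, pool]
  npool <- length(pool)
  denom <- k * (k - 1)
  vapply(seq_len(n_null), function(i) {
    s <- sample.int(npool, k, prob = w)
    sum(D[s, s]) / denom
  }, numeric(1))
}

#' Exact null MPD mean and SD by exhaustive enumeration
#'
#' For small pools (<= 8 species by default) enumerates every richness-k
#' subset and weighs it by its exact probability under sequential
#' prevalence-weighted sampling without replacement — the same scheme the
#' Monte-Carlo null uses. Serves as the independent oracle for the null
#' model.
#'
#' @param pool Character vector of pool species.
#' @param k Community size.
#' @param dist Patristic distance matrix.
#' @param prevalence Named occurrence counts (or weights) for the pool.
#' @param max_pool Safety cap on pool size (default 8).
#' @return List with \code{mean}, \code{sd} (population SD of the subset
#'   distribution) and \code{n_subsets}.
#' @export
null_mpd_exact <- function(pool, k, dist, prevalence, max_pool = 8) {
  pool <- as.character(pool)
  n <- length(pool)
  if (n > max_pool) stop("exhaustive enumeration capped at pool size ", max_pool)
  if (k < 2 || k > n) stop("k must be in 2..pool size")
  w <- as.numeric(prevalence[pool])
  if (anyNA(w) || any(w <= 0)) stop("prevalence must be positive for all pool species")
  W <- sum(w)
  subsets <- combn(n, k)
  probs <- apply(subsets, 2, function(s) .subset_prob(w[s], W))
  mpds <- apply(subsets, 2, function(s) {
    d <- dist[pool[s], pool[s]]
    sum(d) / (k * (k - 1))
  })
  stopifnot(abs(sum(probs) - 1) < 1e-8)
  m <- sum(probs * mpds)
  v <- sum(probs * mpds^2) - m^2
  list(mean = m, sd = sqrt(max(v, 0)), n_subsets = ncol(subsets))
}

# P(the first k sequential weighted draws are exactly this subset), summed
# over draw orders via bitmask DP: f(T) = sum_i f(T\i) * w_i / (W - sum(T\i))
.subset_prob <- function(w, W) {
  k <- length(w)
  f <- numeric(2^k)
  f[1] <- 1
  wsum <- c(0, numeric(2^k - 1))
  for (m in 1:(2^k - 1)) {
    bits <- which(bitwAnd(m, bitwShiftL(1L, 0:(k - 1))) != 0)
    wsum[m + 1] <- sum(w[bits])
    acc <- 0
    for (i in bits) {
      prev <- m - bitwShiftL(1L, i - 1L)
      acc <- acc + f[prev + 1] * w[i] / (W - wsum[prev + 1])
    }
    f[m + 1] <- acc
  }
  f[2^k]
}

#' NRI of one community against a node-restricted null
#'
#' Null communities are drawn by sampling the observed number of species
#' from the pool without replacement, with weights proportional to each
#' species' prevalence (occurrence frequency); richness is held exactly,
#' prevalence in expectation.
#'
#' @param plot_species Species present in the community (subset of
#'   \code{pool}; >= 2).
#' @param pool Species pool (the focal clade's species; >= 3).
#' @param dist Patristic distance matrix.
#' @param prevalence Named occurrence counts per pool species.
#' @param n_null Number of null communities (>= 99; default 999).
#' @param seed Integer seed.
#' @param node_id,plot_id Optional identifiers copied into the record.
#' @return One-row data.frame: node_id, plot_id, n_species_in_clade_in_plot,
#'   mpd_obs, mpd_null_mean, mpd_null_sd (sample SD, n-1), nri, estimable.
#'   Degenerate null SD (e.g. the community saturates the pool) yields a
#'   not-estimable record with NA nri.
#' @export
nri_community <- function(plot_species, pool, dist, prevalence,
                          n_null = 999, seed = 1L,
                          node_id = NA_integer_, plot_id = NA_character_) {
  plot_species <- as.character(plot_species)
  pool <- as.character(pool)
  if (!all(plot_species %in% pool)) stop("'plot_species' must be a subset of 'pool'")
  if (length(plot_species) < 2) stop("community needs >= 2 species")
  if (length(pool) < 3) stop("pool needs >= 3 species")
  if (length(plot_species) > length(pool)) stop("community larger than pool")
  if (n_null < 99) stop("n_null must be >= 99")
  w <- as.numeric(prevalence[pool])
  if (anyNA(w) || any(w <= 0)) stop("positive prevalence required for all pool species")
  obs <- mpd(plot_species, dist)
  set.seed(.substream_seed(seed, 0, length(plot_species)))
  draws <- .null_mpd_draws(match(pool, rownames(dist)), length(plot_species),
                           dist, w, n_null)
  mu <- mean(draws)
  sdev <- sd(draws)
  nri <- if (sdev > 0) -(obs - mu) / sdev else NA_real_
  data.frame(node_id = node_id, plot_id = plot_id,
             n_species_in_clade_in_plot = length(plot_species),
             mpd_obs = obs, mpd_null_mean = mu, mpd_null_sd = sdev,
             nri = nri, estimable = sdev > 0, stringsAsFactors = FALSE)
}

#' Classify a node's mean NRI
#'
#' Mean NRI above 0.5 = clustered, below -0.5 = overdispersed, the closed
#' band [-0.5, 0.5] = random; non-finite values are not estimable.
#'
#' @param mean_nri Numeric (vectorised).
#' @param band Half-width of the random band (default 0.5).
#' @return Character vector in {clustered, overdispersed, random,
#'   not_estimable}.
#' @export
classify_node <- function(mean_nri, band = 0.5) {
  out <- rep("not_estimable", length(mean_nri))
  ok <- is.finite(mean_nri)
  out[ok & mean_nri > band] <- "clustered"
  out[ok & mean_nri < -band] <- "overdispersed"
  out[ok & abs(mean_nri) <= band] <- "random"
  out
}

#' Node-by-node NRI scan over all communities
#'
#' For every internal node, the species pool is the set of tips descending
#' from that node that occur in at least one plot; every plot holding >= 2
#' pool species contributes an NRI value, and the node is summarised by the
#' mean and SD of those values. Nodes whose usable pool has <= 2 species are
#' not estimable. Within a node the null distribution of MPD depends only on
#' community size, so null mean/SD are computed once per distinct richness
#' (n_null draws each) from a deterministic per-(node, richness) substream.
#'
#' @param tree A \code{dated_tree}.
#' @param cm A \code{community_matrix}; species are intersected with the
#'   tree's tips (a warning reports any dropped).
#' @param n_null Null communities per (node, richness) (default 999).
#' @param seed Integer seed for the whole scan.
#' @param nodes Optional integer vector of node ids to restrict the scan.
#' @param band Classification band half-width (default 0.5).
#' @return List of class \code{node_nri_scan}: \code{table} (per-node
#'   summary: node_id, node_age, clade_richness, n_communities, mean_nri,
#'   sd_nri, ci_lo, ci_hi, classification) and \code{records} (all per-plot
#'   NRI records).
#' @export
node_nri_scan <- function(tree, cm, n_null = 999, seed = 1L, nodes = NULL,
                          band = 0.5) {
  stopifnot(inherits(tree, "dated_tree"), inherits(cm, "community_matrix"))
  sp <- intersect(tip_labels(tree), colnames(cm))
  if (!length(sp)) stop("no overlap between tree tips and matrix species")
  dropped <- setdiff(colnames(cm), tip_labels(tree))
  if (length(dropped))
    warning(length(dropped), " matrix species absent from tree dropped")
  P <- presence(cm)[, sp, drop = FALSE]
  prevalence <- colSums(P)
  present_sp <- sp[prevalence > 0]
  dist <- phylo_cophenetic(tree)
  ages <- node_ages(tree)

  ids <- if (is.null(nodes)) tree$node_map$node_id else as.integer(nodes)
  if (!all(ids %in% tree$node_map$node_id)) stop("unknown node id in 'nodes'")

  rec_list <- list()
  tab <- vector("list", length(ids))
  for (j in seq_along(ids)) {
    nid <- ids[j]
    pool <- intersect(subtree_tips(tree, nid), present_sp)
    richness <- length(pool)
    if (richness <= 2) {
      tab[[j]] <- data.frame(node_id = nid, node_age = unname(ages[as.character(nid)]),
                             clade_richness = richness, n_communities = 0L,
                             mean_nri = NA_real_, sd_nri = NA_real_,
                             ci_lo = NA_real_, ci_hi = NA_real_,
                             classification = "not_estimable",
                             stringsAsFactors = FALSE)
      next
    }
    sub <- P[, pool, drop = FALSE]
    kvec <- rowSums(sub)
    use <- which(kvec >= 2)
    nri_vals <- rep(NA_real_, length(use))
    if (length(use)) {
      w <- as.numeric(prevalence[pool])
      pool_idx <- match(pool, rownames(dist))
      null_by_k <- new.env(parent = emptyenv())
      recs <- vector("list", length(use))
      for (m in seq_along(use)) {
        i <- use[m]
        k <- kvec[i]
        key <- as.character(k)
        if (is.null(null_by_k[[key]])) {
          if (k >= richness) {
            null_by_k[[key]] <- c(NA_real_, 0)  # saturated: every draw = pool
          } else {
            set.seed(.substream_seed(seed, nid, k))
            draws <- .null_mpd_draws(pool_idx, k, dist, w, n_null)
            null_by_k[[key]] <- c(mean(draws), sd(draws))
          }
        }
        nm <- null_by_k[[key]]
        pres <- pool[sub[i, ] > 0]
        obs <- mpd(pres, dist)
        if (k >= richness) nm[1] <- obs  # null degenerate at the full pool
        nri <- if (is.finite(nm[2]) && nm[2] > 0) -(obs - nm[1]) / nm[2] else NA_real_
        recs[[m]] <- data.frame(
          node_id = nid, plot_id = rownames(P)[i],
          n_species_in_clade_in_plot = as.integer(k),
          mpd_obs = obs, mpd_null_mean = nm[1], mpd_null_sd = nm[2],
          nri = nri, estimable = is.finite(nri), stringsAsFactors = FALSE)
        nri_vals[m] <- nri
      }
      rec_list[[length(rec_list) + 1L]] <- do.call(rbind, recs)
    }
    ok <- is.finite(nri_vals)
    n_comm <- sum(ok)
    mean_nri <- if (n_comm > 0) mean(nri_vals[ok]) else NA_real_
    sd_nri <- if (n_comm > 1) sd(nri_vals[ok]) else NA_real_
    half <- if (n_comm > 1) 1.96 * sd_nri / sqrt(n_comm) else NA_real_
    tab[[j]] <- data.frame(
      node_id = nid, node_age = unname(ages[as.character(nid)]),
      clade_richness = richness, n_communities = n_comm,
      mean_nri = mean_nri, sd_nri = sd_nri,
      ci_lo = mean_nri - half, ci_hi = mean_nri + half,
      classification = if (n_comm == 0) "not_estimable"
                       else classify_node(mean_nri, band),
      stringsAsFactors = FALSE)
  }
  structure(list(table = do.call(rbind, tab),
                 records = if (length(rec_list)) do.call(rbind, rec_list)
                           else data.frame(),
                 n_null = n_null, seed = as.integer(seed), band = band),
            class = "node_nri_scan")
}

#' @export
print.node_nri_scan <- function(x, ...) {
  cl <- table(factor(x$table$classification,
                     c("clustered", "overdispersed", "random", "not_estimable")))
  cat("Node NRI scan:", nrow(x$table), "nodes (",
      paste(names(cl), cl, sep = "=", collapse = ", "), "); n_null =",
      x$n_null, "\n")
  invisible(x)
}
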