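# shared fixture builders; everything is generated in code

# "((A:1,B:1):1,C:2);" -- the canonical 3-tip worked example
tiny_tree <- function() as_dated_tree(ape::read.tree(text = "((A:1,B:1):1,C:2);"))

# presence/absence community matrix from a named list of occupied plot indices
presence_cm <- function(occupancy, n_plots) {
  m <- matrix(0, n_plots, length(occupancy),
              dimnames = list(paste0("p", seq_len(n_plots)), names(occupancy)))
  for (s in names(occupancy)) m[occupancy[[s]], s] <- 50
  community_matrix(m)
}

# random Bernoulli community matrix where every species occurs at least once
random_cm <- function(n_plots, species, p = 0.3) {
  repeat {
    m <- matrix(rbinom(n_plots * length(species), 1, p) * 50, n_plots,
                dimnames = list(paste0("p", seq_len(n_plots)), species))
    if (all(colSums(m) > 0) && all(rowSums(m) > 0)) return(community_matrix(m))
  }
}

# independent brute-force recomputation of node ages: mean path length from
# the node to each descendant tip, walking raw edges (oracle for node_ages)
brute_force_ages <- function(tree) {
  phy <- tree$phy
  ntip <- length(phy$tip.label)
  children <- split(seq_len(nrow(phy$edge)), phy$edge[, 1])
  dist_to_tips <- function(node) {
    if (node <= ntip) return(0)
    unlist(lapply(children[[as.character(node)]], function(e)
      phy$edge.length[e] + dist_to_tips(phy$edge[e, 2])))
  }
  vapply(seq_len(nrow(tree$node_map)), function(i) {
    d <- dist_to_tips(tree$node_map$ape_node[i])
    if (max(d) - min(d) > 1e-8 * max(d)) stop("tree not ultrametric")
    mean(d)
  }, numeric(1))
}
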