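# ---- pairwise co-occurrence and the global permutation test -----------------

#' Pairwise co-occurrence index for one species pair
#'
#' The number of plots where both species are present, divided by the
#' occurrence count of the rarer of the two: C = N(S1 & S2) / min(N1, N2).
#' Ranges from 0 (no shared plot) to 1 (the rarer species' plots are a subset
#' of the other's).
#'
#' @param cm A \code{community_matrix}.
#' @param s1,s2 Species names.
#' @return A proportion in [0, 1].
#' @export
cooccurrence_index <- function(cm, s1, s2) {
  stopifnot(inherits(cm, "community_matrix"))
  p <- presence(cm)
  for (s in c(s1, s2)) {
    if (!s %in% colnames(p)) stop("unknown species: ", s)
    if (sum(p[, s]) == 0) stop("species with zero occurrences: ", s)
  }
  sum(p[, s1] & p[, s2]) / min(sum(p[, s1]), sum(p[, s2]))
}

#' Pairwise co-occurrence matrix over all species
#'
#' @param cm A \code{community_matrix}; every species must occur at least
#'   once.
#' @return An object of class \code{cooccurrence_matrix}: symmetric species x
#'   species matrix of indices with unit diagonal; attribute \code{n_occ}
#'   carries the per-species occurrence counts.
#' @export
cooccurrence_matrix <- function(cm) {
  stopifnot(inherits(cm, "community_matrix"))
  p <- presence(cm)
  n <- colSums(p)
  if (any(n == 0))
    stop("species with zero occurrences: ",
         paste(colnames(p)[n == 0], collapse = ", "))
  if (ncol(p) < 2) stop("need at least 2 species")
  both <- crossprod(p)
  cmat <- both / outer(n, n, pmin)
  structure(cmat, n_occ = n, class = c("cooccurrence_matrix", "matrix", "array"))
}

#' @export
print.cooccurrence_matrix <- function(x, ...) {
  cat("Co-occurrence matrix:", ncol(x), "species; mean off-diagonal index",
      format(mean(x[upper.tri(x)]), digits = 4), "\n")
  invisible(x)
}

#' Global test of co-occurrence against phylogenetic distance
#'
#' Spearman correlation between the pairwise co-occurrence index and the
#' patristic distance over the upper triangle of species pairs, with a
#' two-sided permutation test: the null is built by permuting the species
#' labels of the distance matrix (Mantel-style) while the co-occurrence
#' matrix, and hence the occupancy structure, stays fixed. A significant
#' negative correlation indicates treewide phylogenetic clustering, a
#' positive one overdispersion.
#'
#' @param cm A \code{community_matrix}.
#' @param dist Patristic distance matrix (see \code{\link{phylo_cophenetic}}).
#' @param n_rand Number of label permutations (default 999; >= 99).
#' @param seed Integer seed for the permutation stream.
#' @param stratum_species Optional species subset (e.g. monocots, or species
#'   of one vegetation zone); pairs are restricted to the stratum.
#' @param stratum Label recorded in the result.
#' @return A one-row data.frame of class \code{global_test_result}:
#'   \code{rho}, \code{p_value} (add-one rule, never exactly 0),
#'   \code{n_pairs}, \code{n_randomizations}, \code{stratum}, \code{seed}.
#' @export
global_phylo_cooccurrence_test <- function(cm, dist, n_rand = 999, seed = 1L,
                                           stratum_species = NULL,
                                           stratum = "all") {
  stopifnot(inherits(cm, "community_matrix"), n_rand >= 99)
  sp <- intersect(colnames(cm), rownames(dist))
  if (!is.null(stratum_species)) sp <- intersect(sp, stratum_species)
  if (length(sp) < 3)
    stop("need at least 3 species in stratum '", stratum, "' (have ",
         length(sp), ")")
  cmat <- cooccurrence_matrix(community_matrix(unclass(cm)[, sp, drop = FALSE]))
  d <- dist[sp, sp]
  ut <- upper.tri(d)
  rc <- rank(cmat[ut])
  rho_obs <- cor(rc, rank(d[ut]))
  S <- length(sp)
  set.seed(as.integer(seed %% .Machine$integer.max))
  rho_perm <- vapply(seq_len(n_rand), function(i) {
    perm <- sample.int(S)
    cor(rc, rank(d[perm, perm][ut]))
  }, numeric(1))
  p <- (1 + sum(abs(rho_perm) >= abs(rho_obs))) / (1 + n_rand)
  structure(data.frame(rho = rho_obs, p_value = p,
                       n_pairs = sum(ut), n_randomizations = n_rand,
                       stratum = stratum, seed = as.integer(seed),
                       stringsAsFactors = FALSE),
            class = c("global_test_result", "data.frame"))
}

#' Long-format pair table of co-occurrence and phylogenetic distance
#'
#' @param cm A \code{community_matrix}.
#' @param dist Optional patristic distance matrix; adds a \code{phylo_dist}
#'   column for shared species.
#' @return data.frame with one row per unordered species pair: s1, s2, N1,
#'   N2, N_both, C and (optionally) phylo_dist.
#' @export
cooccurrence_pair_table <- function(cm, dist = NULL) {
  cmat <- cooccurrence_matrix(cm)
  n <- attr(cmat, "n_occ")
  sp <- colnames(cmat)
  idx <- which(upper.tri(cmat), arr.ind = TRUE)
  p <- presence(cm)
  out <- data.frame(
    s1 = sp[idx[, 1]], s2 = sp[idx[, 2]],
    N1 = n[idx[, 1]], N2 = n[idx[, 2]],
    N_both = crossprod(p)[idx],
    C = cmat[idx], row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(dist)) {
    ok <- out$s1 %in% rownames(dist) & out$s2 %in% rownames(dist)
    pd <- rep(NA_real_, nrow(out))
    pd[ok] <- dist[cbind(out$s1[ok], out$s2[ok])]
    out$phylo_dist <- pd
  }
  out
}
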