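# ---- NRI vs elevation, node age and richness --------------------------------

#' Per-node linear regression of NRI on elevation
#'
#' Ordinary least squares of the per-plot NRI values of one node on plot
#' elevation, with the two-sided t-test of the slope (t distribution with
#' n - 2 df).
#'
#' @param records Data.frame of NRI records for one node (columns
#'   \code{plot_id}, \code{nri}).
#' @param elevations Named vector (plot_id -> metres) or a
#'   \code{plot_metadata}.
#' @param alpha Significance level (default 0.05).
#' @return One-row data.frame of class \code{gradient_fit}: node_id, slope
#'   (NRI per metre), intercept, t_statistic, p_value, n_points, direction
#'   (increasing/decreasing), significant.
#' @export
nri_elevation_regression <- function(records, elevations, alpha = 0.05) {
  if (inherits(elevations, "plot_metadata"))
    elevations <- setNames(elevations$elevation, elevations$plot_id)
  nri <- records$nri
  elev <- as.numeric(elevations[as.character(records$plot_id)])
  ok <- is.finite(nri) & is.finite(elev)
  if (sum(ok) < 3) stop("need >= 3 (plot, NRI) points with finite values")
  nri <- nri[ok]; elev <- elev[ok]
  if (diff(range(elev)) == 0) stop("constant elevation: slope not identifiable")
  fit <- lm(nri ~ elev)
  sm <- summary(fit)$coefficients
  slope <- sm["elev", "Estimate"]
  data.frame(
    node_id = if ("node_id" %in% names(records)) records$node_id[1] else NA_integer_,
    slope = slope, intercept = sm["(Intercept)", "Estimate"],
    t_statistic = sm["elev", "t value"], p_value = sm["elev", "Pr(>|t|)"],
    n_points = sum(ok),
    direction = if (slope >= 0) "increasing" else "decreasing",
    significant = sm["elev", "Pr(>|t|)"] < alpha,
    stringsAsFactors = FALSE)
}

#' Elevation regressions for every estimable node of a scan
#'
#' @param scan A \code{\link{node_nri_scan}} result.
#' @param elevations Named vector or \code{plot_metadata}.
#' @param alpha Significance level.
#' @param adjust If TRUE, adds Benjamini-Hochberg adjusted p-values and a
#'   \code{significant_bh} column (no correction is applied by default).
#' @return Data.frame with one \code{gradient_fit} row per node with >= 3
#'   finite NRI points.
#' @export
gradient_table <- function(scan, elevations, alpha = 0.05, adjust = FALSE) {
  stopifnot(inherits(scan, "node_nri_scan"))
  recs <- scan$records
  if (!nrow(recs)) stop("scan has no NRI records")
  fits <- lapply(split(recs, recs$node_id), function(r) {
    r <- r[is.finite(r$nri), , drop = FALSE]
    if (nrow(r) < 3) return(NULL)
    elev <- if (inherits(elevations, "plot_metadata"))
      setNames(elevations$elevation, elevations$plot_id) else elevations
    e <- as.numeric(elev[as.character(r$plot_id)])
    if (length(unique(e[is.finite(e)])) < 2) return(NULL)
    nri_elevation_regression(r, elevations, alpha)
  })
  out <- do.call(rbind, fits[!vapply(fits, is.null, logical(1))])
  if (is.null(out) || !nrow(out)) stop("no node has enough points for a fit")
  rownames(out) <- NULL
  out <- out[order(out$node_id), , drop = FALSE]
  if (adjust) {
    out$p_bh <- stats::p.adjust(out$p_value, "BH")
    out$significant_bh <- out$p_bh < alpha
  }
  out
}

#' Gaussian GLM of mean node NRI on clade richness and node age
#'
#' Fits mean_nri ~ community_size + node_age with Gaussian errors and
#' identity link (equivalent to OLS) on the estimable nodes of a scan table.
#' "Community size" is the node's clade richness — the number of pool
#' species the node contributes to communities.
#'
#' @param table The \code{table} element of a \code{node_nri_scan} (or any
#'   data.frame with mean_nri, clade_richness, node_age).
#' @param family A \code{stats::family} (default \code{gaussian()}).
#' @return List of class \code{node_model_fit}: \code{coefficients} (named:
#'   intercept, community_size, node_age), \code{p_values}, \code{n_nodes},
#'   \code{fit} (the glm object).
#' @export
fit_age_size_model <- function(table, family = gaussian()) {
  df <- table[is.finite(table$mean_nri), , drop = FALSE]
  if (nrow(df) < 10) stop("need >= 10 estimable nodes (have ", nrow(df), ")")
  if (abs(cor(df$clade_richness, df$node_age)) > 0.999)
    stop("clade richness and node age are collinear")
  fit <- glm(mean_nri ~ clade_richness + node_age, data = df, family = family)
  sm <- summary(fit)$coefficients
  cf <- setNames(sm[, "Estimate"], c("intercept", "community_size", "node_age"))
  pv <- setNames(sm[, 4], c("intercept", "community_size", "node_age"))
  structure(list(coefficients = cf, p_values = pv, n_nodes = nrow(df),
                 fit = fit),
            class = "node_model_fit")
}

#' @export
print.node_model_fit <- function(x, ...) {
  cat("Gaussian GLM of mean node NRI (", x$n_nodes, " nodes):\n", sep = "")
  print(data.frame(estimate = x$coefficients, p_value = x$p_values))
  invisible(x)
}

#' Per-node Spearman correlation between NRI and within-plot clade richness
#'
#' Diagnoses whether a node's NRI values merely track how many of its
#' species co-occur in a plot.
#'
#' @param scan A \code{\link{node_nri_scan}} result.
#' @param alpha Significance level.
#' @return Data.frame per node: rho, p_value, n_points, significant,
#'   defined (FALSE when richness is constant across plots, where rho is
#'   undefined and flagged rather than imputed).
#' @export
richness_nri_correlation <- function(scan, alpha = 0.05) {
  stopifnot(inherits(scan, "node_nri_scan"))
  recs <- scan$records
  if (!nrow(recs)) stop("scan has no NRI records")
  out <- lapply(split(recs, recs$node_id), function(r) {
    r <- r[is.finite(r$nri), , drop = FALSE]
    if (nrow(r) < 3) return(NULL)
    rich <- r$n_species_in_clade_in_plot
    if (length(unique(rich)) < 2)
      return(data.frame(node_id = r$node_id[1], rho = NA_real_,
                        p_value = NA_real_, n_points = nrow(r),
                        significant = FALSE, defined = FALSE))
    ct <- suppressWarnings(cor.test(r$nri, rich, method = "spearman"))
    data.frame(node_id = r$node_id[1], rho = unname(ct$estimate),
               p_value = ct$p.value, n_points = nrow(r),
               significant = ct$p.value < alpha, defined = TRUE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  out[order(out$node_id), , drop = FALSE]
}

# canonical clade key: sorted descendant tip labels
.clade_key <- function(tips) paste(sort(tips), collapse = "|")

#' Robustness of elevation slopes across posterior trees
#'
#' Repeats the node NRI scan and per-node elevation regression on each tree
#' of a posterior sample and summarises the slope per clade. Nodes are
#' matched across trees by descendant tip-set identity (the only
#' topology-safe correspondence); clades recovered in fewer than
#' \code{min_presence} of the trees are flagged unstable.
#'
#' @param trees List of \code{dated_tree} (>= 2), e.g. from
#'   \code{\link{read_trees}}.
#' @param cm A \code{community_matrix}.
#' @param elevations Named vector or \code{plot_metadata}.
#' @param n_null Null draws per (node, richness).
#' @param seed Integer seed (one substream per tree).
#' @param min_presence Minimum fraction of trees a clade must appear in to
#'   count as stable (default 0.5).
#' @return List of class \code{posterior_robustness}: \code{stable}
#'   (data.frame clade_key, n_trees_present, slope_mean, slope_sd),
#'   \code{unstable} (clade keys below the presence threshold),
#'   \code{n_trees}.
#' @export
posterior_tree_scan <- function(trees, cm, elevations, n_null = 199,
                                seed = 1L, min_presence = 0.5) {
  if (length(trees) < 2) stop("need >= 2 trees")
  shared <- Reduce(intersect, lapply(trees, tip_labels))
  if (!length(intersect(shared, colnames(cm))))
    stop("trees share no tips with the community matrix")
  slope_by_clade <- list()
  for (ti in seq_along(trees)) {
    tree <- trees[[ti]]
    # one common seed across trees: identical trees then give identical
    # scans (and zero slope SD), as the matching contract requires
    scan <- suppressWarnings(
      node_nri_scan(tree, cm, n_null = n_null, seed = seed))
    fits <- tryCatch(gradient_table(scan, elevations), error = function(e) NULL)
    if (is.null(fits)) next
    keys <- vapply(fits$node_id, function(nid)
      .clade_key(subtree_tips(tree, nid)), character(1))
    for (i in seq_along(keys)) {
      slope_by_clade[[keys[i]]] <- c(slope_by_clade[[keys[i]]], fits$slope[i])
    }
  }
  n_present <- vapply(slope_by_clade, length, integer(1))
  stable_keys <- names(slope_by_clade)[n_present >= min_presence * length(trees)]
  stable <- data.frame(
    clade_key = stable_keys,
    n_trees_present = n_present[stable_keys],
    slope_mean = vapply(slope_by_clade[stable_keys], mean, numeric(1)),
    slope_sd = vapply(slope_by_clade[stable_keys], function(x)
      if (length(x) > 1) sd(x) else 0, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(stable = stable,
                 unstable = setdiff(names(slope_by_clade), stable_keys),
                 n_trees = length(trees)),
            class = "posterior_robustness")
}

#' @export
print.posterior_robustness <- function(x, ...) {
  cat("Posterior robustness over", x$n_trees, "trees:",
      nrow(x$stable), "stable clades,", length(x$unstable), "unstable\n")
  invisible(x)
}
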