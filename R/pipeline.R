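# ---- end-to-end pipeline ----------------------------------------------------

#' Build a run configuration
#'
#' @param tree Path to a Newick/NEXUS tree, or a \code{dated_tree}.
#' @param community Path to the community CSV (first column plot_id), or a
#'   \code{community_matrix}.
#' @param metadata Path to the metadata CSV (plot_id, elevation[, zone]), or
#'   a \code{plot_metadata}.
#' @param out_dir Output directory (created if missing).
#' @param cover_classes TRUE when the community CSV holds ordinal classes
#'   0..8 rather than percent cover.
#' @param min_occurrences Species retention threshold (kept if present in
#'   strictly more plots than this; default 20).
#' @param min_cover_fraction Plot retention threshold on relative cover of
#'   the retained species (default 0.8, inclusive).
#' @param zone_breakpoints Elevations separating the four vegetation zones
#'   (default 900/1500/2200 m), or NULL to skip zone strata.
#' @param n_null Null communities per (node, richness) (default 999).
#' @param n_rand Permutations of the global test (default 999).
#' @param band NRI classification band half-width (default 0.5).
#' @param alpha Significance level (default 0.05).
#' @param seed Master seed; every stage derives its stream from it.
#' @param outgroups Tip labels pruned from the tree before analysis.
#' @param posterior_trees Optional path to a multi-tree Newick file.
#' @param strata Optional named list of species vectors (e.g. monocots /
#'   eudicots) for additional global-test strata.
#' @return List of class \code{run_config}.
#' @export
run_config <- function(tree, community, metadata, out_dir,
                       cover_classes = FALSE, min_occurrences = 20,
                       min_cover_fraction = 0.8,
                       zone_breakpoints = c(900, 1500, 2200),
                       n_null = 999, n_rand = 999, band = 0.5, alpha = 0.05,
                       seed = 1L, outgroups = NULL, posterior_trees = NULL,
                       strata = NULL) {
  cfg <- list(tree = tree, community = community, metadata = metadata,
              out_dir = out_dir, cover_classes = cover_classes,
              min_occurrences = min_occurrences,
              min_cover_fraction = min_cover_fraction,
              zone_breakpoints = zone_breakpoints, n_null = n_null,
              n_rand = n_rand, band = band, alpha = alpha,
              seed = as.integer(seed), outgroups = outgroups,
              posterior_trees = posterior_trees, strata = strata)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from JSON
#'
#' All fields of \code{\link{run_config}} are accepted; paths are resolved
#' relative to the JSON file's directory.
#' @param path JSON config path.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p) || is.na(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  for (f in c("tree", "community", "metadata", "posterior_trees"))
    if (!is.null(raw[[f]])) raw[[f]] <- resolve(raw[[f]])
  if (is.null(raw$out_dir)) stop("config needs 'out_dir'")
  if (!grepl("^/", raw$out_dir)) raw$out_dir <- file.path(base, raw$out_dir)
  do.call(run_config, raw)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Stages: load and prune the tree; load the community matrix and metadata;
#' species frequency filter; relative-cover plot filter; global
#' co-occurrence vs phylogenetic distance test (all species, optional
#' strata, vegetation zones); node-by-node NRI scan; per-node elevation
#' regressions; Gaussian GLM of mean NRI on clade richness and node age;
#' per-node richness correlations; optional posterior-tree robustness.
#' All tables are written as CSV, the tree as annotated Newick
#' (\code{nodeID|meanNRI|class} labels), and a JSON manifest records the
#' seed, package version and row counts at every stage. Re-running the same
#' configuration reproduces byte-identical outputs.
#'
#' @param config A \code{\link{run_config}} or path to a JSON config.
#' @return The manifest (invisibly a list), with \code{$files} naming all
#'   outputs.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  tree <- .stage("read_tree", {
    tr <- if (inherits(config$tree, "dated_tree")) config$tree
          else read_tree(config$tree)
    if (!is.null(config$outgroups)) tr <- prune_tips(tr, config$outgroups)
    tr
  })
  cm_raw <- .stage("read_community", {
    if (inherits(config$community, "community_matrix")) config$community
    else read_community_csv(config$community, config$cover_classes)
  })
  meta <- .stage("read_metadata", {
    if (inherits(config$metadata, "plot_metadata")) config$metadata
    else read_metadata_csv(config$metadata)
  })
  miss_meta <- setdiff(rownames(cm_raw), meta$plot_id)
  if (length(miss_meta))
    stop("pipeline stage 'read_metadata' failed: plots without metadata: ",
         paste(utils::head(miss_meta, 5), collapse = ", "))

  cm_freq <- .stage("filter_species",
                    filter_species_by_frequency(cm_raw, config$min_occurrences))
  retained <- intersect(colnames(cm_freq), tip_labels(tree))
  n_not_in_tree <- ncol(cm_freq) - length(retained)
  cm <- .stage("filter_plots", suppressWarnings(
    filter_plots_by_relative_cover(cm_raw, retained,
                                   config$min_cover_fraction)))
  meta <- meta[meta$plot_id %in% rownames(cm), , drop = FALSE]
  if (!is.null(config$zone_breakpoints))
    meta <- assign_vegetation_zones(meta, config$zone_breakpoints)
  elev <- setNames(meta$elevation, meta$plot_id)

  dist <- phylo_cophenetic(tree)
  global <- .stage("global_test", {
    res <- list(global_phylo_cooccurrence_test(
      cm, dist, config$n_rand, seed = .substream_seed(config$seed, 11)))
    for (nm in names(config$strata)) {
      res[[length(res) + 1L]] <- tryCatch(
        global_phylo_cooccurrence_test(
          cm, dist, config$n_rand,
          seed = .substream_seed(config$seed, 11, length(res)),
          stratum_species = config$strata[[nm]], stratum = nm),
        error = function(e) NULL)
    }
    if (!is.null(config$zone_breakpoints)) {
      for (z in setdiff(unique(meta$zone), "unassigned")) {
        plots <- meta$plot_id[meta$zone == z]
        if (length(plots) < 2) next
        zcm <- unclass(cm)[plots, , drop = FALSE]
        zcm <- zcm[, colSums(zcm > 0) > 0, drop = FALSE]
        if (ncol(zcm) < 3) next
        res[[length(res) + 1L]] <- tryCatch(
          global_phylo_cooccurrence_test(
            community_matrix(zcm), dist, config$n_rand,
            seed = .substream_seed(config$seed, 12, length(res)), stratum = z),
          error = function(e) NULL)
      }
    }
    do.call(rbind, res[!vapply(res, is.null, logical(1))])
  })

  scan <- .stage("node_nri_scan", suppressWarnings(
    node_nri_scan(tree, cm, n_null = config$n_null,
                  seed = .substream_seed(config$seed, 21),
                  band = config$band)))
  grad <- .stage("gradient_fits",
                 gradient_table(scan, elev, alpha = config$alpha,
                                adjust = TRUE))
  agesize <- .stage("age_size_model", tryCatch(
    fit_age_size_model(scan$table), error = function(e) NULL))
  richcor <- .stage("richness_correlation",
                    richness_nri_correlation(scan, alpha = config$alpha))

  posterior <- NULL
  if (!is.null(config$posterior_trees)) {
    posterior <- .stage("posterior_scan", {
      trees <- read_trees(config$posterior_trees)
      posterior_tree_scan(trees, cm, elev, n_null = min(config$n_null, 199),
                          seed = .substream_seed(config$seed, 31))
    })
  }

  out <- function(f) file.path(config$out_dir, f)
  files <- list(
    pair_table = out("cooccurrence_pairs.csv"),
    global_test = out("global_test.csv"),
    node_table = out("node_nri.csv"),
    nri_records = out("nri_records.csv"),
    gradient = out("gradient_fits.csv"),
    richness_correlation = out("richness_correlation.csv"),
    annotated_tree = out("tree_annotated.nwk"),
    node_map = out("node_map.csv"),
    manifest = out("manifest.json"))
  write.csv(cooccurrence_pair_table(cm, dist), files$pair_table,
            row.names = FALSE)
  write.csv(global, files$global_test, row.names = FALSE)
  write.csv(scan$table, files$node_table, row.names = FALSE)
  write.csv(scan$records, files$nri_records, row.names = FALSE)
  write.csv(grad, files$gradient, row.names = FALSE)
  write.csv(richcor, files$richness_correlation, row.names = FALSE)
  write.csv(tree$node_map, files$node_map, row.names = FALSE)
  write_tree(tree, files$annotated_tree,
             annotations = data.frame(node_id = scan$table$node_id,
                                      mean_nri = scan$table$mean_nri,
                                      classification = scan$table$classification))
  if (!is.null(posterior)) {
    files$posterior <- out("posterior_robustness.csv")
    write.csv(posterior$stable, files$posterior, row.names = FALSE)
  }
  if (!is.null(agesize)) {
    files$age_size_model <- out("age_size_model.csv")
    write.csv(data.frame(term = names(agesize$coefficients),
                         estimate = unname(agesize$coefficients),
                         p_value = unname(agesize$p_values)),
              files$age_size_model, row.names = FALSE)
  }

  manifest <- list(
    package = "lineacom",
    version = as.character(utils::packageVersion("lineacom")),
    seed = config$seed,
    counts = list(
      plots_in = nrow(cm_raw), species_in = ncol(cm_raw),
      species_after_frequency_filter = ncol(cm_freq),
      species_not_in_tree = n_not_in_tree,
      species_retained = length(retained),
      plots_after_cover_filter = nrow(cm),
      internal_nodes = n_internal_nodes(tree),
      nodes_estimable = sum(scan$table$classification != "not_estimable"),
      gradient_fits = nrow(grad)),
    parameters = config[c("min_occurrences", "min_cover_fraction", "n_null",
                          "n_rand", "band", "alpha")],
    files = files)
  jsonlite::write_json(manifest, files$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
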