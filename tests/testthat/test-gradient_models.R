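test_that("noiseless regression is recovered exactly", {
  recs <- data.frame(node_id = 1, plot_id = paste0("p", 1:20),
                     nri = 0.001 * seq(400, 3000, length.out = 20))
  elev <- setNames(seq(400, 3000, length.out = 20), paste0("p", 1:20))
  fit <- suppressWarnings(nri_elevation_regression(recs, elev))
  expect_equal(fit$slope, 0.001, tolerance = 1e-12)
  expect_equal(fit$direction, "increasing")
  expect_true(fit$significant)
  expect_equal(fit$n_points, 20)

  expect_error(nri_elevation_regression(recs[1:2, ], elev), ">= 3")
  expect_error(nri_elevation_regression(recs, setNames(rep(1000, 20),
                                                       paste0("p", 1:20))),
               "constant elevation")
})

test_that("slope t and p are shift- and scale-equivariant in elevation", {
  set.seed(1)
  recs <- data.frame(node_id = 2, plot_id = paste0("p", 1:50),
                     nri = rnorm(50))
  e <- runif(50, 400, 3000)
  elev1 <- setNames(e, recs$plot_id)
  f1 <- nri_elevation_regression(recs, elev1)
  f2 <- nri_elevation_regression(recs, elev1 + 5000)
  f3 <- nri_elevation_regression(recs, setNames(scale(e)[, 1], recs$plot_id))
  expect_equal(f1$t_statistic, f2$t_statistic, tolerance = 1e-10)
  expect_equal(f1$t_statistic, f3$t_statistic, tolerance = 1e-10)
  expect_equal(f1$p_value, f3$p_value, tolerance = 1e-10)
})

test_that("Gaussian-identity GLM equals OLS", {
  set.seed(2)
  tab <- data.frame(node_id = 1:30,
                    mean_nri = rnorm(30),
                    clade_richness = sample(3:40, 30, replace = TRUE),
                    node_age = runif(30, 1, 80))
  fit <- fit_age_size_model(tab)
  ols <- lm(mean_nri ~ clade_richness + node_age, data = tab)
  expect_equal(unname(fit$coefficients), unname(coef(ols)), tolerance = 1e-8)

  const <- transform(tab, mean_nri = 0.42)
  f0 <- fit_age_size_model(const)
  expect_equal(unname(f0$coefficients["community_size"]), 0, tolerance = 1e-12)
  expect_equal(unname(f0$coefficients["node_age"]), 0, tolerance = 1e-12)
  expect_equal(unname(f0$coefficients["intercept"]), 0.42, tolerance = 1e-12)

  colin <- transform(tab, node_age = clade_richness * 2)
  expect_error(fit_age_size_model(colin), "collinear")
  expect_error(fit_age_size_model(tab[1:5, ]), ">= 10")
})

test_that("richness correlation handles monotone, null and degenerate cases", {
  mk_scan <- function(records) structure(list(records = records, table = NULL),
                                         class = "node_nri_scan")
  recs <- data.frame(node_id = 1, plot_id = paste0("p", 1:10),
                     n_species_in_clade_in_plot = 2:11, nri = seq(0.1, 1, 0.1))
  out <- richness_nri_correlation(mk_scan(recs))
  expect_equal(out$rho, 1)
  expect_true(out$defined)

  ties <- transform(recs, n_species_in_clade_in_plot = 5)
  out <- richness_nri_correlation(mk_scan(ties))
  expect_false(out$defined)
  expect_true(is.na(out$rho))

  # null calibration: independent NRI and richness reject ~5% of the time
  set.seed(3)
  hits <- vapply(1:500, function(i) {
    r <- data.frame(node_id = 1, plot_id = paste0("p", 1:30),
                    n_species_in_clade_in_plot = sample(2:12, 30, TRUE),
                    nri = rnorm(30))
    richness_nri_correlation(mk_scan(r))$significant
  }, logical(1))
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / 500)
  expect_gt(mean(hits), ci[1])
  expect_lt(mean(hits), ci[2])
})

test_that("posterior scan matches clades by tip set", {
  tr <- simulate_yule_tree(15, 1, seed = 4)
  set.seed(5)
  cm <- random_cm(40, tip_labels(tr), p = 0.4)
  meta <- plot_metadata(rownames(cm), seq(400, 3000, length.out = 40))
  elev <- setNames(meta$elevation, meta$plot_id)

  # identical trees: every stable clade has slope SD exactly 0
  rob <- suppressWarnings(
    posterior_tree_scan(rep(list(tr), 5), cm, elev, n_null = 99, seed = 1))
  expect_true(nrow(rob$stable) > 0)
  expect_true(all(rob$stable$slope_sd == 0))
  expect_true(all(rob$stable$n_trees_present == 5))

  # +/-5% branch-length jitter keeps the topology: all clades still match
  set.seed(6)
  jit <- lapply(1:3, function(i) {
    phy <- tr$phy
    phy$edge.length <- phy$edge.length * runif(length(phy$edge.length), 0.95, 1.05)
    suppressWarnings(as_dated_tree(phy))
  })
  rob2 <- suppressWarnings(
    posterior_tree_scan(jit, cm, elev, n_null = 99, seed = 2))
  keys1 <- sort(rob$stable$clade_key)
  expect_true(all(sort(rob2$stable$clade_key) == keys1))
  expect_length(rob2$unstable, 0)

  # disjoint tip sets cannot be analysed
  tr2 <- simulate_yule_tree(15, 1, seed = 9)
  tr2$phy$tip.label <- paste0("other", 1:15)
  expect_error(posterior_tree_scan(list(as_dated_tree(tr2$phy), tr),
                                   cm, elev, n_null = 99),
               "share no tips")

  # a clade unique to one tree is flagged unstable (presence threshold)
  rob3 <- suppressWarnings(posterior_tree_scan(
    list(tr, simulate_yule_tree(15, 1, seed = 30)), cm, elev,
    n_null = 99, seed = 3, min_presence = 0.9))
  expect_true(length(rob3$unstable) > 0)
})
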