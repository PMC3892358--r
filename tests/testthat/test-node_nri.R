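test_that("MPD is the mean over unordered pairs", {
  tr <- tiny_tree()
  d <- phylo_cophenetic(tr)
  expect_equal(mpd(c("A", "B", "C"), d), 10 / 3)   # (2 + 4 + 4) / 3
  expect_equal(mpd(c("A", "C"), d), 4)
  expect_error(mpd("A", d), "at least 2")

  # star clade with tip branches t: every subset of a..e has MPD = 2t
  star <- as_dated_tree(ape::read.tree(text = "(f:6,(a:3,b:3,c:3,d:3,e:3):3);"))
  ds <- phylo_cophenetic(star)
  for (k in 2:5)
    expect_equal(mpd(letters[1:k], ds), 6)
})

test_that("abundance-weighted MPD reduces to unweighted under equal abundance", {
  tr <- tiny_tree()
  d <- phylo_cophenetic(tr)
  eq <- setNames(rep(3, 3), c("A", "B", "C"))
  expect_equal(mpd(c("A", "B", "C"), d, abundance = eq),
               mpd(c("A", "B", "C"), d))
  # hand-weighted: abundances 1, 1, 2 -> weights AB:1, AC:2, BC:2
  ab <- c(A = 1, B = 1, C = 2)
  expect_equal(mpd(c("A", "B", "C"), d, abundance = ab),
               (1 * 2 + 2 * 4 + 2 * 4) / 5)
  expect_error(mpd(c("A", "B"), d, abundance = c(A = 1, B = -1)), "positive")
})

test_that("classification bands are inclusive for 'random'", {
  expect_equal(classify_node(0.51), "clustered")
  expect_equal(classify_node(-0.5), "random")
  expect_equal(classify_node(0.5), "random")
  expect_equal(classify_node(0), "random")
  expect_equal(classify_node(-0.51), "overdispersed")
  expect_equal(classify_node(NaN), "not_estimable")
  expect_equal(classify_node(NA_real_), "not_estimable")
})

test_that("saturated communities are not estimable", {
  tr <- simulate_yule_tree(5, 1, seed = 1)
  d <- phylo_cophenetic(tr)
  prev <- setNames(rep(2, 5), tip_labels(tr))
  rec <- nri_community(tip_labels(tr), tip_labels(tr), d, prev, n_null = 99)
  expect_false(rec$estimable)
  expect_true(is.na(rec$nri))
  expect_equal(rec$mpd_null_sd, 0)
})

test_that("equal-weight 2-species null on a star clade has mean 2t exactly", {
  star <- as_dated_tree(ape::read.tree(text = "(f:6,(a:3,b:3,c:3,d:3,e:3):3);"))
  d <- phylo_cophenetic(star)
  ex <- null_mpd_exact(letters[1:5], 2, d, setNames(rep(1, 5), letters[1:5]))
  expect_equal(ex$mean, 6)
  expect_equal(ex$sd, 0)
  expect_equal(ex$n_subsets, 10)
})

test_that("uniform random communities give NRI centred on zero", {
  tr <- simulate_yule_tree(12, 1, seed = 4)
  d <- phylo_cophenetic(tr)
  prev <- setNames(rep(1, 12), tip_labels(tr))
  set.seed(10)
  nris <- vapply(1:200, function(i) {
    comm <- sample(tip_labels(tr), 5)
    nri_community(comm, tip_labels(tr), d, prev, n_null = 199, seed = i)$nri
  }, numeric(1))
  expect_lt(abs(mean(nris)), 0.15)
})

test_that("the most closely related subset has positive NRI", {
  tr <- simulate_yule_tree(10, 1, seed = 6)
  d <- phylo_cophenetic(tr)
  prev <- setNames(rep(1, 10), tip_labels(tr))
  k <- 3
  subsets <- combn(tip_labels(tr), k)
  mpds <- apply(subsets, 2, mpd, dist = d)
  best <- subsets[, which.min(mpds)]
  # brute force confirms this subset minimises MPD over all k-subsets
  expect_equal(mpd(best, d), min(mpds))
  rec <- nri_community(best, tip_labels(tr), d, prev, n_null = 499, seed = 1)
  expect_gt(rec$nri, 0)
})

test_that("NRI is monotone in observed MPD under a fixed null stream", {
  tr <- simulate_yule_tree(10, 1, seed = 2)
  d <- phylo_cophenetic(tr)
  prev <- setNames(rep(1, 10), tip_labels(tr))
  k <- 3
  subsets <- combn(tip_labels(tr), k)
  mpds <- apply(subsets, 2, mpd, dist = d)
  lo <- subsets[, which.min(mpds)]
  hi <- subsets[, which.max(mpds)]
  # same pool, same richness, same seed -> identical null draws
  r_lo <- nri_community(lo, tip_labels(tr), d, prev, n_null = 199, seed = 3)
  r_hi <- nri_community(hi, tip_labels(tr), d, prev, n_null = 199, seed = 3)
  expect_equal(r_lo$mpd_null_mean, r_hi$mpd_null_mean)
  expect_gt(r_lo$nri, r_hi$nri)
})

test_that("exhaustive enumeration matches Monte-Carlo nulls (pool <= 8)", {
  tr <- simulate_yule_tree(7, 1, seed = 8)
  d <- phylo_cophenetic(tr)
  prev <- setNames(c(9, 2, 5, 1, 7, 3, 4), tip_labels(tr))
  for (k in c(2, 4)) {
    ex <- null_mpd_exact(tip_labels(tr), k, d, prev)
    rec <- nri_community(tip_labels(tr)[1:k], tip_labels(tr), d, prev,
                         n_null = 5000, seed = k)
    se_mean <- ex$sd / sqrt(5000)
    expect_lt(abs(rec$mpd_null_mean - ex$mean), 3 * se_mean)
    expect_lt(abs(rec$mpd_null_sd - ex$sd), 3 * ex$sd / sqrt(2 * 5000))
  }
  expect_error(null_mpd_exact(tip_labels(tr), 1, d, prev), "2..pool")
})

test_that("scan enumerates all internal nodes and flags cherries", {
  tr <- simulate_yule_tree(20, 1, seed = 12)
  set.seed(20)
  cm <- random_cm(25, tip_labels(tr), p = 0.4)
  scan <- node_nri_scan(tr, cm, n_null = 99, seed = 1)
  expect_equal(nrow(scan$table), 19)
  expect_equal(scan$table$node_id, 1:19)
  cherries <- scan$table$clade_richness == 2
  expect_true(all(scan$table$classification[cherries] == "not_estimable"))
  expect_true(all(is.na(scan$table$mean_nri[cherries])))
  # null preserves richness: every record's community size is >= 2 and the
  # record count per (node, plot) matches the presence matrix directly
  P <- presence(cm)
  for (r in sample(nrow(scan$records), 20)) {
    rec <- scan$records[r, ]
    pool <- intersect(subtree_tips(tr, rec$node_id),
                      colnames(P)[colSums(P) > 0])
    expect_equal(rec$n_species_in_clade_in_plot,
                 sum(P[rec$plot_id, pool]))
    expect_gte(rec$n_species_in_clade_in_plot, 2)
  }
})

test_that("scan is deterministic and restrictable to chosen nodes", {
  tr <- simulate_yule_tree(15, 1, seed = 3)
  set.seed(31)
  cm <- random_cm(20, tip_labels(tr), p = 0.4)
  s1 <- node_nri_scan(tr, cm, n_null = 99, seed = 7)
  s2 <- node_nri_scan(tr, cm, n_null = 99, seed = 7)
  expect_identical(s1$table, s2$table)
  sub <- node_nri_scan(tr, cm, n_null = 99, seed = 7, nodes = c(1, 3))
  expect_equal(sub$table$node_id, c(1, 3))
  expect_equal(sub$table[1, ], s1$table[1, ])
  expect_error(node_nri_scan(tr, cm, n_null = 99, nodes = 99), "unknown node")
})

test_that("no tree/matrix overlap errors; partial overlap warns", {
  tr <- simulate_yule_tree(10, 1, seed = 5)
  cm <- presence_cm(list(x1 = 1:3, x2 = 2:4, x3 = 1:4), 5)
  expect_error(node_nri_scan(tr, cm, n_null = 99), "no overlap")
  half <- community_matrix(cbind(unclass(cm),
                                 matrix(50, 5, 3,
                                        dimnames = list(NULL, tip_labels(tr)[1:3]))))
  expect_warning(node_nri_scan(tr, half, n_null = 99), "absent from tree")
})

test_that("a neutral world classifies nearly all estimable nodes as random", {
  for (s in 1:2) {
    sc <- assembly_scenario(n_tips = 40, n_plots = 200, mean_richness = 10,
                            filter_strength = 0, seed = s)
    sim <- simulate_scenario(sc)
    scan <- node_nri_scan(sim$tree, sim$cm, n_null = 999, seed = s)
    est <- scan$table$classification[scan$table$classification != "not_estimable"]
    expect_gte(mean(est == "random"), 0.9)
  }
})

test_that("filtering concentrated in one clade is recovered at that node", {
  tr <- simulate_yule_tree(40, 1, seed = 14)
  sizes <- tr$node_map$n_tips
  # a mid-sized focal clade, not the root
  ntip <- length(tip_labels(tr))
  kid_tips <- function(k) {
    if (k <= ntip) tr$phy$tip.label[k]
    else subtree_tips(tr, tr$node_map$node_id[tr$node_map$ape_node == k])
  }
  node_kids <- function(nid)
    tr$phy$edge[tr$phy$edge[, 1] == tr$node_map$ape_node[
      tr$node_map$node_id == nid], 2]
  # focal clade: mid-sized, not the root, with the most balanced child split
  cand <- tr$node_map$node_id[sizes >= 8 & sizes <= 20 & tr$node_map$node_id != 1]
  balance <- vapply(cand, function(nid)
    min(vapply(node_kids(nid), function(k) length(kid_tips(k)), numeric(1))),
    numeric(1))
  focal <- cand[which.max(balance)]
  clade <- subtree_tips(tr, focal)
  # filtering concentrated in the focal clade: its two child subclades get
  # distinct conserved elevation optima, everything outside is neutral
  kids <- node_kids(focal)
  traits <- setNames(rep(1800, ntip), tip_labels(tr))
  traits[kid_tips(kids[1])] <- 700
  traits[kid_tips(kids[2])] <- 2800
  sc <- assembly_scenario(n_tips = 40, n_plots = 200, mean_richness = 10,
                          filter_strength = 10, seed = 16)
  asm <- assemble_communities(tr, traits, sc)
  # an unrelated clade with >= 4 species, disjoint from the focal clade
  other <- tr$node_map$node_id[
    vapply(tr$node_map$node_id, function(n)
      length(intersect(subtree_tips(tr, n), clade)) == 0 &&
        length(subtree_tips(tr, n)) >= 4, logical(1))][1]
  scan <- node_nri_scan(tr, asm$cm, n_null = 499, seed = 17,
                        nodes = c(focal, other))
  tab <- scan$table
  # clustered at the filtered clade: mean NRI > 0 with CI excluding 0
  expect_gt(tab$mean_nri[tab$node_id == focal], 0)
  expect_gt(tab$ci_lo[tab$node_id == focal], 0)
  # near zero at the unrelated clade
  expect_lt(abs(tab$mean_nri[tab$node_id == other]), 0.5)
})
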