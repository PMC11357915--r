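test_that("closest-distance proximity matches per-pair BFS and is directional", {
  g <- path5()
  expect_equal(closest_distance(g, c("1", "2"), c("4", "5")), 2.5)
  expect_equal(closest_distance(g, "3", c("1", "5")), 2.0)
  expect_equal(closest_distance(g, c("1", "2", "3"), c("2", "3")), 0.0)

  # directionality: averages over T, not H (regression vs per-pair oracle)
  set.seed(31)
  for (i in 1:20) {
    gr <- random_connected_graph(40)
    D <- oracle_dist(gr)
    h <- sample(gr$nodes, sample(2:5, 1))
    t <- sample(gr$nodes, sample(2:5, 1))
    expect_equal(closest_distance(gr, h, t), oracle_closest(D, h, t))
  }
  # an asymmetric instance: star centre vs leaves
  star <- as_interactome(rep("c", 4), c("l1", "l2", "l3", "l4"))
  expect_equal(closest_distance(star, "c", c("l1", "l2")), 1.0)
  expect_equal(closest_distance(star, c("l1", "l2"), "c"), 1.0)
  expect_false(isTRUE(all.equal(
    closest_distance(star, c("l1", "l2", "l3"), c("c", "l4")),
    closest_distance(star, c("c", "l4"), c("l1", "l2", "l3")))))
})

test_that("log2 degree bins merge low-occupancy bins per the stated rule", {
  # hub star: degrees {4,2,2,1,1,1,1}; the degree-4 singleton bin merges
  # downward into the degree-2 bin
  g2 <- as_interactome(c("h", "h", "h", "h", "a", "b"),
                       c("a", "b", "c", "d", "x", "y"))
  expect_setequal(unname(node_degree(g2)), c(4, 2, 2, 1, 1, 1, 1))
  bins <- build_degree_bins(g2, min_bin_size = 2)
  sizes <- lengths(bins$bins)
  expect_true(all(sizes >= 2))
  # the hub (degree 4) shares its merged bin with the degree-2 nodes
  hub_bin <- bins$bin_of[match("h", g2$nodes)]
  two_bin <- bins$bin_of[match("a", g2$nodes)]
  expect_equal(hub_bin, two_bin)

  # regular graph: single bin
  k <- clique_graph(5)
  expect_equal(length(build_degree_bins(k, 1)$bins), 1)
  # min_bin_size = n: one bin
  set.seed(2)
  gg <- generate_interactome(50, 2)
  b1 <- build_degree_bins(gg, 50)
  expect_equal(length(b1$bins), 1)
  expect_error(build_degree_bins(gg, 51), "exceeds")
  # bins partition all nodes
  b <- build_degree_bins(gg, 5)
  expect_setequal(unlist(b$bins), seq_along(gg$nodes))
  expect_true(all(b$bin_of >= 1))
})

test_that("degree-matched sampling preserves the reference bin histogram", {
  set.seed(4)
  g <- generate_interactome(300, 2)
  bins <- build_degree_bins(g, 20)
  ref <- sample(g$nodes, 25)
  ref_hist <- tabulate(bins$bin_of[match(ref, g$nodes)],
                       length(bins$bins))
  for (i in 1:200) {
    s <- degree_matched_sample(g, bins, ref)
    expect_equal(length(s), length(ref))
    expect_equal(length(unique(s)), length(s))   # without replacement
    expect_equal(tabulate(bins$bin_of[match(s, g$nodes)],
                          length(bins$bins)), ref_hist)
  }
  # reference = all nodes forces the sample to be all nodes
  s_all <- degree_matched_sample(g, bins, g$nodes)
  expect_setequal(s_all, g$nodes)
})

test_that("proximity permutation test flags embedded targets and handles degenerate nulls", {
  set.seed(6)
  g <- generate_interactome(500, 2)
  mod <- plant_module(g, 30)
  # targets inside the module: observed distance is the minimum possible
  inside <- sample(mod, 10)
  res <- proximity(g, mod, inside, n_perm = 50)
  expect_equal(res$d_obs, 0)
  expect_lt(res$z, 0)
  expect_equal(res$p_empirical, 1 / 51, tolerance = 1e-12)
  expect_true(res$p_empirical >= 1 / (res$n_perm + 1))

  # disease set = whole clique: observed and every permuted distance are
  # 0, so the null degenerates
  k <- clique_graph(8)
  resk <- proximity(k, k$nodes, c("3", "4"), n_perm = 10,
                    min_bin_size = 1)
  expect_true(resk$degenerate_null)
  expect_true(is.na(resk$z))
  expect_false(resk$significant)

  expect_error(proximity(g, mod, inside, n_perm = 1), "at least 2")
})

test_that("z stabilizes as the permutation count grows", {
  set.seed(12)
  g <- generate_interactome(300, 2)
  mod <- plant_module(g, 25)
  tp <- plant_target_profile(g, mod, 10, 2)
  zs <- vapply(1:6, function(i) {
    proximity(g, mod, tp$targets, n_perm = 400, min_bin_size = 50)$z
  }, numeric(1))
  expect_lt(sd(zs), 0.3)
})

test_that("proximity matrix is deterministic and free of cell cross-talk", {
  set.seed(9)
  g <- generate_interactome(300, 2)
  m1 <- plant_module(g, 20)
  m2 <- plant_overlapping_module(g, m1, 20, 0)
  t1 <- plant_target_profile(g, m1, 8, 1)
  t2 <- plant_target_profile(g, m2, 8, 1)
  diseases <- list(D1 = m1, D2 = m2)
  ents <- list(E1 = t1, E2 = t2)
  pm <- proximity_matrix(g, diseases, ents, n_perm = 30, min_bin_size = 50,
                         seed = 77)
  expect_equal(nrow(pm), 4)
  # permuting the entity list permutes rows identically
  pm_rev <- proximity_matrix(g, diseases, rev(ents), n_perm = 30,
                             min_bin_size = 50, seed = 77)
  key <- function(df) df[order(df$disease_id, df$entity_id), ]
  expect_equal(key(pm), key(pm_rev), ignore_attr = TRUE)
  # identical call reproduces bit-identical values
  pm2 <- proximity_matrix(g, diseases, ents, n_perm = 30,
                          min_bin_size = 50, seed = 77)
  expect_identical(pm$z, pm2$z)
  # unusable profiles are skipped with a warning
  bad <- structure(list(entity_id = "bad", entity_kind = "formula",
                        targets = character(0), provenance = NULL,
                        usable = FALSE), class = "target_profile")
  expect_warning(pm3 <- proximity_matrix(g, diseases["D1"],
                                         list(E1 = t1, bad = bad),
                                         n_perm = 10, min_bin_size = 50,
                                         seed = 1),
                 "unusable")
  expect_equal(nrow(pm3), 1)
})
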