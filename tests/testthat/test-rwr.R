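# minimal hand-built protein-only heterogeneous network
protein_pair_network <- function() {
  structure(list(
    nodes = data.frame(id = c("A", "B"), kind = "protein",
                       stringsAsFactors = FALSE),
    edges = matrix(c(1L, 2L), ncol = 2),
    edge_type = "protein-protein",
    flagged_ingredients = character(0)), class = "hetero_network")
}

test_that("heterogeneous network assembly follows the four-layer construction", {
  g <- path5()
  tb <- composition_tables(
    data.frame(f = "F1", h = "H1"),
    data.frame(h = "H1", i = "I1"),
    data.frame(i = c("I1", "I1", "I1"), g = c("1", "3", "off")))
  hn <- build_hetero_network(g, tb)
  # 5 proteins + 1 formula + 1 herb + 1 ingredient
  expect_equal(nrow(hn$nodes), 8)
  # 4 pp + 1 fh + 1 hi + 2 ip (off-network target contributes no edge)
  expect_equal(nrow(hn$edges), 8)
  expect_equal(as.integer(table(hn$edge_type)[c("formula-herb",
                                                "herb-ingredient",
                                                "ingredient-protein",
                                                "protein-protein")]),
               c(1L, 1L, 2L, 4L))
  expect_length(hn$flagged_ingredients, 0)

  # ingredient with only off-network targets is retained but flagged
  tb2 <- composition_tables(
    data.frame(f = "F1", h = "H1"),
    data.frame(h = "H1", i = c("I1", "I2")),
    data.frame(i = c("I1", "I2"), g = c("1", "nowhere")))
  hn2 <- suppressMessages(build_hetero_network(g, tb2))
  expect_equal(hn2$flagged_ingredients, "I2")
  i2 <- which(hn2$nodes$id == "I2" & hn2$nodes$kind == "ingredient")
  expect_equal(sum(hn2$edges == i2), 1)   # herb link only

  # a herb shared by two formulae is a single node with two formula edges
  tb3 <- composition_tables(
    data.frame(f = c("F1", "F2"), h = c("H1", "H1")),
    data.frame(h = "H1", i = "I1"),
    data.frame(i = "I1", g = "1"))
  hn3 <- build_hetero_network(g, tb3)
  expect_equal(sum(hn3$nodes$kind == "herb"), 1)
  expect_equal(sum(hn3$edge_type == "formula-herb"), 2)

  expect_error(build_hetero_network(g, composition_tables(
    data.frame(f = character(0), h = character(0)),
    data.frame(h = character(0), i = character(0)),
    data.frame(i = character(0), g = character(0)))), "empty")
})

test_that("random walk matches the two-node closed form and conserves mass", {
  hn <- protein_pair_network()
  p <- rwr(hn, "A", restart = 0.7, tolerance = 1e-14)
  expect_equal(unname(p["protein:A"]), 0.7 / 0.91, tolerance = 1e-10)
  expect_equal(unname(p["protein:B"]), 0.21 / 0.91, tolerance = 1e-10)
  expect_equal(sum(p), 1, tolerance = 1e-10)

  # restart probability 1 returns the restart vector exactly
  p1 <- rwr(hn, "A", restart = 1)
  expect_identical(unname(p1["protein:A"]), 1)
  expect_identical(unname(p1["protein:B"]), 0)

  expect_error(suppressWarnings(rwr(hn, "ZZ")), "no seed")
  expect_warning(rwr(hn, c("A", "ZZ")), "dropped")
  expect_error(rwr(hn, "A", restart = 0), "\\(0, 1\\]")
})

test_that("power iteration agrees with the dense linear solve", {
  set.seed(15)
  for (i in 1:5) {
    g <- generate_interactome(120, 2)
    mod <- plant_module(g, 15)
    fix <- generate_formula_fixture(g, list(F1 = mod),
                                    decoys_per_formula = 5)
    hn <- suppressMessages(build_hetero_network(g, fix$tables))
    n <- nrow(hn$nodes)
    expect_lte(n, 200)
    r <- 0.7
    p <- rwr(hn, mod, restart = r, tolerance = 1e-14)
    W <- as.matrix(tcmnet:::hetero_transition_matrix(hn))
    e <- numeric(n)
    seed_idx <- which(hn$nodes$kind == "protein" & hn$nodes$id %in% mod)
    e[seed_idx] <- 1 / length(seed_idx)
    p_direct <- solve(diag(n) - (1 - r) * W, r * e)
    expect_equal(as.numeric(p), as.numeric(p_direct), tolerance = 1e-8)
  }
})

test_that("score mass is conserved at every iteration", {
  set.seed(16)
  g <- generate_interactome(150, 2)
  mod <- plant_module(g, 12)
  fix <- generate_formula_fixture(g, list(F1 = mod), decoys_per_formula = 4)
  hn <- suppressMessages(build_hetero_network(g, fix$tables))
  W <- tcmnet:::hetero_transition_matrix(hn)
  n <- nrow(hn$nodes)
  e <- numeric(n)
  seed_idx <- which(hn$nodes$kind == "protein" & hn$nodes$id %in% mod)
  e[seed_idx] <- 1 / length(seed_idx)
  p <- e
  for (it in 1:50) {
    p <- as.numeric(0.3 * (W %*% p)) + 0.7 * e
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
})

test_that("ingredient ranking orders by score with id tie-break and formula annotation", {
  g <- path5()
  tb <- composition_tables(
    data.frame(f = c("F1", "F2"), h = c("H1", "H2")),
    data.frame(h = c("H1", "H1", "H2"), i = c("Ia", "Ib", "Ia")),
    data.frame(i = c("Ia", "Ib"), g = c("2", "2")))
  hn <- build_hetero_network(g, tb)
  # equal-score ties resolve by ingredient id
  sc <- setNames(rep(0.1, nrow(hn$nodes)),
                 paste(hn$nodes$kind, hn$nodes$id, sep = ":"))
  rk <- rank_ingredients(sc, hn)
  expect_equal(rk$ingredient_id, c("Ia", "Ib"))
  expect_equal(rk$rank, 1:2)
  expect_equal(rk$formulae, c("F1,F2", "F1"))

  # single ingredient is rank 1 regardless of score
  tb1 <- composition_tables(data.frame(f = "F1", h = "H1"),
                            data.frame(h = "H1", i = "I1"),
                            data.frame(i = "I1", g = "1"))
  hn1 <- build_hetero_network(g, tb1)
  sc1 <- rwr(hn1, c("1", "2"))
  rk1 <- rank_ingredients(sc1, hn1)
  expect_equal(rk1$rank, 1L)

  # top_fraction truncates
  expect_equal(nrow(rank_ingredients(sc, hn, top_fraction = 0.5)), 1)
})

test_that("per-formula key ingredients keep global rank order and honour k", {
  g <- path5()
  tb <- composition_tables(
    data.frame(f = c("F1", "F2"), h = c("H1", "H2")),
    data.frame(h = c("H1", "H1", "H2", "H2"),
               i = c("Ia", "Ib", "Ia", "Ic")),
    data.frame(i = c("Ia", "Ib", "Ic"), g = c("1", "2", "3")))
  hn <- build_hetero_network(g, tb)
  sc <- setNames(numeric(nrow(hn$nodes)),
                 paste(hn$nodes$kind, hn$nodes$id, sep = ":"))
  sc["ingredient:Ib"] <- 0.3
  sc["ingredient:Ia"] <- 0.2
  sc["ingredient:Ic"] <- 0.1
  rk <- rank_ingredients(sc, hn)
  per <- per_formula_key_ingredients(rk, tb, 3)
  expect_equal(per$F1$ingredient_id, c("Ib", "Ia"))
  expect_equal(per$F2$ingredient_id, c("Ia", "Ic"))
  # shared ingredient appears under each formula with its global rank
  expect_equal(per$F1$rank[per$F1$ingredient_id == "Ia"],
               per$F2$rank[per$F2$ingredient_id == "Ia"])
  # k = 1 keeps each formula's single best member
  per1 <- per_formula_key_ingredients(rk, tb, 1)
  expect_equal(vapply(per1, function(d) d$ingredient_id[1], ""),
               c(F1 = "Ib", F2 = "Ia"))
})

test_that("rwr is deterministic and seeds raise ingredient scores monotonically", {
  set.seed(19)
  g <- generate_interactome(200, 2)
  mod <- plant_module(g, 15)
  fix <- generate_formula_fixture(g, list(F1 = mod), decoys_per_formula = 6)
  hn <- suppressMessages(build_hetero_network(g, fix$tables))
  p1 <- rwr(hn, mod)
  p2 <- rwr(hn, mod)
  expect_identical(p1, p2)
  # moving an ingredient's targets into the seed set never lowers its score
  act <- fix$ground_truth[["F1"]]
  off_mod <- setdiff(g$nodes, mod)
  tb_out <- fix$tables
  tb_out$ingredient_target[
    tb_out$ingredient_target$ingredient_id == act, "gene"] <-
    off_mod[seq_len(sum(tb_out$ingredient_target$ingredient_id == act))]
  hn_out <- suppressMessages(build_hetero_network(g, tb_out))
  p_out <- rwr(hn_out, mod)
  expect_gte(unname(p1[paste0("ingredient:", act)]),
             unname(p_out[paste0("ingredient:", act)]))
})
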