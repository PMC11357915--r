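test_that("edge lists merge with deduplication and self-loop removal", {
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "s1.tsv")
  f2 <- file.path(dir, "s2.tsv")
  writeLines(c("A\tB", "B\tC"), f1)
  writeLines(c("B\tA", "A\tA"), f2)   # reversed duplicate + self-loop
  g <- suppressMessages(load_edge_lists(c(f1, f2)))
  expect_setequal(g$nodes, c("A", "B", "C"))
  expect_equal(nrow(g$edges), 2)
  expect_equal(unname(attr(g, "source_counts")), c(2L, 2L))

  # self-loop only file
  f3 <- file.path(dir, "s3.tsv")
  writeLines("X\tX", f3)
  g3 <- suppressMessages(load_edge_lists(f3))
  expect_equal(nrow(g3$edges), 0)

  expect_error(load_edge_lists(file.path(dir, "nope.tsv")), "not found")
})

test_that("six fixture files with cross-source duplicates merge to the exhaustive pair union", {
  dir <- withr::local_tempdir()
  # 10 unique unordered pairs spread over 6 files with 3 duplicates
  pairs <- list(c("A", "B"), c("B", "C"), c("C", "D"), c("D", "E"),
                c("E", "F"), c("A", "C"), c("B", "D"), c("C", "E"),
                c("D", "F"), c("A", "F"))
  files <- file.path(dir, sprintf("src%d.tsv", 1:6))
  writeLines(c("A\tB", "B\tC"), files[1])
  writeLines(c("C\tD", "B\tA"), files[2])        # dup of A-B (reversed)
  writeLines(c("D\tE", "E\tF"), files[3])
  writeLines(c("A\tC", "C\tB"), files[4])        # dup of B-C
  writeLines(c("B\tD", "C\tE"), files[5])
  writeLines(c("D\tF", "A\tF", "E\tD"), files[6]) # dup of D-E
  g <- suppressMessages(load_edge_lists(files))
  # exhaustive enumeration of distinct unordered pairs
  canon <- unique(vapply(pairs, function(p) paste(sort(p), collapse = "-"),
                         ""))
  got <- apply(g$edges, 1, function(e) {
    paste(sort(g$nodes[e]), collapse = "-")
  })
  expect_setequal(got, canon)
  expect_equal(nrow(g$edges), 10)
})

test_that("merging the same edge list twice is idempotent", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "e.tsv")
  writeLines(c("A\tB", "B\tC", "C\tA"), f)
  g1 <- suppressMessages(load_edge_lists(f))
  g2 <- suppressMessages(load_edge_lists(c(f, f)))
  expect_identical(g1$nodes, g2$nodes)
  expect_identical(g1$edges, g2$edges)
})

test_that("identifier mapping merges collisions and drops unmapped nodes", {
  g <- as_interactome(c("X", "Y", "Y", "Z"), c("Y", "Z", "W", "W"))
  # identity mapping leaves the graph unchanged
  idm <- setNames(g$nodes, g$nodes)
  gid <- apply_mapping(g, idm)
  expect_identical(gid$nodes, g$nodes)
  expect_identical(gid$edges, g$edges)

  # X and Y both map to G: edge X-Y collapses to a removed self-loop
  map <- c(X = "G", Y = "G", Z = "Z2", W = "W2")
  gm <- apply_mapping(g, map)
  expect_setequal(gm$nodes, c("G", "Z2", "W2"))
  got <- apply(gm$edges, 1, function(e) paste(sort(gm$nodes[e]),
                                              collapse = "-"))
  expect_setequal(got, c("G-Z2", "G-W2", "W2-Z2"))

  # unmapped node of degree 2 vanishes with both its edges
  g5 <- as_interactome(c("a", "b", "c", "d"), c("b", "c", "d", "e"))
  map5 <- c(a = "A", b = "B", d = "D", e = "E")   # c unmapped, degree 2
  expect_warning(g5m <- apply_mapping(g5, map5), "without mapping")
  expect_setequal(g5m$nodes, c("A", "B", "D", "E"))
  expect_equal(nrow(g5m$edges), 2)

  expect_error(apply_mapping(g, character(0)), "empty")
})

test_that("LCC extraction keeps the largest component and breaks ties by smallest label", {
  g <- path5()
  expect_identical(extract_lcc(g)$nodes, g$nodes)

  # components of size 4 and 2
  g2 <- as_interactome(c("a", "b", "c", "x"), c("b", "c", "d", "y"))
  lcc <- extract_lcc(g2)
  expect_setequal(lcc$nodes, c("a", "b", "c", "d"))

  # two size-3 components; the one containing "A" (smallest label) wins
  g3 <- as_interactome(c("A", "B", "M", "N"), c("B", "C", "N", "O"))
  expect_setequal(extract_lcc(g3)$nodes, c("A", "B", "C"))

  expect_error(extract_lcc(as_interactome(character(0), character(0))),
               "empty")
})

test_that("LCC output is a node-induced subgraph", {
  set.seed(11)
  for (i in 1:10) {
    n <- sample(15:40, 1)
    pairs <- utils::combn(n, 2)
    keep <- runif(ncol(pairs)) < 0.06
    g <- as_interactome(as.character(pairs[1, keep]),
                        as.character(pairs[2, keep]))
    if (length(g$nodes) == 0) next
    lcc <- extract_lcc(g)
    ig <- as_igraph(g)
    comp <- igraph::components(ig)
    expect_equal(length(lcc$nodes), max(comp$csize))
    # no edge among retained nodes gained or lost
    sub <- igraph::induced_subgraph(ig, lcc$nodes)
    expect_equal(nrow(lcc$edges), igraph::ecount(sub))
    expect_true(igraph::is_connected(sub))
  }
})

test_that("nearest-set distances match per-node BFS on the path graph", {
  g <- path5()
  d <- nearest_set_distance(g, "1")
  expect_equal(unname(d[c("1", "2", "3", "4", "5")]), c(0, 1, 2, 3, 4))
  d2 <- nearest_set_distance(g, c("1", "5"))
  expect_equal(unname(d2[c("1", "2", "3", "4", "5")]), c(0, 1, 2, 1, 0))
  d3 <- nearest_set_distance(g, g$nodes)
  expect_true(all(d3 == 0))
  expect_error(nearest_set_distance(g, c("1", "9")), "9")
})

test_that("multi-source BFS agrees with exhaustive per-pair BFS on random graphs", {
  set.seed(42)
  for (i in 1:30) {
    g <- random_connected_graph(50)
    D <- oracle_dist(g)
    src <- sample(g$nodes, sample(1:4, 1))
    d <- nearest_set_distance(g, src)
    expected <- apply(D[src, , drop = FALSE], 2, min)
    expect_equal(unname(d[colnames(D)]), unname(expected[colnames(D)]))
  }
})

test_that("nearest-other-member distances are correct and need two members", {
  g <- path5()
  expect_equal(nearest_other_member_distance(g, c("1", "2")),
               c("1" = 1, "2" = 1))
  expect_equal(nearest_other_member_distance(g, c("1", "5")),
               c("1" = 4, "5" = 4))
  k <- clique_graph(5)
  expect_true(all(nearest_other_member_distance(k, c("1", "3", "4")) == 1))
  expect_error(nearest_other_member_distance(g, "1"), "at least 2")
})

test_that("degree invariant holds after every construction and operation", {
  check_deg <- function(g) {
    expect_equal(sum(lengths(g$adj)), 2 * nrow(g$edges))
  }
  g <- as_interactome(c("A", "B", "C", "A"), c("B", "C", "A", "B"))
  check_deg(g)
  check_deg(extract_lcc(g))
  check_deg(apply_mapping(g, c(A = "x", B = "y", C = "z")))
  set.seed(3)
  check_deg(generate_interactome(100, 2))
})

test_that("coverage is the fraction of genes on the network", {
  g <- path5()
  expect_equal(coverage(g, c("1", "2")), 1.0)
  expect_equal(coverage(g, c("1", "2", "3", "zz")), 0.75)
  expect_equal(coverage(g, c("x", "y")), 0.0)
  expect_error(coverage(g, character(0)), "empty")
})

test_that("interactome round-trips through its TSV writer", {
  set.seed(5)
  g <- generate_interactome(60, 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_interactome(g, f)
  g2 <- suppressMessages(load_edge_lists(f, header = TRUE))
  expect_identical(g$nodes, g2$nodes)
  expect_identical(g$edges, g2$edges)
})
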