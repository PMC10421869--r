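test_that("edge lists are canonicalized: self-loops, duplicates, reversals dropped", {
  suppressMessages({
    net <- clock_network(data.frame(a = c("a", "b", "a"), b = c("b", "a", "a")))
  })
  expect_equal(length(net$nodes), 2)
  expect_equal(nrow(as_edge_tibble(net)), 1)

  tri <- net_triangle()
  expect_equal(length(tri$nodes), 3)
  expect_equal(nrow(as_edge_tibble(tri)), 3)
})

test_that("read_edge_list is invariant to row order and endpoint swap", {
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "a\tb", "b\tc", "c\ta"), f1)
  writeLines(c("c\tb", "a\tc", "b\ta"), f2)
  n1 <- read_edge_list(f1)
  n2 <- read_edge_list(f2)
  expect_equal(as_edge_tibble(n1), as_edge_tibble(n2))
  expect_equal(sort(n1$nodes), c("a", "b", "c"))
})

test_that("read_edge_list rejects malformed and empty input, reads SIF", {
  bad <- withr::local_tempfile()
  writeLines(c("a\tb", "lonely"), bad)
  expect_error(read_edge_list(bad), "line 2")

  empty <- withr::local_tempfile()
  writeLines("# nothing here", empty)
  expect_error(read_edge_list(empty), "no data rows")

  sif <- withr::local_tempfile(fileext = ".sif")
  writeLines(c("a pp b", "b pp c"), sif)
  net <- read_edge_list(sif, fmt = "sif")
  expect_equal(nrow(as_edge_tibble(net)), 2)
})

test_that("degree filter is single-pass and monotone in k", {
  # path a-b-c: all degrees <= 2, everything goes at k = 3
  gone <- filter_min_degree(net_path3(), 3)
  expect_length(gone$nodes, 0)
  expect_equal(igraph::ecount(gone$graph), 0)

  # star: leaves (degree 1) removed simultaneously; center survives the pass
  # even though its edges vanish with the leaves
  star <- net_claw()
  kept <- filter_min_degree(star, 3)
  expect_equal(kept$nodes, "c")
  expect_equal(igraph::ecount(kept$graph), 0)

  # k = 0 is the identity
  g <- rand_gnp(15, 0.2, seed = 7)
  expect_equal(as_edge_tibble(filter_min_degree(g, 0)), as_edge_tibble(g))

  # node sets shrink monotonically with k
  sizes <- vapply(0:4, function(k) {
    out <- tryCatch(length(filter_min_degree(g, k)$nodes), error = function(e) 0L)
    out
  }, 0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("transition operator is column-stochastic with 1/degree entries", {
  W <- transition_operator(net_k2())
  expect_equal(as.matrix(W), matrix(c(0, 1, 1, 0), 2,
                                    dimnames = list(c("a", "b"), c("a", "b"))))

  Wp <- transition_operator(net_path3())
  expect_equal(as.numeric(Wp[, "b"]), c(1 / 2, 0, 1 / 2))

  g <- rand_gnp(25, 0.15, seed = 3)
  Wg <- transition_operator(g)
  expect_true(all(abs(Matrix::colSums(Wg) - 1) < 1e-12))

  # isolated node: zero column plus a warning
  iso <- net_k2()
  iso$graph <- igraph::add_vertices(iso$graph, 1, name = "z")
  iso <- clockrank:::new_clock_network(iso$graph)
  expect_warning(Wz <- transition_operator(iso), "isolated")
  expect_equal(sum(Wz[, "z"]), 0)
})

test_that("seed mapping partitions ids and errors when nothing maps", {
  net <- net_k2()
  s <- map_seeds(net, c("a", "z"), min_degree = 0)
  expect_equal(s$mapped, "a")
  expect_equal(s$unmapped, "z")

  expect_error(map_seeds(net, c("x", "y"), min_degree = 0), "no seed")

  # low-degree seeds are set aside, order of mapped preserved
  star <- net_claw()
  s2 <- map_seeds(star, c("l1", "c", "l2"), min_degree = 3)
  expect_equal(s2$mapped, "c")
  expect_equal(sort(s2$dropped_low_degree), c("l1", "l2"))
})

test_that("annotation maps invert exactly and collapse duplicates", {
  gmt <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("T1\tdesc\tg1\tg2", "T2\tdesc\tg2\tg3"), gmt)
  ann <- read_annotations(gmt, "gmt", "GO")
  expect_equal(sort(ann$term_to_genes$T1), c("g1", "g2"))
  expect_equal(sort(ann$gene_to_terms$g2), c("T1", "T2"))

  # round-trip: the two indexes are inverses
  pairs_fwd <- as_annotation_tibble(ann)
  rebuilt <- annotation_map(pairs_fwd, "GO")
  expect_equal(rebuilt$term_to_genes[order(names(rebuilt$term_to_genes))],
               ann$term_to_genes[order(names(ann$term_to_genes))])

  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("g1\tT1", "g1\tT1", "g1\tT2"), tsv)
  ann2 <- read_annotations(tsv, "tsv2col", "pathway")
  expect_equal(ann2$gene_to_terms$g1, c("T1", "T2"))

  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines("T1\tonly-desc", bad)
  expect_error(read_annotations(bad, "gmt"), "fewer than 3")
})
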