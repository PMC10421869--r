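test_that("the catalog enumerates 9 graphlets with 15 orbits in standard order", {
  cat_tbl <- build_catalog()
  expect_equal(length(unique(cat_tbl$graphlet)), 9)
  expect_equal(sort(cat_tbl$orbit), 0:14)
  expect_equal(length(nonredundant_orbits()), 11)
  expect_true(all(nonredundant_orbits() %in% cat_tbl$orbit))

  # vertex-transitive graphlets carry a single orbit
  one_orbit <- table(cat_tbl$graphlet)
  expect_equal(unname(one_orbit[as.character(c(0, 2, 5, 8))]), rep(1L, 4),
               ignore_attr = TRUE) # edge, triangle, C4, K4

  # P4 (the 3-edge graphlet with max degree 2) splits into exactly two orbits
  p4_gid <- unique(cat_tbl$graphlet[cat_tbl$size == 4 & cat_tbl$n_edges == 3 &
                                      cat_tbl$degree == 2])
  p4 <- cat_tbl[cat_tbl$graphlet %in% p4_gid & cat_tbl$degree <= 2, ]
  expect_equal(sort(p4$orbit[p4$graphlet == min(p4_gid)]), 4:5)

  # orbits partition each graphlet's nodes
  by_g <- split(cat_tbl, cat_tbl$graphlet)
  for (g in by_g) {
    members <- sort(unlist(g$nodes))
    expect_equal(members, seq_len(g$size[1]))
  }
})

test_that("catalog orbit labels agree with hand-labelled references under VF2", {
  cat_tbl <- build_catalog()
  for (gi in unique(cat_tbl$graphlet)) {
    rows <- cat_tbl[cat_tbl$graphlet == gi, ]
    g <- igraph::graph_from_edgelist(rows$edges[[1]], directed = FALSE)
    ref <- oracle_orbits_by_isomorphism(g)
    expect_false(is.null(ref))
    got <- integer(rows$size[1])
    for (j in seq_len(nrow(rows))) got[rows$nodes[[j]]] <- rows$orbit[j]
    expect_equal(got, ref)
  }
})

test_that("hand-enumerated signatures are reproduced", {
  expect_equal(unname(count_orbits(net_triangle(), "a")),
               c(2, 0, 0, 1, rep(0, 11)))
  expect_equal(unname(count_orbits(net_claw(), "c")),
               c(3, 0, 3, 0, 0, 0, 0, 1, rep(0, 7)))
  expect_equal(unname(count_orbits(net_k2(), "a")), c(1, rep(0, 14)))
  # every K4 node: degree 3, in 3 triangles, one K4
  g4 <- gdv_matrix(net_k4())
  expect_true(all(g4$o0 == 3 & g4$o3 == 3 & g4$o14 == 1))
  expect_true(all(g4$o1 == 0 & g4$o2 == 0))
})

test_that("orbit counts match the exhaustive subset-enumeration oracle", {
  for (s in 1:8) {
    net <- rand_gnp(sample(8:16, 1), 0.25, seed = 300 + s)
    got <- gdv_matrix(net)
    want <- oracle_gdv(net)
    expect_equal(as.matrix(got[, -1]), unname(want[got$node, , drop = FALSE]),
                 ignore_attr = TRUE)
  }
})

test_that("orbit-count linear identities hold on random graphs", {
  for (s in 1:5) {
    net <- rand_gnp(20, 0.2, seed = 400 + s)
    g <- gdv_matrix(net)
    expect_equal(sum(g$o0), 2 * igraph::ecount(net$graph))
    n_tri <- sum(igraph::count_triangles(net$graph)) / 3
    expect_equal(sum(g$o3), 3 * n_tri)
    k4s <- sum(g$o14)
    expect_equal(k4s %% 4, 0)
  }
})

test_that("signature similarity is bounded, symmetric, and 1 on identity", {
  u <- c(2, 0, 0, 1, rep(0, 11))
  v <- c(3, 0, 3, 0, 0, 0, 0, 1, rep(0, 7))
  expect_equal(gdv_similarity(u, u), 1)
  expect_equal(gdv_similarity(u, v, use_reduced = FALSE), 0.4)
  expect_equal(gdv_similarity(u, v), gdv_similarity(v, u))
  expect_equal(gdv_similarity(c(1, rep(0, 10)), c(0, 1, rep(0, 9))), 0)
  expect_equal(gdv_similarity(rep(0, 11), rep(0, 11)), 1)
  expect_error(gdv_similarity(1:3, 1:4), "length")

  set.seed(1)
  for (i in 1:20) {
    a <- rpois(11, 3); b <- rpois(11, 3)
    s <- gdv_similarity(a, b)
    expect_gte(s, 0); expect_lte(s, 1)
  }
})

test_that("similarity is invariant under graph isomorphism", {
  net <- rand_gnp(12, 0.3, seed = 77)
  perm <- setNames(sprintf("y%02d", sample(length(net$nodes))), net$nodes)
  el <- as_edge_tibble(net)
  net2 <- clock_network(data.frame(from = perm[el$from], to = perm[el$to]))
  a <- net$nodes[1]; b <- net$nodes[5]
  s1 <- gdv_similarity(count_orbits(net, a), count_orbits(net, b))
  s2 <- gdv_similarity(count_orbits(net2, unname(perm[a])),
                       count_orbits(net2, unname(perm[b])))
  expect_equal(s1, s2)
})

test_that("threshold search returns the largest grid value with full coverage", {
  sims <- tibble::tibble(
    seed = rep(c("s1", "s2"), each = 3),
    node = rep(c("n1", "n2", "s2"), 2),
    s_gdv = c(0.97, 0.80, 0.99, 0.952, 0.70, 0.99)
  )
  # s2's best non-seed similarity is 0.952 -> grid must drop to 0.95
  expect_equal(select_threshold(sims, c("s1", "s2")), 0.95)

  # both seeds matched at the start value
  sims2 <- sims; sims2$s_gdv[4] <- 0.961
  expect_equal(select_threshold(sims2, c("s1", "s2")), 0.96)

  # no grid value works
  sims3 <- sims; sims3$s_gdv <- 0
  expect_error(select_threshold(sims3, c("s1", "s2"), start = 0.05),
               "no threshold")
})

test_that("raw candidates exclude seeds and record the best-matching seed", {
  net <- rand_gnp(20, 0.25, seed = 500)
  ids <- net$nodes[1:3]
  g <- gdv_matrix(net)
  sims <- gdv_similarity_table(g, ids)
  expect_true(all(sims$seed != sims$node))

  # a perfect wiring twin always qualifies at threshold 1
  twin_sims <- tibble::tibble(seed = "s", node = c("t", "u"),
                              s_gdv = c(1, 0.5))
  raw <- raw_gdv_candidates(twin_sims, "s", threshold = 1)
  expect_equal(raw$node, "t")
  expect_equal(raw$best_seed, "s")

  # impossible threshold -> empty
  raw0 <- raw_gdv_candidates(dplyr::mutate(sims, s_gdv = pmin(s_gdv, 0.9)),
                             ids, threshold = 1)
  expect_equal(nrow(raw0), 0)
})
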