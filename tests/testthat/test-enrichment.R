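test_that("closed neighborhoods include the node itself", {
  expect_equal(sort(neighborhood(net_triangle(), "a")), c("a", "b", "c"))
  expect_equal(sort(neighborhood(net_claw(), "c")), c("c", "l1", "l2", "l3"))
  expect_equal(neighborhood(net_k2(), "a"), c("a", "b"))
  expect_error(neighborhood(net_k2(), "zzz"), "not in network")
})

test_that("enrichment score matches the worked hypergeometric example", {
  # P(X >= 2) with N=10, M=5, n=2 is C(5,2)/C(10,2) = 2/9
  expect_equal(enrichment_score(10, 5, 2, 2), -log10(2 / 9), tolerance = 1e-9)
  expect_equal(enrichment_score(10, 5, 2, 0), 0)   # P(X >= 0) = 1
  expect_equal(enrichment_score(10, 10, 3, 2), 0)  # all genes annotated
  expect_error(enrichment_score(10, 5, 2, 3), "bounds")
  expect_error(enrichment_score(10, 12, 2, 1), "bounds")
})

test_that("enrichment score agrees with the direct-summation oracle", {
  set.seed(13)
  grid <- expand.grid(N = c(5, 10, 23, 41, 60))
  for (N in grid$N) {
    for (rep in 1:40) {
      M <- sample(0:N, 1)
      n <- sample(0:N, 1)
      m <- sample(0:min(n, M), 1)
      got <- enrichment_score(N, M, n, m)
      want <- oracle_enrichment_score(N, M, n, m)
      expect_lt(abs(got - want), 1e-9 * max(1, abs(want)),
                label = sprintf("score gap at N=%d M=%d n=%d m=%d", N, M, n, m))
    }
  }
})

test_that("score is monotone in m and capped on underflow", {
  sc <- enrichment_score(50, 20, 10, 0:10)
  expect_true(all(diff(sc) >= -1e-12))
  expect_equal(enrichment_score(10, 5, 2, 2, cap = 0.5), 0.5)
})

test_that("enrichment vectors score neighborhood-positive terms", {
  # claw plus a sparse annotated background so the neighborhood is a proper
  # subset of the network
  net <- clock_network(data.frame(
    from = c("c", "c", "c", "u", "v"),
    to   = c("l1", "l2", "l3", "v", "w")))
  ann <- annotation_map(data.frame(gene = c("c", "l1", "l2", "zzz"),
                                   term = c("T1", "T1", "T1", "T2")),
                        "GO")
  ev <- enrichment_vector(net, ann, "c")
  expect_equal(ev$term, "T1") # T2 annotates no neighborhood (or network) gene
  expect_gt(ev$score[1], 0)
  expect_equal(ev$namespace[1], "GO")

  # explicit universe: unannotated terms score 0
  ev2 <- enrichment_vector(net, ann, "c", term_universe = c("T1", "T9"))
  expect_equal(ev2$score[ev2$term == "T9"], 0)

  # empty universe -> empty profile
  ev3 <- enrichment_vector(net, ann, "l1", term_universe = character())
  expect_equal(nrow(ev3), 0)
})

test_that("functional similarity is a cosine on the union of term sets", {
  e1 <- setNames(c(1, 1), c("A", "B"))
  e2 <- setNames(c(1, 1), c("A", "C"))
  expect_equal(functional_similarity(e1, e2), 0.5)
  expect_equal(functional_similarity(e1, e1), 1)
  expect_equal(functional_similarity(e1, setNames(1, "Z")), 0)
  expect_equal(functional_similarity(e1, setNames(numeric(0), character(0))), 0)
  # scale invariance
  expect_equal(functional_similarity(e1 * 7, e2 * 0.1),
               functional_similarity(e1, e2))
  # symmetric
  expect_equal(functional_similarity(e2, e1), functional_similarity(e1, e2))

  t1 <- tibble::tibble(gene = "g", namespace = "GO", term = "A", score = 1)
  t2 <- tibble::tibble(gene = "h", namespace = "pathway", term = "A", score = 1)
  expect_error(functional_similarity(t1, t2), "namespaces")
})

test_that("MAS filter requires the threshold in both namespaces", {
  # candidate x mirrors seed s's neighborhood annotations; an unannotated
  # background chain keeps the term from covering the whole network
  net <- clock_network(data.frame(
    from = c("s", "s", "x", "x", "s", "u1", "u2", "u3"),
    to   = c("a", "b", "a", "b", "x", "u2", "u3", "u4")))
  ann_go <- annotation_map(data.frame(gene = c("s", "x", "a", "b"),
                                      term = c("T1", "T1", "T1", "T1")), "GO")
  ann_pw_shared <- annotation_map(data.frame(gene = c("s", "x", "a"),
                                             term = "P1"), "pathway")
  ann_pw_empty <- annotation_map(data.frame(gene = "q", term = "P9"), "pathway")

  kept <- mas_filter("x", "s", net, ann_go, ann_pw_shared, threshold = 0.75)
  expect_equal(kept$mas_go, 1)
  expect_true(kept$kept)
  expect_equal(kept$best_seed_go, "s")

  # unannotated pathway namespace -> MAS 0 there -> dropped despite GO
  dropped <- mas_filter("x", "s", net, ann_go, ann_pw_empty, threshold = 0.75)
  expect_equal(dropped$mas_pathway, 0)
  expect_false(dropped$kept)

  # empty candidate list passes through
  none <- mas_filter(character(), "s", net, ann_go, ann_pw_shared)
  expect_equal(nrow(none), 0)
})
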