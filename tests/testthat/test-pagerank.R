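test_that("two reciprocal equal edges give the symmetric fixed point", {
  g <- structure(list(nodes = c("a", "b"),
                      edges = data.frame(from = c("a", "b"), to = c("b", "a"),
                                         w = c(0.7, 0.7))),
                 class = "weighted_graph")
  pr <- weighted_pagerank(g)
  expect_equal(unname(pr$scores), c(0.5, 0.5), tolerance = 1e-10)
})

test_that("scores conserve mass, including with dangling nodes", {
  set.seed(202)
  for (i in 1:20) {
    g <- random_weighted_graph(sample(3:40, 1))
    pr <- suppressWarnings(weighted_pagerank(g))
    expect_equal(sum(pr$scores), 1, tolerance = 1e-6)
    expect_true(all(pr$scores >= 0))
  }
  # an explicitly dangling sink
  g <- structure(list(nodes = c("a", "b", "sink"),
                      edges = data.frame(from = c("a", "b"),
                                         to = c("b", "sink"),
                                         w = c(0.9, 0.4))),
                 class = "weighted_graph")
  pr <- weighted_pagerank(g)
  expect_equal(sum(pr$scores), 1, tolerance = 1e-10)
})

test_that("power iteration matches the dense stationary-system oracle", {
  set.seed(77)
  for (i in 1:100) {
    g <- random_weighted_graph(sample(3:50, 1))
    pr <- suppressWarnings(weighted_pagerank(g, d = 0.8, tol = 1e-12,
                                             max_iter = 300))
    oracle <- pagerank_dense_oracle(g, d = 0.8)
    expect_lt(sum(abs(pr$scores - oracle[names(pr$scores)])), 1e-8)
  }
})

test_that("equal weights reduce to classic PageRank", {
  set.seed(9)
  for (i in 1:5) {
    g <- random_weighted_graph(25)
    g$edges$w <- 0.5
    pr <- weighted_pagerank(g, d = 0.8, tol = 1e-14, max_iter = 500)
    ig <- igraph::graph_from_data_frame(g$edges[, c("from", "to")],
                                        vertices = g$nodes)
    classic <- igraph::page_rank(ig, damping = 0.8,
                                 algo = "prpack")$vector
    expect_lt(max(abs(pr$scores[names(classic)] - classic)), 1e-10)
  }
})

test_that("non-convergence returns the best iterate with a warning", {
  g <- random_weighted_graph(30)
  expect_warning(pr <- weighted_pagerank(g, tol = 1e-15, max_iter = 2),
                 "did not converge")
  expect_equal(pr$iterations, 2L)
  expect_true(is.finite(pr$residual))
})

test_that("path scores follow the confidence-product x mean-importance rule", {
  steps <- data.frame(h = c("e1", "e2", "e3"), r = c("r", "r", "r"),
                      t = c("e2", "e3", "e4"), s = c(0.9, 0.8, 0.7))
  pr <- structure(list(scores = c(e1 = 0.1, e2 = 0.2, e3 = 0.3, e4 = 0.4),
                       d = 0.8, iterations = 1L, residual = 0),
                  class = "pagerank_result")
  sp <- score_path(reasoning_path(steps), pr)
  expect_equal(sp$score, 0.504 * 0.25, tolerance = 1e-12)  # = 0.126

  one <- reasoning_path(data.frame(h = "e1", r = "r", t = "e2", s = 0.6))
  expect_equal(score_path(one, pr)$score, 0.6 * (0.1 + 0.2) / 2)

  # all confidences 1, equal importance p -> score = p
  ones <- reasoning_path(data.frame(h = c("e1", "e2"), r = "r",
                                    t = c("e2", "e3"), s = c(1, 1)))
  pru <- structure(list(scores = c(e1 = 0.25, e2 = 0.25, e3 = 0.25),
                        d = 0.8, iterations = 1L, residual = 0),
                   class = "pagerank_result")
  expect_equal(score_path(ones, pru)$score, 0.25)

  expect_error(score_path(reasoning_path(
    data.frame(h = "x", r = "r", t = "y", s = 0.5)), pr),
    class = "path_key_error")
})

test_that("path scores stay in [0,1] and drop when any confidence drops", {
  set.seed(33)
  for (i in 1:200) {
    len <- sample(1:4, 1)
    ents <- paste0("e", 0:len)
    steps <- data.frame(h = ents[-length(ents)], r = "r", t = ents[-1],
                        s = runif(len))
    scores <- runif(len + 1)
    pr <- structure(list(scores = stats::setNames(scores / sum(scores) , ents),
                         d = 0.8, iterations = 1L, residual = 0),
                    class = "pagerank_result")
    sc <- score_path(reasoning_path(steps), pr)$score
    expect_gte(sc, 0); expect_lte(sc, 1)
    j <- sample(len, 1)
    lowered <- steps; lowered$s[j] <- lowered$s[j] * runif(1)
    expect_lte(score_path(reasoning_path(lowered), pr)$score, sc)
  }
})

test_that("ranking is stable, capped at k, and breaks ties by length", {
  mk <- function(score, ents) {
    steps <- data.frame(h = ents[-length(ents)], r = "r", t = ents[-1],
                        s = 0.5)
    list(path = reasoning_path(steps), score = score)
  }
  paths <- list(mk(0.3, c("a", "b")), mk(0.9, c("c", "d")),
                mk(0.5, c("e", "f")))
  top2 <- rank_and_filter_paths(paths, k = 2)
  expect_equal(vapply(top2, function(p) p$score, numeric(1)), c(0.9, 0.5))
  expect_length(rank_and_filter_paths(paths, k = 10), 3)

  tie <- list(mk(0.4, c("a", "b", "c")), mk(0.4, c("x", "y")))
  expect_equal(rank_and_filter_paths(tie, k = 2)[[1]]$path$entities,
               c("x", "y"))

  lex <- list(mk(0.4, c("b", "z")), mk(0.4, c("a", "z")))
  expect_equal(rank_and_filter_paths(lex, k = 1)[[1]]$path$entities,
               c("a", "z"))
})

test_that("weighted subgraphs average parallel edges and add neighbors", {
  kg <- ukg(facts = data.frame(
    h = c("j", "j", "a", "c"), r = c("r1", "r2", "r1", "r1"),
    t = c("i", "i", "b", "a"), s = c(0.6, 1.0, 0.9, 0.7)))
  path <- reasoning_path(data.frame(h = "j", r = "r1", t = "i", s = 0.6))
  g <- build_weighted_subgraph(kg, list(path))
  eji <- g$edges[g$edges$from == "j" & g$edges$to == "i", ]
  expect_equal(eji$w, 0.8)   # mean of 0.6 and 1.0

  chain <- chain_kg(extra = data.frame(h = "z", r = "r9", t = "a", s = 0.3))
  p2 <- reasoning_path(chain$facts[1:2, ])
  g2 <- build_weighted_subgraph(chain, list(p2))
  expect_true("z" %in% g2$nodes)   # one-hop neighbor of the path
  expect_setequal(g2$nodes, c("a", "b", "c", "z"))

  empty <- build_weighted_subgraph(kg, list())
  expect_length(empty$nodes, 0)
  expect_error(weighted_pagerank(empty), class = "path_validation_error")
})
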