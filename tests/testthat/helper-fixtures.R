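# Shared fixtures and independent oracles for the test suite.

# Small chain graph a -r1-> b -r2-> c with optional extra edges.
chain_kg <- function(extra = NULL) {
  facts <- data.frame(h = c("a", "b"), r = c("r1", "r2"), t = c("b", "c"),
                      s = c(0.9, 0.8), stringsAsFactors = FALSE)
  if (!is.null(extra)) facts <- rbind(facts, extra)
  ukg(facts = facts)
}

# Independent dense oracle for weighted PageRank: solve the stationary
# system (I - d A) pr = (1 - d)/N directly, where A_ij = w_{j->i}/outsum_j
# and dangling columns redistribute uniformly.
pagerank_dense_oracle <- function(graph, d = 0.8) {
  nodes <- graph$nodes
  n <- length(nodes)
  A <- matrix(0, n, n)
  e <- graph$edges[graph$edges$w > 0, , drop = FALSE]
  if (nrow(e)) {
    fi <- match(e$from, nodes); ti <- match(e$to, nodes)
    outsum <- tapply(e$w, fi, sum)
    for (k in seq_len(nrow(e))) {
      A[ti[k], fi[k]] <- A[ti[k], fi[k]] + e$w[k] / outsum[[as.character(fi[k])]]
    }
  }
  dangling <- setdiff(seq_len(n), unique(match(e$from, nodes)))
  A[, dangling] <- 1 / n
  pr <- solve(diag(n) - d * A, rep((1 - d) / n, n))
  stats::setNames(pr, nodes)
}

# Random weighted directed graph on n nodes as a weighted_graph object.
random_weighted_graph <- function(n, p = 0.15) {
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  keep <- stats::runif(nrow(pairs)) < p
  edges <- pairs[keep, , drop = FALSE]
  edges$w <- stats::runif(nrow(edges), 0.05, 1)
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "weighted_graph")
}

# Default synthetic benchmark world, generated once per test run.
.fixture_env <- new.env(parent = emptyenv())

default_sim <- function() {
  if (is.null(.fixture_env$sim)) .fixture_env$sim <- generate_kg(synthetic_spec())
  .fixture_env$sim
}

default_table <- function() {
  if (is.null(.fixture_env$table)) {
    .fixture_env$table <- fit_confidence_model(default_sim()$kg, seed = 11)
  }
  .fixture_env$table
}

# Scripted mock client whose extraction tasks follow a fixed rule table.
scripted_client <- function(kg = NULL, rules = list()) {
  mock_llm_client(kg = kg, rules = rules)
}

fact_key <- function(df) paste(df$h, df$r, df$t, sep = "\x1f")
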