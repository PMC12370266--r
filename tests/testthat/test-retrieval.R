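test_that("the hash provider meets the embedding contract", {
  prov <- hash_embedding_provider()
  v1 <- prov$embed("Yin-Deficient Constitution")
  v2 <- prov$embed("Yin-Deficient Constitution")
  expect_identical(v1, v2)
  expect_equal(sqrt(sum(v1^2)), 1, tolerance = 1e-6)
  expect_length(v1, 64)
  expect_equal(sqrt(sum(prov$embed("")^2)), 1)
})

test_that("mock keyword extraction recovers entity names from the query", {
  sim <- default_sim()
  client <- mock_llm_client(sim$kg)
  kws <- extract_keywords("I have Symptom 042. What foods would you recommend?",
                          client)
  expect_equal(kws, "Symptom 042")
  expect_equal(extract_keywords("", client), character())
  expect_equal(extract_keywords("nothing matches here", client), character())

  # CJK-style names match as substrings too
  kg <- ukg(facts = data.frame(h = c("手足心热", "失眠多梦"), r = "相关体质",
                               t = "阴虚质", s = 0.9))
  kws2 <- extract_keywords("我最近手足心热、失眠多梦，请推荐食材。",
                           mock_llm_client(kg))
  expect_setequal(kws2, c("手足心热", "失眠多梦"))
})

test_that("candidate retrieval ranks by cosine with deterministic ties", {
  sim <- default_sim()
  prov <- hash_embedding_provider()
  cache <- entity_embedding_matrix(sim$kg, prov)
  top <- candidate_entities("Symptom 042", sim$kg, prov, top_n = 10,
                            cache = cache)
  expect_equal(top[1], "Symptom 042")   # exact name: cosine 1
  expect_length(top, 10)

  tiny <- ukg(facts = data.frame(h = c("aa", "bb"), r = "r",
                                 t = c("cc", "dd"), s = 0.5))
  expect_setequal(candidate_entities("aa", tiny, prov, top_n = 100),
                  c("aa", "bb", "cc", "dd"))

  # regression-pinned ordering on a fixed five-entity graph
  five <- ukg(facts = data.frame(h = c("apple", "apricot", "banana", "berry"),
                                 r = "r", t = "fruit salad", s = 0.5))
  expect_identical(candidate_entities("apric", five, prov, top_n = 5),
                   c("apricot", "banana", "apple", "fruit salad", "berry"))
})

test_that("entity linking honors None and rejects out-of-list picks", {
  sim <- default_sim()
  client <- mock_llm_client(sim$kg)
  cands <- list("Symptom 042" = c("Symptom 042", "Symptom 043"))
  expect_equal(as.character(link_entities("Symptom 042", cands, sim$kg,
                                          client)), "Symptom 042")
  none <- list("unmatchable keyword" = c("Symptom 042", "Symptom 043"))
  expect_length(link_entities("unmatchable keyword", none, sim$kg, client), 0)

  rogue <- scripted_client(rules = list(entity_linking = '["Symptom 999"]'))
  out <- link_entities("Symptom 042", cands, sim$kg, rogue)
  expect_length(as.character(out), 0)
  expect_equal(attr(out, "rejected"), "Symptom 999")
})

test_that("relation-path enumeration is breadth-first and complete", {
  kg <- chain_kg()
  expect_equal(enumerate_relation_paths(kg, "a", max_len = 2),
               list("r1", c("r1", "r2")))
  expect_equal(enumerate_relation_paths(kg, "a", max_len = 1), list("r1"))
  expect_length(enumerate_relation_paths(kg, "c", max_len = 3), 0)
  expect_length(enumerate_relation_paths(kg, "a", max_len = 3,
                                         max_paths = 1), 1)
})

test_that("LLM-proposed relation paths are validated against the graph", {
  kg <- chain_kg()
  scripted <- structure(list(
    complete = function(prompt, task = NULL, payload = list())
      '[["r1", "r2"], ["r1", "not a relation"]]',
    name = "scripted", temperature = 0, enumerate_paths = FALSE),
    class = "llm_client")
  out <- generate_relation_paths("q", "a", kg, scripted)
  expect_length(out, 1)
  expect_identical(out[[1]], c("r1", "r2"))
  expect_length(attr(out, "dropped"), 1)

  mock_out <- generate_relation_paths("q", "a", kg, mock_llm_client(kg))
  expect_equal(mock_out, enumerate_relation_paths(kg, "a", max_len = 3))
})

test_that("reasoning paths instantiate patterns exactly, capped per pattern", {
  kg <- ukg(facts = data.frame(
    h = c("Heat in Hands and Feet", "Yin-deficient Constitution",
          "Yin-deficient Constitution", "Yin-deficient Constitution"),
    r = c("Related Constitution", "Suitable Food", "Suitable Food",
          "Suitable Food"),
    t = c("Yin-deficient Constitution", "Lily Bulb", "White Fungus",
          "Mulberry"),
    s = 0.9))
  paths <- instantiate_reasoning_paths(
    kg, "Heat in Hands and Feet",
    list(c("Related Constitution", "Suitable Food")))
  expect_length(paths, 3)
  expect_setequal(vapply(paths, function(p) p$entities[3], character(1)),
                  c("Lily Bulb", "White Fungus", "Mulberry"))
  expect_true(all(vapply(paths, function(p)
    identical(relation_path_of(p), c("Related Constitution", "Suitable Food")),
    logical(1))))

  expect_length(instantiate_reasoning_paths(kg, "Heat in Hands and Feet",
                                            list("Suitable Food")), 0)
  capped <- instantiate_reasoning_paths(
    kg, "Heat in Hands and Feet",
    list(c("Related Constitution", "Suitable Food")), cap_per_pattern = 2)
  expect_length(capped, 2)
  expect_equal(attr(capped, "overflow"), 1L)
})

test_that("retrieval composes the pipeline and flags unanswerable queries", {
  sim <- default_sim()
  q <- generate_queries(sim, n = 2)[[1]]
  ctx <- retrieve(q$text, sim$kg)
  expect_true(ctx$answerable)
  expect_equal(ctx$linked_entities, q$query_entities)
  expect_lte(length(ctx$reasoning_paths), 10)
  scores <- vapply(ctx$reasoning_paths, function(sp) sp$score, numeric(1))
  expect_true(all(diff(scores) <= 1e-12))
  expect_true(all(vapply(ctx$reasoning_paths, function(sp)
    sp$path$entities[1] %in% ctx$linked_entities, logical(1))))

  hopeless <- retrieve("no overlap with anything in the graph", sim$kg)
  expect_false(hopeless$answerable)
  expect_length(hopeless$reasoning_paths, 0)

  one <- retrieve(q$text, sim$kg, k = 1)
  expect_length(one$reasoning_paths, 1)
})

test_that("the mock pipeline is deterministic end to end", {
  sim <- default_sim()
  q <- generate_queries(sim, n = 1)[[1]]
  cache <- entity_embedding_matrix(sim$kg, hash_embedding_provider())
  c1 <- retrieve(q$text, sim$kg, cache = cache)
  c2 <- retrieve(q$text, sim$kg, cache = cache)
  expect_identical(
    jsonlite::toJSON(query_context_json(c1), auto_unbox = TRUE, digits = NA),
    jsonlite::toJSON(query_context_json(c2), auto_unbox = TRUE, digits = NA))
})

test_that("raising a gold path's confidences never lowers its rank", {
  sim <- default_sim()
  q <- generate_queries(sim, n = 3)[[2]]
  gp <- q$gold_paths[1, ]
  rank_of <- function(kg) {
    ctx <- retrieve(q$text, kg, k = 50)
    hits <- vapply(ctx$reasoning_paths, function(sp) {
      st <- sp$path$steps
      nrow(st) == 2 && st$h[1] == gp$symptom && st$t[1] == gp$constitution &&
        st$t[2] == gp$food
    }, logical(1))
    which(hits)[1]
  }
  base_rank <- rank_of(sim$kg)
  boosted <- sim$kg$facts
  sel1 <- boosted$h == gp$symptom & boosted$r == "Related Constitution" &
    boosted$t == gp$constitution
  sel2 <- boosted$h == gp$constitution & boosted$r == "Suitable Food" &
    boosted$t == gp$food
  boosted$s[sel1 | sel2] <- 0.999
  kg_boost <- ukg(facts = boosted, entities = sim$kg$entities,
                  relations = sim$kg$relations)
  expect_lte(rank_of(kg_boost), base_rank)
})
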