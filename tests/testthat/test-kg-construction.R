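test_that("segmentation is lossless and respects the token budget", {
  set.seed(1)
  words <- paste0("w", seq_len(750))
  doc <- paste(words, collapse = " ")
  ps <- segment_passages(doc, size = 300)
  expect_length(ps, 3)
  expect_true(all(vapply(ps, function(p) p$token_count, integer(1)) <= 300))
  expect_identical(paste(vapply(ps, function(p) p$text, character(1)),
                         collapse = ""), doc)

  tiny <- segment_passages(paste(letters[1:10], collapse = " "), size = 300)
  expect_length(tiny, 1)
  expect_equal(tiny[[1]]$token_count, 10L)

  degenerate <- segment_passages("a b c", size = 1)
  expect_length(degenerate, 3)

  expect_length(segment_passages("", size = 300), 0)

  # character tokenizer for unspaced scripts
  cjk <- segment_passages(strrep("字", 7), size = 3, tokenizer = "character")
  expect_length(cjk, 3)
  expect_identical(paste(vapply(cjk, function(p) p$text, character(1)),
                         collapse = ""), strrep("字", 7))

  # irregular whitespace survives the round trip
  messy <- "  leading   and \t tabbed text\n\nkept  "
  ps2 <- segment_passages(messy, size = 2)
  expect_identical(paste(vapply(ps2, function(p) p$text, character(1)),
                         collapse = ""), messy)
})

test_that("passage refinement is identity under the mock and skips empties", {
  p <- segment_passages("some passage text", doc_id = "d1")[[1]]
  expect_identical(refine_passage(p, title = "T", client = mock_llm_client()),
                   "some passage text")
  empty <- structure(list(doc_id = "d1", index = 1L, text = "",
                          token_count = 0L), class = "passage")
  expect_identical(refine_passage(empty), "")
})

test_that("relation discovery and canonicalization follow the client", {
  p <- segment_passages("lily bulb suits yin deficiency", doc_id = "d")[[1]]
  expect_equal(discover_relations(p, client = mock_llm_client()), character())

  scripted <- scripted_client(rules = list(
    discover_relations = '["Suitable Food"]'))
  expect_equal(discover_relations(p, client = scripted), "Suitable Food")

  cur <- c("Related Constitution", "Suitable Food")
  expect_equal(canonicalize_relations(cur, character()), cur)
  expect_equal(canonicalize_relations(cur, "Suitable Food",
                                      client = mock_llm_client()), cur)
  out <- canonicalize_relations(cur, "Influencing Factor",
                                client = mock_llm_client())
  expect_setequal(out, c(cur, "Influencing Factor"))
  # the current set survives even a client that answers nonsense
  drop_all <- scripted_client(rules = list(canonicalize_relations = "[]"))
  expect_true(all(cur %in% canonicalize_relations(cur, "New", client = drop_all)))
})

test_that("extracted triples are strictly constrained to the relation set", {
  p <- segment_passages("Insomnia relates to yin deficiency", doc_id = "d7")[[1]]
  rsel <- c("Related Constitution", "Suitable Food")
  scripted <- scripted_client(rules = list(extract_triples = jsonlite::toJSON(
    list(
      list("Insomnia and Vivid Dreams", "Related Constitution",
           "Yin-Deficient Constitution"),
      list("Lily Bulb", "Totally Made Up Relation", "Insomnia")
    ), auto_unbox = TRUE)))
  out <- extract_triples(p, rsel, client = scripted)
  expect_equal(nrow(out), 1)
  expect_equal(out$r, "Related Constitution")
  expect_equal(out$doc_id, "d7")
  dropped <- attr(out, "dropped")
  expect_equal(nrow(dropped), 1)
  expect_equal(dropped$r, "Totally Made Up Relation")

  expect_equal(nrow(extract_triples(p, rsel, client = mock_llm_client())), 0)
})

test_that("attribute extraction populates only what the client returned", {
  p <- segment_passages("Lily bulb calms the mind.", doc_id = "d")[[1]]
  scripted <- scripted_client(rules = list(food_attributes = jsonlite::toJSON(
    list(name = "Lily Bulb", primary_effects = list("calms the mind"),
         indications = list("insomnia")), auto_unbox = TRUE)))
  rec <- extract_entity_attributes(p, "food", client = scripted)
  expect_s3_class(rec, "food_attributes")
  expect_equal(rec$primary_effects, "calms the mind")
  expect_equal(rec$contraindications, character())

  bare <- extract_entity_attributes(p, "food", entity_name = "Lily Bulb",
                                    client = mock_llm_client())
  expect_equal(bare$name, "Lily Bulb")
  expect_equal(bare$primary_effects, character())

  dish_client <- scripted_client(rules = list(dish_attributes = jsonlite::toJSON(
    list(name = "Lotus Soup", ingredients = list("lotus seed", "lily bulb"),
         cooking_method = "simmer"), auto_unbox = TRUE)))
  dish <- extract_entity_attributes(p, "dish", client = dish_client)
  expect_s3_class(dish, "dish_attributes")
  expect_equal(dish$ingredients, c("lotus seed", "lily bulb"))
})

test_that("document construction yields a closed, provenance-tracked graph", {
  docs <- list(
    d1 = "Insomnia and Vivid Dreams relates to Yin-Deficient Constitution.",
    d2 = "Yin-Deficient Constitution suits Lily Bulb. And again: suits Lily Bulb.")
  triple_rule <- function(payload) {
    txt <- payload$passage
    out <- list()
    if (grepl("Insomnia", txt)) {
      out <- c(out, list(list("Insomnia and Vivid Dreams",
                              "Related Constitution",
                              "Yin-Deficient Constitution")))
    }
    if (grepl("suits Lily Bulb", txt)) {
      out <- c(out, list(list("Yin-Deficient Constitution", "Suitable Food",
                              "Lily Bulb")))
    }
    as.character(jsonlite::toJSON(out, auto_unbox = TRUE))
  }
  client <- scripted_client(rules = list(extract_triples = triple_rule))
  res <- build_kg_from_documents(
    docs, client = client,
    initial_relations = c("Related Constitution", "Suitable Food"))
  expect_true(all(res$kg$facts$r %in% res$relation_set))
  expect_equal(nrow(res$kg$facts), 2)
  expect_true(all(res$kg$facts$s == 1.0))   # placeholder until scoring
  key <- paste("Yin-Deficient Constitution", "Suitable Food", "Lily Bulb",
               sep = "\x1f")
  expect_equal(unname(res$evidence_counts[key]), 1L)

  # identical transcripts give identical graphs
  res2 <- build_kg_from_documents(
    docs, client = scripted_client(rules = list(extract_triples = triple_rule)),
    initial_relations = c("Related Constitution", "Suitable Food"))
  expect_identical(res$kg$facts, res2$kg$facts)
})
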