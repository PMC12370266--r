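#' Deterministic text-embedding providers
#'
#' The query pipeline encodes entity names and keywords into dense unit
#' vectors for cosine-similarity candidate retrieval.  The provider
#' contract is a list with `embed(text)` returning a unit-norm vector of
#' fixed dimension, deterministic per input.  The built-in hash provider
#' maps character 3-grams (with boundary padding) into `dim` signed
#' buckets by FNV-1a hashing and L2-normalizes the counts: it needs no
#' model download, is reproducible everywhere, and gives graded
#' similarity for overlapping strings.  A semantic sentence encoder can
#' be slotted in behind the same contract.
#'
#' @param dim embedding dimension (default 64).
#' @return an `embedding_provider` with fields `embed`, `dim`, `name`.
#' @export
hash_embedding_provider <- function(dim = 64) {
  embed <- function(text) {
    text <- tolower(enc2utf8(as.character(text)))
    v <- numeric(dim)
    if (nzchar(text)) {
      padded <- paste0("⌂", text, "⌂")
      chars <- strsplit(padded, "")[[1]]
      n <- length(chars)
      grams <- if (n >= 3) {
        vapply(seq_len(n - 2), function(i)
          paste(chars[i:(i + 2)], collapse = ""), character(1))
      } else padded
      for (g in grams) {
        h <- strtoi(substr(fnv1a32(g), 1, 7), 16L)
        bucket <- h %% dim + 1
        sgn <- if ((h %/% dim) %% 2 == 0) 1 else -1
        v[bucket] <- v[bucket] + sgn
      }
    }
    nrm <- sqrt(sum(v^2))
    if (nrm == 0) v[1] <- 1 else v <- v / nrm
    v
  }
  structure(list(embed = embed, dim = dim, name = "hash3gram"),
            class = "embedding_provider")
}

#' Precompute entity-name embeddings for a graph
#'
#' Entities are embedded from their names only, so linking stays
#' independent of attribute coverage.
#'
#' @param kg a [ukg].
#' @param provider an `embedding_provider`.
#' @return matrix with one unit-norm row per entity, rownames = ids.
#' @export
entity_embedding_matrix <- function(kg, provider = hash_embedding_provider()) {
  ids <- kg$entities$id
  if (!length(ids)) {
    return(matrix(numeric(), 0, provider$dim))
  }
  m <- t(vapply(kg$entities$name, provider$embed, numeric(provider$dim)))
  rownames(m) <- ids
  m
}

#' Extract query keywords
#'
#' Asks the client for the keywords capturing the query's health-related
#' intent.  The mock policy returns the longest knowledge-graph entity
#' names occurring verbatim in the query, which makes the offline
#' pipeline fully deterministic.
#'
#' @param query user query text.
#' @param client an `llm_client`.
#' @return character vector of keywords (possibly empty).
#' @export
extract_keywords <- function(query, client = mock_llm_client()) {
  if (!nzchar(trimws(query))) return(character())
  prompt <- render_prompt("keyword_extraction", list(user_query = query))
  out <- complete_json(client, prompt, shape = "list",
                       task = "keyword_extraction",
                       payload = list(user_query = query))
  unique(trimws(as.character(unlist(out))))
}

#' Retrieve candidate entities for a keyword
#'
#' Ranks graph entities by cosine similarity between the keyword
#' embedding and precomputed entity-name embeddings, returning the top
#' `top_n` (default 10).  Ties are broken lexicographically by entity id
#' for reproducibility.
#'
#' @param keyword keyword string.
#' @param kg a [ukg].
#' @param provider an `embedding_provider`.
#' @param top_n number of candidates.
#' @param cache optional precomputed [entity_embedding_matrix()].
#' @return character vector of entity ids, best first.
#' @export
candidate_entities <- function(keyword, kg,
                               provider = hash_embedding_provider(),
                               top_n = 10, cache = NULL) {
  if (!nrow(kg$entities)) return(character())
  m <- cache %||% entity_embedding_matrix(kg, provider)
  q <- provider$embed(keyword)
  sims <- as.numeric(m %*% q)   # rows and q are unit norm: dot = cosine
  ord <- order(-sims, rownames(m))
  rownames(m)[ord][seq_len(min(top_n, nrow(m)))]
}

#' Link keywords to graph entities
#'
#' For each keyword, the client chooses at most one entity from its
#' candidate list, or "None".  "None" selections contribute nothing (the
#' query degrades rather than aborting), and a selection outside the
#' candidate list is rejected and treated as "None".  The result is the
#' query entity set.
#'
#' @param keywords character vector.
#' @param candidates named list: keyword -> candidate entity ids.
#' @param kg a [ukg] (used to map candidate ids to display names).
#' @param client an `llm_client`.
#' @return character vector of linked entity ids (unique, query order);
#'   rejected selections are reported in `attr(, "rejected")`.
#' @export
link_entities <- function(keywords, candidates, kg,
                          client = mock_llm_client()) {
  linked <- character()
  rejected <- character()
  name_of <- stats::setNames(kg$entities$name, kg$entities$id)
  for (kw in keywords) {
    cand_ids <- candidates[[kw]] %||% character()
    if (!length(cand_ids)) next
    cand_names <- unname(name_of[cand_ids])
    prompt <- render_prompt("entity_linking", list(
      keyword = kw, candidate_entities = cand_names))
    out <- complete_json(client, prompt, shape = "list",
                         task = "entity_linking",
                         payload = list(keyword = kw,
                                        candidate_entities = cand_names))
    pick <- trimws(as.character(unlist(out)))[1] %||% "None"
    if (is.na(pick) || identical(pick, "None")) next
    hit <- cand_ids[cand_names == pick | cand_ids == pick]
    if (!length(hit)) {
      rejected <- c(rejected, pick)   # outside the candidate list
      next
    }
    linked <- c(linked, hit[1])
  }
  structure(unique(linked), rejected = rejected)
}

#' Enumerate instantiable relation paths
#'
#' Deterministic breadth-first enumeration of all relation sequences of
#' length at most `max_len` that can be instantiated starting from at
#' least one query entity.  This is the offline substitute the mock
#' client uses in place of LLM relation-path generation.
#'
#' @param kg a [ukg].
#' @param query_entities character vector of entity ids.
#' @param max_len maximum path length (default 3).
#' @param max_paths cap on the number of returned sequences.
#' @param terminal_types optional entity types the final hop must be able
#'   to reach (e.g. `c("food", "dish")` for dietary answers, mirroring
#'   the instruction that relation paths serve to retrieve entities able
#'   to answer the query).  Sequences that cannot terminate at such an
#'   entity are dropped; if none qualifies the unfiltered enumeration is
#'   returned, so untyped graphs degrade gracefully.
#' @return list of character vectors (relation sequences), BFS order.
#' @export
enumerate_relation_paths <- function(kg, query_entities, max_len = 3,
                                     max_paths = 100,
                                     terminal_types = NULL) {
  stopifnot(max_len >= 1)
  query_entities <- intersect(query_entities, kg$entities$id)
  if (!length(query_entities) || !nrow(kg$facts)) return(list())
  etype <- stats::setNames(kg$entities$etype, kg$entities$id)
  out <- list()
  all_out <- list()
  seen <- character()
  queue <- list(list(rels = character(), ents = query_entities))
  while (length(queue) && length(out) < max_paths) {
    state <- queue[[1]]; queue <- queue[-1]
    if (length(state$rels) >= max_len) next
    sub <- kg$facts[kg$facts$h %in% state$ents, , drop = FALSE]
    for (r in sort(unique(sub$r))) {
      rels <- c(state$rels, r)
      key <- paste(rels, collapse = "\x1f")
      ents <- unique(sub$t[sub$r == r])
      if (!(key %in% seen)) {
        seen <- c(seen, key)
        all_out[[length(all_out) + 1L]] <- rels
        keep <- is.null(terminal_types) ||
          any(etype[ents] %in% terminal_types)
        if (keep) out[[length(out) + 1L]] <- rels
        if (length(out) >= max_paths) break
      }
      queue[[length(queue) + 1L]] <- list(rels = rels, ents = ents)
    }
  }
  if (!is.null(terminal_types) && !length(out)) {
    return(all_out[seq_len(min(length(all_out), max_paths))])
  }
  out
}

#' Generate relation paths for a query
#'
#' Few-shot prompts the client for relation paths; every returned path is
#' validated against the graph's relation set and paths containing an
#' unknown relation are dropped (reported via `attr(, "dropped")`).  The
#' mock client delegates to [enumerate_relation_paths()].
#'
#' @param query user query text.
#' @param query_entities linked entity ids.
#' @param kg a [ukg].
#' @param client an `llm_client`.
#' @param examples few-shot examples rendered into the prompt.
#' @param max_len,max_paths bounds for the enumeration fallback.
#' @return list of relation sequences (character vectors).
#' @export
generate_relation_paths <- function(query, query_entities, kg,
                                    client = mock_llm_client(),
                                    examples = default_few_shot_examples(),
                                    max_len = 3, max_paths = 100,
                                    terminal_types = NULL) {
  if (isTRUE(client$enumerate_paths)) {
    return(enumerate_relation_paths(kg, query_entities, max_len, max_paths,
                                    terminal_types))
  }
  prompt <- render_prompt("relation_paths", list(
    existing_relations = kg$relations, user_query = query,
    query_entities = query_entities, examples = examples))
  out <- complete_json(client, prompt, shape = "list",
                       task = "relation_paths",
                       payload = list(user_query = query,
                                      query_entities = query_entities))
  paths <- lapply(out, function(p) trimws(as.character(unlist(p))))
  ok <- vapply(paths, function(p) length(p) >= 1 && all(p %in% kg$relations),
               logical(1))
  structure(paths[ok], dropped = paths[!ok])
}

#' @rdname generate_relation_paths
#' @export
default_few_shot_examples <- function() {
  paste(
    'Query: "What should someone with night sweats eat?" ->',
    '[["Related Constitution", "Suitable Food"]];',
    'Query: "Which dishes fit a fatigue-prone constitution?" ->',
    '[["Related Constitution", "Suitable Dish"]]')
}

#' Instantiate reasoning paths
#'
#' Walks each relation path from each query entity through the graph's
#' `(head, relation)` index, producing every matching chain of facts.
#' Paths are deduplicated and the count per relation-path pattern is
#' capped (hub entities can otherwise blow up combinatorially; overflow
#' is reported via `attr(, "overflow")`).
#'
#' @param kg a [ukg].
#' @param query_entities starting entity ids.
#' @param relation_paths list of relation sequences.
#' @param cap_per_pattern per-pattern cap (default 1000).
#' @return list of `reasoning_path` objects.
#' @export
instantiate_reasoning_paths <- function(kg, query_entities, relation_paths,
                                        cap_per_pattern = 1000) {
  out <- list()
  seen <- character()
  overflow <- 0L
  for (pattern in relation_paths) {
    found <- 0L
    # iterative frontier of partial step tables
    frontier <- lapply(intersect(query_entities, kg$entities$id),
                       function(e) list(at = e, rows = integer()))
    for (depth in seq_along(pattern)) {
      nxt <- list()
      for (st in frontier) {
        rows <- kg$out_index_hr[[paste0(st$at, "\x1f", pattern[depth])]]
        for (ri in rows %||% integer()) {
          nxt[[length(nxt) + 1L]] <- list(at = kg$facts$t[ri],
                                          rows = c(st$rows, ri))
        }
      }
      frontier <- nxt
      if (!length(frontier)) break
    }
    for (st in frontier) {
      if (length(st$rows) != length(pattern)) next
      key <- paste(st$rows, collapse = ",")
      if (key %in% seen) next
      if (found >= cap_per_pattern) { overflow <- overflow + 1L; next }
      seen <- c(seen, key)
      found <- found + 1L
      out[[length(out) + 1L]] <-
        reasoning_path(kg$facts[st$rows, , drop = FALSE])
    }
  }
  structure(out, overflow = overflow)
}

#' Retrieve ranked reasoning paths for a query
#'
#' The full query-side pipeline: keyword extraction, candidate retrieval
#' by cosine similarity, entity linking, relation-path generation,
#' reasoning-path instantiation, confidence-weighted PageRank over the
#' one-hop subgraph, path scoring and top-`k` filtering.  Attribute
#' records for food/dish entities on the retained paths are collected
#' when an attribute store is supplied.  A query whose keywords link to
#' no graph entity yields an unanswerable context, not an error.
#'
#' @param query user query text.
#' @param kg a [ukg].
#' @param provider an `embedding_provider`.
#' @param client an `llm_client`; defaults to the mock bound to `kg`.
#' @param k number of reasoning paths to retain (default 10).
#' @param d PageRank damping factor (default 0.8).
#' @param top_n candidate entities per keyword (default 10).
#' @param max_len maximum relation-path length (default 3).
#' @param attributes optional attribute store ([load_attributes()]).
#' @param cache optional precomputed [entity_embedding_matrix()].
#' @param answer_types entity types an answer may have; relation paths
#'   unable to terminate at such an entity are not pursued (set `NULL`
#'   to disable the filter).
#' @return object of class `query_context` with fields `query_text`,
#'   `keywords`, `linked_entities`, `relation_paths`, `reasoning_paths`
#'   (ranked `scored_path` list), `pagerank`, `attributes`, `answerable`.
#' @export
retrieve <- function(query, kg, provider = hash_embedding_provider(),
                     client = mock_llm_client(kg), k = 10, d = 0.8,
                     top_n = 10, max_len = 3, attributes = NULL,
                     cache = NULL, answer_types = c("food", "dish")) {
  stopifnot(inherits(kg, "ukg"), k >= 1, d > 0, d < 1)
  ctx <- structure(list(query_text = query, keywords = character(),
                        linked_entities = character(),
                        relation_paths = list(), reasoning_paths = list(),
                        pagerank = NULL, attributes = list(),
                        answerable = FALSE),
                   class = "query_context")
  ctx$keywords <- extract_keywords(query, client)
  if (!length(ctx$keywords)) return(ctx)

  cache <- cache %||% entity_embedding_matrix(kg, provider)
  cands <- stats::setNames(
    lapply(ctx$keywords, candidate_entities, kg = kg, provider = provider,
           top_n = top_n, cache = cache),
    ctx$keywords)
  ctx$linked_entities <- as.character(link_entities(ctx$keywords, cands, kg,
                                                    client))
  if (!length(ctx$linked_entities)) return(ctx)

  ctx$relation_paths <- generate_relation_paths(query, ctx$linked_entities,
                                                kg, client, max_len = max_len,
                                                terminal_types = answer_types)
  paths <- instantiate_reasoning_paths(kg, ctx$linked_entities,
                                       ctx$relation_paths)
  if (!length(paths)) return(ctx)

  graph <- build_weighted_subgraph(kg, paths)
  ctx$pagerank <- weighted_pagerank(graph, d = d)
  scored <- lapply(paths, score_path, pr = ctx$pagerank)
  ctx$reasoning_paths <- rank_and_filter_paths(scored, k = k)
  ctx$answerable <- TRUE

  if (!is.null(attributes)) {
    terms <- unique(unlist(lapply(ctx$reasoning_paths, function(sp)
      sp$path$entities)))
    fd <- kg$entities$id[kg$entities$etype %in% c("food", "dish")]
    ctx$attributes <- attributes[intersect(terms, fd)]
    ctx$attributes <- ctx$attributes[!vapply(ctx$attributes, is.null,
                                             logical(1))]
  }
  ctx
}

#' @export
print.query_context <- function(x, ...) {
  cat("Query:", x$query_text, "\n")
  cat("Keywords:", if (length(x$keywords)) paste(x$keywords, collapse = ", ")
      else "(none)", "\n")
  cat("Linked entities:",
      if (length(x$linked_entities)) paste(x$linked_entities, collapse = ", ")
      else "(none)", "\n")
  if (!x$answerable) {
    cat("Unanswerable: no reasoning paths retrieved.\n")
    return(invisible(x))
  }
  cat(sprintf("Top %d reasoning paths:\n", length(x$reasoning_paths)))
  for (sp in x$reasoning_paths) {
    cat(sprintf("  [%.4g] %s\n", sp$score, format_reasoning_path(sp$path)))
  }
  invisible(x)
}
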