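#' Segment a document into passages
#'
#' Documents are cut into passages of at most `size` tokens before
#' extraction.  "Token" is tokenizer-dependent: `"whitespace"` counts
#' maximal non-blank runs (suitable for space-delimited scripts) and
#' `"character"` counts single characters (reproducible for CJK text
#' without a model tokenizer).  Segmentation is lossless: concatenating
#' the passage texts reproduces the document body byte for byte.
#'
#' @param text document body (single string).
#' @param doc_id document identifier.
#' @param size maximum tokens per passage (default 300).
#' @param tokenizer `"whitespace"` or `"character"`.
#' @return list of `passage` records with fields `doc_id`, `index`,
#'   `text`, `token_count`.
#' @export
segment_passages <- function(text, doc_id = "doc", size = 300,
                             tokenizer = c("whitespace", "character")) {
  tokenizer <- match.arg(tokenizer)
  stopifnot(size > 0)
  text <- enc2utf8(as.character(text))
  if (!nzchar(text)) return(list())

  if (tokenizer == "whitespace") {
    # token = non-blank run with its trailing whitespace, so joins are lossless
    chunks <- regmatches(text, gregexpr("\\S+\\s*|^\\s+", text))[[1]]
    is_token <- grepl("\\S", chunks)
    groups <- cumsum(is_token)
    groups[groups == 0] <- 1          # leading whitespace rides with token 1
    pieces <- split(chunks, ceiling(pmax(groups, 1) / size))
    texts <- vapply(pieces, paste, character(1), collapse = "")
    counts <- vapply(pieces, function(p) sum(grepl("\\S", p)), integer(1))
  } else {
    chars <- strsplit(text, "", fixed = FALSE)[[1]]
    pieces <- split(chars, ceiling(seq_along(chars) / size))
    texts <- vapply(pieces, paste, character(1), collapse = "")
    counts <- lengths(pieces)
  }
  lapply(seq_along(texts), function(i) {
    structure(list(doc_id = doc_id, index = i, text = texts[[i]],
                   token_count = as.integer(counts[[i]])),
              class = "passage")
  })
}

#' Refine a passage with an LLM
#'
#' Asks the client to rewrite a passage so it stands alone, resolving
#' pronouns from the document title and neighboring passages and dropping
#' off-topic content.  The mock client returns the passage verbatim.
#' Empty passages are returned unchanged without an LLM call.
#'
#' @param passage a `passage` record from [segment_passages()].
#' @param title document title used as context.
#' @param neighbors character vector of neighboring passage texts.
#' @param client an `llm_client`.
#' @return refined passage text.
#' @export
refine_passage <- function(passage, title = "", neighbors = character(),
                           client = mock_llm_client()) {
  if (!nzchar(passage$text)) return("")
  prompt <- render_prompt("refine_passage", list(
    title = title, passage = passage$text,
    neighbor_passages = paste(neighbors, collapse = "\n---\n")))
  out <- tryCatch(
    client$complete(prompt, task = "refine_passage",
                    payload = list(passage = passage$text, title = title)),
    error = function(e) {
      stop_mfh(paste0("LLM failure refining passage ", passage$doc_id, "#",
                      passage$index, ": ", conditionMessage(e)),
               "gateway_error")
    })
  as.character(out)
}

#' Discover and curate the relation set
#'
#' `discover_relations()` asks the LLM for relation types expressed in a
#' passage; `canonicalize_relations()` asks it to merge the candidates
#' into the current relation set, filtering redundant rewordings.  The
#' result of canonicalization is always a superset of the current set with
#' no duplicates.
#'
#' @param passage a `passage` record.
#' @param current character vector: the current relation set.
#' @param client an `llm_client`.
#' @return `discover_relations()`: character vector of candidate names;
#'   `canonicalize_relations()`: the updated relation set.
#' @export
discover_relations <- function(passage, current = character(),
                               client = mock_llm_client()) {
  prompt <- render_prompt("discover_relations", list(
    relation_definitions = paste(current, collapse = "; "),
    passage = passage$text))
  out <- complete_json(client, prompt, shape = "list",
                       task = "discover_relations",
                       payload = list(passage = passage$text,
                                      existing_relations = current))
  unique(trimws(as.character(unlist(out))))
}

#' @param candidates character vector of proposed relation names.
#' @rdname discover_relations
#' @export
canonicalize_relations <- function(current, candidates,
                                   client = mock_llm_client()) {
  if (!length(candidates)) return(unique(current))
  prompt <- render_prompt("canonicalize_relations", list(
    existing_relations = current, candidate_relations = candidates))
  out <- complete_json(client, prompt, shape = "list",
                       task = "canonicalize_relations",
                       payload = list(existing_relations = current,
                                      candidate_relations = candidates))
  updated <- unique(trimws(as.character(unlist(out))))
  # the current set is never dropped, whatever the model answers
  unique(c(current, updated))
}

#' Extract entity-relation triples from a passage
#'
#' Relations of extracted triples are strictly constrained to the curated
#' relation set: a triple whose relation is outside the set is dropped and
#' reported via the `"dropped"` attribute, never admitted.
#'
#' @param passage a `passage` record.
#' @param rsel character vector: the relation set (non-empty).
#' @param client an `llm_client`.
#' @return data frame of columns `h`, `r`, `t` plus provenance columns
#'   `doc_id`, `passage_index`; dropped triples in `attr(, "dropped")`.
#' @export
extract_triples <- function(passage, rsel, client = mock_llm_client()) {
  stopifnot(length(rsel) > 0)
  prompt <- render_prompt("extract_triples", list(
    relation_set = rsel, passage = passage$text))
  out <- complete_json(client, prompt, shape = "list",
                       task = "extract_triples",
                       payload = list(passage = passage$text,
                                      relation_set = rsel))
  if (!length(out)) {
    res <- data.frame(h = character(), r = character(), t = character(),
                      doc_id = character(), passage_index = integer(),
                      stringsAsFactors = FALSE)
    attr(res, "dropped") <- res[0, c("h", "r", "t")]
    return(res)
  }
  triples <- do.call(rbind, lapply(out, function(tr) {
    tr <- as.character(unlist(tr))
    if (length(tr) != 3) return(NULL)
    data.frame(h = tr[1], r = trimws(tr[2]), t = tr[3],
               stringsAsFactors = FALSE)
  }))
  if (is.null(triples)) triples <- data.frame(h = character(), r = character(),
                                              t = character())
  keep <- triples$r %in% rsel
  dropped <- triples[!keep, , drop = FALSE]
  res <- triples[keep, , drop = FALSE]
  if (nrow(res)) {
    res$doc_id <- passage$doc_id
    res$passage_index <- passage$index
  } else {
    res$doc_id <- character(); res$passage_index <- integer()
  }
  rownames(res) <- NULL
  attr(res, "dropped") <- dropped
  res
}

#' Extract food or dish attributes from a passage
#'
#' The parser populates only fields the LLM returned; missing fields stay
#' empty and are never invented.
#'
#' @param passage a `passage` record.
#' @param entity_kind `"food"` or `"dish"`.
#' @param entity_name fallback name if the LLM omits one.
#' @param client an `llm_client`.
#' @return a [food_attributes()] or [dish_attributes()] record.
#' @export
extract_entity_attributes <- function(passage,
                                      entity_kind = c("food", "dish"),
                                      entity_name = "",
                                      client = mock_llm_client()) {
  entity_kind <- match.arg(entity_kind)
  template <- paste0(entity_kind, "_attributes")
  prompt <- render_prompt(template, list(passage = passage$text))
  rec <- complete_json(client, prompt, shape = "record", task = template,
                       payload = list(passage = passage$text,
                                      entity_name = entity_name))
  nm <- as.character(rec$name %||% entity_name)
  if (!nzchar(nm)) nm <- entity_name
  chr <- function(x) as.character(unlist(x %||% character()))
  if (entity_kind == "food") {
    food_attributes(nm,
                    primary_effects = chr(rec$primary_effects),
                    consumption_methods = chr(rec$consumption_methods),
                    indications = chr(rec$indications),
                    contraindications = chr(rec$contraindications))
  } else {
    dish_attributes(nm,
                    ingredients = chr(rec$ingredients),
                    cooking_method = paste(chr(rec$cooking_method),
                                           collapse = " "),
                    dietary_benefits = chr(rec$dietary_benefits))
  }
}

#' Build a knowledge graph from documents
#'
#' End-to-end construction: segment each document, refine passages,
#' discover and canonicalize relations, extract triples constrained to
#' the final relation set, and assemble the uncertain KG.  Newly
#' extracted facts enter the graph with placeholder confidence 1.0 until
#' [assign_confidences()] replaces it with model scores.  Each extracted
#' triple's provenance `(doc_id, passage index)` is kept in a sidecar
#' table whose per-triple row counts feed the evidence-count channel of
#' the confidence scorer.
#'
#' @param docs named list of document texts (names are doc ids), or a
#'   character vector of file paths when `from_files = TRUE`.
#' @param client an `llm_client`.
#' @param initial_relations starting relation set.
#' @param size,tokenizer passed to [segment_passages()].
#' @param titles optional named character vector of document titles.
#' @param from_files read `docs` as UTF-8 files, filename as doc id.
#' @return list with components `kg` (a [ukg]), `relation_set`,
#'   `provenance` (data frame) and `evidence_counts` (named integer
#'   vector keyed by `h\x1fr\x1ft`).
#' @export
build_kg_from_documents <- function(docs, client = mock_llm_client(),
                                    initial_relations = character(),
                                    size = 300,
                                    tokenizer = "whitespace",
                                    titles = NULL, from_files = FALSE) {
  if (from_files) {
    paths <- docs
    docs <- lapply(paths, function(p)
      paste(readLines(p, encoding = "UTF-8", warn = FALSE), collapse = "\n"))
    names(docs) <- tools::file_path_sans_ext(basename(paths))
  }
  rsel <- unique(initial_relations)
  prov <- list()
  for (id in names(docs)) {
    title <- titles[[id]] %||% id
    passages <- segment_passages(docs[[id]], doc_id = id, size = size,
                                 tokenizer = tokenizer)
    for (j in seq_along(passages)) {
      p <- passages[[j]]
      neigh <- c(if (j > 1) passages[[j - 1]]$text,
                 if (j < length(passages)) passages[[j + 1]]$text)
      p$text <- refine_passage(p, title = title, neighbors = neigh,
                               client = client)
      cand <- discover_relations(p, current = rsel, client = client)
      rsel <- canonicalize_relations(rsel, setdiff(cand, rsel),
                                     client = client)
      if (length(rsel)) {
        prov[[length(prov) + 1L]] <- extract_triples(p, rsel, client = client)
      }
    }
  }
  prov <- if (length(prov)) do.call(rbind, prov) else
    data.frame(h = character(), r = character(), t = character(),
               doc_id = character(), passage_index = integer())
  evidence <- if (nrow(prov)) {
    counts <- table(paste(prov$h, prov$r, prov$t, sep = "\x1f"))
    stats::setNames(as.integer(counts), names(counts))
  } else stats::setNames(integer(), character())
  facts <- unique(prov[, c("h", "r", "t")])
  facts$s <- 1.0   # placeholder until assign_confidences() runs
  kg <- ukg(facts = facts, relations = rsel)
  list(kg = kg, relation_set = rsel, provenance = prov,
       evidence_counts = evidence)
}
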