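#' Prompt templates
#'
#' Templates are UTF-8 text files with `{placeholder}` markers (lowercase
#' names).  The package ships templates for every pipeline step under
#' `inst/templates`; rendering fails if a required placeholder is unbound
#' and refuses to emit text with residual markers.
#'
#' @param name template name, e.g. `"keyword_extraction"`.
#' @return a `prompt_template` object with fields `name`, `text` and
#'   `required` (placeholder names).
#' @export
prompt_template <- function(name) {
  reg <- template_registry()
  if (!name %in% names(reg))
    stop_mfh(paste0("unknown template: ", name), "gateway_error")
  path <- system.file("templates", paste0(name, ".txt"), package = "mfhrag")
  if (!nzchar(path))
    stop_mfh(paste0("template file missing for ", name), "gateway_error")
  text <- paste(readLines(path, encoding = "UTF-8", warn = FALSE),
                collapse = "\n")
  structure(list(name = name, text = text, required = reg[[name]]),
            class = "prompt_template")
}

template_registry <- function() {
  list(
    keyword_extraction     = "user_query",
    entity_linking         = c("keyword", "candidate_entities"),
    relation_paths         = c("existing_relations", "user_query",
                               "query_entities", "examples"),
    answer_generation      = c("user_query", "reasoning_paths",
                               "entity_attributes"),
    refine_passage         = c("title", "passage", "neighbor_passages"),
    discover_relations     = c("relation_definitions", "passage"),
    canonicalize_relations = c("existing_relations", "candidate_relations"),
    extract_triples        = c("relation_set", "passage"),
    food_attributes        = "passage",
    dish_attributes        = "passage"
  )
}

#' Render a prompt template
#'
#' @param template a [prompt_template()] object or template name.
#' @param bindings named list of placeholder values (coerced to character;
#'   vectors are collapsed with `", "`).
#' @return rendered prompt text.
#' @export
render_prompt <- function(template, bindings = list()) {
  if (is.character(template)) template <- prompt_template(template)
  missing <- setdiff(template$required, names(bindings))
  if (length(missing)) {
    stop_mfh(paste0("unbound placeholder(s) in template '", template$name,
                    "': ", paste(missing, collapse = ", ")),
             "gateway_render_error")
  }
  text <- template$text
  for (nm in names(bindings)) {
    val <- bindings[[nm]]
    if (!is.character(val) || length(val) != 1)
      val <- paste(as.character(unlist(val)), collapse = ", ")
    text <- gsub(paste0("{", nm, "}"), val, text, fixed = TRUE)
  }
  leftover <- regmatches(text, gregexpr("\\{[a-z_]+\\}", text))[[1]]
  if (length(leftover)) {
    stop_mfh(paste0("residual placeholder(s) after render: ",
                    paste(unique(leftover), collapse = ", ")),
             "gateway_render_error")
  }
  text
}

#' LLM clients
#'
#' All language-model access goes through a small client contract: a list
#' with a `complete(prompt, task, payload)` function returning response
#' text, a `name`, and configuration metadata.  Three clients ship with
#' the package:
#'
#' * `mock_llm_client()` — a deterministic, fully offline client.  Its
#'   responses are pure functions of the prompt content: keywords are the
#'   longest KG entity names occurring in the query, entity linking is
#'   exact normalized-name match, relation-path generation defers to
#'   breadth-first enumeration, passage refinement is the identity, and
#'   answer generation lists the terminal food/dish entities of the
#'   retrieved paths.  Extraction tasks consult a user-supplied `rules`
#'   table (task name -> function(payload) or static value) and return an
#'   empty result when no rule applies.
#' * `replay_client()` — replays a recorded transcript; an unknown prompt
#'   is a hard error naming the prompt hash, so silent drift is impossible.
#' * `recording_client()` — wraps another client and appends
#'   `{prompt_hash, prompt, response}` JSON-Lines records to a transcript
#'   file for later replay.
#'
#' @param kg optional [ukg] used by the mock's keyword/linking rules.
#' @param rules named list of mock extraction rules.
#' @return an object of class `llm_client`.
#' @export
mock_llm_client <- function(kg = NULL, rules = list()) {
  client <- new.env(parent = emptyenv())
  client$kg <- kg
  client$rules <- rules
  complete <- function(prompt, task = NULL, payload = list()) {
    mock_respond(client, prompt, task, payload)
  }
  structure(list(complete = complete, name = "mock", temperature = 0,
                 enumerate_paths = TRUE, env = client),
            class = "llm_client")
}

mock_respond <- function(client, prompt, task, payload) {
  if (!is.null(task) && !is.null(client$rules[[task]])) {
    rule <- client$rules[[task]]
    out <- if (is.function(rule)) rule(payload) else rule
    if (!is.character(out) || length(out) != 1)
      out <- as.character(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA))
    return(out)
  }
  switch(task %||% "unknown",
    keyword_extraction = {
      kws <- mock_keywords(payload$user_query %||% "", client$kg)
      as.character(jsonlite::toJSON(kws, digits = NA))
    },
    entity_linking = {
      kw <- normalize_entity_id(payload$keyword %||% "")
      cands <- payload$candidate_entities %||% character()
      hit <- cands[normalize_entity_id(cands) == kw]
      as.character(jsonlite::toJSON(
        if (length(hit)) hit[1] else "None", auto_unbox = FALSE, digits = NA))
    },
    relation_paths = "[]",  # retrieval delegates to enumeration for mock
    answer_generation = {
      foods <- payload$answer_entities %||% character()
      ans <- if (length(foods)) {
        paste0("Recommended foods based on the retrieved reasoning paths: ",
               paste(foods, collapse = ", "), ".")
      } else {
        "No dietary recommendation could be derived from the knowledge graph."
      }
      as.character(jsonlite::toJSON(list(answer = ans), auto_unbox = TRUE,
                                    digits = NA))
    },
    refine_passage = payload$passage %||% "",
    discover_relations = "[]",
    canonicalize_relations = {
      # default mock policy: keep all distinct new names
      cur <- payload$existing_relations %||% character()
      cand <- payload$candidate_relations %||% character()
      as.character(jsonlite::toJSON(unique(c(cur, cand)), digits = NA))
    },
    extract_triples = "[]",
    food_attributes = as.character(jsonlite::toJSON(
      list(name = payload$entity_name %||% ""), auto_unbox = TRUE, digits = NA)),
    dish_attributes = as.character(jsonlite::toJSON(
      list(name = payload$entity_name %||% ""), auto_unbox = TRUE, digits = NA)),
    "[]"
  )
}

# Longest non-overlapping KG entity names occurring verbatim in the query.
mock_keywords <- function(query, kg) {
  if (is.null(kg) || !nzchar(query)) return(character())
  names_ <- kg$entities$name[order(-nchar(kg$entities$name), kg$entities$name)]
  found <- character()
  remaining <- query
  for (nm in names_) {
    if (nzchar(nm) && grepl(nm, remaining, fixed = TRUE)) {
      found <- c(found, nm)
      remaining <- gsub(nm, " ", remaining, fixed = TRUE)
    }
  }
  found
}

#' @param transcript_path JSON-Lines transcript file.
#' @rdname mock_llm_client
#' @export
replay_client <- function(transcript_path) {
  if (!file.exists(transcript_path))
    stop_mfh(paste0("no such transcript: ", transcript_path), "gateway_error")
  lines <- readLines(transcript_path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  store <- new.env(parent = emptyenv())
  for (ln in lines) {
    rec <- jsonlite::fromJSON(ln)
    assign(rec$prompt_hash, rec, envir = store)
  }
  complete <- function(prompt, task = NULL, payload = list()) {
    h <- fnv1a32(prompt)
    if (!exists(h, envir = store, inherits = FALSE)) {
      stop_mfh(paste0("replay transcript has no record for prompt hash ", h),
               "gateway_replay_error")
    }
    rec <- get(h, envir = store)
    if (!identical(rec$prompt, prompt)) {
      stop_mfh(paste0("prompt hash collision or drift for hash ", h),
               "gateway_replay_error")
    }
    rec$response
  }
  structure(list(complete = complete, name = "replay", temperature = 0,
                 enumerate_paths = FALSE),
            class = "llm_client")
}

#' @param inner client to wrap.
#' @rdname mock_llm_client
#' @export
recording_client <- function(inner, transcript_path) {
  stopifnot(inherits(inner, "llm_client"))
  complete <- function(prompt, task = NULL, payload = list()) {
    response <- inner$complete(prompt, task, payload)
    rec <- jsonlite::toJSON(list(prompt_hash = fnv1a32(prompt),
                                 prompt = prompt, response = response),
                            auto_unbox = TRUE, digits = NA)
    cat(enc2utf8(as.character(rec)), "\n", sep = "",
        file = transcript_path, append = TRUE)
    response
  }
  structure(list(complete = complete,
                 name = paste0("recording(", inner$name, ")"),
                 temperature = inner$temperature,
                 enumerate_paths = isTRUE(inner$enumerate_paths)),
            class = "llm_client")
}

#' @export
print.llm_client <- function(x, ...) {
  cat(sprintf("<llm_client: %s, temperature %s>\n", x$name,
              format(x$temperature)))
  invisible(x)
}

#' Structured-output completion
#'
#' Sends a prompt and parses the response as JSON of an expected shape.
#' If the raw response fails to parse, one automatic repair is attempted
#' (strip markdown code fences and surrounding prose, keep the first JSON
#' array/object); a second failure raises a gateway error carrying the raw
#' response.  Silent repair beyond that is deliberately not attempted, so
#' extraction drift fails loudly.
#'
#' @param client an `llm_client`.
#' @param prompt prompt text.
#' @param shape `"list"` (JSON array) or `"record"` (JSON object).
#' @param task,payload passed through to the client (used by the mock).
#' @return parsed value: character vector or list for `"list"`, named
#'   list for `"record"`.
#' @export
complete_json <- function(client, prompt, shape = c("list", "record"),
                          task = NULL, payload = list()) {
  shape <- match.arg(shape)
  raw <- client$complete(prompt, task = task, payload = payload)
  parsed <- try_parse_json(raw, shape)
  if (is.null(parsed)) {
    parsed <- try_parse_json(repair_json_text(raw, shape), shape)
  }
  if (is.null(parsed)) {
    stop_mfh(paste0("unparseable LLM output for task '",
                    task %||% "?", "'"),
             "gateway_extraction_error", raw_response = raw)
  }
  parsed
}

try_parse_json <- function(text, shape) {
  if (is.null(text) || !nzchar(trimws(text))) return(NULL)
  val <- tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                  error = function(e) NULL)
  if (is.null(val)) return(NULL)
  if (shape == "list") {
    if (!is.list(val) && length(val) == 1) val <- list(val)
    if (!is.null(names(val)) && length(names(val))) return(NULL)
    return(val)
  }
  if (!is.list(val) || is.null(names(val))) return(NULL)
  val
}

repair_json_text <- function(text, shape) {
  if (is.null(text)) return("")
  text <- gsub("```[a-zA-Z]*", "", text)
  text <- gsub("```", "", text)
  open <- if (shape == "list") "\\[" else "\\{"
  close <- if (shape == "list") "\\]" else "\\}"
  m <- regmatches(text, regexpr(paste0(open, ".*", close), text))
  if (length(m)) m[1] else trimws(text)
}

#' Generate the final answer from retrieved paths and attributes
#'
#' Fills the answer-generation template with the user query, the retained
#' reasoning paths and the attribute records of the food/dish entities on
#' them, asks the client for a JSON object with an `"answer"` field and
#' returns that field.  The mock client produces a deterministic answer
#' listing the terminal food/dish entities of the top paths.
#'
#' @param query user query text.
#' @param top_paths list of scored reasoning paths (see
#'   [rank_and_filter_paths()]).
#' @param attributes named list of attribute records for entities on the
#'   paths (may be empty).
#' @param client an `llm_client`.
#' @return answer text.
#' @export
generate_answer <- function(query, top_paths, attributes = list(),
                            client = mock_llm_client()) {
  path_text <- vapply(top_paths, function(sp) format_reasoning_path(sp$path),
                      character(1))
  attr_text <- if (length(attributes)) {
    paste(vapply(attributes, function(a)
      as.character(jsonlite::toJSON(unclass(a), auto_unbox = TRUE, digits = NA)),
      character(1)), collapse = "\n")
  } else "(none)"
  prompt <- render_prompt("answer_generation", list(
    user_query = query,
    reasoning_paths = if (length(path_text)) paste(path_text, collapse = "\n")
                      else "(none)",
    entity_attributes = attr_text
  ))
  terminal <- unique(vapply(top_paths, function(sp)
    sp$path$entities[length(sp$path$entities)], character(1)))
  rec <- complete_json(client, prompt, shape = "record",
                       task = "answer_generation",
                       payload = list(user_query = query,
                                      answer_entities = terminal))
  as.character(rec$answer %||% "")
}
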