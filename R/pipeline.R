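#' Pipeline configuration
#'
#' One configuration object drives every command: file paths, retrieval
#' parameters, client and provider modes and the master seed from which
#' all per-module seeds are derived.  Values can come from a YAML file,
#' with direct arguments overriding file values.
#'
#' @param config_file optional YAML file of defaults.
#' @param ... overrides: `kg_path`, `attributes_path`, `transcript_path`,
#'   `out_path`, `k` (top paths, default 10), `d` (damping, default 0.8),
#'   `threshold` (completion, default 0.85), `top_n` (candidates per
#'   keyword, default 10), `cap` (completion candidates per head/relation,
#'   default 200), `max_len`, `client` ("mock", "replay"), `provider`
#'   ("hash"), `seed`, `n_queries`, `noise_fraction` (default 0).
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(config_file = NULL, ...) {
  cfg <- list(kg_path = NULL, attributes_path = NULL, transcript_path = NULL,
              out_path = NULL, k = 10, d = 0.8, threshold = 0.85,
              top_n = 10, cap = 200, max_len = 3, client = "mock",
              provider = "hash", seed = 7, n_queries = 50,
              noise_fraction = 0, query = NULL)
  if (!is.null(config_file)) {
    if (!file.exists(config_file))
      stop_mfh(paste0("no such config file: ", config_file), "config_error")
    file_cfg <- yaml::read_yaml(config_file)
    cfg[names(file_cfg)] <- file_cfg
  }
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  bad <- function(msg) stop_mfh(paste0("invalid configuration: ", msg),
                                "config_error")
  if (!is.numeric(cfg$k) || cfg$k < 1) bad("k must be >= 1")
  if (!is.numeric(cfg$d) || cfg$d <= 0 || cfg$d >= 1)
    bad("damping d must lie in (0, 1)")
  if (cfg$threshold <= 0 || cfg$threshold >= 1)
    bad("completion threshold must lie in (0, 1)")
  if (cfg$top_n < 1) bad("top_n must be >= 1")
  if (!cfg$client %in% c("mock", "replay")) bad("client must be mock or replay")
  if (!identical(cfg$provider, "hash")) bad("provider must be 'hash'")
  structure(cfg, class = "pipeline_config")
}

#' Run a pipeline command
#'
#' Dispatches the subcommands tying the modules together:
#'
#' * `simulate` — generate a synthetic KG and gold queries; writes the
#'   quadruple file to `kg_path` and queries (JSON-Lines) to `out_path`.
#' * `assign-confidence` — fit the stand-in scorer on the KG at
#'   `kg_path` and rewrite its confidences.
#' * `complete` — threshold-based completion of the KG at `kg_path`.
#' * `retrieve` — run the query pipeline for `query` against `kg_path`;
#'   writes the context as JSON when `out_path` is set.
#' * `answer` — retrieve and generate the final answer text.
#' * `evaluate` — run the benchmark over queries (JSON-Lines produced by
#'   `simulate`); writes a JSON report when `out_path` is set.
#'
#' @param command one of the subcommand names.
#' @param config a [pipeline_config()].
#' @param verbose log progress to stderr.
#' @return the command's artifact (graph, context, report, ...),
#'   invisibly for file-writing commands.
#' @export
run_command <- function(command, config = pipeline_config(),
                        verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  log_ <- function(...) if (verbose) message("[mfhrag] ", sprintf(...))
  cmds <- c("simulate", "assign-confidence", "complete", "retrieve",
            "answer", "evaluate")
  if (!command %in% cmds) {
    stop_mfh(paste0("unknown command '", command, "'; expected one of: ",
                    paste(cmds, collapse = ", ")), "config_error")
  }
  need_kg <- function() {
    if (is.null(config$kg_path) || !file.exists(config$kg_path))
      stop_mfh("command needs an existing kg_path", "config_error")
    load_quadruples(config$kg_path)
  }
  client_for <- function(kg) {
    if (config$client == "replay") {
      if (is.null(config$transcript_path))
        stop_mfh("replay client needs transcript_path", "config_error")
      replay_client(config$transcript_path)
    } else mock_llm_client(kg)
  }

  switch(command,
    "simulate" = {
      sim <- generate_kg(synthetic_spec(noise_fraction = config$noise_fraction,
                                        seed = config$seed))
      queries <- generate_queries(sim, n = config$n_queries,
                                  seed = config$seed)
      if (!is.null(config$kg_path)) {
        save_quadruples(sim$kg, config$kg_path)
        log_("wrote %d facts to %s", nrow(sim$kg$facts), config$kg_path)
      }
      if (!is.null(config$out_path)) {
        lines <- vapply(queries, function(q)
          as.character(jsonlite::toJSON(unclass(q[c("id", "text",
                                                    "query_entities",
                                                    "gold_answers")]),
                                        auto_unbox = FALSE, digits = NA)),
          character(1))
        writeLines(enc2utf8(lines), config$out_path, useBytes = TRUE)
        log_("wrote %d queries to %s", length(queries), config$out_path)
      }
      invisible(list(sim = sim, queries = queries))
    },
    "assign-confidence" = {
      kg <- need_kg()
      table <- fit_confidence_model(kg, seed = config$seed)
      kg2 <- assign_confidences(kg, table)
      if (!is.null(config$out_path)) save_quadruples(kg2, config$out_path)
      log_("re-assigned %d confidences", nrow(kg2$facts))
      invisible(kg2)
    },
    "complete" = {
      kg <- need_kg()
      table <- fit_confidence_model(kg, seed = config$seed)
      kg2 <- complete_graph(kg, table, threshold = config$threshold,
                            cap = config$cap)
      log_("added %d facts at threshold %g", nrow(attr(kg2, "added")),
           config$threshold)
      if (!is.null(config$out_path)) save_quadruples(kg2, config$out_path)
      invisible(kg2)
    },
    "retrieve" = {
      kg <- need_kg()
      if (is.null(config$query)) stop_mfh("retrieve needs a query",
                                          "config_error")
      ctx <- retrieve(config$query, kg, client = client_for(kg),
                      k = config$k, d = config$d, top_n = config$top_n,
                      max_len = config$max_len)
      if (!is.null(config$out_path)) {
        jsonlite::write_json(query_context_json(ctx), config$out_path,
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
      }
      ctx
    },
    "answer" = {
      kg <- need_kg()
      if (is.null(config$query)) stop_mfh("answer needs a query",
                                          "config_error")
      client <- client_for(kg)
      attrs <- if (!is.null(config$attributes_path))
        load_attributes(config$attributes_path) else NULL
      ctx <- retrieve(config$query, kg, client = client, k = config$k,
                      d = config$d, top_n = config$top_n,
                      max_len = config$max_len, attributes = attrs)
      generate_answer(config$query, ctx$reasoning_paths, ctx$attributes,
                      client)
    },
    "evaluate" = {
      kg <- need_kg()
      if (is.null(config$out_path) && verbose) log_("no out_path; report returned only")
      queries <- read_queries_jsonl(config[["queries_path"]] %||%
                                      config$out_path)
      bench <- run_benchmark(kg, queries, k = config$k, d = config$d,
                             client = client_for(kg))
      if (!is.null(config[["report_path"]])) {
        jsonlite::write_json(list(summary = bench$summary,
                                  records = bench$records),
                             config[["report_path"]], digits = NA,
                             dataframe = "rows")
      }
      bench
    })
}

query_context_json <- function(ctx) {
  list(
    query_text = ctx$query_text,
    keywords = ctx$keywords,
    linked_entities = ctx$linked_entities,
    relation_paths = ctx$relation_paths,
    answerable = ctx$answerable,
    reasoning_paths = lapply(ctx$reasoning_paths, function(sp)
      list(score = sp$score, entities = sp$path$entities,
           relations = sp$path$steps$r, confidences = sp$path$steps$s))
  )
}

read_queries_jsonl <- function(path) {
  if (is.null(path) || !file.exists(path))
    stop_mfh("evaluate needs queries_path pointing at a JSON-Lines query file",
             "config_error")
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    rec <- jsonlite::fromJSON(ln)
    structure(list(id = as.character(rec$id), text = as.character(rec$text),
                   query_entities = as.character(rec$query_entities),
                   gold_answers = as.character(rec$gold_answers),
                   gold_paths = NULL),
              class = "gold_query")
  })
}
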