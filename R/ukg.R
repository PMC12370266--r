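#' Uncertain knowledge graphs of quadruple facts
#'
#' An uncertain knowledge graph (UKG) stores facts as quadruples
#' `(h, r, t, s)`: a head entity, a relation, a tail entity and a
#' confidence score `s` in `[0, 1]` reflecting how likely the triple
#' `(h, r, t)` is to hold.  The graph `G = (E, R, F)` carries a typed
#' entity table `E` (symptom, constitution, food, dish, factor, effect or
#' other), a relation set `R` and the fact set `F`, together with
#' adjacency indexes by head, by (head, relation) and by tail.
#'
#' @param entities data frame with columns `id`, `name`, `etype` and
#'   optionally `attributes_ref`, or `NULL` to create entities from the
#'   fact endpoints with type `"other"`.
#' @param relations character vector of relation names; defaults to the
#'   distinct relations appearing in `facts`.
#' @param facts data frame with columns `h`, `r`, `t` (character) and `s`
#'   (numeric confidence in `[0, 1]`).  Duplicate `(h, r, t)` rows are
#'   merged by [merge_duplicate_facts()].
#' @return an object of class `ukg` with components `entities`,
#'   `relations`, `facts`, `out_index` (entity id -> fact rows),
#'   `out_index_hr` (head/relation -> fact rows) and `in_index`
#'   (entity id -> fact rows).
#' @examples
#' kg <- ukg(facts = data.frame(
#'   h = "Insomnia and Vivid Dreams", r = "Related Constitution",
#'   t = "Yin-Deficient Constitution", s = 0.87))
#' kg
#' @export
ukg <- function(facts = NULL, entities = NULL, relations = NULL) {
  facts <- normalize_facts(facts)
  if (nrow(facts)) facts <- merge_duplicate_facts(facts)

  if (is.null(entities)) {
    ids <- unique(c(facts$h, facts$t))
    entities <- data.frame(
      id = ids, name = ids, etype = rep("other", length(ids)),
      attributes_ref = rep(NA_character_, length(ids)),
      stringsAsFactors = FALSE
    )
  } else {
    entities <- as.data.frame(entities, stringsAsFactors = FALSE)
    if (!all(c("id", "name", "etype") %in% names(entities))) {
      if (!"id" %in% names(entities))
        stop_mfh("entity table must have an 'id' column", "ukg_validation_error")
      if (!"name" %in% names(entities)) entities$name <- entities$id
      if (!"etype" %in% names(entities)) entities$etype <- "other"
    }
    if (!"attributes_ref" %in% names(entities))
      entities$attributes_ref <- NA_character_
    entities$id <- normalize_entity_id(entities$id)
    # auto-create endpoints that the entity table does not list
    missing <- setdiff(unique(c(facts$h, facts$t)), entities$id)
    if (length(missing)) {
      entities <- rbind(entities[, c("id", "name", "etype", "attributes_ref")],
        data.frame(id = missing, name = missing, etype = "other",
                   attributes_ref = NA_character_, stringsAsFactors = FALSE))
    }
  }
  validate_entities(entities)
  relations <- unique(c(as.character(relations %||% character()), facts$r))

  bad_rel <- setdiff(facts$r, relations)
  if (length(bad_rel)) {
    stop_mfh(paste0("facts use relations outside the relation set: ",
                    paste(bad_rel, collapse = ", ")), "ukg_validation_error")
  }

  g <- structure(
    list(entities = entities, relations = relations, facts = facts),
    class = "ukg"
  )
  rebuild_indexes(g)
}

normalize_facts <- function(facts) {
  if (is.null(facts) || NROW(facts) == 0) {
    return(data.frame(h = character(), r = character(), t = character(),
                      s = numeric(), stringsAsFactors = FALSE))
  }
  facts <- as.data.frame(facts, stringsAsFactors = FALSE)
  need <- c("h", "r", "t", "s")
  if (!all(need %in% names(facts)))
    stop_mfh("facts need columns h, r, t, s", "ukg_validation_error")
  facts <- facts[, need]
  facts$h <- normalize_entity_id(facts$h)
  facts$t <- normalize_entity_id(facts$t)
  facts$r <- trimws(as.character(facts$r))
  facts$s <- as.numeric(facts$s)
  if (any(!nzchar(facts$h)) || any(!nzchar(facts$t)))
    stop_mfh("fact endpoints must be non-empty", "ukg_validation_error")
  if (any(!is.finite(facts$s)) || any(facts$s < 0) || any(facts$s > 1))
    stop_mfh("confidence scores must lie in [0, 1]", "ukg_validation_error")
  rownames(facts) <- NULL
  facts
}

validate_entities <- function(entities) {
  if (any(!nzchar(entities$id)))
    stop_mfh("entity ids must be non-empty", "ukg_validation_error")
  if (anyDuplicated(entities$id))
    stop_mfh("entity ids must be unique", "ukg_validation_error")
  ok <- entities$etype %in% entity_types()
  if (!all(ok)) {
    stop_mfh(paste0("unknown entity types: ",
                    paste(unique(entities$etype[!ok]), collapse = ", ")),
             "ukg_validation_error")
  }
  invisible(entities)
}

#' @rdname ukg
#' @export
entity_types <- function() {
  c("symptom", "constitution", "food", "dish", "factor", "effect", "other")
}

rebuild_indexes <- function(g) {
  n <- nrow(g$facts)
  idx <- seq_len(n)
  g$out_index <- if (n) split(idx, g$facts$h) else list()
  g$out_index_hr <- if (n) split(idx, paste0(g$facts$h, "\x1f", g$facts$r)) else list()
  g$in_index <- if (n) split(idx, g$facts$t) else list()
  g
}

# Fact rows going out of `h` (optionally restricted to relation `r`).
facts_from <- function(kg, h, r = NULL) {
  rows <- if (is.null(r)) kg$out_index[[h]] else kg$out_index_hr[[paste0(h, "\x1f", r)]]
  kg$facts[rows %||% integer(), , drop = FALSE]
}

facts_into <- function(kg, t) {
  kg$facts[kg$in_index[[t]] %||% integer(), , drop = FALSE]
}

#' Merge duplicate facts by maximum confidence
#'
#' Collapses rows sharing `(h, r, t)` to a single fact whose confidence is
#' the maximum of the duplicates' confidences (keep the strongest
#' evidence).  Merge events are reported via a `"merged"` attribute giving
#' the number of rows collapsed.
#'
#' @param facts data frame of quadruples (`h`, `r`, `t`, `s`).
#' @return data frame with one row per `(h, r, t)`, original first-seen
#'   order preserved.
#' @export
merge_duplicate_facts <- function(facts) {
  facts <- normalize_facts(facts)
  if (!nrow(facts)) return(facts)
  key <- paste(facts$h, facts$r, facts$t, sep = "\x1f")
  if (!anyDuplicated(key)) {
    attr(facts, "merged") <- 0L
    return(facts)
  }
  smax <- tapply(facts$s, key, max)
  keep <- !duplicated(key)
  out <- facts[keep, , drop = FALSE]
  out$s <- as.numeric(smax[key[keep]])
  rownames(out) <- NULL
  attr(out, "merged") <- as.integer(nrow(facts) - nrow(out))
  out
}

#' One-hop neighborhood subgraph
#'
#' Extracts the subgraph spanned by a set of seed entities and their
#' one-hop neighbors.  Neighborhood membership treats edges as undirected
#' (a one-hop neighbor may be reached along or against an edge) while the
#' retained facts keep their direction.  Every fact with at least one
#' endpoint in `seeds` is retained.
#'
#' @param kg a [ukg] object.
#' @param seeds character vector of entity ids; must all exist in `kg`.
#' @return a [ukg] containing the seeds, their neighbors and the incident
#'   facts.
#' @export
one_hop_subgraph <- function(kg, seeds) {
  stopifnot(inherits(kg, "ukg"))
  seeds <- unique(normalize_entity_id(seeds))
  unknown <- setdiff(seeds, kg$entities$id)
  if (length(unknown)) {
    stop_mfh(paste0("unknown seed entities: ", paste(unknown, collapse = ", ")),
             "ukg_key_error")
  }
  keep <- kg$facts$h %in% seeds | kg$facts$t %in% seeds
  facts <- kg$facts[keep, , drop = FALSE]
  ids <- unique(c(seeds, facts$h, facts$t))
  ukg(facts = facts,
      entities = kg$entities[kg$entities$id %in% ids, , drop = FALSE],
      relations = kg$relations)
}

#' @export
print.ukg <- function(x, ...) {
  cat(sprintf(
    "Uncertain knowledge graph: %d entities, %d relations, %d facts\n",
    nrow(x$entities), length(x$relations), nrow(x$facts)))
  if (nrow(x$facts)) {
    cat(sprintf("  confidence range [%.3f, %.3f], mean %.3f\n",
                min(x$facts$s), max(x$facts$s), mean(x$facts$s)))
  }
  tab <- table(x$entities$etype)
  cat("  entity types:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.ukg <- function(object, ...) {
  rel <- if (nrow(object$facts)) sort(table(object$facts$r), decreasing = TRUE)
         else table(character())
  structure(list(
    n_entities = nrow(object$entities),
    n_relations = length(object$relations),
    n_facts = nrow(object$facts),
    facts_per_relation = rel,
    confidence = if (nrow(object$facts)) summary(object$facts$s) else NULL
  ), class = "summary.ukg")
}

#' @export
print.summary.ukg <- function(x, ...) {
  cat(sprintf("UKG with %d entities, %d relations, %d facts\n",
              x$n_entities, x$n_relations, x$n_facts))
  if (!is.null(x$confidence)) {
    cat("Confidence scores:\n"); print(x$confidence)
    cat("Facts per relation (top 10):\n")
    print(utils::head(x$facts_per_relation, 10))
  }
  invisible(x)
}

# Internal consistency check used by tests and after bulk mutations.
ukg_check <- function(kg) {
  stopifnot(inherits(kg, "ukg"))
  f <- kg$facts
  stopifnot(
    all(f$h %in% kg$entities$id), all(f$t %in% kg$entities$id),
    all(f$r %in% kg$relations),
    all(f$s >= 0 & f$s <= 1),
    !anyDuplicated(paste(f$h, f$r, f$t, sep = "\x1f"))
  )
  for (i in seq_len(nrow(f))) {
    stopifnot(
      i %in% kg$out_index[[f$h[i]]],
      i %in% kg$out_index_hr[[paste0(f$h[i], "\x1f", f$r[i])]],
      i %in% kg$in_index[[f$t[i]]]
    )
  }
  invisible(TRUE)
}
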