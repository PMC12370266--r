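#' Read and write quadruple files
#'
#' Quadruple files come in two dialects.  The TSV dialect has four
#' tab-separated columns `head<TAB>relation<TAB>tail<TAB>confidence`,
#' UTF-8, no header.  The JSON-Lines dialect has one object per line with
#' keys `h`, `r`, `t`, `s`.  Confidences are written with six decimal
#' places so that a save/load round trip reproduces the fact set exactly.
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"jsonl"`; for reading, `"auto"` picks by
#'   file extension (`.jsonl`/`.json` are JSON-Lines, anything else TSV).
#' @return `load_quadruples()` returns a [ukg]; `save_quadruples()`
#'   returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' kg <- ukg(facts = data.frame(h = "a", r = "rel", t = "b", s = 0.5))
#' save_quadruples(kg, f)
#' load_quadruples(f)
#' @export
load_quadruples <- function(path, dialect = c("auto", "tsv", "jsonl")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop_mfh(paste0("no such file: ", path), "ukg_io_error")
  if (dialect == "auto") {
    dialect <- if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl" else "tsv"
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(ukg())

  if (dialect == "tsv") {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 4L)
    if (length(bad)) {
      stop_mfh(sprintf("malformed TSV row at line %d: expected 4 fields, got %d",
                       bad[1], length(parts[[bad[1]]])), "ukg_parse_error")
    }
    m <- do.call(rbind, parts)
    s <- suppressWarnings(as.numeric(m[, 4]))
    if (anyNA(s)) {
      stop_mfh(sprintf("unparseable confidence at line %d: '%s'",
                       which(is.na(s))[1], m[which(is.na(s))[1], 4]),
               "ukg_parse_error")
    }
    facts <- data.frame(h = m[, 1], r = m[, 2], t = m[, 3], s = s,
                        stringsAsFactors = FALSE)
  } else {
    recs <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) e)
      if (inherits(rec, "error") || !all(c("h", "r", "t", "s") %in% names(rec))) {
        stop_mfh(sprintf("malformed JSON-Lines record at line %d", i),
                 "ukg_parse_error")
      }
      recs[[i]] <- data.frame(h = as.character(rec$h), r = as.character(rec$r),
                              t = as.character(rec$t), s = as.numeric(rec$s),
                              stringsAsFactors = FALSE)
    }
    facts <- do.call(rbind, recs)
  }
  bad_s <- which(facts$s < 0 | facts$s > 1 | !is.finite(facts$s))
  if (length(bad_s)) {
    stop_mfh(sprintf("confidence out of [0, 1] at line %d: %s",
                     bad_s[1], format(facts$s[bad_s[1]])), "ukg_validation_error")
  }
  ukg(facts = facts)
}

#' @param kg a [ukg] object.
#' @rdname load_quadruples
#' @export
save_quadruples <- function(kg, path, dialect = c("auto", "tsv", "jsonl")) {
  stopifnot(inherits(kg, "ukg"))
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl" else "tsv"
  }
  f <- kg$facts
  lines <- if (!nrow(f)) {
    character()
  } else if (dialect == "tsv") {
    sprintf("%s\t%s\t%s\t%.6f", f$h, f$r, f$t, f$s)
  } else {
    vapply(seq_len(nrow(f)), function(i) {
      jsonlite::toJSON(list(h = f$h[i], r = f$r[i], t = f$t[i],
                            s = round(f$s[i], 6)),
                       auto_unbox = TRUE, digits = NA)
    }, character(1))
  }
  con <- tryCatch(file(path, open = "wb"), error = function(e)
    stop_mfh(paste0("cannot write ", path, ": ", conditionMessage(e)),
             "ukg_io_error"))
  on.exit(close(con))
  if (length(lines)) writeLines(enc2utf8(lines), con, useBytes = TRUE)
  invisible(path)
}

#' Read and write entity attribute stores
#'
#' Food and dish attribute records travel as JSON-Lines, one object per
#' entity keyed by `name`.  Food records carry `primary_effects`,
#' `consumption_methods`, `indications` and `contraindications`; dish
#' records carry `ingredients`, `cooking_method` and `dietary_benefits`.
#'
#' @param path file path of the JSON-Lines attribute store.
#' @return named list of [food_attributes()] / [dish_attributes()]
#'   records, keyed by normalized name.
#' @export
load_attributes <- function(path) {
  if (!file.exists(path))
    stop_mfh(paste0("no such file: ", path), "ukg_io_error")
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e)
      stop_mfh(sprintf("malformed attribute record at line %d", i),
               "ukg_parse_error"))
    rec <- if (identical(rec$kind, "dish")) {
      dish_attributes(rec$name, rec$ingredients, rec$cooking_method %||% "",
                      rec$dietary_benefits)
    } else {
      food_attributes(rec$name, rec$primary_effects, rec$consumption_methods,
                      rec$indications, rec$contraindications)
    }
    out[[normalize_entity_id(rec$name)]] <- rec
  }
  out
}

#' @param attrs named list of attribute records.
#' @rdname load_attributes
#' @export
save_attributes <- function(attrs, path) {
  lines <- vapply(attrs, function(a) {
    a$kind <- if (inherits(a, "dish_attributes")) "dish" else "food"
    as.character(jsonlite::toJSON(unclass(a), auto_unbox = TRUE, digits = NA))
  }, character(1))
  writeLines(enc2utf8(unname(lines)), path, useBytes = TRUE)
  invisible(path)
}

#' Attribute records for food and dish entities
#'
#' @param name entity display name (non-empty).
#' @param primary_effects,consumption_methods,indications,contraindications
#'   character vectors describing a food entity.
#' @param ingredients,cooking_method,dietary_benefits fields of a dish
#'   entity.
#' @return a list of class `food_attributes` or `dish_attributes`.
#' @export
food_attributes <- function(name, primary_effects = character(),
                            consumption_methods = character(),
                            indications = character(),
                            contraindications = character()) {
  if (!nzchar(trimws(name))) stop_mfh("food name must be non-empty",
                                      "ukg_validation_error")
  structure(list(
    name = as.character(name),
    primary_effects = as.character(primary_effects %||% character()),
    consumption_methods = as.character(consumption_methods %||% character()),
    indications = as.character(indications %||% character()),
    contraindications = as.character(contraindications %||% character())
  ), class = "food_attributes")
}

#' @rdname food_attributes
#' @export
dish_attributes <- function(name, ingredients = character(),
                            cooking_method = "",
                            dietary_benefits = character()) {
  if (!nzchar(trimws(name))) stop_mfh("dish name must be non-empty",
                                      "ukg_validation_error")
  structure(list(
    name = as.character(name),
    ingredients = as.character(ingredients %||% character()),
    cooking_method = as.character(cooking_method %||% ""),
    dietary_benefits = as.character(dietary_benefits %||% character())
  ), class = "dish_attributes")
}
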