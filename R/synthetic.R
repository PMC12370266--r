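#' Specification of a synthetic medicine-food-homology knowledge graph
#'
#' The generator emulates the structure of an MFH knowledge graph at desk
#' scale: typed entities (symptoms, TCM constitutions, foods, dishes,
#' influencing factors), a 22-relation schema including "Related
#' Constitution", "Suitable Food" and "Influencing Factor", and planted
#' two-hop gold answer paths symptom -> constitution -> food whose
#' confidences are drawn from a high-confidence Beta distribution.
#' Distractor two-hop paths run through the factor layer (symptom ->
#' factor -> food) at low confidence, so they compete in ranking without
#' borrowing gold-strength edges, and each gold food carries "Relieves
#' Symptom" edges back to its constitution's symptoms, closing the
#' triangle that makes held-out facts inferable by the embedding model.
#' Optional noise facts are typed at random across the schema.  Defaults
#' give 500 entities and about 2,000 facts with every query answerable
#' through the planted paths.
#'
#' @param n_symptoms,n_constitutions,n_foods,n_dishes,n_factors entity
#'   counts per type.  The nine constitutions mirror the classical TCM
#'   constitution typology.
#' @param gold_foods_per_constitution gold "Suitable Food" edges per
#'   constitution.
#' @param distractor_paths_per_symptom planted low-confidence two-hop
#'   paths per symptom.
#' @param noise_fraction fraction of the final fact set that is random
#'   typed noise (0 disables noise).
#' @param gold_shape,distractor_shape Beta shape pairs for gold and
#'   distractor confidences; defaults Beta(9, 1) and Beta(2, 4) separate
#'   the signal while leaving overlap to exercise ranking.
#' @param noise_range uniform range for noise confidences.
#' @param seed RNG seed; generation is deterministic per seed.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_symptoms = 200, n_constitutions = 9,
                           n_foods = 180, n_dishes = 60, n_factors = 51,
                           gold_foods_per_constitution = 8,
                           distractor_paths_per_symptom = 3,
                           noise_fraction = 0,
                           gold_shape = c(9, 1),
                           distractor_shape = c(2, 4),
                           noise_range = c(0.05, 0.6),
                           seed = 7) {
  spec <- list(n_symptoms = n_symptoms, n_constitutions = n_constitutions,
               n_foods = n_foods, n_dishes = n_dishes, n_factors = n_factors,
               gold_foods_per_constitution = gold_foods_per_constitution,
               distractor_paths_per_symptom = distractor_paths_per_symptom,
               noise_fraction = noise_fraction, gold_shape = gold_shape,
               distractor_shape = distractor_shape, noise_range = noise_range,
               seed = seed)
  counts <- c(n_symptoms, n_constitutions, n_foods)
  if (any(counts < 1)) {
    stop_mfh("spec needs at least one symptom, constitution and food",
             "synthetic_spec_error")
  }
  stopifnot(n_dishes >= 0, n_factors >= 0,
            all(gold_shape > 0), all(distractor_shape > 0),
            noise_fraction >= 0, noise_fraction < 1,
            noise_range[1] >= 0, noise_range[2] <= 1,
            noise_range[1] <= noise_range[2])
  structure(spec, class = "synthetic_spec")
}

#' The default MFH relation schema
#'
#' Twenty-two relation names with head/tail type constraints, covering
#' the symptom/constitution/food/dish/factor topology.
#'
#' @return data frame with columns `relation`, `head_type`, `tail_type`.
#' @export
mfh_relation_schema <- function() {
  schema <- rbind(
    c("Related Constitution", "symptom", "constitution"),
    c("Suitable Food", "constitution", "food"),
    c("Influencing Factor", "symptom", "factor"),
    c("Suitable Dish", "constitution", "dish"),
    c("Avoid Food", "constitution", "food"),
    c("Avoid Dish", "constitution", "dish"),
    c("Relieves Symptom", "food", "symptom"),
    c("Aggravates Symptom", "food", "symptom"),
    c("Related Symptom", "symptom", "symptom"),
    c("Contraindicated Constitution", "food", "constitution"),
    c("Alleviating Factor", "symptom", "factor"),
    c("Aggravating Factor", "symptom", "factor"),
    c("Factor Suitable Food", "factor", "food"),
    c("Common Ingredient", "dish", "food"),
    c("Derived Dish", "food", "dish"),
    c("Has Effect", "food", "factor"),
    c("Seasonal Suitability", "food", "factor"),
    c("Has Flavor", "food", "factor"),
    c("Has Nature", "food", "factor"),
    c("Meridian Tropism", "food", "factor"),
    c("Dietary Caution", "constitution", "factor"),
    c("Therapeutic Principle", "constitution", "factor")
  )
  data.frame(relation = schema[, 1], head_type = schema[, 2],
             tail_type = schema[, 3], stringsAsFactors = FALSE)
}

#' Generate a synthetic uncertain MFH knowledge graph
#'
#' Plants gold two-hop paths (symptom -Related Constitution-> constitution
#' -Suitable Food-> food) with confidences from the gold Beta
#' distribution, factor-layer distractor paths from the low-confidence
#' Beta, a gold relief channel (food -Relieves Symptom-> symptom), and
#' typed random noise facts.  A planted-truth ledger records every
#' fact's true confidence and kind, and every gold path with its
#' terminus.
#'
#' @param spec a [synthetic_spec()].
#' @return list of class `synthetic_mfh_kg` with components `kg` (a
#'   [ukg]), `ledger` (data frame `h`, `r`, `t`, `s_true`, `kind`,
#'   `path_id`), `gold_paths` (data frame `path_id`, `symptom`,
#'   `constitution`, `food`, `s1`, `s2`) and `spec`.
#' @export
generate_kg <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(derive_seed(spec$seed, "generate-kg"), generate_kg_impl(spec))
}

generate_kg_impl <- function(spec) {
  pad <- function(prefix, n) sprintf("%s %03d", prefix, seq_len(n))
  symptoms <- pad("Symptom", spec$n_symptoms)
  constitutions <- pad("Constitution", spec$n_constitutions)
  foods <- pad("Food", spec$n_foods)
  dishes <- if (spec$n_dishes) pad("Dish", spec$n_dishes) else character()
  factors <- if (spec$n_factors) pad("Factor", spec$n_factors) else character()

  entities <- data.frame(
    id = c(symptoms, constitutions, foods, dishes, factors),
    name = c(symptoms, constitutions, foods, dishes, factors),
    etype = c(rep("symptom", length(symptoms)),
              rep("constitution", length(constitutions)),
              rep("food", length(foods)),
              rep("dish", length(dishes)),
              rep("factor", length(factors))),
    stringsAsFactors = FALSE)

  rbeta2 <- function(n, shape) stats::rbeta(n, shape[1], shape[2])
  clamp <- function(s) pmin(pmax(s, 0.001), 0.999)

  # gold skeleton: every constitution gets a gold food set; every symptom
  # links to one gold constitution
  gold_food_sets <- lapply(seq_along(constitutions), function(i)
    sample(foods, min(spec$gold_foods_per_constitution, length(foods))))
  sym_const <- sample(seq_along(constitutions), length(symptoms),
                      replace = TRUE)

  hop1 <- data.frame(h = symptoms, r = "Related Constitution",
                     t = constitutions[sym_const],
                     s_true = clamp(rbeta2(length(symptoms), spec$gold_shape)),
                     kind = "gold", stringsAsFactors = FALSE)
  hop2 <- do.call(rbind, lapply(seq_along(constitutions), function(i) {
    data.frame(h = constitutions[i], r = "Suitable Food",
               t = gold_food_sets[[i]],
               s_true = clamp(rbeta2(length(gold_food_sets[[i]]),
                                     spec$gold_shape)),
               kind = "gold", stringsAsFactors = FALSE)
  }))

  # relief channel: each gold food also relieves a couple of the symptoms
  # of its constitution, closing the symptom/constitution/food triangle
  relief <- do.call(rbind, lapply(seq_along(constitutions), function(i) {
    syms <- symptoms[sym_const == i]
    if (!length(syms)) return(NULL)
    do.call(rbind, lapply(gold_food_sets[[i]], function(fd) {
      tgt <- if (length(syms) <= 8) syms else sample(syms, 8)
      data.frame(h = fd, r = "Relieves Symptom", t = tgt,
                 s_true = clamp(rbeta2(length(tgt), spec$gold_shape)),
                 kind = "gold", stringsAsFactors = FALSE)
    }))
  }))

  # distractor paths run through the factor layer (symptom -Influencing
  # Factor-> factor -Factor Suitable Food-> food), both hops low
  # confidence: they compete in ranking without interleaving with the
  # gold constitution channel
  distr <- NULL
  if (spec$distractor_paths_per_symptom > 0 && length(factors)) {
    k <- spec$distractor_paths_per_symptom
    dsym <- rep(symptoms, each = k)
    dfac <- sample(factors, length(dsym), replace = TRUE)
    dfood <- sample(foods, length(dsym), replace = TRUE)
    d1 <- data.frame(h = dsym, r = "Influencing Factor", t = dfac,
                     s_true = clamp(rbeta2(length(dsym),
                                           spec$distractor_shape)),
                     kind = "distractor", stringsAsFactors = FALSE)
    d2 <- data.frame(h = dfac, r = "Factor Suitable Food", t = dfood,
                     s_true = clamp(rbeta2(length(dsym),
                                           spec$distractor_shape)),
                     kind = "distractor", stringsAsFactors = FALSE)
    distr <- rbind(d1, d2)
  }

  planted <- rbind(hop1, hop2, relief, distr)
  key <- paste(planted$h, planted$r, planted$t, sep = "\x1f")
  planted <- planted[!duplicated(key), , drop = FALSE]   # gold rows first win

  # typed noise facts across the full relation schema
  schema <- mfh_relation_schema()
  pools <- list(symptom = symptoms, constitution = constitutions,
                food = foods, dish = dishes, factor = factors)
  noise <- NULL
  if (spec$noise_fraction > 0) {
    n_noise <- round(spec$noise_fraction * nrow(planted) /
                       (1 - spec$noise_fraction))
    usable <- schema[lengths(pools[schema$head_type]) > 0 &
                       lengths(pools[schema$tail_type]) > 0, , drop = FALSE]
    ri <- sample(nrow(usable), n_noise, replace = TRUE)
    nh <- vapply(ri, function(i) sample(pools[[usable$head_type[i]]], 1),
                 character(1))
    nt <- vapply(ri, function(i) sample(pools[[usable$tail_type[i]]], 1),
                 character(1))
    noise <- data.frame(h = nh, r = usable$relation[ri], t = nt,
                        s_true = stats::runif(n_noise, spec$noise_range[1],
                                              spec$noise_range[2]),
                        kind = "noise", stringsAsFactors = FALSE)
    noise <- noise[noise$h != noise$t, , drop = FALSE]
    nkey <- paste(noise$h, noise$r, noise$t, sep = "\x1f")
    noise <- noise[!duplicated(nkey) & !(nkey %in% key), , drop = FALSE]
  }

  ledger <- rbind(planted, noise)
  ledger$path_id <- NA_integer_
  rownames(ledger) <- NULL

  # gold path table: one row per (symptom, gold constitution, gold food)
  gp <- do.call(rbind, lapply(seq_along(symptoms), function(i) {
    ci <- sym_const[i]
    data.frame(symptom = symptoms[i], constitution = constitutions[ci],
               food = gold_food_sets[[ci]], stringsAsFactors = FALSE)
  }))
  gp$path_id <- seq_len(nrow(gp))
  s1 <- stats::setNames(hop1$s_true, hop1$h)
  s2key <- paste(hop2$h, hop2$t, sep = "\x1f")
  s2 <- stats::setNames(hop2$s_true, s2key)
  gp$s1 <- as.numeric(s1[gp$symptom])
  gp$s2 <- as.numeric(s2[paste(gp$constitution, gp$food, sep = "\x1f")])

  kg <- ukg(facts = data.frame(h = ledger$h, r = ledger$r, t = ledger$t,
                               s = ledger$s_true, stringsAsFactors = FALSE),
            entities = entities,
            relations = schema$relation)
  structure(list(kg = kg, ledger = ledger, gold_paths = gp, spec = spec),
            class = "synthetic_mfh_kg")
}

#' @export
print.synthetic_mfh_kg <- function(x, ...) {
  cat("Synthetic MFH knowledge graph (seed", format(x$spec$seed), ")\n")
  print(x$kg)
  cat(sprintf("  planted: %d gold, %d distractor, %d noise facts; %d gold paths\n",
              sum(x$ledger$kind == "gold"),
              sum(x$ledger$kind == "distractor"),
              sum(x$ledger$kind == "noise"), nrow(x$gold_paths)))
  invisible(x)
}

#' Generate gold-labeled queries over a synthetic graph
#'
#' Query text is a fixed template over the symptom entity name ("I have
#' {symptom}. What foods would you recommend?"), so the mock keyword rule
#' (longest entity-name substring) recovers the query entity exactly.
#' Gold answers are the termini of the symptom's planted gold paths.
#'
#' @param sim a `synthetic_mfh_kg` from [generate_kg()].
#' @param n number of queries; if it exceeds the number of distinct
#'   symptoms, symptoms are re-used (sampling with replacement).
#' @param seed RNG seed.
#' @return list of `gold_query` records: `id`, `text`, `query_entities`,
#'   `gold_answers`, `gold_paths` (rows of the path table).
#' @export
generate_queries <- function(sim, n = 50, seed = sim$spec$seed) {
  stopifnot(inherits(sim, "synthetic_mfh_kg"), n >= 1)
  gp <- sim$gold_paths
  symptoms <- unique(gp$symptom)
  if (!length(symptoms)) {
    stop_mfh("no gold paths to build queries from", "synthetic_spec_error")
  }
  chosen <- with_seed(derive_seed(seed, "queries"), {
    if (n <= length(symptoms)) sample(symptoms, n)
    else sample(symptoms, n, replace = TRUE)
  })
  lapply(seq_along(chosen), function(i) {
    sym <- chosen[i]
    rows <- gp[gp$symptom == sym, , drop = FALSE]
    structure(list(
      id = sprintf("q%03d", i),
      text = sprintf("I have %s. What foods would you recommend?", sym),
      query_entities = sym,
      gold_answers = unique(rows$food),
      gold_paths = rows
    ), class = "gold_query")
  })
}

#' Corrupt triples for negative sampling
#'
#' Produces `m` distinct triples absent from the graph by tail
#' corruption: a fact's tail is replaced by another entity observed as a
#' tail of the same relation (range-respecting corruption).
#'
#' @param kg a [ukg].
#' @param m number of corruptions.
#' @param seed RNG seed.
#' @param allow_fewer return what was found instead of erroring when the
#'   graph is too small to produce `m` distinct corruptions.
#' @return data frame `h`, `r`, `t` of absent triples.
#' @export
corrupt_triples <- function(kg, m, seed = 1, allow_fewer = FALSE) {
  stopifnot(inherits(kg, "ukg"), m >= 1)
  f <- kg$facts
  if (!nrow(f)) stop_mfh("cannot corrupt an empty graph",
                         "synthetic_spec_error")
  existing <- paste(f$h, f$r, f$t, sep = "\x1f")
  range_tails <- lapply(split(f$t, f$r), unique)
  with_seed(derive_seed(seed, "corrupt"), {
    out <- character(0)
    rows <- list()
    for (attempt in 1:60) {
      need <- m - length(out)
      if (need <= 0) break
      idx <- sample(nrow(f), max(need * 2, 10), replace = TRUE)
      new_t <- vapply(idx, function(i) sample(range_tails[[f$r[i]]], 1),
                      character(1))
      cand <- data.frame(h = f$h[idx], r = f$r[idx], t = new_t,
                         stringsAsFactors = FALSE)
      ckey <- paste(cand$h, cand$r, cand$t, sep = "\x1f")
      keep <- !(ckey %in% existing) & !(ckey %in% out) & !duplicated(ckey) &
        cand$h != cand$t
      cand <- cand[keep, , drop = FALSE]
      if (nrow(cand)) {
        rows[[length(rows) + 1L]] <- cand
        out <- c(out, ckey[keep])
      }
    }
    res <- if (length(rows)) do.call(rbind, rows) else
      data.frame(h = character(), r = character(), t = character())
    if (nrow(res) > m) res <- res[seq_len(m), , drop = FALSE]
    if (nrow(res) < m && !allow_fewer) {
      stop_mfh(sprintf("graph too small: produced %d of %d corruptions",
                       nrow(res), m), "synthetic_spec_error")
    }
    rownames(res) <- NULL
    res
  })
}
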