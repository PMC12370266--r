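#' Fit the stand-in confidence model
#'
#' Learns low-dimensional embeddings of entities and relations whose
#' translational plausibility reproduces the observed confidence scores.
#' For a triple `(h, r, t)` the structural score is
#' `f = exp(-||v_h + v_r - v_t||^2)`, a value in `(0, 1]` that is 1 when
#' the translation is exact and decays with distance.  Training minimizes
#' the squared error between `f` and the observed confidence for the
#' graph's facts, and between `f` and 0 for uniformly tail-corrupted
#' negatives (`negatives` per positive, corruptions drawn within each
#' relation's observed tail range).  The fit works in distance space,
#' where gradients do not saturate: for a positive with confidence `s`
#' the squared distance is regressed onto `-log(s)` (so `f` reproduces
#' `s` at the optimum), and a negative is hinge-pushed beyond the
#' distance at which its implied score would still exceed 0.05.  Errors
#' are confidence-weighted, so reliable facts anchor the geometry while
#' low-confidence facts (whose distance targets typically conflict at
#' shared entities) weigh less.  Full-batch gradient descent with
#' degree-preconditioned gradients and backtracking line search
#' guarantees a non-increasing loss curve; a final monotone linear
#' calibration maps the learned squared distances back onto the
#' `-log(s)` scale, leaving every ranking unchanged.  The fit is
#' deterministic for a fixed seed.
#'
#' This scorer is a documented stand-in for an external
#' uncertain-KG-embedding library: it reproduces the two evidence
#' channels of the original design — embedding structure and corpus
#' support — behind a small interface so a different scorer can be
#' substituted.
#'
#' @param kg a [ukg] with at least 2 entities and 1 fact.
#' @param dim embedding dimension (default 32; 64 also works at desk
#'   scale but doubles the fit time).
#' @param epochs number of accepted gradient steps (default 150).
#' @param negatives negative samples per positive fact (default 5).
#' @param seed RNG seed controlling initialization and negative sampling.
#' @param blend_weight convex weight of the embedding channel when an
#'   evidence count is supplied to [score_triple()] (default 0.7).
#' @return object of class `embedding_table`: `entity_vecs`,
#'   `relation_vecs` (matrices with named rows), `dim`, `seed`,
#'   `blend_weight`, `loss` (per-epoch training loss).
#' @export
fit_confidence_model <- function(kg, dim = 32, epochs = 150, negatives = 5,
                                 seed = 42, blend_weight = 0.7) {
  stopifnot(inherits(kg, "ukg"))
  if (nrow(kg$entities) < 2 || nrow(kg$facts) < 1) {
    stop_mfh("confidence model needs at least 2 entities and 1 fact",
             "confidence_training_error")
  }
  ids <- kg$entities$id
  rels <- kg$relations
  npos <- nrow(kg$facts)

  E <- with_seed(derive_seed(seed, "embed-init"), {
    a <- 1 / sqrt(dim)
    matrix(stats::runif(length(ids) * dim, -a, a), nrow = length(ids),
           dimnames = list(ids, NULL))
  })
  R <- with_seed(derive_seed(seed, "rel-init"), {
    a <- 1 / sqrt(dim)
    matrix(stats::runif(length(rels) * dim, -a, a), nrow = length(rels),
           dimnames = list(rels, NULL))
  })

  neg <- if (negatives > 0) {
    corrupt_triples(kg, m = min(negatives * npos, 20L * npos),
                    seed = derive_seed(seed, "neg-sample"),
                    allow_fewer = TRUE)
  } else data.frame(h = character(), r = character(), t = character())

  hi <- c(match(kg$facts$h, ids), match(neg$h, ids))
  ri <- c(match(kg$facts$r, rels), match(neg$r, rels))
  ti <- c(match(kg$facts$t, ids), match(neg$t, ids))
  is_pos <- c(rep(TRUE, npos), rep(FALSE, nrow(neg)))
  # target squared distance: -log(s) maps confidence to translation error
  q_pos <- -log(pmin(pmax(kg$facts$s, 0.01), 0.99))
  q_neg <- -log(0.05)   # negatives must land at least this far out
  target_q <- c(q_pos, rep(q_neg, nrow(neg)))
  # confidence-weighted errors: reliable facts anchor the geometry,
  # uncertain ones (whose distance targets conflict) weigh less
  wts <- c(kg$facts$s, rep(0.25, nrow(neg)))

  loss_of <- function(E, R) {
    D <- E[hi, , drop = FALSE] + R[ri, , drop = FALSE] - E[ti, , drop = FALSE]
    q <- rowSums(D * D)
    err <- ifelse(is_pos, q - target_q, pmin(q - target_q, 0))
    sum(wts * err^2)
  }

  loss_hist <- numeric(0)
  lr <- 0.05
  loss <- loss_of(E, R)
  step <- 0L
  while (step < epochs) {
    D <- E[hi, , drop = FALSE] + R[ri, , drop = FALSE] - E[ti, , drop = FALSE]
    q <- rowSums(D * D)
    err <- ifelse(is_pos, q - target_q, pmin(q - target_q, 0))
    G <- (4 * wts * err) * D   # dL/dD = 2 w err * dq/dD = 4 w err D
    gE <- matrix(0, nrow(E), dim)
    gR <- matrix(0, nrow(R), dim)
    gh <- rowsum(G, group = hi)
    gE[as.integer(rownames(gh)), ] <- gE[as.integer(rownames(gh)), ] + gh
    gt <- rowsum(-G, group = ti)
    gE[as.integer(rownames(gt)), ] <- gE[as.integer(rownames(gt)), ] + gt
    gr <- rowsum(G, group = ri)
    gR[as.integer(rownames(gr)), ] <- gR[as.integer(rownames(gr)), ] + gr
    # precondition by incidence degree so hub entities do not set the pace
    degE <- tabulate(hi, nrow(E)) + tabulate(ti, nrow(E))
    degR <- tabulate(ri, nrow(R))
    gE <- gE / pmax(degE, 1)
    gR <- gR / pmax(degR, 1)

    accepted <- FALSE
    for (try in 1:25) {
      E2 <- E - lr * gE
      R2 <- R - lr * gR
      l2 <- loss_of(E2, R2)
      if (l2 <= loss) {
        E <- E2; R <- R2; loss <- l2
        lr <- lr * 1.1
        accepted <- TRUE
        break
      }
      lr <- lr / 2
    }
    step <- step + 1L
    loss_hist <- c(loss_hist, loss)
    if (!accepted) break   # at a (numerical) stationary point
  }
  dimnames(E) <- list(ids, NULL); dimnames(R) <- list(rels, NULL)
  # calibration: gradient descent leaves the learned distances on a
  # compressed scale; a monotone linear map of squared distance onto the
  # -log(s) targets (least squares over the positives) puts scores back
  # on the confidence scale without changing any ranking
  Dp <- E[hi[is_pos], , drop = FALSE] + R[ri[is_pos], , drop = FALSE] -
    E[ti[is_pos], , drop = FALSE]
  qp <- rowSums(Dp * Dp)
  cal <- if (stats::var(qp) > 1e-12) {
    a <- stats::cov(qp, q_pos) / stats::var(qp)
    if (!is.finite(a) || a < 0.01) a <- 0.01
    c(a = a, b = mean(q_pos) - a * mean(qp))
  } else c(a = 1, b = 0)
  structure(list(entity_vecs = E, relation_vecs = R, dim = dim, seed = seed,
                 blend_weight = blend_weight, loss = loss_hist,
                 calibration = cal),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf(
    "Embedding table: %d entities, %d relations, dim %d (seed %s)\n",
    nrow(x$entity_vecs), nrow(x$relation_vecs), x$dim, format(x$seed)))
  if (length(x$loss)) {
    cat(sprintf("  training loss %.4f -> %.4f over %d epochs\n",
                x$loss[1], x$loss[length(x$loss)], length(x$loss)))
  }
  invisible(x)
}

# Vectorized embedding channel for triples given as id vectors.
embedding_score <- function(table, h, r, t) {
  hi <- match(h, rownames(table$entity_vecs))
  ri <- match(r, rownames(table$relation_vecs))
  ti <- match(t, rownames(table$entity_vecs))
  if (anyNA(hi) || anyNA(ti) || anyNA(ri)) {
    missing <- unique(c(h[is.na(hi)], t[is.na(ti)], r[is.na(ri)]))
    stop_mfh(paste0("ids unknown to the embedding table: ",
                    paste(missing, collapse = ", ")), "confidence_key_error")
  }
  D <- table$entity_vecs[hi, , drop = FALSE] +
    table$relation_vecs[ri, , drop = FALSE] -
    table$entity_vecs[ti, , drop = FALSE]
  q <- rowSums(D * D)
  cal <- table$calibration %||% c(a = 1, b = 0)
  pmin(exp(-(cal[["a"]] * q + cal[["b"]])), 1)
}

#' Score a triple's confidence
#'
#' Combines the embedding channel `f` (translational plausibility
#' squashed into `(0, 1]`) with the corpus-support channel
#' `1 - exp(-evidence_count)` in a convex blend with weight
#' `blend_weight` on the embedding side.  When `evidence_count` is `NULL`
#' (no corpus evidence is being considered, as for candidate triples in
#' graph completion), the score is the embedding channel alone.  The
#' score always lies in `[0, 1]` and is monotone non-decreasing in
#' `evidence_count` at fixed embeddings.
#'
#' @param table an `embedding_table`.
#' @param h,r,t triple components (ids known to the table).
#' @param evidence_count nonnegative number of supporting passages, or
#'   `NULL` to score on the embedding channel alone.
#' @return object of class `confidence_score`: `value` in `[0, 1]` and
#'   `evidence_count`.
#' @export
score_triple <- function(table, h, r, t, evidence_count = NULL) {
  f <- embedding_score(table, h, r, t)
  value <- if (is.null(evidence_count)) {
    f
  } else {
    stopifnot(evidence_count >= 0)
    lam <- table$blend_weight
    lam * f + (1 - lam) * (1 - exp(-evidence_count))
  }
  structure(list(value = as.numeric(value),
                 evidence_count = evidence_count %||% NA_integer_),
            class = "confidence_score")
}

#' Re-assign confidences across a graph
#'
#' Replaces every fact's confidence by the model score, optionally
#' blending in per-triple evidence counts (supporting passages from the
#' construction sidecar, keyed by `h\x1fr\x1ft`).
#'
#' @param kg a [ukg].
#' @param table an `embedding_table` trained on `kg`'s vocabulary.
#' @param evidence_counts optional named integer vector keyed
#'   `paste(h, r, t, sep = "\x1f")`; triples without an entry count 0.
#' @return a [ukg] with updated confidences.
#' @export
assign_confidences <- function(kg, table, evidence_counts = NULL) {
  stopifnot(inherits(kg, "ukg"), inherits(table, "embedding_table"))
  if (!nrow(kg$facts)) return(kg)
  f <- embedding_score(table, kg$facts$h, kg$facts$r, kg$facts$t)
  s <- if (is.null(evidence_counts)) {
    f
  } else {
    key <- paste(kg$facts$h, kg$facts$r, kg$facts$t, sep = "\x1f")
    ec <- ifelse(is.na(evidence_counts[key]), 0, evidence_counts[key])
    lam <- table$blend_weight
    lam * f + (1 - lam) * (1 - exp(-ec))
  }
  facts <- kg$facts
  facts$s <- pmin(pmax(as.numeric(s), 0), 1)
  ukg(facts = facts, entities = kg$entities, relations = kg$relations)
}

#' Threshold-based graph completion
#'
#' For every head/relation combination observed in the graph, candidate
#' tails are enumerated from the relation's observed tail range (entities
#' already seen as tails of that relation), capped per `(h, r)` by
#' embedding proximity.  Candidates absent from the graph whose model
#' score is strictly greater than `threshold` are added with that score
#' as confidence; existing facts are never modified or removed.  The
#' default threshold 0.85 matches the completion rule under which a
#' candidate scoring exactly 0.85 is not admitted.
#'
#' @param kg a [ukg].
#' @param table an `embedding_table` covering `kg`'s vocabulary.
#' @param threshold admission threshold in (0, 1); strictly-greater rule.
#' @param cap maximum candidates scored per `(h, r)` pair (default 200),
#'   nearest first by embedding distance.
#' @return a [ukg] containing the original facts plus the admitted
#'   triples; the added facts (with scores) are in `attr(, "added")`.
#' @export
complete_graph <- function(kg, table, threshold = 0.85, cap = 200) {
  stopifnot(inherits(kg, "ukg"), threshold > 0, threshold < 1, cap >= 1)
  if (!nrow(kg$facts)) {
    out <- kg
    attr(out, "added") <- kg$facts[0, ]
    return(out)
  }
  existing <- paste(kg$facts$h, kg$facts$r, kg$facts$t, sep = "\x1f")
  range_tails <- split(kg$facts$t, kg$facts$r)
  range_tails <- lapply(range_tails, unique)
  hr <- unique(kg$facts[, c("h", "r")])

  cand <- vector("list", nrow(hr))
  for (i in seq_len(nrow(hr))) {
    h <- hr$h[i]; r <- hr$r[i]
    tails <- setdiff(range_tails[[r]], c(facts_from(kg, h, r)$t, h))
    if (!length(tails)) next
    if (length(tails) > cap) {
      d2 <- -log(embedding_score(table, rep(h, length(tails)),
                                 rep(r, length(tails)), tails))
      tails <- tails[order(d2, tails)][seq_len(cap)]
    }
    cand[[i]] <- data.frame(h = h, r = r, t = tails, stringsAsFactors = FALSE)
  }
  cand <- do.call(rbind, cand)
  if (is.null(cand) || !nrow(cand)) {
    out <- kg
    attr(out, "added") <- kg$facts[0, ]
    return(out)
  }
  cand <- cand[!(paste(cand$h, cand$r, cand$t, sep = "\x1f") %in% existing), ,
               drop = FALSE]
  score <- if (nrow(cand)) embedding_score(table, cand$h, cand$r, cand$t)
           else numeric()
  admitted <- cand[score > threshold, , drop = FALSE]
  admitted$s <- score[score > threshold]
  rownames(admitted) <- NULL
  out <- ukg(facts = rbind(kg$facts, admitted), entities = kg$entities,
             relations = kg$relations)
  attr(out, "added") <- admitted
  out
}
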