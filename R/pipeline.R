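# Two-phase pipeline: phase 1 labels every token with an event type (or
# Not-Event); phase 2 labels trigger-candidate pairs inside each sentence
# with Theme/Cause/None; transitivity post-processing then copies each
# argument's role to all of its coreference antecedents.

NOT_EVENT <- "Not-Event"
NO_ROLE <- "None"

token_feature_list <- function(tokens, lexicon) {
  tf <- token_features(tokens, lexicon)
  feats <- rep(tf$feature, tf$count)
  key <- rep(paste(tf$doc_id, tf$doc_index), tf$count)
  out <- split(feats, key)
  # align to the token table's own order
  out[paste(tokens$doc_id, tokens$doc_index)]
}

phase1_examples <- function(corpus, lexicon) {
  tk <- arrange(corpus$tokens, .data$doc_id, .data$doc_index)
  feats <- token_feature_list(tk, lexicon)
  lab <- rep(NOT_EVENT, nrow(tk))
  m <- match(paste(tk$doc_id, tk$doc_index),
             paste(corpus$triggers$doc_id, corpus$triggers$anchor))
  lab[!is.na(m)] <- corpus$triggers$event_type[m[!is.na(m)]]
  list(tokens = tk, feats = feats, labels = lab)
}

#' Predict event triggers (phase 1)
#'
#' Every token receives one label from the event-type inventory plus
#' `Not-Event`; tokens labeled with an event type become triggers.
#'
#' @param model A trained `event_pipeline`.
#' @param corpus An `event_corpus`.
#' @return Trigger tibble `doc_id`, `anchor`, `event_type`.
#' @export
phase1_predict <- function(model, corpus) {
  if (nrow(corpus$tokens) == 0) {
    return(tibble(doc_id = character(), anchor = integer(),
                  event_type = character()))
  }
  ex <- phase1_examples(corpus, model$lexicon)
  lab <- predict_ovr(model$phase1, ex$feats)
  keep <- lab != NOT_EVENT
  tibble(doc_id = ex$tokens$doc_id[keep], anchor = ex$tokens$doc_index[keep],
         event_type = lab[keep])
}

phase2_candidate_set <- function(tokens_sent, trigger_anchors) {
  sort(unique(c(tokens_sent$doc_index[tokens_sent$ne != "O"],
                intersect(trigger_anchors, tokens_sent$doc_index))))
}

phase2_examples <- function(corpus, triggers, lexicon, coref = NULL,
                            tok_feats = NULL) {
  tk <- corpus$tokens
  tok_feats <- tok_feats %||% token_feature_list(tk, lexicon)
  names(tok_feats) <- paste(tk$doc_id, tk$doc_index)
  clusters <- if (is.null(coref)) NULL else coref_closure(coref)
  gold_key <- paste(corpus$roles$doc_id, corpus$roles$event_anchor,
                    corpus$roles$arg_anchor)
  metas <- list(); feats <- list(); labels <- character()
  copy_cache <- new.env(parent = emptyenv())
  for (d in unique(triggers$doc_id)) {
    td <- tk[tk$doc_id == d, ]
    trig_d <- triggers[triggers$doc_id == d, ]
    sent_of <- setNames(td$sentence_index, as.character(td$doc_index))
    for (s in unique(sent_of[as.character(trig_d$anchor)])) {
      ts <- td[td$sentence_index == s, ]
      trig_s <- trig_d$anchor[sent_of[as.character(trig_d$anchor)] == s]
      cand <- phase2_candidate_set(ts, trig_d$anchor)
      for (i in trig_s) {
        for (j in setdiff(cand, i)) {
          if (sent_of[[as.character(j)]] != s) {
            abort("phase 2 pairs must be intra-sentence")
          }
          f <- c(paste0("e:", tok_feats[[paste(d, i)]]),
                 paste0("a:", tok_feats[[paste(d, j)]]),
                 pair_features(ts, i, j))
          if (!is.null(clusters)) {
            ck <- paste(d, j)
            if (is.null(copy_cache[[ck]])) {
              copy_cache[[ck]] <- copy_features(tk, clusters, d, j)
            }
            f <- c(f, copy_cache[[ck]])
          }
          g <- corpus$roles$role[match(paste(d, i, j), gold_key)]
          metas[[length(metas) + 1]] <- c(d, i, j)
          feats[[length(feats) + 1]] <- f
          labels <- c(labels, if (is.na(g)) NO_ROLE else g)
        }
      }
    }
  }
  meta <- if (length(metas) == 0) {
    tibble(doc_id = character(), event_anchor = integer(),
           arg_anchor = integer())
  } else {
    m <- do.call(rbind, metas)
    tibble(doc_id = m[, 1], event_anchor = as.integer(m[, 2]),
           arg_anchor = as.integer(m[, 3]))
  }
  list(meta = meta, feats = feats, labels = labels)
}

#' Predict event-argument links (phase 2)
#'
#' For every phase-1 trigger, the candidate arguments are the NE-tagged
#' tokens and the other triggers of the same sentence; each trigger-candidate
#' pair is labeled Theme, Cause or None. Pairs never span sentences at this
#' stage — cross-sentence links only arise from [propagate_transitivity()].
#'
#' @param model A trained `event_pipeline`.
#' @param corpus An `event_corpus`.
#' @param triggers Trigger tibble (typically [phase1_predict()] output).
#' @param coref Optional coreference tibble; enables feature copy.
#' @return Role-link tibble `doc_id`, `event_anchor`, `arg_anchor`, `role`.
#' @export
phase2_predict <- function(model, corpus, triggers, coref = NULL) {
  ex <- phase2_examples(corpus, triggers, model$lexicon, coref)
  if (nrow(ex$meta) == 0) {
    return(tibble(doc_id = character(), event_anchor = integer(),
                  arg_anchor = integer(), role = character()))
  }
  lab <- predict_ovr(model$phase2, ex$feats)
  keep <- lab != NO_ROLE
  out <- ex$meta[keep, ]
  out$role <- lab[keep]
  out
}

#' Transitivity post-processing
#'
#' Deterministically attaches, for every argument of an event, all of the
#' argument's coreference antecedents with the same role: from a link
#' `role(e, a, r)` and an earlier cluster mate `b` of `a`, the link
#' `role(e, b, r)` is added. The output is a superset of the input and the
#' operation is idempotent. This is how the pipeline — whose classifiers only
#' see intra-sentence pairs — produces cross-sentence links.
#'
#' @param links Role-link tibble.
#' @param clusters Entity clusters from [coref_closure()].
#' @return Role-link tibble including all propagated links (deduplicated).
#' @export
propagate_transitivity <- function(links, clusters) {
  if (nrow(links) == 0 || nrow(clusters) == 0) return(links)
  extra <- purrr::pmap_dfr(
    links[c("doc_id", "event_anchor", "arg_anchor", "role")],
    function(doc_id, event_anchor, arg_anchor, role) {
      b <- cluster_mates(clusters, doc_id, arg_anchor, before_only = TRUE)
      b <- setdiff(b, event_anchor)
      if (length(b) == 0) return(NULL)
      tibble(doc_id = doc_id, event_anchor = event_anchor, arg_anchor = b,
             role = role)
    })
  bind_rows(links[c("doc_id", "event_anchor", "arg_anchor", "role")], extra) %>%
    distinct() %>%
    arrange(.data$doc_id, .data$event_anchor, .data$arg_anchor, .data$role)
}

#' Train the two-phase pipeline
#'
#' Phase 1 is a one-vs-rest regularized linear model over token features with
#' label space = event-type inventory + `Not-Event`; phase 2 is the same over
#' trigger-candidate pair features with labels Theme/Cause/None, trained on
#' gold triggers. Supplying `coref` adds copied antecedent features to
#' phase 2.
#'
#' @param corpus Training `event_corpus` (gold layers used as supervision).
#' @param coref Optional coreference tibble available at train time (`NULL`
#'   for the no-coreference system).
#' @param lambda Ridge penalty for both phases.
#' @return An `event_pipeline` object.
#' @export
pipeline_train <- function(corpus, coref = NULL, lambda = 1e-4) {
  lexicon <- build_trigger_lexicon(corpus)
  ex1 <- phase1_examples(corpus, lexicon)
  phase1 <- fit_ovr(ex1$feats, ex1$labels,
                    label_space = c(corpus$event_types, NOT_EVENT),
                    lambda = lambda)
  ex2 <- phase2_examples(corpus, corpus$triggers, lexicon, coref)
  phase2 <- fit_ovr(ex2$feats, ex2$labels,
                    label_space = c(role_classes(), NO_ROLE),
                    lambda = lambda)
  structure(list(lexicon = lexicon, phase1 = phase1, phase2 = phase2,
                 event_types = corpus$event_types, lambda = lambda,
                 trained_with_coref = !is.null(coref)),
            class = "event_pipeline")
}

#' Run the trained pipeline over a corpus
#'
#' Phase 1, phase 2, then (when coreference is supplied) transitivity
#' post-processing. Without coreference the output provably contains no
#' cross-sentence links.
#'
#' @param model An `event_pipeline`.
#' @param corpus An `event_corpus` to annotate (gold layers ignored).
#' @param coref Optional coreference tibble (system or gold).
#' @return List with tibbles `triggers` and `roles`.
#' @export
pipeline_predict <- function(model, corpus, coref = NULL) {
  triggers <- phase1_predict(model, corpus)
  roles <- phase2_predict(model, corpus, triggers, coref)
  if (!is.null(coref) && nrow(coref) > 0) {
    roles <- propagate_transitivity(roles, coref_closure(coref))
  }
  list(triggers = triggers, roles = roles)
}

#' @export
print.event_pipeline <- function(x, ...) {
  cat("<event_pipeline> ", length(x$event_types) + 1,
      "-class trigger model + Theme/Cause/None pair model\n",
      "  trigger lexicon: ", length(x$lexicon), " stems; coref features: ",
      x$trained_with_coref, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.event_pipeline <- function(x, ...) {
  bind_rows(mutate(tidy(x$phase1), phase = "phase1"),
            mutate(tidy(x$phase2), phase = "phase2"))
}

#' @export
glance.event_pipeline <- function(x, ...) {
  tibble(n_event_types = length(x$event_types),
         phase1_classes = length(x$event_types) + 1L,
         phase2_classes = 3L, lambda = x$lambda,
         trained_with_coref = x$trained_with_coref)
}
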