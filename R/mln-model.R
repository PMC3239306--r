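# The joint model: hidden predicates event(i), eventType(i,t), role(i,j,r);
# local formulae over observed token/pair features; four hard consistency
# formulae; and the three coreference formulae —
#   SiD: corefer(j,k) => exists i. role(i,j,r)          (salience in discourse)
#   T:   role(i,j,r) & corefer(j,k) => role(i,k,r)      (transitivity)
#   FC:  corefer(j,k) & F(k,f) => role(i,j,r)           (feature copy)
# Instances are grounded per sentence plus the antecedent candidates reachable
# through the supplied coreference links; documents are never grounded whole.

#' Model specification for the joint extractor
#'
#' @param fc,sid,t Enable the Feature-Copy, Salience-in-Discourse and
#'   Transitivity formulae.
#' @param arg_domain `"typed"` restricts role atoms to plausible endpoints
#'   (event side: tokens in the trigger lexicon; argument side: NE-tagged or
#'   lexicon tokens, plus antecedent candidates); `"all"` grounds role atoms
#'   over every token pair of the sentence.
#' @return An `mln_spec`.
#' @export
mln_spec <- function(fc = FALSE, sid = FALSE, t = FALSE,
                     arg_domain = c("typed", "all")) {
  structure(list(fc = fc, sid = sid, t = t,
                 arg_domain = match.arg(arg_domain)),
            class = "mln_spec")
}

#' Named model presets
#'
#' `baseline` disables every coreference formula; `fc`, `fc_sid`, `fc_t` and
#' `full` add Feature Copy, then Salience in Discourse and/or Transitivity,
#' `full` being FC+SiD+T.
#'
#' @param preset One of `"baseline"`, `"fc"`, `"fc_sid"`, `"fc_t"`, `"full"`.
#' @param ... Passed to [mln_spec()].
#' @return An `mln_spec`.
#' @export
mln_preset <- function(preset = c("baseline", "fc", "fc_sid", "fc_t", "full"),
                       ...) {
  preset <- match.arg(preset)
  flags <- switch(preset,
                  baseline = c(FALSE, FALSE, FALSE),
                  fc = c(TRUE, FALSE, FALSE),
                  fc_sid = c(TRUE, TRUE, FALSE),
                  fc_t = c(TRUE, FALSE, TRUE),
                  full = c(TRUE, TRUE, TRUE))
  mln_spec(fc = flags[1], sid = flags[2], t = flags[3], ...)
}

#' List the formula templates of a model specification
#'
#' @param spec An [mln_spec()].
#' @return Tibble with `template`, `kind` (`local`, `global`, `coref`),
#'   `hard`, and whether the template conditions on `corefer` atoms.
#' @export
instantiate_model <- function(spec) {
  base <- tibble(
    template = c("event_local", "eventType_local", "role_local",
                 "event_implies_type", "type_implies_event",
                 "role_implies_event", "event_implies_theme"),
    kind = c("local", "local", "local", "global", "global", "global",
             "global"),
    hard = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
    uses_corefer = FALSE
  )
  extra <- list()
  if (spec$fc) extra$fc <- tibble(template = "FC", kind = "coref",
                                  hard = FALSE, uses_corefer = TRUE)
  if (spec$sid) extra$sid <- tibble(template = "SiD", kind = "coref",
                                    hard = FALSE, uses_corefer = TRUE)
  if (spec$t) extra$t <- tibble(template = "T", kind = "coref",
                                hard = FALSE, uses_corefer = TRUE)
  bind_rows(base, bind_rows(extra))
}

#' Observed ground atoms of a corpus
#'
#' Materializes the observed predicates: the simple-token-property atoms
#' (word/pos/stem/ne/chunk/dict/capital/numeric/punct/bigram/trigram) per
#' token, the linked-tokens-property atoms (dep/path/pathNL/lca) per ordered
#' intra-sentence token pair, the symmetric closure of `corefer` over entity
#' clusters, and — when `with_fc` — the copied-feature atoms available to the
#' Feature-Copy formula.
#'
#' @param corpus An `event_corpus`.
#' @param coref Coreference tibble (possibly empty).
#' @param with_fc Also emit copied-feature atoms.
#' @param lexicon Trigger lexicon for the `dict` atoms.
#' @return Tibble `doc_id`, `pred`, `i`, `j` (`NA` for token atoms), `value`.
#' @export
build_observed_atoms <- function(corpus, coref = NULL, with_fc = FALSE,
                                 lexicon = character()) {
  tf <- token_features(corpus$tokens, lexicon)
  split_feat <- function(f) {
    has_val <- grepl("=", f, fixed = TRUE)
    pred <- ifelse(has_val, sub("=.*$", "", f), f)
    val <- ifelse(has_val, sub("^[^=]*=", "", f), NA_character_)
    pred[pred == "punct"] <- "punc"
    list(pred = pred, val = val)
  }
  sf <- split_feat(tf$feature)
  tok_atoms <- tibble(doc_id = rep(tf$doc_id, tf$count),
                      pred = rep(sf$pred, tf$count),
                      i = rep(tf$doc_index, tf$count),
                      j = NA_integer_, value = rep(sf$val, tf$count))
  pair_atoms <- list()
  for (d in unique(corpus$tokens$doc_id)) {
    td <- corpus$tokens[corpus$tokens$doc_id == d, ]
    for (s in unique(td$sentence_index)) {
      ts <- td[td$sentence_index == s, ]
      for (i in ts$doc_index) for (j in setdiff(ts$doc_index, i)) {
        pf <- split_feat(pair_features(ts, i, j))
        pair_atoms[[length(pair_atoms) + 1]] <-
          tibble(doc_id = d, pred = pf$pred, i = i, j = j, value = pf$val)
      }
    }
  }
  out <- bind_rows(tok_atoms, bind_rows(pair_atoms))
  clusters <- coref_closure(coref %||%
                              tibble(doc_id = character(), anaphor = integer(),
                                     antecedent = integer()))
  if (nrow(clusters) > 0) {
    crf <- clusters %>% group_by(.data$doc_id, .data$cluster) %>%
      summarise(pairs = list({
        cmb <- expand.grid(i = .data$token, j = .data$token)
        cmb[cmb$i != cmb$j, ]
      }), .groups = "drop") %>% tidyr::unnest("pairs")
    out <- bind_rows(out, tibble(doc_id = crf$doc_id, pred = "corefer",
                                 i = as.integer(crf$i), j = as.integer(crf$j),
                                 value = NA_character_))
    if (with_fc) {
      fc_atoms <- purrr::map_dfr(seq_len(nrow(clusters)), function(r) {
        d <- clusters$doc_id[r]; j <- clusters$token[r]
        cf <- copy_features(corpus$tokens, clusters, d, j)
        if (length(cf) == 0) return(NULL)
        tibble(doc_id = d, pred = "copied", i = j, j = NA_integer_,
               value = cf)
      })
      out <- bind_rows(out, fc_atoms)
    }
  }
  arrange(out, .data$doc_id, .data$pred, .data$i, .data$j, .data$value)
}

# --- grounding -------------------------------------------------------------

#' Ground one sentence instance
#'
#' Builds the ground network for a single sentence: hidden `event`,
#' `eventType` and `role` atoms over the sentence and its antecedent
#' candidates, local factors from the observed features, the four hard
#' consistency clauses, and the enabled coreference formulae.
#'
#' @param corpus An `event_corpus`.
#' @param doc Document id.
#' @param sentence Sentence index within the document.
#' @param spec An [mln_spec()] or preset name.
#' @param coref Coreference tibble defining the `corefer` atoms (`NULL` for
#'   none).
#' @param lexicon Trigger lexicon; defaults to one built from the corpus's
#'   own gold triggers.
#' @return An [mln_network()] with `doc`, `sentence` and `candidates`
#'   attributes.
#' @export
ground_sentence <- function(corpus, doc, sentence, spec = "full",
                            coref = NULL, lexicon = NULL) {
  spec <- if (inherits(spec, "mln_spec")) spec else mln_preset(spec)
  lexicon <- lexicon %||% build_trigger_lexicon(corpus)
  clusters <- coref_closure(coref %||% corpus$coref[0, ])
  td <- corpus$tokens[corpus$tokens$doc_id == doc, ]
  if (nrow(td) == 0) abort(paste0("unknown document: ", doc))
  tok_feats <- token_feature_list(td, lexicon)
  names(tok_feats) <- paste(doc, td$doc_index)
  mln_ground(td, doc, sentence, spec, clusters, lexicon, tok_feats,
             corpus$event_types)
}

mln_ground <- function(tokens_doc, doc, sentence, spec, clusters, lexicon,
                       tok_feats, event_types) {
  ts <- tokens_doc[tokens_doc$sentence_index == sentence, ]
  ts <- ts[order(ts$doc_index), ]
  sent_tokens <- ts$doc_index
  cand <- candidate_arguments(tokens_doc, doc, sentence, clusters)
  # the antecedent extension of the candidate set serves the Transitivity
  # formula; without T the model reasons over the sentence only, so no
  # cross-sentence role atom can ever be part of a MAP solution
  if (!spec$t) cand <- intersect(cand, sent_tokens)
  dict_tok <- tokens_doc$doc_index[tokens_doc$stem %in% lexicon]
  if (spec$arg_domain == "typed") {
    ev_dom <- intersect(sent_tokens, dict_tok)
    arg_dom <- intersect(
      cand, union(tokens_doc$doc_index[tokens_doc$ne != "O"],
                  union(dict_tok, setdiff(cand, sent_tokens))))
  } else {
    ev_dom <- sent_tokens
    arg_dom <- cand
  }
  roles <- role_classes()
  # hidden atoms: events and types over sentence tokens, roles over domains
  at_event <- tibble(pred = "event", i = sent_tokens, a2 = NA_character_,
                     a3 = NA_character_)
  at_type <- tidyr::expand_grid(i = sent_tokens, a2 = event_types) %>%
    mutate(pred = "eventType", a3 = NA_character_) %>%
    select("pred", "i", "a2", "a3")
  role_grid <- tidyr::expand_grid(i = ev_dom, j = arg_dom, a3 = roles) %>%
    filter(.data$i != .data$j)
  at_role <- tibble(pred = "role", i = role_grid$i,
                    a2 = as.character(role_grid$j), a3 = role_grid$a3)
  atoms <- bind_rows(at_event, at_type, at_role)
  atoms$name <- paste0(atoms$pred, "(", atoms$i,
                       ifelse(is.na(atoms$a2), "", paste0(",", atoms$a2)),
                       ifelse(is.na(atoms$a3), "", paste0(",", atoms$a3)), ")")
  id_of <- setNames(seq_len(nrow(atoms)), atoms$name)
  ev_id <- function(i) id_of[[paste0("event(", i, ")")]]
  ty_id <- function(i, t) id_of[[paste0("eventType(", i, ",", t, ")")]]
  ro_id <- function(i, j, r) id_of[[paste0("role(", i, ",", j, ",", r, ")")]]

  # local factors
  feats_of <- function(i) tok_feats[[paste(doc, i)]]
  copy_cache <- new.env(parent = emptyenv())
  copies_of <- function(j) {
    k <- as.character(j)
    if (is.null(copy_cache[[k]])) {
      copy_cache[[k]] <- copy_features(tokens_doc, clusters, doc, j)
    }
    copy_cache[[k]]
  }
  local <- rep(list(character()), nrow(atoms))
  for (i in sent_tokens) {
    fi <- feats_of(i)
    local[[ev_id(i)]] <- paste0("event|", fi)
    for (t in event_types) {
      local[[ty_id(i, t)]] <- paste0("type|", t, "|", fi)
    }
  }
  sent_set <- as.integer(sent_tokens)
  for (k in seq_len(nrow(role_grid))) {
    i <- role_grid$i[k]; j <- role_grid$j[k]; r <- role_grid$a3[k]
    keys <- c(paste0("roleE|", r, "|", feats_of(i)),
              paste0("roleA|", r, "|", feats_of(j)))
    if (j %in% sent_set) {
      keys <- c(keys, paste0("roleP|", r, "|", pair_features(ts, i, j)))
      if (spec$fc) {
        cp <- copies_of(j)
        if (length(cp) > 0) keys <- c(keys, paste0("fc|", cp))
      }
    }
    local[[ro_id(i, j, r)]] <- keys
  }

  clauses <- list()
  add <- function(neg, pos, key = NA_character_, hard = FALSE) {
    clauses[[length(clauses) + 1]] <<- list(neg = as.integer(neg),
                                            pos = as.integer(pos),
                                            key = key, hard = hard)
  }
  for (i in sent_tokens) {
    tids <- vapply(event_types, function(t) ty_id(i, t), integer(1))
    add(neg = ev_id(i), pos = tids, hard = TRUE)            # event => E t.type
    for (tid in tids) add(neg = tid, pos = ev_id(i), hard = TRUE)
    theme_ids <- atoms$name[atoms$pred == "role" & atoms$i == i &
                              atoms$a3 == "Theme"]
    # exists-j grounded as a disjunction; an empty domain makes the
    # consequent false, i.e. such a token cannot be an event
    add(neg = ev_id(i), pos = id_of[theme_ids], hard = TRUE)
  }
  for (k in seq_len(nrow(role_grid))) {
    add(neg = ro_id(role_grid$i[k], role_grid$j[k], role_grid$a3[k]),
        pos = ev_id(role_grid$i[k]), hard = TRUE)
  }
  clustered_sent <- intersect(
    sent_tokens, clusters$token[clusters$doc_id == doc])
  if (spec$t && nrow(clusters) > 0) {
    for (j in intersect(arg_dom, clusters$token[clusters$doc_id == doc])) {
      mates <- intersect(cluster_mates(clusters, doc, j), arg_dom)
      for (k in mates) for (i in ev_dom) {
        if (i == j || i == k) next
        for (r in roles) {
          add(neg = ro_id(i, j, r), pos = ro_id(i, k, r), key = "T")
        }
      }
    }
  }
  if (spec$sid) {
    for (j in intersect(clustered_sent, arg_dom)) {
      for (r in roles) {
        pos <- vapply(setdiff(ev_dom, j), function(i) ro_id(i, j, r),
                      integer(1))
        if (length(pos) > 0) add(neg = integer(), pos = pos, key = "SiD")
      }
    }
  }
  net <- mln_network(atoms, local, clauses)
  attr(net, "doc") <- doc
  attr(net, "sentence") <- sentence
  attr(net, "candidates") <- cand
  net
}

gold_assignment <- function(network, triggers_doc, roles_doc) {
  atoms <- network$atoms
  g <- logical(nrow(atoms))
  ev <- atoms$pred == "event"
  g[ev] <- atoms$i[ev] %in% triggers_doc$anchor
  ty <- atoms$pred == "eventType"
  g[ty] <- paste(atoms$i[ty], atoms$a2[ty]) %in%
    paste(triggers_doc$anchor, triggers_doc$event_type)
  ro <- atoms$pred == "role"
  g[ro] <- paste(atoms$i[ro], atoms$a2[ro], atoms$a3[ro]) %in%
    paste(roles_doc$event_anchor, roles_doc$arg_anchor, roles_doc$role)
  g
}

mln_instances <- function(corpus, spec, coref, lexicon, with_gold = TRUE) {
  clusters <- coref_closure(coref %||% corpus$coref[0, ])
  tok_feats <- token_feature_list(corpus$tokens, lexicon)
  names(tok_feats) <- paste(corpus$tokens$doc_id, corpus$tokens$doc_index)
  out <- list()
  for (d in unique(corpus$tokens$doc_id)) {
    td <- corpus$tokens[corpus$tokens$doc_id == d, ]
    trig_d <- corpus$triggers[corpus$triggers$doc_id == d, ]
    rol_d <- corpus$roles[corpus$roles$doc_id == d, ]
    for (s in sort(unique(td$sentence_index))) {
      net <- mln_ground(td, d, s, spec, clusters, lexicon, tok_feats,
                        corpus$event_types)
      inst <- list(network = net, doc = d, sentence = s)
      if (with_gold) inst$gold <- gold_assignment(net, trig_d, rol_d)
      out[[length(out) + 1]] <- inst
    }
  }
  out
}

#' Train the joint model
#'
#' Grounds one instance per sentence (with antecedent candidates from the
#' supplied coreference links), then learns all soft-formula weights by
#' averaged passive-aggressive updates with exact loss-augmented MAP
#' decoding ([mln_learn()]). The four consistency formulae are hard
#' constraints throughout; Feature-Copy weights are per copied feature,
#' Transitivity and Salience-in-Discourse carry one shared weight each.
#'
#' @param corpus Training `event_corpus`.
#' @param preset Model preset name or an [mln_spec()].
#' @param coref Coreference tibble available to the model (`NULL` = none).
#' @param epochs,seed,aggressiveness Passed to [mln_learn()].
#' @return An `mln_model`.
#' @export
mln_train <- function(corpus, preset = "full", coref = NULL, epochs = 3L,
                      seed = 1L, aggressiveness = 1) {
  spec <- if (inherits(preset, "mln_spec")) preset else mln_preset(preset)
  lexicon <- build_trigger_lexicon(corpus)
  insts <- mln_instances(corpus, spec, coref, lexicon)
  weights <- mln_learn(insts, epochs = epochs, seed = seed,
                       aggressiveness = aggressiveness)
  structure(list(spec = spec, weights = weights, lexicon = lexicon,
                 event_types = corpus$event_types),
            class = "mln_model")
}

decode_assignment <- function(network, assignment, weights) {
  atoms <- network$atoms
  s <- atom_scores(network, weights)
  ev_true <- atoms$i[atoms$pred == "event" & assignment]
  trig <- list(); rol <- NULL
  for (i in ev_true) {
    ty <- which(atoms$pred == "eventType" & atoms$i == i & assignment)
    if (length(ty) == 0) next
    ty <- ty[order(-s[ty])][1]  # best-scored true type
    trig[[length(trig) + 1]] <- tibble(anchor = i, event_type = atoms$a2[ty])
  }
  ro <- atoms$pred == "role" & assignment
  rol <- tibble(event_anchor = atoms$i[ro],
                arg_anchor = as.integer(atoms$a2[ro]), role = atoms$a3[ro])
  list(triggers = bind_rows(trig) %||% tibble(anchor = integer(),
                                              event_type = character()),
       roles = rol)
}

#' Predict with a trained joint model
#'
#' @param model An `mln_model` from [mln_train()].
#' @param corpus An `event_corpus` to annotate (gold layers ignored).
#' @param coref Coreference tibble to condition on (`NULL` = none).
#' @return List with tibbles `triggers` and `roles`.
#' @export
mln_predict <- function(model, corpus, coref = NULL) {
  insts <- mln_instances(corpus, model$spec, coref, model$lexicon,
                         with_gold = FALSE)
  trig <- list(); rol <- list()
  for (inst in insts) {
    res <- map_infer(inst$network, model$weights)
    dec <- decode_assignment(inst$network, res$assignment, model$weights)
    if (nrow(dec$triggers) > 0) {
      dec$triggers$doc_id <- inst$doc
      trig[[length(trig) + 1]] <- dec$triggers
    }
    if (nrow(dec$roles) > 0) {
      dec$roles$doc_id <- inst$doc
      rol[[length(rol) + 1]] <- dec$roles
    }
  }
  empty_t <- tibble(doc_id = character(), anchor = integer(),
                    event_type = character())
  empty_r <- tibble(doc_id = character(), event_anchor = integer(),
                    arg_anchor = integer(), role = character())
  trig <- if (length(trig)) bind_rows(trig)[c("doc_id", "anchor",
                                              "event_type")] else empty_t
  rol <- if (length(rol)) bind_rows(rol)[c("doc_id", "event_anchor",
                                           "arg_anchor", "role")] else empty_r
  # one trigger per anchor by construction; drop duplicate role rows that a
  # transitivity pair can produce twice
  list(triggers = distinct(trig), roles = distinct(rol))
}

#' @export
print.mln_model <- function(x, ...) {
  cat("<mln_model> FC=", x$spec$fc, " SiD=", x$spec$sid, " T=", x$spec$t,
      "; ", length(x$weights), " learned weights\n", sep = "")
  invisible(x)
}

#' @export
tidy.mln_model <- function(x, ...) tidy(x$weights)

#' @export
glance.mln_model <- function(x, ...) {
  dplyr::bind_cols(tibble(fc = x$spec$fc, sid = x$spec$sid, t = x$spec$t),
                   glance(x$weights))
}
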