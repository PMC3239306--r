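# Synthetic corpus generator. Documents emulate the structure of an
# event-annotated biomedical corpus — nominal triggers typed from a small
# invented inventory (deliberately not a real corpus ontology), Theme/Cause
# arguments anchored on NP heads, coreference chains whose anaphors are
# arguments, and cross-sentence links realized through those chains except
# for a configurable zero-anaphora fraction with no overt bridge.

#' Configuration of the synthetic corpus generator
#'
#' @param n_docs Number of documents.
#' @param sentences,tokens Integer ranges `c(min, max)`: sentences per
#'   document and filler-padded target tokens per sentence.
#' @param event_types Event-type inventory; the default is a small invented
#'   set, not the ontology of any real corpus.
#' @param trigger_rate Probability that a sentence carries a second event
#'   trigger (every sentence has at least one).
#' @param cause_rate Probability that an event has a Cause argument in
#'   addition to its mandatory Theme.
#' @param chain_rate Probability, per non-initial sentence, of an additional
#'   non-argument re-mention of an earlier entity; chains are disabled
#'   entirely when 0.
#' @param cross_link_rate Probability, per non-initial sentence, of a
#'   cross-sentence event-argument situation.
#' @param zero_anaphora Fraction of cross-link situations realized with no
#'   bridging coreference chain (default 0.20).
#' @param noise_rate Probability that a trigger's word form is drawn from the
#'   ambiguous shared pool instead of its type-specific lexicon; 0 gives a
#'   lexically separable corpus.
#' @param seed Default seed used by [simulate_corpus()].
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_docs = 100, sentences = c(3, 5),
                             tokens = c(7, 10),
                             event_types = c("Activation", "Inhibition",
                                             "Binding", "Expression",
                                             "Regulation", "Transport"),
                             trigger_rate = 0.3, cause_rate = 0.35,
                             chain_rate = 0.2, cross_link_rate = 0.35,
                             zero_anaphora = 0.20, noise_rate = 0.05,
                             seed = 1L) {
  rates <- c(trigger_rate = trigger_rate, cause_rate = cause_rate,
             chain_rate = chain_rate, cross_link_rate = cross_link_rate,
             zero_anaphora = zero_anaphora, noise_rate = noise_rate)
  if (any(rates < 0 | rates > 1)) {
    abort(paste0("rates must lie in [0, 1]: ",
                 paste(names(rates)[rates < 0 | rates > 1], collapse = ", ")))
  }
  if (cross_link_rate > 0 && chain_rate == 0 && zero_anaphora < 1) {
    abort(paste0("inconsistent config: chained cross-links need chain_rate ",
                 "> 0 (or zero_anaphora = 1)"))
  }
  structure(list(n_docs = n_docs, sentences = sentences, tokens = tokens,
                 event_types = event_types, trigger_rate = trigger_rate,
                 cause_rate = cause_rate, chain_rate = chain_rate,
                 cross_link_rate = cross_link_rate,
                 zero_anaphora = zero_anaphora, noise_rate = noise_rate,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

sim_lexicons <- function(config) {
  list(
    trigger = setNames(lapply(seq_along(config$event_types), function(k) {
      paste0("trg", tolower(substr(config$event_types[k], 1, 4)), 1:8)
    }), config$event_types),
    ambiguous = paste0("procss", 1:10),
    entity = c(paste0("prot", sprintf("%02d", 1:40)),
               paste0("gene", sprintf("%02d", 1:30))),
    filler = c("the", "of", "in", "with", "cells", "we", "observed", "that",
               "level", "also", "during", "response", "after", "analysis")
  )
}

entity_ne <- function(word) if (startsWith(word, "gene")) "Gene" else "Protein"

#' Generate a synthetic annotated corpus
#'
#' Deterministic given the seed: the same `(config, seed)` pair yields a
#' byte-identical corpus. Every event has at least one Theme; the gold role
#' layer is closed under transitivity across the gold coreference chains, so
#' an anaphoric argument's earlier cluster mates are also gold arguments
#' (cross-links); a `zero_anaphora` fraction of cross-link situations are
#' instead direct links with no bridging chain.
#'
#' @param config A [synthetic_config()].
#' @param seed Overrides `config$seed`.
#' @return An `event_corpus` (validated).
#' @export
simulate_corpus <- function(config = synthetic_config(), seed = NULL) {
  set.seed(seed %||% config$seed)
  lex <- sim_lexicons(config)
  toks <- list(); trigs <- list(); rols <- list(); crfs <- list()
  for (dnum in seq_len(config$n_docs)) {
    d <- sprintf("doc%04d", dnum)
    doc <- sim_document(d, config, lex)
    toks[[d]] <- doc$tokens; trigs[[d]] <- doc$triggers
    rols[[d]] <- doc$roles; crfs[[d]] <- doc$coref
  }
  corpus <- event_corpus(
    tokens = bind_rows(toks), triggers = bind_rows(trigs),
    roles = bind_rows(rols), coref = bind_rows(crfs),
    event_types = config$event_types
  )
  attr(corpus, "config") <- config
  corpus
}

sim_document <- function(d, config, lex) {
  n_sent <- sample(config$sentences[1]:config$sentences[2], 1)
  doc_entities <- sample(lex$entity, 12)
  used_entities <- character()
  # mentions: head doc_index, sentence, entity word
  mentions <- tibble(head = integer(), sentence = integer(),
                     entity = character())
  rows <- list(); trig_rows <- list(); role_rows <- list(); coref_rows <- list()
  next_idx <- 0L

  for (s in 0:(n_sent - 1)) {
    sent <- list()  # per-token rows before indexing
    push <- function(word, pos, ne, chunk, parent, dep) {
      sent[[length(sent) + 1]] <<- list(word = word, pos = pos, ne = ne,
                                        chunk = chunk, parent = parent,
                                        dep = dep)
      length(sent)  # local 1-based position
    }
    new_mention <- function(entity, parent, dep) {
      # 1- or 2-token NP; returns local position of the head
      if (runif(1) < 0.5) {
        det <- push("the", "DT", "O", "B-NP", NA, "det")
        h <- push(entity, "NN", entity_ne(entity), "I-NP", parent, dep)
        sent[[det]]$parent <<- h
      } else {
        h <- push(entity, "NN", entity_ne(entity), "B-NP", parent, dep)
      }
      h
    }
    fresh_entity <- function() {
      pool <- setdiff(doc_entities, used_entities)
      if (length(pool) == 0) pool <- doc_entities
      e <- sample(pool, 1)
      used_entities <<- union(used_entities, e)
      e
    }
    root_pos <- NA_integer_
    sent_links <- list()   # (event local pos, arg local pos, role)
    sent_coref <- list()   # (anaphor local pos, antecedent doc_index)
    cross_gold <- list()   # (event local pos, antecedent doc_index, role)
    # cross-link situation for this sentence?
    want_cross <- s > 0 && nrow(mentions) > 0 &&
      runif(1) < config$cross_link_rate
    cross_zero <- want_cross && runif(1) < config$zero_anaphora
    cross_chained <- want_cross && !cross_zero && config$chain_rate > 0
    n_ev <- 1L + rbinom(1, 1, config$trigger_rate)
    # anaphoric-argument sentences carry a second event, so resolving the
    # anaphor also means picking the right event for it
    if (cross_chained) n_ev <- 2L
    ev_pos <- integer(n_ev); ev_type <- character(n_ev)

    for (e in seq_len(n_ev)) {
      ty <- sample(config$event_types, 1)
      w <- if (runif(1) < config$noise_rate) sample(lex$ambiguous, 1) else {
        sample(lex$trigger[[ty]], 1)
      }
      pos_tag <- if (runif(1) < 0.3) "VB" else "NN"
      tp <- push(w, pos_tag, "O", "B-NP", root_pos, "conj")
      if (is.na(root_pos)) {
        root_pos <- tp
        sent[[tp]]$parent <- NA
        sent[[tp]]$dep <- "ROOT"
      }
      ev_pos[e] <- tp; ev_type[e] <- ty
      # Theme (mandatory)
      if (e == 1 && cross_chained) {
        # anaphoric mentions ("The region"-style) attach with uninformative
        # syntax: dependency evidence alone cannot identify them as arguments
        ent <- sample(unique(mentions$entity), 1)
        h <- new_mention(ent, tp, "nmod")
        prev <- mentions[mentions$entity == ent, ]
        sent_coref[[length(sent_coref) + 1]] <-
          list(ana = h, ante = max(prev$head))
        # gold closed under transitivity: all earlier mentions are arguments
        for (m in prev$head) {
          cross_gold[[length(cross_gold) + 1]] <- list(ev = tp, ante = m,
                                                       role = "Theme")
        }
        # a non-argument distractor with the same weak attachment
        new_mention(fresh_entity(), tp, "nmod")
      } else {
        h <- new_mention(fresh_entity(), tp, "obj")
      }
      sent_links[[length(sent_links) + 1]] <- list(ev = tp, arg = h,
                                                   role = "Theme")
      if (cross_zero && e == 1) {
        k <- mentions$head[sample.int(nrow(mentions), 1)]
        cross_gold[[length(cross_gold) + 1]] <- list(ev = tp, ante = k,
                                                     role = "Theme")
      }
      # optional Cause
      if (runif(1) < config$cause_rate) {
        if (e > 1 && runif(1) < 0.3) {
          sent_links[[length(sent_links) + 1]] <-
            list(ev = tp, arg = ev_pos[1], role = "Cause")
        } else {
          h2 <- new_mention(fresh_entity(), tp, "nsubj")
          sent_links[[length(sent_links) + 1]] <- list(ev = tp, arg = h2,
                                                       role = "Cause")
        }
      }
    }
    # non-argument re-mention of an earlier entity, attached exactly like an
    # anaphoric argument: clustered-ness is informative but not conclusive
    # evidence of argument-hood
    if (s > 0 && nrow(mentions) > 0 && runif(1) < config$chain_rate) {
      ent <- sample(unique(mentions$entity), 1)
      h <- new_mention(ent, root_pos, "nmod")
      prev <- mentions[mentions$entity == ent, ]
      sent_coref[[length(sent_coref) + 1]] <- list(ana = h,
                                                   ante = max(prev$head))
    }
    # pad with fillers up to the target length
    target <- sample(config$tokens[1]:config$tokens[2], 1)
    while (length(sent) < target) {
      push(sample(lex$filler, 1), sample(c("IN", "RB", "VB"), 1), "O", "O",
           root_pos, "mod")
    }
    # commit: local positions -> document-global indices
    base <- next_idx
    gl <- function(p) base + p - 1L
    for (p in seq_along(sent)) {
      tkr <- sent[[p]]
      rows[[length(rows) + 1]] <- tibble(
        doc_id = d, doc_index = gl(p), sentence_index = s,
        word = tkr$word, stem = tolower(tkr$word), pos = tkr$pos,
        ne = tkr$ne, chunk = tkr$chunk,
        head = if (is.na(tkr$parent)) NA_integer_ else gl(tkr$parent),
        dep_label = tkr$dep)
    }
    next_idx <- base + length(sent)
    for (e in seq_len(n_ev)) {
      trig_rows[[length(trig_rows) + 1]] <- tibble(
        doc_id = d, anchor = gl(ev_pos[e]), event_type = ev_type[e])
    }
    for (lk in sent_links) {
      role_rows[[length(role_rows) + 1]] <- tibble(
        doc_id = d, event_anchor = gl(lk$ev), arg_anchor = gl(lk$arg),
        role = lk$role)
    }
    for (cg in cross_gold) {
      role_rows[[length(role_rows) + 1]] <- tibble(
        doc_id = d, event_anchor = gl(cg$ev), arg_anchor = cg$ante,
        role = cg$role)
    }
    for (cr in sent_coref) {
      coref_rows[[length(coref_rows) + 1]] <- tibble(
        doc_id = d, anaphor = gl(cr$ana), antecedent = cr$ante)
    }
    # register this sentence's entity mentions
    for (p in seq_along(sent)) {
      tkr <- sent[[p]]
      if (tkr$ne != "O") {
        mentions <- bind_rows(mentions, tibble(head = gl(p), sentence = s,
                                               entity = tkr$word))
      }
    }
  }
  list(tokens = bind_rows(rows), triggers = bind_rows(trig_rows),
       roles = distinct(bind_rows(role_rows)),
       coref = bind_rows(coref_rows))
}

#' Degrade gold coreference to a target precision and recall
#'
#' Subsamples the gold links binomially to the target recall, then injects
#' spurious links among NP-head pairs outside the gold clusters until the
#' link set's precision matches the target (up to rounding). Enables
#' contrasts between system-quality and gold coreference input.
#'
#' @param corpus An `event_corpus` with gold coreference.
#' @param precision Target precision in (0, 1].
#' @param recall Target recall in \[0, 1\].
#' @param seed Random seed.
#' @return A degraded coreference tibble.
#' @export
corrupt_coref <- function(corpus, precision, recall, seed = 1L) {
  if (precision <= 0 || precision > 1) abort("precision must be in (0, 1]")
  if (recall < 0 || recall > 1) abort("recall must be in [0, 1]")
  gold <- corpus$coref
  if (precision == 1 && recall == 1) return(gold)
  set.seed(seed)
  keep <- runif(nrow(gold)) < recall
  kept <- gold[keep, ]
  n_false <- round(nrow(kept) * (1 - precision) / precision)
  if (n_false == 0) return(kept)
  clusters <- coref_closure(gold)
  cl_key <- paste(clusters$doc_id, clusters$token)
  pairs <- generate_pairs(extract_mentions(corpus$tokens))
  ca <- clusters$cluster[match(paste(pairs$doc_id, pairs$antecedent), cl_key)]
  cb <- clusters$cluster[match(paste(pairs$doc_id, pairs$anaphor), cl_key)]
  wrong <- is.na(ca) | is.na(cb) | ca != cb
  pool <- pairs[wrong, ]
  if (nrow(pool) < n_false) {
    abort("target precision unreachable: not enough non-coreferent pairs")
  }
  pick <- pool[sample.int(nrow(pool), n_false), ]
  bind_rows(kept, tibble(doc_id = pick$doc_id, anaphor = pick$anaphor,
                         antecedent = pick$antecedent)) %>%
    arrange(.data$doc_id, .data$anaphor, .data$antecedent)
}
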