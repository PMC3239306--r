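#' Event-annotated corpus objects
#'
#' An `event_corpus` bundles four keyed tibbles describing a set of documents
#' that have been tokenized, tagged and dependency parsed, together with their
#' event annotations:
#'
#' * `tokens`: one row per token with columns `doc_id`, `doc_index` (0-based,
#'   document-global), `sentence_index` (0-based), `word`, `stem`, `pos`, `ne`
#'   (named-entity tag, `"O"` for none), `chunk` (e.g. `"B-NP"`), `head`
#'   (`doc_index` of the dependency head, `NA` for a sentence root) and
#'   `dep_label`.
#' * `triggers`: event triggers, columns `doc_id`, `anchor` (token
#'   `doc_index`), `event_type`.
#' * `roles`: event-argument links, columns `doc_id`, `event_anchor`,
#'   `arg_anchor`, `role` (`"Theme"` or `"Cause"`).
#' * `coref`: directed coreference links, columns `doc_id`, `anaphor`,
#'   `antecedent` (the antecedent precedes the anaphor in document order).
#'
#' All anchors are token `doc_index` values, so cross-sentence atoms such as a
#' link from an event in sentence 2 to an antecedent in sentence 1 live in one
#' shared index space per document.
#'
#' @param tokens,triggers,roles,coref Tibbles as described above. Annotation
#'   layers may be empty tibbles with zero rows.
#' @param event_types Character vector: the event-type inventory. The label
#'   space of trigger classification is this inventory plus `"Not-Event"`.
#' @param validate Check all corpus invariants (default `TRUE`).
#' @return An object of class `event_corpus`.
#' @export
event_corpus <- function(tokens, triggers = NULL, roles = NULL, coref = NULL,
                         event_types = character(), validate = TRUE) {
  empty_triggers <- tibble(doc_id = character(), anchor = integer(),
                           event_type = character())
  empty_roles <- tibble(doc_id = character(), event_anchor = integer(),
                        arg_anchor = integer(), role = character())
  empty_coref <- tibble(doc_id = character(), anaphor = integer(),
                        antecedent = integer())
  x <- structure(list(
    tokens = as_tibble(tokens),
    triggers = if (is.null(triggers)) empty_triggers else as_tibble(triggers),
    roles = if (is.null(roles)) empty_roles else as_tibble(roles),
    coref = if (is.null(coref)) empty_coref else as_tibble(coref),
    event_types = as.character(event_types)
  ), class = "event_corpus")
  if (validate) validate_corpus(x)
  x
}

role_classes <- function() c("Theme", "Cause")

#' Validate all invariants of an event corpus
#'
#' Checks that every anchor references an existing token, that dependency
#' heads stay within their sentence and form an acyclic single-root structure,
#' that roles are `Theme`/`Cause` with distinct endpoints, that trigger types
#' are in the inventory with at most one trigger per anchor, and that every
#' coreference antecedent precedes its anaphor.
#'
#' @param corpus An `event_corpus`.
#' @return The corpus, invisibly; aborts with an informative message naming
#'   the offending field on violation.
#' @export
validate_corpus <- function(corpus) {
  tok <- corpus$tokens
  need <- c("doc_id", "doc_index", "sentence_index", "word", "stem", "pos",
            "ne", "chunk", "head", "dep_label")
  miss <- setdiff(need, names(tok))
  if (length(miss) > 0) {
    abort(paste0("tokens is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(tok[c("doc_id", "doc_index")])) {
    abort("tokens: duplicated (doc_id, doc_index)")
  }
  # heads stay in-sentence and the per-sentence head relation is a tree
  for (d in unique(tok$doc_id)) {
    td <- tok[tok$doc_id == d, ]
    td <- td[order(td$doc_index), ]
    idx <- td$doc_index
    sent_of <- setNames(td$sentence_index, as.character(idx))
    has_head <- !is.na(td$head)
    if (any(!td$head[has_head] %in% idx)) {
      abort(paste0("tokens: head outside document in doc ", d))
    }
    if (any(sent_of[as.character(td$head[has_head])] !=
            td$sentence_index[has_head])) {
      abort(paste0("tokens: head crosses a sentence boundary in doc ", d))
    }
    for (s in unique(td$sentence_index)) {
      ts <- td[td$sentence_index == s, ]
      if (sum(is.na(ts$head)) != 1) {
        abort(paste0("tokens: sentence ", s, " of doc ", d,
                     " must have exactly one root"))
      }
      # acyclicity: walk each token to the root
      parent <- setNames(ts$head, as.character(ts$doc_index))
      for (i in ts$doc_index) {
        seen <- character()
        cur <- as.character(i)
        while (!is.na(parent[[cur]])) {
          if (cur %in% seen) {
            abort(paste0("tokens: dependency cycle in doc ", d,
                         " sentence ", s))
          }
          seen <- c(seen, cur)
          cur <- as.character(parent[[cur]])
        }
      }
    }
  }
  check_anchor <- function(layer, col) {
    df <- corpus[[layer]]
    if (nrow(df) == 0) return(invisible())
    key <- paste(df$doc_id, df[[col]])
    ok <- key %in% paste(tok$doc_id, tok$doc_index)
    if (!all(ok)) {
      abort(paste0(layer, "$", col, ": anchor not a token (first bad: ",
                   key[!ok][1], ")"))
    }
  }
  check_anchor("triggers", "anchor")
  check_anchor("roles", "event_anchor")
  check_anchor("roles", "arg_anchor")
  check_anchor("coref", "anaphor")
  check_anchor("coref", "antecedent")
  if (nrow(corpus$triggers) > 0) {
    if (anyDuplicated(corpus$triggers[c("doc_id", "anchor")])) {
      abort("triggers: more than one trigger per anchor token")
    }
    bad <- setdiff(unique(corpus$triggers$event_type), corpus$event_types)
    if (length(bad) > 0) {
      abort(paste0("triggers$event_type: not in inventory: ",
                   paste(bad, collapse = ", ")))
    }
  }
  if (nrow(corpus$roles) > 0) {
    if (any(corpus$roles$event_anchor == corpus$roles$arg_anchor)) {
      abort("roles: event_anchor equals arg_anchor")
    }
    if (!all(corpus$roles$role %in% role_classes())) {
      abort("roles$role: must be Theme or Cause")
    }
  }
  if (nrow(corpus$coref) > 0 &&
      !all(corpus$coref$antecedent < corpus$coref$anaphor)) {
    abort("coref: antecedent must precede anaphor")
  }
  invisible(corpus)
}

#' @export
print.event_corpus <- function(x, ...) {
  cat("<event_corpus> ", length(unique(x$tokens$doc_id)), " document(s), ",
      nrow(x$tokens), " tokens, ", nrow(x$triggers), " triggers, ",
      nrow(x$roles), " role links, ", nrow(x$coref),
      " coreference links\n", sep = "")
  cat("  event types: ", paste(x$event_types, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Restrict a corpus to a subset of documents
#'
#' @param corpus An `event_corpus`.
#' @param doc_ids Character vector of document ids to keep.
#' @return An `event_corpus` with all layers filtered.
#' @export
corpus_subset <- function(corpus, doc_ids) {
  event_corpus(
    tokens = filter(corpus$tokens, .data$doc_id %in% doc_ids),
    triggers = filter(corpus$triggers, .data$doc_id %in% doc_ids),
    roles = filter(corpus$roles, .data$doc_id %in% doc_ids),
    coref = filter(corpus$coref, .data$doc_id %in% doc_ids),
    event_types = corpus$event_types, validate = FALSE
  )
}

#' Anchor token of a phrasal span
#'
#' Phrasal mentions are represented by a single anchor token: the root of the
#' span on the sentence's dependency tree, i.e. the unique token whose head
#' lies outside the span. If the (possibly ill-parsed) span has several such
#' tokens, the leftmost qualifies.
#'
#' @param tokens Token tibble of one document (columns as in
#'   [event_corpus()]).
#' @param span Integer vector of token `doc_index` values; must be non-empty
#'   and lie within one sentence.
#' @return The anchor token's `doc_index`.
#' @export
anchor_token <- function(tokens, span) {
  if (length(span) == 0) abort("span is empty")
  rows <- tokens[match(span, tokens$doc_index), ]
  if (anyNA(rows$doc_index)) abort("span references unknown tokens")
  if (length(unique(rows$sentence_index)) > 1) {
    abort("span crosses a sentence boundary")
  }
  exits <- is.na(rows$head) | !(rows$head %in% span)
  if (!any(exits)) abort("span has no token with head outside the span")
  min(rows$doc_index[exits])
}

#' Entity clusters from coreference links
#'
#' Takes the symmetric-transitive closure of the (directed) coreference links:
#' tokens connected by any chain of links belong to one entity cluster.
#' Clusters never span documents.
#'
#' @param coref Coreference tibble (`doc_id`, `anaphor`, `antecedent`).
#' @return A tibble with columns `doc_id`, `token`, `cluster` (an integer id,
#'   arbitrary but stable given the input). Tokens not mentioned in any link
#'   do not appear; they are implicit singletons.
#' @export
coref_closure <- function(coref) {
  if (nrow(coref) == 0) {
    return(tibble(doc_id = character(), token = integer(), cluster = integer()))
  }
  v <- unique(c(paste0(coref$doc_id, "\r", coref$anaphor),
                paste0(coref$doc_id, "\r", coref$antecedent)))
  v <- sort(v)
  g <- igraph::graph_from_data_frame(
    data.frame(from = paste0(coref$doc_id, "\r", coref$anaphor),
               to = paste0(coref$doc_id, "\r", coref$antecedent)),
    directed = FALSE, vertices = v
  )
  comp <- igraph::components(g)
  parts <- strsplit(names(comp$membership), "\r", fixed = TRUE)
  tibble(
    doc_id = vapply(parts, `[[`, "", 1L),
    token = as.integer(vapply(parts, `[[`, "", 2L)),
    cluster = as.integer(comp$membership)
  ) %>% arrange(.data$doc_id, .data$token)
}

#' Cluster mates of a token
#'
#' @param clusters Output of [coref_closure()].
#' @param doc One document id.
#' @param token A token `doc_index`.
#' @param before_only Keep only mates that precede `token` (antecedents).
#' @return Integer vector of cluster-mate `doc_index` values (excluding
#'   `token` itself); empty if the token is unclustered.
#' @export
cluster_mates <- function(clusters, doc, token, before_only = FALSE) {
  cl <- clusters$cluster[clusters$doc_id == doc & clusters$token == token]
  if (length(cl) == 0) return(integer())
  mates <- clusters$token[clusters$doc_id == doc & clusters$cluster == cl[1]]
  mates <- setdiff(mates, token)
  if (before_only) mates <- mates[mates < token]
  sort(mates)
}

#' Categorize event-argument links as Cross, W-ANT or Normal
#'
#' Every event-argument link falls into exactly one of three categories:
#' `Cross` if it crosses a sentence boundary; otherwise `W-ANT` if its
#' argument token belongs to a non-singleton entity cluster (the argument has
#' coreferent mentions elsewhere); otherwise `Normal`.
#'
#' @param links Role-link tibble (`doc_id`, `event_anchor`, `arg_anchor`,
#'   `role`).
#' @param clusters Entity clusters from [coref_closure()], conventionally
#'   computed from *gold* coreference so categories are comparable across
#'   systems.
#' @param tokens Token tibble covering the linked documents.
#' @return `links` with an added `category` factor column.
#' @export
categorize_links <- function(links, clusters, tokens) {
  if (nrow(links) == 0) {
    links$category <- factor(character(), levels = c("Cross", "W-ANT", "Normal"))
    return(links)
  }
  sent <- setNames(tokens$sentence_index, paste(tokens$doc_id, tokens$doc_index))
  s_ev <- sent[paste(links$doc_id, links$event_anchor)]
  s_ar <- sent[paste(links$doc_id, links$arg_anchor)]
  clustered <- paste(links$doc_id, links$arg_anchor) %in%
    paste(clusters$doc_id, clusters$token)
  cat <- ifelse(s_ev != s_ar, "Cross", ifelse(clustered, "W-ANT", "Normal"))
  links$category <- factor(cat, levels = c("Cross", "W-ANT", "Normal"))
  links
}

#' Candidate argument tokens for one sentence
#'
#' Argument candidates for the events of a sentence are all tokens of that
#' sentence plus every earlier-sentence token that is an antecedent (a
#' cluster mate in an earlier sentence) of some token in the sentence. With no
#' coreference information the candidates are exactly the sentence's tokens —
#' which is why systems without coreference cannot, structurally, propose
#' cross-sentence links.
#'
#' @param tokens Token tibble of one document.
#' @param doc The document id.
#' @param sentence A `sentence_index` present in the document.
#' @param clusters Entity clusters from [coref_closure()] (possibly empty).
#' @return Sorted integer vector of candidate `doc_index` values.
#' @export
candidate_arguments <- function(tokens, doc, sentence, clusters) {
  td <- tokens[tokens$doc_id == doc, ]
  own <- td$doc_index[td$sentence_index == sentence]
  extra <- integer()
  if (nrow(clusters) > 0) {
    sent_of <- setNames(td$sentence_index, as.character(td$doc_index))
    for (j in own) {
      mates <- cluster_mates(clusters, doc, j)
      if (length(mates) > 0) {
        earlier <- mates[sent_of[as.character(mates)] < sentence]
        extra <- c(extra, earlier)
      }
    }
  }
  sort(unique(c(own, extra)))
}
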