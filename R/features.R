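#' Build an event-trigger lexicon from gold triggers
#'
#' The dictionary-membership feature fires when a token's stem occurs among
#' the stems of gold trigger anchors in the *training* documents, so no
#' external lexical resource is needed.
#'
#' @param corpus An `event_corpus` (training split).
#' @return Character vector of trigger stems.
#' @export
build_trigger_lexicon <- function(corpus) {
  if (nrow(corpus$triggers) == 0) return(character())
  key <- paste(corpus$triggers$doc_id, corpus$triggers$anchor)
  stems <- corpus$tokens$stem[match(key, paste(corpus$tokens$doc_id,
                                               corpus$tokens$doc_index))]
  sort(unique(stems))
}

char_ngrams <- function(word, n) {
  len <- nchar(word)
  if (len < n) return(character())
  substring(word, seq_len(len - n + 1), seq_len(len - n + 1) + n - 1)
}

#' Local features of single tokens
#'
#' Emits, per token, the simple-token-property features: word form, POS,
#' stem, named-entity tag, chunk tag, trigger-dictionary membership,
#' capital/numeric/punctuation character flags, character bigrams and
#' trigrams, and the token's incoming dependency label.
#'
#' @param tokens A token tibble (any number of documents).
#' @param lexicon Trigger lexicon from [build_trigger_lexicon()].
#' @return A long tibble `doc_id`, `doc_index`, `feature`, `count`.
#' @export
token_features <- function(tokens, lexicon = character()) {
  tk <- tokens
  base <- tibble(
    doc_id = rep(tk$doc_id, 6),
    doc_index = rep(tk$doc_index, 6),
    feature = c(paste0("word=", tk$word), paste0("pos=", tk$pos),
                paste0("stem=", tk$stem), paste0("ne=", tk$ne),
                paste0("chunk=", tk$chunk),
                paste0("dep=", ifelse(is.na(tk$dep_label), "ROOT",
                                      tk$dep_label)))
  )
  flags <- list(
    dict = tk$stem %in% lexicon,
    capital = grepl("[A-Z]", tk$word),
    numeric = grepl("[0-9]", tk$word),
    punct = grepl("[^A-Za-z0-9]", tk$word)
  )
  flag_rows <- purrr::imap(flags, function(on, nm) {
    tibble(doc_id = tk$doc_id[on], doc_index = tk$doc_index[on], feature = nm)
  })
  # n-grams computed once per distinct word form, then joined back
  uw <- unique(tk$word)
  grams <- purrr::map(uw, function(w) {
    c(paste0("bi=", char_ngrams(w, 2)), paste0("tri=", char_ngrams(w, 3)))
  })
  names(grams) <- uw
  ng_per_tok <- grams[tk$word]
  ng <- tibble(
    doc_id = rep(tk$doc_id, lengths(ng_per_tok)),
    doc_index = rep(tk$doc_index, lengths(ng_per_tok)),
    feature = unlist(ng_per_tok, use.names = FALSE) %||% character()
  )
  bind_rows(base, bind_rows(flag_rows), ng) %>%
    dplyr::count(.data$doc_id, .data$doc_index, .data$feature,
                 name = "count") %>%
    arrange(.data$doc_id, .data$doc_index, .data$feature)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sentence_parents <- function(tokens_sent) {
  setNames(tokens_sent$head, as.character(tokens_sent$doc_index))
}

path_to_root <- function(parent, i) {
  path <- i
  cur <- as.character(i)
  while (!is.na(parent[[cur]])) {
    cur <- as.character(parent[[cur]])
    path <- c(path, as.integer(cur))
  }
  path
}

#' Dependency path between two tokens of one sentence
#'
#' The unique path in the (undirected) dependency tree, rendered with rise
#' (`^`) and descent (`v`) markers: the labeled variant interleaves the
#' dependency label of each edge, the unlabeled variant keeps directions
#' only. The least common ancestor is the path's topmost node.
#'
#' @param tokens Token tibble covering the sentence of `i` and `j`.
#' @param i,j Token `doc_index` values; must share a sentence.
#' @return A list with `labeled`, `unlabeled` (strings, empty for `i == j`)
#'   and `lca` (a `doc_index`).
#' @export
dependency_path <- function(tokens, i, j) {
  ri <- tokens[match(c(i, j), tokens$doc_index), ]
  if (anyNA(ri$doc_index)) abort("unknown token index")
  if (ri$sentence_index[1] != ri$sentence_index[2] ||
      (length(unique(tokens$doc_id)) > 1 && ri$doc_id[1] != ri$doc_id[2])) {
    abort("dependency paths are intra-sentence only")
  }
  ts <- tokens[tokens$doc_id == ri$doc_id[1] &
                 tokens$sentence_index == ri$sentence_index[1], ]
  if (i == j) return(list(labeled = "", unlabeled = "", lca = i))
  parent <- sentence_parents(ts)
  lab <- setNames(ts$dep_label, as.character(ts$doc_index))
  pi <- path_to_root(parent, i)
  pj <- path_to_root(parent, j)
  common <- intersect(pi, pj)
  lca <- pi[min(match(common, pi))]
  up <- pi[seq_len(match(lca, pi) - 1)]        # i .. just below lca
  down <- rev(pj[seq_len(match(lca, pj) - 1)]) # just below lca .. j
  labeled <- paste0(
    paste0(vapply(up, function(t) paste0("^", lab[[as.character(t)]]),
                  character(1)), collapse = ""),
    paste0(vapply(down, function(t) paste0("v", lab[[as.character(t)]]),
                  character(1)), collapse = "")
  )
  unlabeled <- paste0(strrep("^", length(up)), strrep("v", length(down)))
  list(labeled = labeled, unlabeled = unlabeled, lca = lca)
}

#' Link-token features of an intra-sentence token pair
#'
#' The linked-tokens-property features of a pair `(i, j)`: the dependency
#' label when one token heads the other, the labeled and unlabeled dependency
#' paths, and the word of the least common ancestor.
#'
#' @inheritParams dependency_path
#' @return Character vector of feature strings.
#' @export
pair_features <- function(tokens, i, j) {
  dp <- dependency_path(tokens, i, j)
  out <- c(paste0("path=", dp$labeled), paste0("pathNL=", dp$unlabeled),
           paste0("lca=", tokens$word[match(dp$lca, tokens$doc_index)]))
  hi <- tokens$head[match(i, tokens$doc_index)]
  hj <- tokens$head[match(j, tokens$doc_index)]
  if (!is.na(hj) && hj == i) {
    out <- c(out, paste0("dep=", tokens$dep_label[match(j, tokens$doc_index)]))
  } else if (!is.na(hi) && hi == j) {
    out <- c(out, paste0("dep=", tokens$dep_label[match(i, tokens$doc_index)]))
  }
  out
}

dependency_children <- function(tokens_doc, k) {
  tokens_doc$doc_index[!is.na(tokens_doc$head) & tokens_doc$head == k]
}

copied_basic_features <- function(tokens_doc, k) {
  fam <- c(k, dependency_children(tokens_doc, k))
  rows <- tokens_doc[match(fam, tokens_doc$doc_index), ]
  c(paste0("word=", rows$word), paste0("pos=", rows$pos),
    paste0("ne=", rows$ne))
}

#' Copied features of an anaphoric token
#'
#' Feature copy supplements an anaphor's representation with the basic
#' features of its antecedents: for every earlier cluster mate `k` of token
#' `j`, the word/POS/NE of `k` and of `k`'s dependency children are emitted
#' under a distinguishing `copy:` namespace, so a learner can weight copied
#' evidence separately from the token's own features. An unclustered token
#' yields an empty vector.
#'
#' @param tokens Token tibble of one document.
#' @param clusters Entity clusters from [coref_closure()].
#' @param doc Document id.
#' @param j Anaphor token `doc_index`.
#' @return Character vector of `copy:`-prefixed feature strings (unique).
#' @export
copy_features <- function(tokens, clusters, doc, j) {
  mates <- cluster_mates(clusters, doc, j, before_only = TRUE)
  if (length(mates) == 0) return(character())
  td <- tokens[tokens$doc_id == doc, ]
  unique(paste0("copy:", unlist(lapply(mates, function(k) {
    copied_basic_features(td, k)
  }))))
}
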