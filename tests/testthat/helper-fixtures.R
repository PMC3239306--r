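# Shared fixtures and independent oracles used across the test files.

# A two-sentence document with a cross-sentence Theme mediated by
# coreference: sentence 1 introduces "The IRF-2 promoter region" (anchor 4),
# sentence 2 has the event "inducible" (13) with the anaphoric Theme
# "The region" (11) and the Cause "interferons" (15); corefer(11, 4).
fig1_corpus <- function() {
  tok <- function(doc_index, sentence_index, word, pos, ne, chunk, head,
                  dep_label) {
    tibble::tibble(doc_id = "fig1", doc_index = doc_index,
                   sentence_index = sentence_index, word = word,
                   stem = tolower(word), pos = pos, ne = ne, chunk = chunk,
                   head = head, dep_label = dep_label)
  }
  tokens <- dplyr::bind_rows(
    tok(0L, 0L, "Here", "RB", "O", "O", 5L, "mod"),
    tok(1L, 0L, "The", "DT", "O", "B-NP", 4L, "det"),
    tok(2L, 0L, "IRF-2", "NN", "Protein", "I-NP", 4L, "nmod"),
    tok(3L, 0L, "promoter", "NN", "O", "I-NP", 4L, "nmod"),
    tok(4L, 0L, "region", "NN", "Protein", "I-NP", 5L, "nsubj"),
    tok(5L, 0L, "contains", "VB", "O", "O", NA, "ROOT"),
    tok(6L, 0L, "elements", "NN", "O", "B-NP", 5L, "obj"),
    tok(7L, 1L, "Interestingly", "RB", "O", "O", 13L, "mod"),
    tok(8L, 1L, "in", "IN", "O", "O", 13L, "mod"),
    tok(9L, 1L, "cells", "NN", "O", "O", 8L, "pobj"),
    tok(10L, 1L, "The", "DT", "O", "B-NP", 11L, "det"),
    tok(11L, 1L, "region", "NN", "Protein", "I-NP", 13L, "nsubj"),
    tok(12L, 1L, "was", "VB", "O", "O", 13L, "aux"),
    tok(13L, 1L, "inducible", "NN", "O", "B-NP", NA, "ROOT"),
    tok(14L, 1L, "by", "IN", "O", "O", 15L, "case"),
    tok(15L, 1L, "interferons", "NN", "Protein", "B-NP", 13L, "obl"),
    tok(16L, 1L, ".", ".", "O", "O", 13L, "punct")
  )
  event_corpus(
    tokens = tokens,
    triggers = tibble::tibble(doc_id = "fig1", anchor = 13L,
                              event_type = "Activation"),
    roles = tibble::tibble(doc_id = "fig1",
                           event_anchor = c(13L, 13L, 13L),
                           arg_anchor = c(11L, 15L, 4L),
                           role = c("Theme", "Cause", "Theme")),
    coref = tibble::tibble(doc_id = "fig1", anaphor = 11L, antecedent = 4L),
    event_types = c("Activation", "Binding")
  )
}

# reflexive-symmetric-transitive closure by Floyd-Warshall reachability;
# independent of the package's component-based implementation
closure_oracle <- function(links) {
  toks <- sort(unique(c(links$anaphor, links$antecedent)))
  n <- length(toks)
  m <- diag(TRUE, n)
  for (k in seq_len(nrow(links))) {
    a <- match(links$anaphor[k], toks); b <- match(links$antecedent[k], toks)
    m[a, b] <- m[b, a] <- TRUE
  }
  for (mid in seq_len(n)) for (a in seq_len(n)) for (b in seq_len(n)) {
    if (m[a, mid] && m[mid, b]) m[a, b] <- TRUE
  }
  # cluster label = smallest reachable token
  vapply(seq_len(n), function(a) toks[min(which(m[a, ]))], numeric(1)) |>
    stats::setNames(toks)
}

# shortest undirected path in the dependency graph by breadth-first search
bfs_path_oracle <- function(tokens_sent, i, j) {
  edges <- tokens_sent[!is.na(tokens_sent$head),
                       c("doc_index", "head")]
  adj <- list()
  add_edge <- function(a, b) {
    adj[[as.character(a)]] <<- c(adj[[as.character(a)]], b)
  }
  for (k in seq_len(nrow(edges))) {
    add_edge(edges$doc_index[k], edges$head[k])
    add_edge(edges$head[k], edges$doc_index[k])
  }
  frontier <- list(i); seen <- i; parent <- list()
  while (length(frontier) > 0) {
    nxt <- list()
    for (v in frontier) {
      for (w in adj[[as.character(v)]]) {
        if (!(w %in% seen)) {
          seen <- c(seen, w)
          parent[[as.character(w)]] <- v
          nxt[[length(nxt) + 1]] <- w
        }
      }
    }
    frontier <- nxt
  }
  path <- j; cur <- j
  while (cur != i) { cur <- parent[[as.character(cur)]]; path <- c(cur, path) }
  path
}

# random single-root dependency tree over n tokens (doc_index 0..n-1),
# as a token tibble for one sentence
random_tree_tokens <- function(n, doc = "rt", sentence = 0L) {
  head <- rep(NA_integer_, n)
  if (n > 1) for (k in 2:n) head[k] <- sample(seq_len(k - 1), 1) - 1L
  tibble::tibble(
    doc_id = doc, doc_index = 0:(n - 1), sentence_index = sentence,
    word = paste0("w", 0:(n - 1)), stem = paste0("w", 0:(n - 1)),
    pos = "NN", ne = "O", chunk = "O", head = head,
    dep_label = ifelse(is.na(head), "ROOT", sample(c("a", "b", "c"), n,
                                                   replace = TRUE))
  )
}

# a small random clause network over n atoms for MAP-inference checks
random_network <- function(n, n_clauses = 6, seed = 1) {
  set.seed(seed)
  atoms <- tibble::tibble(name = paste0("x", seq_len(n)), pred = "x")
  local <- lapply(seq_len(n), function(k) paste0("u", k))
  weights <- stats::setNames(round(stats::rnorm(n), 2), paste0("u", seq_len(n)))
  clauses <- list()
  for (k in seq_len(n_clauses)) {
    sz <- sample(1:min(3, n), 1)
    ids <- sample(n, sz)
    nn <- rbinom(1, sz, 0.5)
    hard <- runif(1) < 0.2
    key <- paste0("c", k)
    if (!hard) weights[key] <- round(stats::rnorm(1), 2)
    neg <- ids[seq_len(nn)]
    pos <- setdiff(ids, neg)
    if (hard && length(pos) == 0 && length(neg) == 0) next
    clauses[[length(clauses) + 1]] <- list(
      neg = neg, pos = pos, key = if (hard) NA_character_ else key,
      hard = hard)
  }
  list(network = mln_network(atoms, local, clauses), weights = weights)
}

small_sim <- function(n_docs = 12, seed = 5, ...) {
  simulate_corpus(synthetic_config(n_docs = n_docs, ...), seed = seed)
}
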