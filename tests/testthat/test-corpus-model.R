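test_that("anchor_token returns the span's subtree root, leftmost on ties", {
  cp <- fig1_corpus()
  tk <- cp$tokens
  # single-token span is its own anchor
  expect_identical(anchor_token(tk, 6L), 6L)
  # "The IRF-2 promoter region": only "region" (4) has its head outside
  expect_identical(anchor_token(tk, 1:4), 4L)
  # brute-force check: enumerate tokens whose head exits the span
  span <- 1:4
  rows <- tk[tk$doc_index %in% span, ]
  exits <- rows$doc_index[is.na(rows$head) | !(rows$head %in% span)]
  expect_identical(anchor_token(tk, span), min(exits))
  # two tokens both headed outside the span: leftmost wins
  # (tokens 7 and 8 both attach to 13)
  expect_identical(anchor_token(tk, 7:8), 7L)
  expect_error(anchor_token(tk, c(4L, 13L)), "sentence boundary")
  expect_error(anchor_token(tk, integer()), "empty")
})

test_that("coref_closure matches a Floyd-Warshall closure oracle", {
  # no links: nothing clustered
  expect_identical(nrow(coref_closure(tibble::tibble(
    doc_id = character(), anaphor = integer(), antecedent = integer()))), 0L)
  # the two-mention chain from the worked example
  cl <- coref_closure(tibble::tibble(doc_id = "d", anaphor = 11L,
                                     antecedent = 4L))
  expect_setequal(cl$token, c(4L, 11L))
  expect_identical(length(unique(cl$cluster)), 1L)
  # a three-link chain collapses into one cluster
  chain <- tibble::tibble(doc_id = "d", anaphor = c(5L, 9L), antecedent = c(2L, 5L))
  cl <- coref_closure(chain)
  expect_identical(length(unique(cl$cluster)), 1L)
  # randomized instances against the oracle
  for (seed in 1:20) {
    set.seed(seed)
    n_links <- sample(1:10, 1)
    ana <- sample(5:20, n_links, replace = TRUE)
    ante <- vapply(ana, function(a) sample(seq_len(a - 1), 1), integer(1))
    links <- dplyr::distinct(tibble::tibble(doc_id = "d", anaphor = ana,
                                            antecedent = ante))
    got <- coref_closure(links)
    oracle <- closure_oracle(links)
    expect_setequal(got$token, as.integer(names(oracle)))
    # same-cluster relation must agree exactly
    for (a in got$token) for (b in got$token) {
      same_got <- got$cluster[got$token == a] == got$cluster[got$token == b]
      same_or <- oracle[[as.character(a)]] == oracle[[as.character(b)]]
      expect_identical(same_got, same_or)
    }
  }
})

test_that("link categorization follows Cross > W-ANT > Normal and partitions", {
  cp <- fig1_corpus()
  cl <- coref_closure(cp$coref)
  cat <- categorize_links(cp$roles, cl, cp$tokens)
  lab <- stats::setNames(as.character(cat$category), cat$arg_anchor)
  expect_identical(lab[["4"]], "Cross")    # event in S2, argument in S1
  expect_identical(lab[["11"]], "W-ANT")   # intra, argument clustered
  expect_identical(lab[["15"]], "Normal")  # intra, unclustered
  # partition property on a generated corpus
  cp2 <- small_sim(15)
  cl2 <- coref_closure(cp2$coref)
  cat2 <- categorize_links(cp2$roles, cl2, cp2$tokens)
  expect_false(anyNA(cat2$category))
  expect_identical(sum(table(cat2$category)), nrow(cp2$roles))
})

test_that("candidate arguments extend the sentence by its antecedents only", {
  cp <- fig1_corpus()
  none <- coref_closure(cp$coref[0, ])
  cl <- coref_closure(cp$coref)
  s1_tokens <- cp$tokens$doc_index[cp$tokens$sentence_index == 1]
  # empty coreference layer: the sentence's own tokens, nothing else
  expect_identical(candidate_arguments(cp$tokens, "fig1", 1L, none),
                   sort(s1_tokens))
  # corefer(11, 4) adds token 4 to sentence 2's candidates
  expect_identical(candidate_arguments(cp$tokens, "fig1", 1L, cl),
                   sort(c(s1_tokens, 4L)))
  # a chain 20 -> 11 -> 4 exposes both earlier mentions to the last sentence
  tk3 <- dplyr::bind_rows(cp$tokens, tibble::tibble(
    doc_id = "fig1", doc_index = 17:20, sentence_index = 2L,
    word = c("It", "bound", "the", "region"), stem = c("it", "bound", "the", "region"),
    pos = c("PR", "VB", "DT", "NN"), ne = c("O", "O", "O", "Protein"),
    chunk = c("O", "O", "B-NP", "I-NP"),
    head = c(18L, NA, 20L, 18L), dep_label = c("nsubj", "ROOT", "det", "obj")))
  cl3 <- coref_closure(tibble::tibble(doc_id = "fig1",
                                      anaphor = c(11L, 20L),
                                      antecedent = c(4L, 11L)))
  cands <- candidate_arguments(tk3, "fig1", 2L, cl3)
  expect_true(all(c(4L, 11L) %in% cands))
  # monotone in the coreference layer
  expect_true(all(candidate_arguments(cp$tokens, "fig1", 1L, none) %in%
                    candidate_arguments(cp$tokens, "fig1", 1L, cl)))
})

test_that("corpus validation rejects broken structures", {
  cp <- fig1_corpus()
  bad <- cp$tokens
  bad$head[bad$doc_index == 11] <- 4L  # head crosses sentence boundary
  expect_error(event_corpus(bad, cp$triggers, cp$roles, cp$coref,
                            cp$event_types), "sentence boundary")
  expect_error(event_corpus(cp$tokens, cp$triggers, cp$roles,
                            tibble::tibble(doc_id = "fig1", anaphor = 4L,
                                           antecedent = 11L),
                            cp$event_types), "precede")
  expect_error(event_corpus(cp$tokens,
                            tibble::tibble(doc_id = "fig1", anchor = 13L,
                                           event_type = "NotAType"),
                            event_types = cp$event_types), "inventory")
})
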