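test_that("generation is deterministic and validated", {
  cfg <- synthetic_config(n_docs = 15)
  a <- simulate_corpus(cfg, seed = 81)
  b <- simulate_corpus(cfg, seed = 81)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_corpus_jsonl(a, f1); write_corpus_jsonl(b, f2)
  expect_identical(readLines(f1), readLines(f2))
  # a different seed gives a different corpus
  c2 <- simulate_corpus(cfg, seed = 82)
  expect_false(identical(a$tokens$word, c2$tokens$word))
  # every generated document passes validation (constructor validates) and
  # round-trips through the canonical format
  back <- read_corpus_jsonl(f1)
  expect_identical(nrow(back$tokens), nrow(a$tokens))
})

test_that("configuration rates are checked", {
  expect_error(synthetic_config(trigger_rate = 1.2), "rates")
  expect_error(synthetic_config(chain_rate = 0, cross_link_rate = 0.4,
                                zero_anaphora = 0.5), "chain_rate")
  # all-zero-anaphora cross-links need no chains
  expect_s3_class(synthetic_config(chain_rate = 0, cross_link_rate = 0.4,
                                   zero_anaphora = 1), "synthetic_config")
})

test_that("cross-link structure follows the configured rates", {
  # no cross situations: every link is intra-sentence
  cp0 <- simulate_corpus(synthetic_config(n_docs = 10, cross_link_rate = 0),
                         seed = 83)
  sent <- stats::setNames(cp0$tokens$sentence_index,
                          paste(cp0$tokens$doc_id, cp0$tokens$doc_index))
  expect_true(all(sent[paste(cp0$roles$doc_id, cp0$roles$event_anchor)] ==
                    sent[paste(cp0$roles$doc_id, cp0$roles$arg_anchor)]))
  # gold role links are closed under transitivity over gold chains
  cp <- simulate_corpus(synthetic_config(n_docs = 20), seed = 84)
  cl <- coref_closure(cp$coref)
  closed <- propagate_transitivity(cp$roles, cl)
  expect_identical(nrow(closed), nrow(cp$roles))
})

test_that("the zero-anaphora fraction matches its binomial expectation", {
  # classify each event carrying cross-links as chained (some cross argument
  # has a cluster mate inside the event's sentence) or zero-anaphora (no
  # bridging chain); the zero count is Binomial(n, 0.20) per construction
  cp <- simulate_corpus(synthetic_config(n_docs = 150), seed = 85)
  cl <- coref_closure(cp$coref)
  cats <- categorize_links(cp$roles, cl, cp$tokens)
  cross <- cats[cats$category == "Cross", ]
  sent <- stats::setNames(cp$tokens$sentence_index,
                          paste(cp$tokens$doc_id, cp$tokens$doc_index))
  ev <- unique(cross[c("doc_id", "event_anchor")])
  chained <- vapply(seq_len(nrow(ev)), function(k) {
    d <- ev$doc_id[k]; e <- ev$event_anchor[k]
    args <- cross$arg_anchor[cross$doc_id == d & cross$event_anchor == e]
    s_ev <- sent[[paste(d, e)]]
    any(vapply(args, function(a) {
      mates <- cluster_mates(cl, d, a)
      any(sent[paste(d, mates)] == s_ev, na.rm = TRUE)
    }, logical(1)))
  }, logical(1))
  n <- nrow(ev)
  n_zero <- sum(!chained)
  band <- stats::qbinom(c(0.005, 0.995), n, 0.20)
  expect_gte(n_zero, band[1])
  expect_lte(n_zero, band[2])
})

test_that("every gold event keeps at least one Theme (hard-constraint shape)", {
  cp <- simulate_corpus(synthetic_config(n_docs = 25), seed = 86)
  themes <- cp$roles[cp$roles$role == "Theme", ]
  expect_true(all(paste(cp$triggers$doc_id, cp$triggers$anchor) %in%
                    paste(themes$doc_id, themes$event_anchor)))
  # and the intra-sentence Theme survives candidate restriction: for every
  # event some Theme argument lies in the event's own sentence
  sent <- stats::setNames(cp$tokens$sentence_index,
                          paste(cp$tokens$doc_id, cp$tokens$doc_index))
  intra <- themes[sent[paste(themes$doc_id, themes$event_anchor)] ==
                    sent[paste(themes$doc_id, themes$arg_anchor)], ]
  expect_true(all(paste(cp$triggers$doc_id, cp$triggers$anchor) %in%
                    paste(intra$doc_id, intra$event_anchor)))
})

test_that("coreference corruption hits the requested precision and recall", {
  cp <- simulate_corpus(synthetic_config(n_docs = 120, chain_rate = 0.5),
                        seed = 87)
  gold <- cp$coref
  # identity at (1, 1)
  expect_identical(corrupt_coref(cp, 1, 1), gold)
  # recall subsampling is binomial
  half <- corrupt_coref(cp, precision = 1, recall = 0.5, seed = 2)
  band <- stats::qbinom(c(0.005, 0.995), nrow(gold), 0.5)
  expect_gte(nrow(half), band[1]); expect_lte(nrow(half), band[2])
  # achieved precision close to target after injection
  deg <- corrupt_coref(cp, precision = 0.7, recall = 0.9, seed = 3)
  cl <- coref_closure(gold)
  key <- paste(cl$doc_id, cl$token)
  ca <- cl$cluster[match(paste(deg$doc_id, deg$antecedent), key)]
  cb <- cl$cluster[match(paste(deg$doc_id, deg$anaphor), key)]
  correct <- !is.na(ca) & !is.na(cb) & ca == cb
  expect_lt(abs(mean(correct) - 0.7), 0.02)
  expect_error(corrupt_coref(cp, precision = 0, recall = 1), "precision")
})
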