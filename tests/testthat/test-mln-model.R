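ground_fig1 <- function(spec, coref = NULL) {
  cp <- fig1_corpus()
  clusters <- coref_closure(coref %||% cp$coref[0, ])
  lexicon <- build_trigger_lexicon(cp)
  tok_feats <- corevent:::token_feature_list(cp$tokens, lexicon)
  names(tok_feats) <- paste(cp$tokens$doc_id, cp$tokens$doc_index)
  corevent:::mln_ground(cp$tokens, "fig1", 1L, spec, clusters, lexicon,
                        tok_feats, cp$event_types)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("observed atoms cover token, pair, corefer and copied predicates", {
  cp <- fig1_corpus()
  obs <- build_observed_atoms(cp, coref = cp$coref, with_fc = TRUE,
                              lexicon = build_trigger_lexicon(cp))
  at <- function(p, i) obs[obs$pred == p & obs$i == i, ]
  # "IRF-2" carries the character-class atoms
  expect_gt(nrow(at("capital", 2L)), 0)
  expect_gt(nrow(at("numeric", 2L)), 0)
  expect_gt(nrow(at("punc", 2L)), 0)
  # corefer atoms appear in both directions (symmetric closure)
  crf <- obs[obs$pred == "corefer", ]
  expect_setequal(paste(crf$i, crf$j), c("11 4", "4 11"))
  # copied atoms exist for the anaphor when feature copy is on
  expect_true(any(obs$pred == "copied" & obs$i == 11L))
  expect_true(any(obs$pred == "copied" & obs$value == "copy:word=IRF-2"))
  # token-atom counts agree with an independent re-extraction
  tf <- token_features(cp$tokens, build_trigger_lexicon(cp))
  tok_preds <- c("word", "pos", "stem", "ne", "chunk", "dep", "dict",
                 "capital", "numeric", "punc", "bi", "tri")
  expect_identical(sum(obs$pred %in% tok_preds & is.na(obs$j)),
                   sum(tf$count))
})

test_that("single-sentence grounding enumerates the declared atom domains", {
  cp <- fig1_corpus()
  net <- ground_sentence(cp, "fig1", 1L, spec = "full", coref = cp$coref)
  at <- net$atoms
  s1 <- cp$tokens$doc_index[cp$tokens$sentence_index == 1]
  expect_setequal(at$i[at$pred == "event"], s1)
  # eventType atoms: every (sentence token, type) combination
  expect_identical(sum(at$pred == "eventType"),
                   length(s1) * length(cp$event_types))
  # hand-enumerated factor count on the hard side: per token one
  # event=>type clause and one event=>Theme clause, one type=>event clause
  # per (token, type), one role=>event clause per role atom
  n_role <- sum(at$pred == "role")
  hard <- Filter(function(cl) isTRUE(cl$hard), net$clauses)
  expect_identical(length(hard),
                   2L * length(s1) + length(s1) * length(cp$event_types) +
                     n_role)
})

test_that("model templates reflect the preset flags", {
  expect_false(any(instantiate_model(mln_preset("baseline"))$uses_corefer))
  tm <- instantiate_model(mln_preset("full"))
  expect_setequal(tm$template[tm$uses_corefer], c("FC", "SiD", "T"))
  expect_identical(sum(tm$hard), 4L)  # the four consistency formulae
  tm_t <- instantiate_model(mln_preset("fc_t"))
  expect_false("SiD" %in% tm_t$template)
})

test_that("grounding materializes the transitivity factor of the example", {
  cp <- fig1_corpus()
  net <- ground_fig1(mln_spec(fc = TRUE, sid = TRUE, t = TRUE), cp$coref)
  nm <- net$atoms$name
  # with corefer(11,4), the antecedent's role atom is a decision variable
  expect_true("role(13,4,Theme)" %in% nm)
  id <- stats::setNames(seq_along(nm), nm)
  t_cl <- Filter(function(cl) identical(cl$key, "T"), net$clauses)
  sig <- vapply(t_cl, function(cl) paste(nm[cl$neg], "=>", nm[cl$pos]),
                character(1))
  expect_true("role(13,11,Theme) => role(13,4,Theme)" %in% sig)
  # without T, the antecedent is not even a candidate
  net0 <- ground_fig1(mln_spec(fc = TRUE, sid = TRUE, t = FALSE), cp$coref)
  expect_false(any(grepl(",4,", net0$atoms$name[net0$atoms$pred == "role"],
                         fixed = TRUE)))
})

test_that("hand-set weights drive transitivity through MAP inference", {
  cp <- fig1_corpus()
  net <- ground_fig1(mln_spec(t = TRUE), cp$coref)
  # reward the gold intra links and the event directly, make T profitable
  # the intra link must be worth more than one forgone T factor, so the
  # anaphor's link survives even when the antecedent's atom is blocked
  w <- c(2, 2, 4, 3)
  names(w) <- c(net$local[[match("event(13)", net$atoms$name)]][1],
                net$local[[match("eventType(13,Activation)", net$atoms$name)]][1],
                net$local[[match("role(13,11,Theme)", net$atoms$name)]][1],
                "T")
  res <- map_infer(net, w)
  expect_true(res$assignment[["role(13,11,Theme)"]])
  expect_true(res$assignment[["role(13,4,Theme)"]])
  # with a hostile unit score on the antecedent atom, T can be outweighed;
  # attach an extra local factor private to that atom
  i4 <- match("role(13,4,Theme)", net$atoms$name)
  net$local[[i4]] <- c(net$local[[i4]], "hostile")
  w2 <- c(w, hostile = -10)
  res2 <- map_infer(net, w2)
  expect_true(res2$assignment[["role(13,11,Theme)"]])
  expect_false(res2$assignment[["role(13,4,Theme)"]])
})

test_that("salience pressure prefers the clustered candidate", {
  cp <- fig1_corpus()
  # two equally-scored candidates: 11 (clustered) and 15 (not); no other
  # evidence distinguishes them
  net <- ground_fig1(mln_spec(sid = TRUE), cp$coref)
  nm <- net$atoms$name
  w <- c(2, 2, 0.5, 0.5, 1)
  names(w) <- c(net$local[[match("event(13)", nm)]][1],
                net$local[[match("eventType(13,Activation)", nm)]][1],
                paste0("tie|", c("a", "b")), "SiD")
  # overwrite the two candidates' locals with identical tie keys
  net$local[[match("role(13,11,Theme)", nm)]] <- "tie|a"
  net$local[[match("role(13,15,Theme)", nm)]] <- "tie|b"
  w["tie|a"] <- -0.4; w["tie|b"] <- -0.4
  res <- map_infer(net, w)
  expect_true(res$assignment[["role(13,11,Theme)"]])   # SiD tips this one
  expect_false(res$assignment[["role(13,15,Theme)"]])  # no pressure here
})

test_that("every MAP decode satisfies the four consistency implications", {
  cp <- small_sim(12, seed = 71)
  fit <- mln_train(cp, preset = "full", coref = cp$coref, epochs = 2,
                   seed = 2)
  insts <- corevent:::mln_instances(cp, fit$spec, cp$coref, fit$lexicon,
                                    with_gold = FALSE)
  for (inst in insts) {
    a <- map_infer(inst$network, fit$weights)$assignment
    at <- inst$network$atoms
    ev_true <- at$i[at$pred == "event" & a]
    ty_true <- at$i[at$pred == "eventType" & a]
    ro_ev <- at$i[at$pred == "role" & a]
    th_ev <- at$i[at$pred == "role" & a & at$a3 == "Theme"]
    expect_true(all(ty_true %in% ev_true))        # type => event
    expect_true(all(ro_ev %in% ev_true))          # role => event
    expect_true(all(ev_true %in% ty_true))        # event => some type
    expect_true(all(ev_true %in% th_ev))          # event => some Theme
  }
})

test_that("without coreference templates no cross-sentence role is decoded", {
  cp <- small_sim(15, seed = 72)
  ids <- unique(cp$tokens$doc_id)
  fit <- mln_train(corpus_subset(cp, ids[1:11]), preset = "baseline",
                   epochs = 2, seed = 2)
  te <- corpus_subset(cp, ids[12:15])
  pred <- mln_predict(fit, te)
  sent <- stats::setNames(te$tokens$sentence_index,
                          paste(te$tokens$doc_id, te$tokens$doc_index))
  expect_true(all(sent[paste(pred$roles$doc_id, pred$roles$event_anchor)] ==
                    sent[paste(pred$roles$doc_id, pred$roles$arg_anchor)]))
})

test_that("feature-copy weights are per copied feature", {
  cp <- small_sim(10, seed = 73)
  fit <- mln_train(cp, preset = "fc", coref = cp$coref, epochs = 2, seed = 2)
  fc_keys <- grep("^fc\\|", names(fit$weights), value = TRUE)
  insts <- corevent:::mln_instances(cp, fit$spec, cp$coref, fit$lexicon)
  seen <- unique(unlist(lapply(insts, function(i) {
    grep("^fc\\|", unlist(i$network$local), value = TRUE)
  })))
  expect_true(length(fc_keys) > 1)
  expect_true(all(fc_keys %in% seen))
})
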