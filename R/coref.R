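#' Noun-phrase head mentions of a corpus
#'
#' Candidate mentions for coreference are NP heads, taken as the rightmost
#' token of every NP chunk (`B-NP` opening, `I-NP` continuation).
#'
#' @param tokens A token tibble.
#' @return Tibble `doc_id`, `mention` (token `doc_index`), `sentence_index`.
#' @export
extract_mentions <- function(tokens) {
  tk <- arrange(tokens, .data$doc_id, .data$doc_index)
  opens <- tk$chunk == "B-NP"
  inside <- tk$chunk == "I-NP"
  # rightmost token of each maximal B-NP I-NP* run
  last_of_np <- (opens | inside) & !c(inside[-1], FALSE)
  tk[last_of_np & (opens | inside), ] %>%
    dplyr::transmute(.data$doc_id, mention = .data$doc_index,
                     .data$sentence_index)
}

#' All ordered mention pairs within a sentence window
#'
#' @param mentions Output of [extract_mentions()].
#' @param window Maximum sentence distance between the two mentions
#'   (`Inf` = unlimited).
#' @return Tibble `doc_id`, `antecedent`, `anaphor` (antecedent earlier).
#' @export
generate_pairs <- function(mentions, window = Inf) {
  out <- list()
  for (d in unique(mentions$doc_id)) {
    md <- mentions[mentions$doc_id == d, ]
    md <- md[order(md$mention), ]
    n <- nrow(md)
    if (n < 2) next
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    ante <- md$mention[idx[, 1]]
    ana <- md$mention[idx[, 2]]
    dist <- md$sentence_index[idx[, 2]] - md$sentence_index[idx[, 1]]
    keep <- dist <= window
    out[[d]] <- tibble(doc_id = d, antecedent = ante[keep],
                       anaphor = ana[keep])
  }
  bind_rows(out) %||% tibble(doc_id = character(), antecedent = integer(),
                             anaphor = integer())
}

coref_pair_features <- function(tokens, pairs) {
  key <- paste(tokens$doc_id, tokens$doc_index)
  a <- tokens[match(paste(pairs$doc_id, pairs$antecedent), key), ]
  b <- tokens[match(paste(pairs$doc_id, pairs$anaphor), key), ]
  sdist <- pmin(b$sentence_index - a$sentence_index, 3)
  feats <- purrr::pmap(list(a$word, a$stem, a$pos, a$ne, b$word, b$stem,
                            b$pos, b$ne, sdist),
    function(aw, as_, ap, an, bw, bs, bp, bn, sd) {
      f <- c(paste0("posPair=", ap, "_", bp), paste0("nePair=", an, "_", bn),
             paste0("sdist=", sd))
      if (aw == bw) f <- c(f, "wordMatch")
      if (as_ == bs) f <- c(f, "stemMatch")
      if (grepl(bw, aw, fixed = TRUE) || grepl(aw, bw, fixed = TRUE)) {
        f <- c(f, "substring")
      }
      if (toupper(bw) == bw && nchar(bw) <= 5 && nchar(aw) > nchar(bw)) {
        f <- c(f, "acronymShape")
      }
      f
    })
  feats
}

label_pairs <- function(pairs, clusters) {
  cl_key <- paste(clusters$doc_id, clusters$token)
  ca <- clusters$cluster[match(paste(pairs$doc_id, pairs$antecedent), cl_key)]
  cb <- clusters$cluster[match(paste(pairs$doc_id, pairs$anaphor), cl_key)]
  !is.na(ca) & !is.na(cb) & ca == cb
}

#' Train the pairwise coreference model
#'
#' A linear max-margin classifier over basic mention-pair features (word,
#' stem, POS and NE agreement, sentence distance, substring/acronym shape).
#' Class imbalance — negative pairs vastly outnumber positives — is handled
#' by a positive-class cost multiplier, and the decision threshold is then
#' chosen precision-first on a held-out development split: the most permissive
#' threshold whose dev precision still reaches `target_precision` (falling
#' back to the maximum-precision threshold when the target is unreachable).
#' The resulting operating point trades recall away for precision, which is
#' what a downstream event extractor needs from its coreference input.
#'
#' @param corpus An `event_corpus` with gold coreference.
#' @param window Maximum sentence distance for candidate pairs.
#' @param cost Positive-class cost multiplier; default = #negatives/#positives.
#' @param target_precision Development precision to aim for (default 0.9).
#' @param dev_fraction Fraction of documents held out for threshold selection.
#' @param seed Seed for the document split.
#' @return A `coref_model` with the fitted SVM, threshold, and dev metrics.
#' @export
coref_train <- function(corpus, window = Inf, cost = NULL,
                        target_precision = 0.9, dev_fraction = 0.25,
                        seed = 1L) {
  clusters <- coref_closure(corpus$coref)
  ids <- sort(unique(corpus$tokens$doc_id))
  set.seed(seed)
  n_dev <- max(1L, floor(length(ids) * dev_fraction))
  dev_ids <- sort(sample(ids, n_dev))
  tr_ids <- setdiff(ids, dev_ids)

  build <- function(sub_ids) {
    tk <- filter(corpus$tokens, .data$doc_id %in% sub_ids)
    pairs <- generate_pairs(extract_mentions(tk), window)
    list(pairs = pairs, feats = coref_pair_features(tk, pairs),
         y = label_pairs(pairs, clusters))
  }
  tr <- build(tr_ids)
  if (sum(tr$y) == 0 || sum(!tr$y) == 0) {
    abort("degenerate training data: need both coreferent and non-coreferent pairs")
  }
  if (is.null(cost)) cost <- max(1, sum(!tr$y) / sum(tr$y))
  fm <- feature_matrix(tr$feats)
  x <- as.matrix(fm$m)
  y <- factor(ifelse(tr$y, "corefer", "not"), levels = c("corefer", "not"))
  svm_fit <- e1071::svm(x, y, kernel = "linear", scale = FALSE,
                        class.weights = c(corefer = cost, not = 1))
  dv_sign <- if (svm_fit$labels[1] == 1) 1 else -1  # orient dv toward "corefer"

  decision <- function(feats) {
    xm <- as.matrix(feature_matrix(feats, vocab = fm$vocab)$m)
    dv <- attr(predict(svm_fit, xm, decision.values = TRUE),
               "decision.values")[, 1]
    dv_sign * dv
  }
  dev <- build(dev_ids)
  dev_dv <- decision(dev$feats)
  cand <- sort(unique(c(dev_dv, 0)), decreasing = TRUE)
  best <- list(thr = 0, prec = -1, rec = -1, hit_target = FALSE)
  for (thr in cand) {
    pred <- dev_dv >= thr
    tp <- sum(pred & dev$y); fp <- sum(pred & !dev$y)
    prec <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
    rec <- if (sum(dev$y) == 0) NA_real_ else tp / sum(dev$y)
    if (is.na(prec)) next
    if (prec >= target_precision) {
      # most permissive threshold still meeting the target
      if (!best$hit_target || rec > best$rec) {
        best <- list(thr = thr, prec = prec, rec = rec, hit_target = TRUE)
      }
    } else if (!best$hit_target && prec > best$prec) {
      best <- list(thr = thr, prec = prec, rec = rec, hit_target = FALSE)
    }
  }
  structure(list(svm = svm_fit, vocab = fm$vocab, dv_sign = dv_sign,
                 threshold = best$thr, cost = cost, window = window,
                 dev_precision = best$prec, dev_recall = best$rec,
                 hit_target = best$hit_target,
                 target_precision = target_precision),
            class = "coref_model")
}

coref_decision_values <- function(model, tokens, pairs) {
  feats <- coref_pair_features(tokens, pairs)
  xm <- as.matrix(feature_matrix(feats, vocab = model$vocab)$m)
  dv <- attr(predict(model$svm, xm, decision.values = TRUE),
             "decision.values")[, 1]
  model$dv_sign * dv
}

#' Resolve coreference over a corpus
#'
#' Scores all candidate mention pairs with a trained [coref_train()] model;
#' every pair at or above the selected threshold becomes a directed
#' antecedent-anaphor link.
#'
#' @param corpus An `event_corpus` (gold coreference, if present, is ignored).
#' @param model A `coref_model`.
#' @param threshold Override the model's stored operating point.
#' @return A coreference tibble `doc_id`, `anaphor`, `antecedent`.
#' @export
coref_predict <- function(corpus, model, threshold = NULL) {
  thr <- threshold %||% model$threshold
  pairs <- generate_pairs(extract_mentions(corpus$tokens), model$window)
  if (nrow(pairs) == 0) {
    return(tibble(doc_id = character(), anaphor = integer(),
                  antecedent = integer()))
  }
  dv <- coref_decision_values(model, corpus$tokens, pairs)
  keep <- dv >= thr
  tibble(doc_id = pairs$doc_id[keep], anaphor = pairs$anaphor[keep],
         antecedent = pairs$antecedent[keep]) %>%
    arrange(.data$doc_id, .data$anaphor, .data$antecedent)
}

#' Pairwise coreference evaluation
#'
#' Precision/recall/F1 over mention pairs: a predicted link counts as correct
#' when its two tokens share a gold entity cluster.
#'
#' @param pred Predicted coreference tibble.
#' @param gold Gold coreference tibble.
#' @return One-row tibble with `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
coref_eval <- function(pred, gold) {
  clusters <- coref_closure(gold)
  gold_pairs <- unlist(lapply(split(clusters, clusters$doc_id), function(cd) {
    unlist(lapply(split(cd$token, cd$cluster), function(ts) {
      if (length(ts) < 2) return(character())
      cmb <- utils::combn(sort(ts), 2)
      paste(cd$doc_id[1], cmb[1, ], cmb[2, ])
    }))
  }), use.names = FALSE)
  pred_pairs <- paste(pred$doc_id, pmin(pred$antecedent, pred$anaphor),
                      pmax(pred$antecedent, pred$anaphor))
  pred_pairs <- unique(pred_pairs)
  tp <- sum(pred_pairs %in% gold_pairs)
  prf_row(tp = tp, fp = length(pred_pairs) - tp,
          fn = length(gold_pairs) - tp)
}

#' @export
print.coref_model <- function(x, ...) {
  cat("<coref_model> linear pairwise SVM, cost multiplier ",
      format(x$cost, digits = 4), "\n  threshold ",
      format(x$threshold, digits = 4), " (dev precision ",
      format(x$dev_precision, digits = 3), ", dev recall ",
      format(x$dev_recall, digits = 3), ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.coref_model <- function(x, ...) {
  w <- as.numeric(crossprod(x$svm$coefs, x$svm$SV)) * x$dv_sign
  tibble(term = c(x$vocab, rep("(pad)", length(w) - length(x$vocab))),
         estimate = w) %>% filter(.data$term != "(pad)")
}

#' @export
glance.coref_model <- function(x, ...) {
  tibble(cost = x$cost, threshold = x$threshold,
         dev_precision = x$dev_precision, dev_recall = x$dev_recall,
         hit_target = x$hit_target, n_support = nrow(x$svm$SV))
}
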