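prf_row <- function(tp, fp, fn) {
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  tibble(tp = tp, fp = fp, fn = fn, precision = p, recall = r, f1 = f)
}

set_prf <- function(pred_keys, gold_keys) {
  pred_keys <- unique(pred_keys); gold_keys <- unique(gold_keys)
  tp <- sum(pred_keys %in% gold_keys)
  prf_row(tp, length(pred_keys) - tp, length(gold_keys) - tp)
}

#' Score predicted annotations against gold
#'
#' Exact-match precision/recall/F1 for the three target layers — `event`
#' (trigger anchors), `eventType` (anchor + type) and `role` (event anchor,
#' argument anchor, role) — plus a per-category breakdown of the role layer
#' into Cross / W-ANT / Normal links. Categories are always computed against
#' *gold* coreference clusters (for predictions as well as gold links), so
#' systems run with different coreference inputs stay comparable.
#'
#' @param gold An `event_corpus` carrying the gold layers.
#' @param pred A list with tibbles `triggers` and `roles` (as returned by
#'   [pipeline_predict()] / [mln_predict()]).
#' @return An `ea_report`: a tibble with columns `predicate`, `category`,
#'   `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
score_corpus <- function(gold, pred) {
  bad <- setdiff(unique(c(pred$triggers$doc_id, pred$roles$doc_id)),
                 unique(gold$tokens$doc_id))
  if (length(bad) > 0) {
    abort(paste0("predictions reference unknown doc_ids: ",
                 paste(head(bad, 3), collapse = ", ")))
  }
  clusters <- coref_closure(gold$coref)
  rows <- list()
  rows$event <- set_prf(paste(pred$triggers$doc_id, pred$triggers$anchor),
                        paste(gold$triggers$doc_id, gold$triggers$anchor)) %>%
    mutate(predicate = "event", category = "all")
  rows$eventType <- set_prf(
    paste(pred$triggers$doc_id, pred$triggers$anchor,
          pred$triggers$event_type),
    paste(gold$triggers$doc_id, gold$triggers$anchor,
          gold$triggers$event_type)) %>%
    mutate(predicate = "eventType", category = "all")
  role_key <- function(x) paste(x$doc_id, x$event_anchor, x$arg_anchor,
                                x$role)
  rows$role <- set_prf(role_key(pred$roles), role_key(gold$roles)) %>%
    mutate(predicate = "role", category = "all")
  pred_cat <- categorize_links(distinct(pred$roles), clusters, gold$tokens)
  gold_cat <- categorize_links(distinct(gold$roles), clusters, gold$tokens)
  for (cat in levels(gold_cat$category)) {
    rows[[cat]] <- set_prf(role_key(pred_cat[pred_cat$category == cat, ]),
                           role_key(gold_cat[gold_cat$category == cat, ])) %>%
      mutate(predicate = "role", category = cat)
  }
  out <- bind_rows(rows) %>%
    select("predicate", "category", "tp", "fp", "fn", "precision", "recall",
           "f1")
  class(out) <- c("ea_report", class(out))
  out
}

#' @export
print.ea_report <- function(x, ...) {
  cat("Event-argument extraction report (exact match)\n")
  NextMethod()
  invisible(x)
}

#' Aggregate reports by pooling counts
#'
#' @param reports List of `ea_report` objects (e.g. one per fold).
#' @return A pooled (micro-averaged) `ea_report`.
#' @export
pool_reports <- function(reports) {
  out <- bind_rows(reports) %>%
    group_by(.data$predicate, .data$category) %>%
    summarise(tp = sum(.data$tp), fp = sum(.data$fp), fn = sum(.data$fn),
              .groups = "drop") %>%
    dplyr::rowwise() %>%
    mutate(prf_row(.data$tp, .data$fp, .data$fn)[c("precision", "recall",
                                                   "f1")]) %>%
    ungroup()
  class(out) <- c("ea_report", class(out))
  out
}

#' Document-level k-fold partition
#'
#' @param doc_ids Character vector of document ids (or an `event_corpus`).
#' @param k Number of folds (default 5).
#' @param seed Seed for the random permutation.
#' @return Tibble `doc_id`, `fold` (1..k); folds are disjoint, cover all
#'   documents, and differ in size by at most one.
#' @export
kfold <- function(doc_ids, k = 5L, seed = 1L) {
  if (inherits(doc_ids, "event_corpus")) {
    doc_ids <- unique(doc_ids$tokens$doc_id)
  }
  doc_ids <- sort(unique(doc_ids))
  if (length(doc_ids) < k) abort("fewer documents than folds")
  set.seed(seed)
  perm <- sample(doc_ids)
  tibble(doc_id = perm,
         fold = rep_len(seq_len(k), length(perm))) %>%
    arrange(.data$doc_id)
}

#' Exact McNemar test on discordant counts
#'
#' Two-tailed exact binomial test on the discordant pairs of two paired
#' classifiers: `b` decisions only system A got right, `c` only system B.
#' Under the null the discordant counts are Binomial(b + c, 1/2); the
#' two-tailed p-value is twice the smaller tail, clipped to 1.
#'
#' @param b,c Non-negative discordant counts.
#' @return The p-value.
#' @export
mcnemar_exact <- function(b, c) {
  if (b < 0 || c < 0) abort("counts must be non-negative")
  n <- b + c
  if (n == 0) return(1)
  min(1, 2 * stats::pbinom(min(b, c), n, 0.5))
}

#' Compare two systems' role predictions with McNemar's test
#'
#' The decision units are the links in the union of the gold set and either
#' system's predictions; a system is "correct" on a unit when its
#' inclusion/exclusion of the link agrees with gold.
#'
#' @param gold_roles,roles_a,roles_b Role-link tibbles.
#' @return Tibble with discordant counts `b` (A-only correct), `c` (B-only
#'   correct) and `p_value` from [mcnemar_exact()].
#' @export
mcnemar_compare <- function(gold_roles, roles_a, roles_b) {
  key <- function(x) unique(paste(x$doc_id, x$event_anchor, x$arg_anchor,
                                  x$role))
  g <- key(gold_roles); a <- key(roles_a); b <- key(roles_b)
  units <- unique(c(g, a, b))
  ok_a <- (units %in% a) == (units %in% g)
  ok_b <- (units %in% b) == (units %in% g)
  bb <- sum(ok_a & !ok_b); cc <- sum(!ok_a & ok_b)
  tibble(b = bb, c = cc, p_value = mcnemar_exact(bb, cc))
}
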