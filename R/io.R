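#' Read a corpus from JSON-lines
#'
#' The canonical on-disk dialect is JSON-lines: one JSON object per line with
#' fields `doc_id`, `event_types`, `tokens`, `triggers`, `roles`, `coref`
#' mirroring the layers of an [event_corpus()]. All corpus invariants are
#' validated on load; failures report the offending line.
#'
#' @param path Path to a `.jsonl` file.
#' @param event_types Optional inventory; defaults to the union of the
#'   per-document inventories in the file.
#' @return An `event_corpus`.
#' @export
read_corpus_jsonl <- function(path, event_types = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(event_corpus(tibble(
      doc_id = character(), doc_index = integer(),
      sentence_index = integer(), word = character(), stem = character(),
      pos = character(), ne = character(), chunk = character(),
      head = integer(), dep_label = character()),
      event_types = event_types %||% character()))
  }
  toks <- list(); trig <- list(); rol <- list(); crf <- list()
  types <- character()
  for (ln in seq_along(lines)) {
    obj <- tryCatch(
      jsonlite::fromJSON(lines[[ln]], simplifyDataFrame = TRUE),
      error = function(e) abort(paste0("parse error at line ", ln, ": ",
                                       conditionMessage(e)))
    )
    if (is.null(obj$doc_id) || is.null(obj$tokens)) {
      abort(paste0("line ", ln, ": document object needs doc_id and tokens"))
    }
    tk <- as_tibble(obj$tokens)
    tk$doc_id <- obj$doc_id
    tk$doc_index <- as.integer(tk$doc_index)
    tk$sentence_index <- as.integer(tk$sentence_index)
    tk$head <- suppressWarnings(as.integer(tk$head))
    toks[[ln]] <- tk
    grab <- function(field, int_cols) {
      df <- obj[[field]]
      if (is.null(df) || length(df) == 0 ||
          (is.data.frame(df) && nrow(df) == 0)) return(NULL)
      df <- as_tibble(df)
      for (cc in int_cols) df[[cc]] <- as.integer(df[[cc]])
      df$doc_id <- obj$doc_id
      df
    }
    trig[[ln]] <- grab("triggers", "anchor")
    rol[[ln]] <- grab("roles", c("event_anchor", "arg_anchor"))
    crf[[ln]] <- grab("coref", c("anaphor", "antecedent"))
    types <- union(types, unlist(obj$event_types))
  }
  need <- c("doc_id", "doc_index", "sentence_index", "word", "stem", "pos",
            "ne", "chunk", "head", "dep_label")
  tokens <- bind_rows(toks)
  tokens <- tokens[intersect(need, names(tokens))]
  if (!is.null(event_types)) types <- event_types
  drop_null <- function(x) x[!vapply(x, is.null, TRUE)]
  reorder <- function(df, cols) if (is.null(df)) df else df[c(cols, "doc_id")]
  corpus <- tryCatch(
    event_corpus(
      tokens = tokens[need],
      triggers = bind_rows(drop_null(trig)),
      roles = bind_rows(drop_null(rol)),
      coref = bind_rows(drop_null(crf)),
      event_types = types
    ),
    error = function(e) abort(paste0("validation error in ", path, ": ",
                                     conditionMessage(e)))
  )
  corpus
}

#' Write a corpus as JSON-lines
#'
#' Serialization is canonical (fixed field order, nulls for missing heads), so
#' `write -> read -> write` is byte-identical.
#'
#' @param corpus An `event_corpus`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  ids <- unique(corpus$tokens$doc_id)
  lines <- vapply(ids, function(d) {
    tk <- filter(corpus$tokens, .data$doc_id == d) %>%
      arrange(.data$doc_index) %>%
      select("doc_index", "sentence_index", "word", "stem", "pos", "ne",
             "chunk", "head", "dep_label")
    obj <- list(
      doc_id = d,
      event_types = corpus$event_types,
      tokens = tk,
      triggers = filter(corpus$triggers, .data$doc_id == d) %>%
        arrange(.data$anchor) %>% select("anchor", "event_type"),
      roles = filter(corpus$roles, .data$doc_id == d) %>%
        arrange(.data$event_anchor, .data$arg_anchor, .data$role) %>%
        select("event_anchor", "arg_anchor", "role"),
      coref = filter(corpus$coref, .data$doc_id == d) %>%
        arrange(.data$anaphor, .data$antecedent) %>%
        select("anaphor", "antecedent")
    )
    jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE, na = "null",
                     digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

doc_text <- function(tokens_doc) {
  tk <- tokens_doc[order(tokens_doc$doc_index), ]
  txt <- paste(tk$word, collapse = " ")
  starts <- cumsum(c(0L, nchar(tk$word) + 1L))[seq_len(nrow(tk))]
  list(text = txt, start = setNames(starts, tk$doc_index),
       end = setNames(starts + nchar(tk$word), tk$doc_index))
}

#' Export a corpus in BioNLP-style standoff format
#'
#' Writes, per document, `<doc_id>.txt` (whitespace-joined tokens),
#' `<doc_id>.a1` (one `T` line per annotated token: triggers with their event
#' type, argument/coreference mentions as `Entity`), and `<doc_id>.a2`
#' (`E` lines carrying Theme/Cause arguments, `R` lines for coreference).
#' Character offsets are 0-based half-open over the reconstructed text. This
#' format is export-oriented; JSON-lines is the canonical dialect.
#'
#' @param corpus An `event_corpus`.
#' @param directory Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_standoff <- function(corpus, directory) {
  ok <- dir.exists(directory) || dir.create(directory, recursive = TRUE)
  if (!ok) abort(paste0("cannot create directory ", directory))
  for (d in unique(corpus$tokens$doc_id)) {
    tk <- filter(corpus$tokens, .data$doc_id == d)
    geo <- doc_text(tk)
    writeLines(geo$text, file.path(directory, paste0(d, ".txt")))
    trig <- filter(corpus$triggers, .data$doc_id == d) %>% arrange(.data$anchor)
    rol <- filter(corpus$roles, .data$doc_id == d) %>%
      arrange(.data$event_anchor, .data$arg_anchor, .data$role)
    crf <- filter(corpus$coref, .data$doc_id == d) %>%
      arrange(.data$anaphor, .data$antecedent)
    anchors <- sort(unique(c(trig$anchor, rol$arg_anchor,
                             crf$anaphor, crf$antecedent)))
    anchors <- union(trig$anchor, setdiff(anchors, trig$anchor))
    t_id <- setNames(paste0("T", seq_along(anchors)), anchors)
    word_of <- setNames(tk$word, tk$doc_index)
    a1 <- vapply(anchors, function(a) {
      ty <- trig$event_type[match(a, trig$anchor)]
      if (is.na(ty)) ty <- "Entity"
      paste0(t_id[[as.character(a)]], "\t", ty, " ",
             geo$start[[as.character(a)]], " ", geo$end[[as.character(a)]],
             "\t", word_of[[as.character(a)]])
    }, character(1))
    writeLines(a1, file.path(directory, paste0(d, ".a1")))
    a2 <- character()
    if (nrow(trig) > 0) {
      for (k in seq_len(nrow(trig))) {
        a <- trig$anchor[k]
        args <- rol[rol$event_anchor == a, ]
        parts <- paste0(trig$event_type[k], ":", t_id[[as.character(a)]])
        if (nrow(args) > 0) {
          # repeated roles get numbered slots (Theme, Theme2, ...)
          slot <- stats::ave(seq_len(nrow(args)), args$role, FUN = seq_along)
          nm <- ifelse(slot == 1, args$role, paste0(args$role, slot))
          parts <- c(parts, paste0(nm, ":", t_id[as.character(args$arg_anchor)]))
        }
        a2 <- c(a2, paste0("E", k, "\t", paste(parts, collapse = " ")))
      }
    }
    if (nrow(crf) > 0) {
      a2 <- c(a2, paste0("R", seq_len(nrow(crf)), "\tCoref Anaphor:",
                         t_id[as.character(crf$anaphor)], " Antecedent:",
                         t_id[as.character(crf$antecedent)]))
    }
    writeLines(a2, file.path(directory, paste0(d, ".a2")))
  }
  invisible(directory)
}

#' Read back a standoff export
#'
#' Reconstructs the annotation layers (trigger anchors and types, role links,
#' coreference links) from files written by [write_standoff()]. Tokenization
#' is recovered by splitting the text on spaces; sentence boundaries and
#' token tags are not represented in standoff, so the returned tibbles carry
#' anchors and labels only.
#'
#' @param directory Directory holding `.txt`/`.a1`/`.a2` files.
#' @return A list with tibbles `triggers`, `roles`, `coref`.
#' @export
read_standoff <- function(directory) {
  txts <- list.files(directory, pattern = "\\.txt$", full.names = TRUE)
  trig <- list(); rol <- list(); crf <- list()
  for (f in txts) {
    d <- sub("\\.txt$", "", basename(f))
    words <- strsplit(readLines(f, warn = FALSE)[1], " ", fixed = TRUE)[[1]]
    starts <- cumsum(c(0L, nchar(words) + 1L))[seq_along(words)]
    idx_of <- setNames(seq_along(words) - 1L, starts)
    a1 <- readLines(file.path(directory, paste0(d, ".a1")), warn = FALSE)
    t_anchor <- integer(); t_type <- character(); t_name <- character()
    for (line in a1[nzchar(a1)]) {
      fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
      mid <- strsplit(fields[2], " ", fixed = TRUE)[[1]]
      t_name <- c(t_name, fields[1])
      t_type <- c(t_type, mid[1])
      t_anchor <- c(t_anchor, idx_of[[mid[2]]])
    }
    anchor_of <- setNames(t_anchor, t_name)
    is_trig <- t_type != "Entity"
    trig[[d]] <- tibble(doc_id = d, anchor = t_anchor[is_trig],
                        event_type = t_type[is_trig])
    a2 <- readLines(file.path(directory, paste0(d, ".a2")), warn = FALSE)
    for (line in a2[nzchar(a2)]) {
      fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
      parts <- strsplit(fields[2], " ", fixed = TRUE)[[1]]
      # R lines lead with a bare relation name; drop it before key:value parsing
      parts <- parts[grepl(":", parts, fixed = TRUE)]
      kv <- strsplit(parts, ":", fixed = TRUE)
      keys <- vapply(kv, `[[`, "", 1)
      vals <- vapply(kv, `[[`, "", 2)
      if (startsWith(fields[1], "E")) {
        ev <- anchor_of[[vals[1]]]
        for (k in seq_along(keys)[-1]) {
          rol[[length(rol) + 1]] <- tibble(
            doc_id = d, event_anchor = ev, arg_anchor = anchor_of[[vals[k]]],
            role = sub("[0-9]+$", "", keys[k]))
        }
      } else if (startsWith(fields[1], "R")) {
        crf[[length(crf) + 1]] <- tibble(
          doc_id = d,
          anaphor = anchor_of[[vals[keys == "Anaphor"]]],
          antecedent = anchor_of[[vals[keys == "Antecedent"]]])
      }
    }
  }
  list(triggers = bind_rows(trig), roles = bind_rows(rol),
       coref = bind_rows(crf))
}
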