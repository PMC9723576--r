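# Session/message data model, tokenization, block segmentation, inclusion
# filtering and TF-IDF vocabulary selection.

ROLE_HELP_SEEKER <- "help_seeker"
ROLE_COUNSELOR <- "counselor"

norm_role <- function(role) {
  out <- rep(NA_character_, length(role))
  out[role %in% c("H", "h", ROLE_HELP_SEEKER)] <- ROLE_HELP_SEEKER
  out[role %in% c("C", "c", ROLE_COUNSELOR)] <- ROLE_COUNSELOR
  out
}

#' Construct a counseling session
#'
#' A session is an ordered sequence of messages exchanged between a
#' help-seeker and a counselor.
#'
#' @param session_id session identifier.
#' @param seq integer message order indices, strictly increasing.
#' @param role character vector, each `"help_seeker"` or `"counselor"`
#'   (abbreviations `"H"`/`"C"` accepted).
#' @param text character vector of message texts.
#' @return An object of class `session`: a list with `session_id`,
#'   `messages` (data.frame with columns `seq`, `role`, `text`) and
#'   `n_exchanges` (total message count, both roles).
#' @export
session <- function(session_id, seq, role, text) {
  stopifnot(length(seq) == length(role), length(role) == length(text))
  role <- norm_role(role)
  if (anyNA(role)) stop("unknown_role: role must be help_seeker/H or counselor/C")
  o <- order(seq)
  seq <- as.integer(seq[o])
  if (any(duplicated(seq))) stop("duplicate seq within session ", session_id)
  structure(
    list(
      session_id = as.character(session_id),
      messages = data.frame(seq = seq, role = role[o], text = as.character(text[o]),
                            stringsAsFactors = FALSE),
      n_exchanges = length(seq)
    ),
    class = "session"
  )
}

#' @export
print.session <- function(x, ...) {
  cat(sprintf("<session %s: %d messages (%d help-seeker)>\n",
              x$session_id, x$n_exchanges,
              sum(x$messages$role == ROLE_HELP_SEEKER)))
  invisible(x)
}

#' Read counseling sessions from disk
#'
#' Two dialects are supported. `"jsonl"`: one JSON object per line with keys
#' `session_id`, `seq`, `role` (`"H"`/`"C"`), `text`. `"tsv"`: a two-column
#' tab-separated file (role, text) holding a single session whose id is the
#' file name (messages numbered in file order); a header row is not expected.
#'
#' Malformed records are not fatal: they are collected in an error report
#' attached to the result as attribute `"errors"` (a data.frame with `line`
#' and `reason`).
#'
#' @param path file path.
#' @param format `"jsonl"` (default) or `"tsv"`.
#' @return A list of [session] objects, with attribute `errors`.
#' @export
read_sessions <- function(path, format = c("jsonl", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read sessions: no such file: ", path)
  errors <- data.frame(line = integer(), reason = character())
  if (format == "tsv") {
    dt <- data.table::fread(path, sep = "\t", header = FALSE, quote = "",
                            col.names = c("role", "text"), colClasses = "character")
    sid <- sub("\\.[^.]*$", "", basename(path))
    recs <- data.frame(session_id = sid, seq = seq_len(nrow(dt)),
                       role = dt$role, text = dt$text, stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines_keep <- nzchar(trimws(lines))
    parsed <- vector("list", length(lines))
    for (li in which(lines_keep)) {
      rec <- tryCatch(jsonlite::fromJSON(lines[[li]]), error = function(e) NULL)
      if (is.null(rec)) {
        errors <- rbind(errors, data.frame(line = li, reason = "unparseable_json"))
        next
      }
      miss <- setdiff(c("session_id", "seq", "role", "text"), names(rec))
      if (length(miss)) {
        errors <- rbind(errors, data.frame(
          line = li, reason = paste0("missing_field:", paste(miss, collapse = ","))))
        next
      }
      parsed[[li]] <- data.frame(session_id = as.character(rec$session_id),
                                 seq = as.integer(rec$seq),
                                 role = as.character(rec$role),
                                 text = as.character(rec$text),
                                 stringsAsFactors = FALSE)
    }
    recs <- do.call(rbind, parsed[!vapply(parsed, is.null, logical(1))])
    if (is.null(recs)) recs <- data.frame(session_id = character(), seq = integer(),
                                          role = character(), text = character())
  }
  bad_role <- is.na(norm_role(recs$role))
  if (any(bad_role)) {
    errors <- rbind(errors, data.frame(line = which(bad_role), reason = "unknown_role"))
    recs <- recs[!bad_role, , drop = FALSE]
  }
  out <- lapply(split(recs, recs$session_id), function(d)
    session(d$session_id[1], d$seq, d$role, d$text))
  out <- out[order(names(out))]
  attr(out, "errors") <- errors
  out
}

#' Write sessions as JSON-lines
#'
#' Inverse of [read_sessions()] for the `"jsonl"` dialect.
#'
#' @param sessions list of [session] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sessions <- function(sessions, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (s in sessions) {
    m <- s$messages
    role <- ifelse(m$role == ROLE_HELP_SEEKER, "H", "C")
    for (k in seq_len(nrow(m))) {
      writeLines(jsonlite::toJSON(
        list(session_id = s$session_id, seq = m$seq[k], role = role[k], text = m$text[k]),
        auto_unbox = TRUE), con)
    }
  }
  invisible(path)
}

#' Tokenize text
#'
#' The default segmenter lowercases and splits on any run of characters that
#' is neither a Unicode letter nor a digit, so punctuation-only tokens vanish.
#' A custom segmenter (for example a Chinese word segmenter) may be supplied
#' as a function `character(1) -> character()`; it is applied as-is.
#'
#' @param text character vector (elements are tokenized independently and
#'   concatenated).
#' @param tokenizer optional segmenter function; `NULL` uses the default.
#' @return Character vector of tokens (possibly empty).
#' @export
tokenize <- function(text, tokenizer = NULL) {
  if (!is.null(tokenizer)) return(unlist(lapply(text, tokenizer), use.names = FALSE))
  if (!length(text)) return(character())
  toks <- unlist(strsplit(tolower(text), "[^\\p{L}\\p{N}]+", perl = TRUE),
                 use.names = FALSE)
  toks[nzchar(toks)]
}

#' Segment a session into help-seeker blocks
#'
#' The unit of analysis is the block: a run of `block_size` consecutive
#' help-seeker messages (default ten). Counselor messages never enter block
#' tokens unless `include_counselor_tokens = TRUE`, in which case counselor
#' messages falling between the block's help-seeker messages are appended.
#' A trailing remainder shorter than `block_size` becomes a final block
#' flagged `is_partial`.
#'
#' @param session a [session].
#' @param block_size messages per block, >= 1.
#' @param tokenizer passed to [tokenize()].
#' @param include_counselor_tokens include interleaved counselor text in the
#'   block token multiset (default `FALSE`).
#' @return List of `iss_block` objects, each a list with `session_id`,
#'   `block_index` (0-based), `message_seqs`, `message_tokens` (list of
#'   per-message token vectors), `tokens` (flattened), `label`
#'   (`"UNLABELED"`), `is_partial`.
#' @export
segment_blocks <- function(session, block_size = 10, tokenizer = NULL,
                           include_counselor_tokens = FALSE) {
  stopifnot(inherits(session, "session"), block_size >= 1)
  m <- session$messages
  hs <- which(m$role == ROLE_HELP_SEEKER)
  if (!length(hs)) return(list())
  grp <- (seq_along(hs) - 1L) %/% as.integer(block_size)
  unname(lapply(split(hs, grp), function(idx) {
    texts <- m$text[idx]
    if (include_counselor_tokens) {
      lo <- min(idx); hi <- max(idx)
      cs <- which(m$role == ROLE_COUNSELOR & seq_len(nrow(m)) > lo & seq_len(nrow(m)) < hi)
      texts <- c(texts, m$text[cs])
    }
    toks <- lapply(texts, tokenize, tokenizer = tokenizer)
    structure(
      list(
        session_id = session$session_id,
        block_index = grp[match(idx[1], hs)],
        message_seqs = m$seq[idx],
        message_tokens = toks,
        tokens = unlist(toks, use.names = FALSE),
        label = "UNLABELED",
        is_partial = length(idx) < block_size
      ),
      class = "iss_block"
    )
  }))
}

#' @export
print.iss_block <- function(x, ...) {
  cat(sprintf("<block %s/%d: %d msgs, %d tokens, label=%s%s>\n",
              x$session_id, x$block_index, length(x$message_seqs),
              length(x$tokens), x$label, if (x$is_partial) ", partial" else ""))
  invisible(x)
}

#' Apply session inclusion criteria
#'
#' Sessions with fewer than ten message exchanges (both roles counted) are
#' excluded with reason `"too_short"`. When labeled blocks are supplied,
#' sessions whose first ISS block is the very first block — leaving no prior
#' block to serve as the prediction target — are excluded with reason
#' `"no_pissb"`. Each excluded session carries exactly one reason (the first
#' that applies).
#'
#' @param sessions list of [session] objects.
#' @param labeled_blocks optional list of labeled blocks (from
#'   [label_blocks()]) used for the `"no_pissb"` rule.
#' @param min_exchanges minimum total message count (default 10).
#' @return List with `kept` (sessions) and `excluded`
#'   (data.frame `session_id`, `reason`).
#' @export
filter_sessions <- function(sessions, labeled_blocks = NULL, min_exchanges = 10) {
  no_pissb_ids <- character()
  if (!is.null(labeled_blocks)) {
    first_iss <- vapply(split(labeled_blocks,
                              vapply(labeled_blocks, `[[`, "", "session_id")),
                        function(bs) {
                          lb <- vapply(bs, `[[`, "", "label")
                          bi <- vapply(bs, `[[`, 0, "block_index")
                          iss <- bi[lb == "ISSB"]
                          if (length(iss)) min(iss) else NA_real_
                        }, 0)
    no_pissb_ids <- names(first_iss)[!is.na(first_iss) & first_iss == 0]
  }
  kept <- list(); exc_id <- character(); exc_reason <- character()
  for (s in sessions) {
    if (s$n_exchanges < min_exchanges) {
      exc_id <- c(exc_id, s$session_id); exc_reason <- c(exc_reason, "too_short")
    } else if (s$session_id %in% no_pissb_ids) {
      exc_id <- c(exc_id, s$session_id); exc_reason <- c(exc_reason, "no_pissb")
    } else kept <- c(kept, list(s))
  }
  list(kept = kept,
       excluded = data.frame(session_id = exc_id, reason = exc_reason,
                             stringsAsFactors = FALSE))
}

#' Select the TF-IDF vocabulary
#'
#' Each session is one document. For a word with document frequency `df` in
#' a corpus of `N` sessions, `idf = log(N/df)` (natural log, no smoothing)
#' and the importance score is the total corpus term frequency times `idf`,
#' so a word present in every session scores exactly zero. The top `k` words
#' by score are retained; ties at the boundary are broken lexicographically
#' (earlier alphabetical word wins).
#'
#' @param corpus list of [session] objects, or a list of character token
#'   vectors (one per document).
#' @param k number of words to retain (the study default is 5000).
#' @param tokenizer passed to [tokenize()] when `corpus` holds sessions.
#' @return A `vocabulary` object: data.frame with columns `word`, `score`,
#'   `rank`, plus attribute `k`.
#' @export
select_vocabulary <- function(corpus, k, tokenizer = NULL) {
  stopifnot(length(corpus) >= 1, k >= 1)
  docs <- corpus_token_docs(corpus, tokenizer)
  N <- length(docs)
  dt <- data.table::data.table(
    word = unlist(docs, use.names = FALSE),
    doc = rep(seq_len(N), lengths(docs)))
  if (!nrow(dt)) stop("corpus contains no tokens")
  stats <- dt[, .(tf = .N, df = data.table::uniqueN(doc)), by = word]
  stats[, score := tf * log(N / df)]
  data.table::setorder(stats, -score, word)
  n_pos <- stats[, sum(score > 0)]
  if (k > nrow(stats)) {
    warning("k exceeds distinct word count; retaining all words")
  }
  keep <- utils::head(stats, min(k, nrow(stats)))
  out <- data.frame(word = keep$word, score = keep$score,
                    rank = seq_len(nrow(keep)), stringsAsFactors = FALSE)
  structure(out, k = as.integer(k), n_distinct = nrow(stats),
            n_positive = n_pos, class = c("vocabulary", "data.frame"))
}

# Coerce sessions or raw token-vector lists into one token vector per document.
corpus_token_docs <- function(corpus, tokenizer = NULL) {
  if (length(corpus) && inherits(corpus[[1]], "session")) {
    lapply(corpus, function(s) tokenize(s$messages$text, tokenizer = tokenizer))
  } else {
    corpus
  }
}

#' @export
print.vocabulary <- function(x, ...) {
  cat(sprintf("<vocabulary: %d words retained (k=%d) of %d distinct>\n",
              nrow(x), attr(x, "k"), attr(x, "n_distinct")))
  invisible(x)
}

#' Write a vocabulary as TSV (word, score, rank)
#' @param vocab a `vocabulary`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vocabulary <- function(vocab, path) {
  data.table::fwrite(as.data.frame(vocab), path, sep = "\t")
  invisible(path)
}
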