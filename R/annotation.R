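# Lexicon-based ISS detection with false-alarm filtering, block labeling
# (ISSB / PISSB / NISSB), human overrides and NISSB counterpart sampling.

FILTER_REASONS <- c("negation", "subject", "tense", "quoting", "dream", "none")

# First-person tokens used to decide whether the nearest subject is the
# help-seeker themselves; everything in `other_subject_cues` marks a third party.
SELF_CUES <- c("i", "im", "me", "my", "myself", "ive", "id", "ill")

#' Construct an ISS keyword lexicon
#'
#' `iss_terms` are the words/phrases whose occurrence marks explicit ISS
#' disclosure; the five cue sets drive the false-alarm filters (negated
#' ideation, ideation about another subject, past-tense ideation, quoted
#' speech, dream accounts). All entries are normalized with the corpus
#' tokenizer so that matching happens in token space.
#'
#' @param iss_terms character vector, nonempty.
#' @param negation_cues,other_subject_cues,past_tense_cues,reporting_cues,dream_cues
#'   character vectors (may be empty).
#' @param tokenizer passed to [tokenize()].
#' @return A `lexicon` object (list of tokenized term lists).
#' @export
lexicon <- function(iss_terms, negation_cues = character(),
                    other_subject_cues = character(),
                    past_tense_cues = character(),
                    reporting_cues = character(),
                    dream_cues = character(), tokenizer = NULL) {
  if (!length(iss_terms)) stop("lexicon configuration error: iss_terms is empty")
  tok <- function(x) unique(Filter(length, lapply(x, tokenize, tokenizer = tokenizer)))
  structure(
    list(
      iss_terms = tok(iss_terms),
      negation_cues = tok(negation_cues),
      other_subject_cues = tok(other_subject_cues),
      past_tense_cues = tok(past_tense_cues),
      reporting_cues = tok(reporting_cues),
      dream_cues = tok(dream_cues)
    ),
    class = "lexicon"
  )
}

#' Read a lexicon from JSON
#'
#' The file holds six named string arrays: `iss_terms`, `negation_cues`,
#' `other_subject_cues`, `past_tense_cues`, `reporting_cues`, `dream_cues`.
#'
#' @param path JSON file path.
#' @param tokenizer passed to [lexicon()].
#' @return A `lexicon`.
#' @export
read_lexicon <- function(path, tokenizer = NULL) {
  raw <- jsonlite::fromJSON(path)
  get <- function(k) if (is.null(raw[[k]])) character() else as.character(raw[[k]])
  lexicon(get("iss_terms"), get("negation_cues"), get("other_subject_cues"),
          get("past_tense_cues"), get("reporting_cues"), get("dream_cues"),
          tokenizer = tokenizer)
}

#' The packaged English demo lexicon
#'
#' A small English lexicon sufficient for worked examples and tests; real
#' deployments supply their own lexicon file (study-specific keyword lists
#' are not redistributable).
#'
#' @return A `lexicon`.
#' @export
demo_lexicon <- function() {
  read_lexicon(system.file("extdata", "demo_lexicon.json", package = "issnet"))
}

#' @export
print.lexicon <- function(x, ...) {
  cat(sprintf("<lexicon: %d ISS terms; cues n/s/t/q/d = %d/%d/%d/%d/%d>\n",
              length(x$iss_terms), length(x$negation_cues),
              length(x$other_subject_cues), length(x$past_tense_cues),
              length(x$reporting_cues), length(x$dream_cues)))
  invisible(x)
}

# Longest-match, non-overlapping occurrences of any term (list of token
# vectors) in one tokenized message. Returns data.frame(start, end, term).
match_terms_in_tokens <- function(tokens, terms) {
  hits <- data.frame(start = integer(), end = integer(), term = character())
  if (!length(tokens) || !length(terms)) return(hits)
  lens <- lengths(terms)
  ord <- order(-lens)  # longest terms first
  pos <- 1L
  n <- length(tokens)
  while (pos <= n) {
    matched <- FALSE
    for (ti in ord) {
      tt <- terms[[ti]]
      L <- length(tt)
      if (pos + L - 1L <= n && identical(tokens[pos:(pos + L - 1L)], tt)) {
        hits <- rbind(hits, data.frame(
          start = pos, end = pos + L - 1L,
          term = paste(tt, collapse = " "), stringsAsFactors = FALSE))
        pos <- pos + L
        matched <- TRUE
        break
      }
    }
    if (!matched) pos <- pos + 1L
  }
  hits
}

#' Match ISS terms in a block
#'
#' Scans every help-seeker message of the block for occurrences of the
#' lexicon's ISS terms (longest match, non-overlapping, per occurrence).
#' Every hit is returned with `status = "retained"`; run
#' [filter_false_alarms()] to demote false alarms.
#'
#' @param block an `iss_block` from [segment_blocks()].
#' @param lex a [lexicon].
#' @return data.frame with columns `session_id`, `block_index`,
#'   `message_seq`, `term`, `start`, `end`, `status`, `filter_reason`.
#' @export
match_iss <- function(block, lex) {
  stopifnot(inherits(block, "iss_block"))
  if (!inherits(lex, "lexicon") || !length(lex$iss_terms))
    stop("lexicon configuration error: no ISS terms loaded")
  out <- lapply(seq_along(block$message_tokens), function(k) {
    h <- match_terms_in_tokens(block$message_tokens[[k]], lex$iss_terms)
    if (!nrow(h)) return(NULL)
    data.frame(session_id = block$session_id, block_index = block$block_index,
               message_seq = block$message_seqs[k], term = h$term,
               start = h$start, end = h$end,
               status = "retained", filter_reason = "none",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(session_id = character(), block_index = integer(),
                      message_seq = integer(), term = character(),
                      start = integer(), end = integer(), status = character(),
                      filter_reason = character(), stringsAsFactors = FALSE)
  out
}

# positions (token indices) at which any cue term occurs in a message
cue_positions <- function(tokens, cues) {
  if (!length(cues)) return(integer())
  m <- match_terms_in_tokens(tokens, cues)
  m$start
}

#' Demote keyword false alarms
#'
#' Re-scores each retained match against five false-alarm classes, in fixed
#' precedence order (first triggered rule wins):
#' \describe{
#'   \item{negation}{a negation cue occurs within `window` tokens before the term;}
#'   \item{subject}{the nearest subject mention before the term (first-person
#'     pronoun or an `other_subject` cue) is a third party;}
#'   \item{tense}{a past-tense cue occurs within `window` tokens before the
#'     term or inside the matched span (inflected past forms of ISS verbs act
#'     as their own cue);}
#'   \item{quoting}{a reporting cue precedes the term in the message;}
#'   \item{dream}{a dream cue occurs anywhere in the message.}
#' }
#'
#' @param matches output of [match_iss()].
#' @param block the same block.
#' @param lex the [lexicon].
#' @param window cue proximity window in tokens (default 6).
#' @return `matches` with `status`/`filter_reason` updated. Idempotent.
#' @export
filter_false_alarms <- function(matches, block, lex, window = 6) {
  if (!nrow(matches)) return(matches)
  for (r in seq_len(nrow(matches))) {
    k <- match(matches$message_seq[r], block$message_seqs)
    toks <- block$message_tokens[[k]]
    s <- matches$start[r]; e <- matches$end[r]
    before <- function(pos) pos < s
    near_before <- function(pos) pos < s & pos >= s - window
    neg <- cue_positions(toks, lex$negation_cues)
    subj_other <- cue_positions(toks, lex$other_subject_cues)
    subj_self <- cue_positions(toks, list_of_tokens(SELF_CUES))
    past <- cue_positions(toks, lex$past_tense_cues)
    rep_ <- cue_positions(toks, lex$reporting_cues)
    drm <- cue_positions(toks, lex$dream_cues)
    reason <- "none"
    if (any(near_before(neg))) {
      reason <- "negation"
    } else if (length(subj_other) && any(before(subj_other))) {
      nearest_other <- max(subj_other[before(subj_other)])
      nearest_self <- if (any(before(subj_self))) max(subj_self[before(subj_self)]) else -Inf
      if (nearest_other > nearest_self) reason <- "subject"
    }
    if (reason == "none" && any(near_before(past) | (past >= s & past <= e)))
      reason <- "tense"
    if (reason == "none" && any(before(rep_))) reason <- "quoting"
    if (reason == "none" && length(drm)) reason <- "dream"
    matches$filter_reason[r] <- reason
    matches$status[r] <- if (reason == "none") "retained" else "filtered"
  }
  matches
}

list_of_tokens <- function(words) lapply(words, function(w) w)

#' Label a session's blocks as ISSB / PISSB / NISSB
#'
#' A block is an ISS block when it has at least one retained match. Within a
#' session only the first ISS block is labeled `ISSB`; the block immediately
#' before it becomes `PISSB`; every other block becomes `NISSB` (later ISS
#' blocks included). When the first ISS block is block 0 there is no prior
#' block to predict, and the session is flagged `no_pissb` (it is still
#' labeled, the ISSB keeping its label, for downstream exclusion).
#'
#' @param blocks list of `iss_block`s from one session, in order.
#' @param iss_status logical vector, one per block: block has >= 1 retained
#'   ISS match. Alternatively pass the row-bound match table via
#'   `matches` and it is reduced per block.
#' @param matches optional data.frame of (filtered) matches for the session.
#' @param allow_partial_labels may a partial (short final) block anchor the
#'   ISSB/PISSB pair (default `FALSE`; partial blocks stay eligible as NISSB).
#' @return The blocks with `label` set, plus attribute `no_pissb` (logical).
#' @export
label_blocks <- function(blocks, iss_status = NULL, matches = NULL,
                         allow_partial_labels = FALSE) {
  stopifnot(xor(is.null(iss_status), is.null(matches)))
  bi <- vapply(blocks, `[[`, 0, "block_index")
  stopifnot(!is.unsorted(bi))
  if (is.null(iss_status)) {
    retained <- matches[matches$status == "retained", , drop = FALSE]
    iss_status <- bi %in% retained$block_index
  }
  stopifnot(length(iss_status) == length(blocks))
  if (!allow_partial_labels)
    iss_status <- iss_status & !vapply(blocks, `[[`, TRUE, "is_partial")
  labels <- rep("NISSB", length(blocks))
  no_pissb <- FALSE
  first <- which(iss_status)[1]
  if (!is.na(first)) {
    labels[first] <- "ISSB"
    if (first == 1L) no_pissb <- TRUE else labels[first - 1L] <- "PISSB"
  }
  out <- Map(function(b, l) { b$label <- l; b }, blocks, labels)
  attr(out, "no_pissb") <- no_pissb
  out
}

#' Apply human label overrides
#'
#' Overrides come from a TSV with columns `session_id`, `block_index`,
#' `decision` (`ISS` or `not_ISS`) and take absolute precedence over the
#' automatic ISS status. Overrides naming unknown blocks are ignored with a
#' warning. Provenance is recorded in the returned table.
#'
#' @param status data.frame with `session_id`, `block_index`, `iss` (logical)
#'   — the automatic per-block ISS status.
#' @param overrides data.frame with `session_id`, `block_index`, `decision`,
#'   or a path to such a TSV.
#' @return `status` with `iss` corrected and a `source` column
#'   (`"auto"`/`"override"`); attribute `n_unknown` counts ignored overrides.
#' @export
apply_overrides <- function(status, overrides) {
  if (is.character(overrides))
    overrides <- as.data.frame(data.table::fread(overrides, sep = "\t"))
  status$source <- "auto"
  n_unknown <- 0L
  if (!is.null(overrides) && nrow(overrides)) {
    for (r in seq_len(nrow(overrides))) {
      hit <- which(status$session_id == as.character(overrides$session_id[r]) &
                   status$block_index == overrides$block_index[r])
      if (!length(hit)) {
        warning("override for unknown block ", overrides$session_id[r], "/",
                overrides$block_index[r], " ignored")
        n_unknown <- n_unknown + 1L
        next
      }
      status$iss[hit] <- overrides$decision[r] == "ISS"
      status$source[hit] <- "override"
    }
  }
  attr(status, "n_unknown") <- n_unknown
  status
}

#' Sample NISSB counterpart blocks
#'
#' Uniform sampling without replacement from the NISSB pool, reproducible
#' under the supplied seed (the sampling leaves the global RNG state alone).
#'
#' @param nissb_pool list of blocks (or any list).
#' @param n sample size.
#' @param seed integer seed.
#' @return A list of `n` elements of the pool.
#' @export
sample_nissb <- function(nissb_pool, n, seed) {
  if (length(nissb_pool) < n)
    stop(sprintf("NISSB pool too small: need %d, have %d", n, length(nissb_pool)))
  idx <- withr::with_seed(seed, sample.int(length(nissb_pool), n))
  nissb_pool[idx]
}
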