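# Synthetic counseling-corpus generator. Emulates the structure the method
# assumes: a minority of sessions carry an explicit-ISS block preceded by a
# "prodromal" block whose vocabulary is network-close to ISS vocabulary;
# everything else is neutral chatter. Also a direct score-distribution
# sampler matching reported group statistics.

#' Generator configuration
#'
#' Defaults define the packaged study conditions: 2000 network-construction
#' sessions and 600 labeled sessions (half with a planted ISS disclosure),
#' a 700/60/40 neutral/prodromal/ISS lexicon (800 words total), Zipf token
#' frequencies with exponent 1.1, prodromal mixture 0.35 and ISS mixture
#' 0.4, ten help-seeker messages per block.
#'
#' @param seed integer seed (mandatory; every output is a pure function of
#'   the config including this seed).
#' @param n_wan_sessions sessions for network construction.
#' @param n_labeled_sessions sessions for the labeled corpus.
#' @param iss_session_fraction fraction of sessions with a planted ISS block.
#' @param messages_per_session integer range `c(lo, hi)` of total messages
#'   (both speakers; speakers alternate starting with the help-seeker).
#' @param tokens_per_message integer range of tokens per message.
#' @param n_neutral,n_prodromal,n_iss lexicon sizes (>= 10 each).
#' @param zipf_exponent Zipf exponent over each lexicon (default 1.1).
#' @param prodromal_mix fraction of prodromal-block tokens drawn from the
#'   prodromal (ISS-adjacent) lexicon; 0 plants no signal.
#' @param iss_mix fraction of ISS-block tokens drawn from the ISS lexicon.
#' @param block_size help-seeker messages per block (default 10).
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed,
                             n_wan_sessions = 2000,
                             n_labeled_sessions = 600,
                             iss_session_fraction = 0.5,
                             messages_per_session = c(60, 100),
                             tokens_per_message = c(6, 12),
                             n_neutral = 700, n_prodromal = 60, n_iss = 40,
                             zipf_exponent = 1.1,
                             prodromal_mix = 0.35, iss_mix = 0.4,
                             block_size = 10) {
  stopifnot(!missing(seed),
            iss_session_fraction >= 0, iss_session_fraction <= 1,
            prodromal_mix >= 0, prodromal_mix <= 1,
            iss_mix >= 0, iss_mix <= 1,
            n_neutral >= 10, n_prodromal >= 10, n_iss >= 10,
            length(messages_per_session) == 2, block_size >= 1)
  if (messages_per_session[1] < 6 * block_size)
    stop("messages_per_session too small to host neutral + prodromal + ISS blocks")
  structure(list(seed = as.integer(seed), n_wan_sessions = n_wan_sessions,
                 n_labeled_sessions = n_labeled_sessions,
                 iss_session_fraction = iss_session_fraction,
                 messages_per_session = as.integer(messages_per_session),
                 tokens_per_message = as.integer(tokens_per_message),
                 n_neutral = n_neutral, n_prodromal = n_prodromal, n_iss = n_iss,
                 zipf_exponent = zipf_exponent, prodromal_mix = prodromal_mix,
                 iss_mix = iss_mix, block_size = block_size),
            class = "generator_config")
}

#' Make the three disjoint synthetic lexicons
#'
#' Word strings are synthetic (`ntr####`, `pro####`, `iss####`); a quarter of
#' the ISS lexicon entries are two-token phrases (`issp####a issp####b`), so
#' phrase matching in the annotator is exercised. Deterministic under the
#' config seed.
#'
#' @param config a [generator_config()].
#' @return List with `neutral`, `prodromal` (character vectors of words) and
#'   `iss` (character vector of entries, some two-token phrases).
#' @export
make_lexicons <- function(config) {
  n_phrase <- max(1L, config$n_iss %/% 4L)
  n_single <- config$n_iss - n_phrase
  list(
    neutral = sprintf("ntr%04d", seq_len(config$n_neutral)),
    prodromal = sprintf("pro%04d", seq_len(config$n_prodromal)),
    iss = c(sprintf("iss%04d", seq_len(n_single)),
            sprintf("issp%04da issp%04db", seq_len(n_phrase), seq_len(n_phrase)))
  )
}

#' Annotation lexicon matching the synthetic ISS entries
#'
#' @param lexicons output of [make_lexicons()].
#' @return A [lexicon] whose `iss_terms` are the planted ISS entries (cue
#'   sets empty: the generator plants no false alarms).
#' @export
synthetic_annotation_lexicon <- function(lexicons) {
  lexicon(iss_terms = lexicons$iss)
}

zipf_probs <- function(n, s) {
  p <- (seq_len(n))^(-s)
  p / sum(p)
}

# draw n entries from a lexicon under Zipf ranks (entries are in rank order)
draw_entries <- function(lexicon_entries, n, s) {
  if (n == 0) return(character())
  sample(lexicon_entries, n, replace = TRUE, prob = zipf_probs(length(lexicon_entries), s))
}

# one block's worth of help-seeker message texts
gen_block_messages <- function(n_msgs, kind, config, lex) {
  s <- config$zipf_exponent
  vapply(seq_len(n_msgs), function(i) {
    L <- sample(config$tokens_per_message[1]:config$tokens_per_message[2], 1)
    cat_draw <- stats::runif(L)
    toks <- character(L)
    if (kind == "iss") {
      is_iss <- cat_draw < config$iss_mix
      is_pro <- !is_iss & cat_draw < config$iss_mix +
        (1 - config$iss_mix) * config$prodromal_mix
      toks[is_iss] <- draw_entries(lex$iss, sum(is_iss), s)
      toks[is_pro] <- draw_entries(lex$prodromal, sum(is_pro), s)
      toks[!is_iss & !is_pro] <- draw_entries(lex$neutral, sum(!is_iss & !is_pro), s)
    } else if (kind == "prodromal") {
      is_pro <- cat_draw < config$prodromal_mix
      toks[is_pro] <- draw_entries(lex$prodromal, sum(is_pro), s)
      toks[!is_pro] <- draw_entries(lex$neutral, sum(!is_pro), s)
    } else {
      toks <- draw_entries(lex$neutral, L, s)
    }
    paste(toks, collapse = " ")
  }, "")
}

#' Generate one synthetic session
#'
#' Messages alternate help-seeker / counselor (counselor messages always
#' neutral). A `kind = "neutral"` session is neutral throughout. A
#' `kind = "iss"` session contains, in help-seeker block order: at least one
#' neutral block, one prodromal block (mixture `prodromal_mix` from the
#' prodromal lexicon), then one ISS block (mixture `iss_mix` from the ISS
#' lexicon, remainder prodromal/neutral so that prodromal words co-occur
#' with explicit ISS terms), then neutral blocks.
#'
#' The caller is responsible for seeding; [generate_corpus()] wraps
#' everything under the config seed.
#'
#' @param config a [generator_config()].
#' @param session_id identifier for the session.
#' @param kind `"neutral"` or `"iss"`.
#' @param lexicons from [make_lexicons()].
#' @return A [session]; attribute `planted` gives the 0-based indices of the
#'   prodromal and ISS blocks (`NULL` for neutral sessions).
#' @export
generate_session <- function(config, session_id, kind = c("neutral", "iss"),
                             lexicons = make_lexicons(config)) {
  kind <- match.arg(kind)
  bs <- config$block_size
  n_msgs <- sample(config$messages_per_session[1]:config$messages_per_session[2], 1)
  n_h <- ceiling(n_msgs / 2)
  nb_full <- n_h %/% bs
  planted <- NULL
  block_kinds <- rep("neutral", ceiling(n_h / bs))
  if (kind == "iss") {
    if (nb_full < 3) stop("session too short to host the planted ISS pattern")
    p <- if (nb_full == 3) 1L else sample(seq_len(nb_full - 2L), 1)
    block_kinds[p + 1L] <- "prodromal"
    block_kinds[p + 2L] <- "iss"
    planted <- c(prodromal = p, iss = p + 1L)
  }
  h_texts <- unlist(lapply(seq_along(block_kinds), function(b) {
    n_in_block <- min(bs, n_h - (b - 1) * bs)
    gen_block_messages(n_in_block, block_kinds[b], config, lexicons)
  }), use.names = FALSE)
  c_texts <- gen_block_messages(n_msgs - n_h, "neutral", config, lexicons)
  roles <- rep(c("H", "C"), length.out = n_msgs)
  texts <- character(n_msgs)
  texts[roles == "H"] <- h_texts
  texts[roles == "C"] <- c_texts
  s <- session(session_id, seq = seq_len(n_msgs), role = roles, text = texts)
  attr(s, "planted") <- planted
  s
}

#' Generate a full synthetic corpus
#'
#' Two independent session sets from the same generative process: one for
#' word-affinity-network construction, one for labeling/training. All
#' randomness derives from `config$seed`.
#'
#' @param config a [generator_config()].
#' @return List with `wan_corpus`, `labeled_corpus` (lists of [session]s),
#'   `lexicons`, `annotation_lexicon`, `truth` (data.frame of planted
#'   prodromal/ISS block indices for the labeled corpus) and `config`.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  lex <- make_lexicons(config)
  withr::with_seed(config$seed, {
    gen_set <- function(n, prefix) {
      n_iss <- round(n * config$iss_session_fraction)
      kinds <- rep(c("iss", "neutral"), c(n_iss, n - n_iss))
      kinds <- sample(kinds)
      lapply(seq_len(n), function(k)
        generate_session(config, sprintf("%s%05d", prefix, k), kinds[k], lex))
    }
    wan_corpus <- gen_set(config$n_wan_sessions, "w")
    labeled_corpus <- gen_set(config$n_labeled_sessions, "s")
    truth <- do.call(rbind, lapply(labeled_corpus, function(s) {
      pl <- attr(s, "planted")
      data.frame(session_id = s$session_id,
                 prodromal_block = if (is.null(pl)) NA_integer_ else pl[["prodromal"]],
                 iss_block = if (is.null(pl)) NA_integer_ else pl[["iss"]],
                 stringsAsFactors = FALSE)
    }))
    list(wan_corpus = wan_corpus, labeled_corpus = labeled_corpus,
         lexicons = lex, annotation_lexicon = synthetic_annotation_lexicon(lex),
         truth = truth, config = config)
  })
}

#' Sample labeled s-bar scores from two normal group distributions
#'
#' Draws `n_per_class` scores from `Normal(pissb_mean, pissb_sd)` labeled
#' `PISSB` and the same number from `Normal(nissb_mean, nissb_sd)` labeled
#' `NISSB`. The defaults are the reported group statistics for the two
#' classes (0.23 +/- 0.03 vs 0.30 +/- 0.05).
#'
#' @param n_per_class draws per class (default 1168).
#' @param pissb_mean,pissb_sd,nissb_mean,nissb_sd normal parameters.
#' @param seed integer seed.
#' @return data.frame with `score`, `label`.
#' @export
generate_scores <- function(n_per_class = 1168,
                            pissb_mean = 0.23, pissb_sd = 0.03,
                            nissb_mean = 0.30, nissb_sd = 0.05, seed = 1) {
  stopifnot(pissb_sd > 0, nissb_sd > 0)
  withr::with_seed(seed, {
    data.frame(
      score = c(stats::rnorm(n_per_class, pissb_mean, pissb_sd),
                stats::rnorm(n_per_class, nissb_mean, nissb_sd)),
      label = rep(c("PISSB", "NISSB"), each = n_per_class),
      stringsAsFactors = FALSE)
  })
}
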