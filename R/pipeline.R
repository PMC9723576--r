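# End-to-end orchestration: annotate a labeled corpus, project blocks onto
# the network, score s-bar against the ISSB reference set, train/evaluate
# the threshold classifier, replicate with NISSB resampling, and write the
# artifact tree.

#' Annotate a corpus: segment, match, filter, label
#'
#' Applies the inclusion criteria (>= `min_exchanges` messages), segments
#' every kept session into help-seeker blocks, runs ISS keyword matching
#' with false-alarm filtering, applies any human overrides, and labels
#' blocks ISSB / PISSB / NISSB (first-ISSB rule). Sessions whose first ISS
#' block is block 0 are excluded with reason `no_pissb`.
#'
#' @param sessions list of [session] objects.
#' @param lex a [lexicon].
#' @param block_size help-seeker messages per block (default 10).
#' @param overrides optional overrides table or TSV path (see
#'   [apply_overrides()]).
#' @param min_exchanges inclusion threshold on total messages (default 10).
#' @param tokenizer passed to [tokenize()].
#' @param window false-alarm cue window (default 6).
#' @return List with `blocks` (flat list of labeled `iss_block`s from kept
#'   sessions), `labels` (data.frame), `excluded` (data.frame with reasons).
#' @export
annotate_corpus <- function(sessions, lex, block_size = 10, overrides = NULL,
                            min_exchanges = 10, tokenizer = NULL, window = 6) {
  flt <- filter_sessions(sessions, min_exchanges = min_exchanges)
  excluded <- flt$excluded
  all_blocks <- list()
  label_rows <- list()
  for (s in flt$kept) {
    blocks <- segment_blocks(s, block_size = block_size, tokenizer = tokenizer)
    if (!length(blocks)) next
    matches <- do.call(rbind, lapply(blocks, function(b)
      filter_false_alarms(match_iss(b, lex), b, lex, window = window)))
    bi <- vapply(blocks, `[[`, 0, "block_index")
    n_ret <- vapply(bi, function(i)
      sum(matches$block_index == i & matches$status == "retained"), 0)
    status <- data.frame(session_id = s$session_id, block_index = bi,
                         iss = n_ret > 0, stringsAsFactors = FALSE)
    if (!is.null(overrides)) status <- apply_overrides(status, overrides)
    labeled <- label_blocks(blocks, iss_status = status$iss)
    if (attr(labeled, "no_pissb")) {
      excluded <- rbind(excluded, data.frame(session_id = s$session_id,
                                             reason = "no_pissb"))
      next
    }
    all_blocks <- c(all_blocks, labeled)
    label_rows[[s$session_id]] <- data.frame(
      session_id = s$session_id, block_index = bi,
      label = vapply(labeled, `[[`, "", "label"),
      n_retained_matches = n_ret,
      is_partial = vapply(labeled, `[[`, TRUE, "is_partial"),
      stringsAsFactors = FALSE)
  }
  list(blocks = all_blocks,
       labels = if (length(label_rows)) do.call(rbind, c(label_rows, make.row.names = FALSE))
                else data.frame(session_id = character(), block_index = integer(),
                                label = character(), n_retained_matches = integer(),
                                is_partial = logical()),
       excluded = excluded)
}

#' Project all blocks with a given label onto the network
#'
#' Convenience selector: keeps blocks labeled `label`, projects each with
#' [block_module()], and drops modules with no in-network words.
#'
#' @param blocks list of labeled `iss_block`s (from [annotate_corpus()]).
#' @param label `"ISSB"`, `"PISSB"` or `"NISSB"`.
#' @param net an `affinity_network`.
#' @return List of `block_module`s.
#' @export
modules_by_label <- function(blocks, label, net) {
  sel <- Filter(function(b) b$label == label, blocks)
  mods <- lapply(sel, block_module, net = net)
  Filter(function(m) m$n >= 1, mods)
}

#' Train and evaluate the PISSB classifier with NISSB resampling
#'
#' The replication protocol over a fixed network: in each trial, NISSB
#' counterpart modules are resampled from the pool (same count as PISSBs),
#' the PISSB+NISSB records are split 80/20 stratified, every block is scored
#' by its mean separation s-bar from the ISSB reference set, the optimal
#' threshold is trained, and train/test c-statistics are recorded.
#'
#' The ISSB reference set defaults to ISSBs of training-split sessions only,
#' and a scored block never sees its own session's ISSB
#' (`leakage_guard`); `paper_naive = TRUE` uses all ISSBs for every block.
#'
#' @param net an `affinity_network` (largest connected component).
#' @param issb,pissb,nissb_pool lists of `block_module`s.
#' @param n_reps trials (default 50).
#' @param frac training fraction (default 0.8).
#' @param seed master seed; trial r uses `seed + r`.
#' @param metric `"hops"` (default) or `"length"`.
#' @param leakage_guard exclude a block's own session's ISSB from its
#'   reference set (default `TRUE`).
#' @param paper_naive reference set = all ISSBs regardless of split.
#' @param dist optional precomputed distance matrix.
#' @return List with `trials` (data.frame), `summary`, and `last` (details
#'   of the final trial: records, model, eval).
#' @export
run_experiment <- function(net, issb, pissb, nissb_pool, n_reps = 50,
                           frac = 0.8, seed = 1,
                           metric = c("hops", "length"),
                           leakage_guard = TRUE, paper_naive = FALSE,
                           dist = NULL) {
  metric <- match.arg(metric)
  stopifnot(length(issb) >= 1, length(pissb) >= 2)
  if (length(nissb_pool) < length(pissb))
    stop("NISSB pool smaller than the PISSB set")
  if (is.null(dist)) dist <- net_distances(net, metric = metric)
  S_p <- s_score_matrix(pissb, issb, dist)
  S_n <- s_score_matrix(nissb_pool, issb, dist)
  sid_p <- vapply(pissb, `[[`, "", "session_id")
  sid_n <- vapply(nissb_pool, `[[`, "", "session_id")
  sid_i <- vapply(issb, `[[`, "", "session_id")

  sbar <- function(S, row_sids, ref_cols) {
    w <- length(ref_cols)
    rs <- rowSums(S[, ref_cols, drop = FALSE])
    if (!leakage_guard) return(rs / w)
    own <- match(row_sids, sid_i[ref_cols])
    has_own <- !is.na(own)
    out <- rs / w
    if (any(has_own)) {
      own_vals <- S[cbind(which(has_own), ref_cols[own[has_own]])]
      out[has_own] <- if (w > 1) (rs[has_own] - own_vals) / (w - 1) else NA_real_
    }
    out
  }

  rows <- vector("list", n_reps)
  last <- NULL
  for (r in seq_len(n_reps)) {
    trial_seed <- seed + r
    n_idx <- withr::with_seed(trial_seed * 2L + 1L,
                              sample.int(length(nissb_pool), length(pissb)))
    rec <- data.frame(
      kind = rep(c("P", "N"), c(length(pissb), length(n_idx))),
      idx = c(seq_along(pissb), n_idx),
      session_id = c(sid_p, sid_n[n_idx]),
      label = rep(c("PISSB", "NISSB"), c(length(pissb), length(n_idx))),
      stringsAsFactors = FALSE)
    sp <- split_train_test(rec, frac = frac, seed = trial_seed)
    ref_cols <- if (paper_naive) seq_along(issb)
                else which(sid_i %in% sp$train$session_id)
    if (!length(ref_cols)) ref_cols <- seq_along(issb)
    score_of <- function(d) {
      out <- numeric(nrow(d))
      isP <- d$kind == "P"
      out[isP] <- sbar(S_p[d$idx[isP], , drop = FALSE], d$session_id[isP], ref_cols)
      out[!isP] <- sbar(S_n[d$idx[!isP], , drop = FALSE], d$session_id[!isP], ref_cols)
      out
    }
    tr_scores <- score_of(sp$train); te_scores <- score_of(sp$test)
    model <- optimal_threshold(tr_scores, sp$train$label)
    ev <- evaluate_threshold(model, te_scores, sp$test$label)
    rows[[r]] <- data.frame(trial = r, seed = trial_seed, t = model$t,
                            train_c = c_statistic(tr_scores, sp$train$label),
                            test_c = ev$c_statistic,
                            test_sens = ev$sensitivity, test_spec = ev$specificity,
                            n_ref_issb = length(ref_cols))
    if (r == n_reps)
      last <- list(model = model, eval = ev,
                   train = data.frame(sp$train, s_bar = tr_scores),
                   test = data.frame(sp$test, s_bar = te_scores))
  }
  trials <- do.call(rbind, rows)
  list(trials = trials,
       summary = list(n_reps = n_reps,
                      mean_test_c = mean(trials$test_c),
                      sd_test_c = stats::sd(trials$test_c),
                      mean_train_c = mean(trials$train_c),
                      mean_t = mean(trials$t)),
       last = last)
}

#' Validate and default a pipeline run configuration
#'
#' Unknown fields are rejected; missing fields are filled with defaults;
#' contradictory settings (both `theta_s` and `top_k`) are rejected. All
#' violations are reported together.
#'
#' @param config named list of settings (may be empty).
#' @return The completed config (class `run_config`); attribute `applied_defaults`
#'   names every field that was defaulted.
#' @export
validate_config <- function(config = list()) {
  defaults <- list(
    seed = 1L, outdir = NULL,
    corpus_path = NULL, lexicon_path = NULL, overrides_path = NULL,
    n_wan_sessions = 2000, n_labeled_sessions = 600,
    iss_session_fraction = 0.5, prodromal_mix = 0.35, iss_mix = 0.4,
    block_size = 10, k_vocab = 800,
    window = 5, min_count = 3, dim = 32, epochs = 20,
    theta_s = 0.6, top_k = NULL,
    metric = "hops", frac = 0.8, n_reps = 50,
    n_null_draws = 200, n_modularity_blocks = 50,
    leakage_guard = TRUE, paper_naive = FALSE)
  errs <- character()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    errs <- c(errs, paste0("unknown field(s): ", paste(unknown, collapse = ", ")))
  filled <- utils::modifyList(defaults, config[intersect(names(config), names(defaults))],
                              keep.null = TRUE)
  applied <- setdiff(names(defaults), names(config))
  if (!is.null(filled$frac) && (filled$frac <= 0 || filled$frac >= 1))
    errs <- c(errs, "frac: split fraction out of range (0, 1)")
  if (!is.null(config$theta_s) && !is.null(config$top_k))
    errs <- c(errs, "theta_s, top_k: set only one similarity retention rule")
  if (!filled$metric %in% c("hops", "length"))
    errs <- c(errs, "metric: must be 'hops' or 'length'")
  for (f in c("corpus_path", "lexicon_path", "overrides_path"))
    if (!is.null(filled[[f]]) && !file.exists(filled[[f]]))
      errs <- c(errs, paste0(f, ": file does not exist: ", filled[[f]]))
  if (length(errs)) stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "))
  if (!is.null(config$top_k)) filled$theta_s <- NULL
  structure(filled, applied_defaults = applied, class = "run_config")
}

log_line <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  writeLines(msg, con)
  message(msg)
}

#' Run the whole pipeline and write the artifact tree
#'
#' simulate (unless a corpus file is given) -> annotate -> build network ->
#' modularity report -> s-bar scoring -> threshold training -> replication
#' -> path explanations. Deterministic given the config (including its
#' seed). Artifacts written to `config$outdir`: `vocabulary.tsv`,
#' `wan.graphml`, `labels.tsv`, `modularity.json`, `scores.tsv`,
#' `threshold.json`, `eval.json`, `explanations.tsv`, `run.log`.
#'
#' @param config a list accepted by [validate_config()]; `outdir` required.
#' @return Invisibly, a list with the in-memory results (`net`, `annotated`,
#'   `modularity`, `experiment`, `paths`).
#' @export
run_all <- function(config) {
  cfg <- validate_config(config)
  if (is.null(cfg$outdir)) stop("config$outdir is required")
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  logcon <- file(file.path(cfg$outdir, "run.log"), open = "w")
  on.exit(close(logcon))
  log_line(logcon, "config: ", jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, null = "null"))
  log_line(logcon, "defaults applied: ",
           paste(attr(cfg, "applied_defaults"), collapse = ", "))

  stage <- function(name, expr) {
    log_line(logcon, "stage ", name, " ...")
    tryCatch(expr, error = function(e) {
      writeLines("FAILED", file.path(cfg$outdir, "FAILED"))
      log_line(logcon, "stage ", name, " FAILED: ", conditionMessage(e))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  corp <- stage("simulate", {
    if (is.null(cfg$corpus_path)) {
      gc_ <- generator_config(seed = cfg$seed,
                              n_wan_sessions = cfg$n_wan_sessions,
                              n_labeled_sessions = cfg$n_labeled_sessions,
                              iss_session_fraction = cfg$iss_session_fraction,
                              prodromal_mix = cfg$prodromal_mix,
                              iss_mix = cfg$iss_mix,
                              block_size = cfg$block_size)
      generate_corpus(gc_)
    } else {
      sess <- read_sessions(cfg$corpus_path)
      list(wan_corpus = sess, labeled_corpus = sess,
           annotation_lexicon = read_lexicon(cfg$lexicon_path))
    }
  })
  lex <- if (!is.null(cfg$lexicon_path)) read_lexicon(cfg$lexicon_path)
         else corp$annotation_lexicon

  vocab <- stage("vocabulary", {
    v <- select_vocabulary(corp$wan_corpus, k = cfg$k_vocab)
    write_vocabulary(v, file.path(cfg$outdir, "vocabulary.tsv"))
    v
  })

  net <- stage("build-wan", {
    n <- build_wan(corp$wan_corpus, vocab, window = cfg$window,
                   min_count = cfg$min_count, dim = cfg$dim,
                   epochs = cfg$epochs, theta_s = cfg$theta_s,
                   top_k = cfg$top_k, seed = cfg$seed)
    n <- restrict_to_lcc(n)
    write_wan_graphml(n, file.path(cfg$outdir, "wan.graphml"))
    n
  })

  ann <- stage("annotate", {
    a <- annotate_corpus(corp$labeled_corpus, lex, block_size = cfg$block_size,
                         overrides = cfg$overrides_path)
    data.table::fwrite(a$labels, file.path(cfg$outdir, "labels.tsv"), sep = "\t")
    a
  })

  dist <- net_distances(net, metric = cfg$metric)
  issb <- modules_by_label(ann$blocks, "ISSB", net)
  pissb <- modules_by_label(ann$blocks, "PISSB", net)
  nissb <- modules_by_label(ann$blocks, "NISSB", net)

  modrep <- stage("modularity", {
    sel <- utils::head(c(issb, pissb), cfg$n_modularity_blocks)
    rep_ <- group_modularity_report(sel, net, n_draws = cfg$n_null_draws,
                                    seed = cfg$seed, metric = cfg$metric, dist = dist)
    jsonlite::write_json(rep_$group, file.path(cfg$outdir, "modularity.json"),
                         auto_unbox = TRUE, digits = NA)
    rep_
  })

  exp_ <- stage("score-train-evaluate", {
    e <- run_experiment(net, issb, pissb, nissb, n_reps = cfg$n_reps,
                        frac = cfg$frac, seed = cfg$seed, metric = cfg$metric,
                        leakage_guard = cfg$leakage_guard,
                        paper_naive = cfg$paper_naive, dist = dist)
    scores <- rbind(data.frame(e$last$train, split = "train"),
                    data.frame(e$last$test, split = "test"))
    data.table::fwrite(scores[, c("session_id", "label", "split", "s_bar")],
                       file.path(cfg$outdir, "scores.tsv"), sep = "\t")
    jsonlite::write_json(
      list(t = e$last$model$t, metric = cfg$metric,
           reference_set_policy = if (cfg$paper_naive) "all_issb" else "train_sessions",
           train_sensitivity = e$last$model$train_sensitivity,
           train_specificity = e$last$model$train_specificity),
      file.path(cfg$outdir, "threshold.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      list(seed = cfg$seed, replication = e$summary,
           final_trial = list(test_c = e$last$eval$c_statistic,
                              sensitivity = e$last$eval$sensitivity,
                              specificity = e$last$eval$specificity,
                              confusion = as.list(e$last$eval$confusion)),
           trials = e$trials),
      file.path(cfg$outdir, "eval.json"), auto_unbox = TRUE, digits = NA)
    e
  })

  paths <- stage("explain", {
    p <- if (length(pissb) && length(issb))
      explain_paths(pissb[[1]], issb, net, top_n = 5)
    else data.frame()
    data.table::fwrite(p, file.path(cfg$outdir, "explanations.tsv"), sep = "\t")
    p
  })

  log_line(logcon, sprintf("done: mean test c-statistic %.4f over %d trials",
                           exp_$summary$mean_test_c, cfg$n_reps))
  invisible(list(config = cfg, net = net, annotated = ann, modularity = modrep,
                 experiment = exp_, paths = paths))
}
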