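# Shortest-path machinery, block compactness l_block, degree-matched random
# null with one-tailed z-test (modularity), the separation s-score, mean set
# distances s-bar, and ranked shortest-path explanations.
#
# Two distance metrics live on the same network: "hops" (unweighted steps,
# the default for l_block / s-score) and "length" (1 - affinity edge weights,
# used for human-readable path explanations).

SD_FLOOR <- 1e-9

metric_weights <- function(net, metric) {
  if (metric == "hops") NA else igraph::E(net$graph)$length
}

#' Shortest-path distances on the affinity network
#'
#' @param net an `affinity_network`.
#' @param sources optional character vector of source words (default: all).
#' @param to optional character vector of target words (default: all).
#' @param metric `"hops"` (unweighted) or `"length"` (1 - affinity weights).
#' @return Numeric matrix of distances (`Inf` marks unreachable pairs),
#'   dimnames = words.
#' @export
net_distances <- function(net, sources = NULL, to = NULL,
                          metric = c("hops", "length")) {
  metric <- match.arg(metric)
  nodes <- network_words(net)
  for (s in c(sources, to)) if (!s %in% nodes) stop("unknown word: ", s)
  igraph::distances(net$graph,
                    v = if (is.null(sources)) igraph::V(net$graph) else sources,
                    to = if (is.null(to)) igraph::V(net$graph) else to,
                    weights = metric_weights(net, metric))
}

#' Project a block onto the network as a word module
#'
#' The module is the set of distinct block tokens that are network nodes;
#' out-of-vocabulary tokens are counted, not kept.
#'
#' @param block an `iss_block` (or a character vector of tokens).
#' @param net an `affinity_network`.
#' @return A `block_module`: list with `session_id`, `block_index`, `label`,
#'   `words`, `n`, `oov_dropped`.
#' @export
block_module <- function(block, net) {
  if (inherits(block, "iss_block")) {
    toks <- unique(block$tokens)
    sid <- block$session_id; bix <- block$block_index; lab <- block$label
  } else {
    toks <- unique(as.character(block))
    sid <- NA_character_; bix <- NA_integer_; lab <- "UNLABELED"
  }
  words <- intersect(toks, network_words(net))
  structure(list(session_id = sid, block_index = bix, label = lab,
                 words = words, n = length(words),
                 oov_dropped = length(toks) - length(words)),
            class = "block_module")
}

#' @export
print.block_module <- function(x, ...) {
  cat(sprintf("<block_module %s/%s [%s]: %d words (%d OOV dropped)>\n",
              x$session_id, x$block_index, x$label, x$n, x$oov_dropped))
  invisible(x)
}

module_words <- function(module) {
  if (inherits(module, "block_module")) module$words else as.character(module)
}

# mean over a distance submatrix under the disconnected-pair policy
mean_dist_policy <- function(sub, on_disconnected) {
  if (any(is.infinite(sub))) {
    if (on_disconnected == "error")
      stop("infinite shortest-path distance between module words; restrict the ",
           "network to its largest connected component or use on_disconnected='drop_pairs'")
    fin <- sub[is.finite(sub)]
    if (!length(fin)) return(structure(Inf, dropped = length(sub)))
    return(structure(mean(fin), dropped = sum(is.infinite(sub))))
  }
  structure(mean(sub), dropped = 0L)
}

#' Block compactness: mean shortest-path length over all ordered word pairs
#'
#' `l_block = sum_{vi,vj in block} d(vi, vj) / n^2`, the sum running over all
#' ordered pairs including self-pairs (d = 0), with `n` the module size. A
#' single-word module has `l_block = 0`.
#'
#' @param module a `block_module` or character vector of words.
#' @param net an `affinity_network` (may be omitted when `dist` is given).
#' @param metric `"hops"` or `"length"`.
#' @param dist optional precomputed full distance matrix from
#'   [net_distances()] (for repeated scoring).
#' @param on_disconnected `"error"` (default) or `"drop_pairs"` (infinite
#'   pairs removed from numerator and denominator; attribute `dropped` set).
#' @return Numeric scalar.
#' @export
l_block <- function(module, net = NULL, metric = c("hops", "length"),
                    dist = NULL, on_disconnected = c("error", "drop_pairs")) {
  metric <- match.arg(metric)
  on_disconnected <- match.arg(on_disconnected)
  w <- module_words(module)
  if (!length(w)) stop("cannot score an empty module")
  if (is.null(dist)) dist <- net_distances(net, sources = w, to = w, metric = metric)
  mean_dist_policy(dist[w, w, drop = FALSE], on_disconnected)
}

#' Separation s-score between two word modules
#'
#' `s(x, y) = b(x, y) - (l_x + l_y) / 2` where `b(x, y)` is the mean shortest
#' distance over the m x n cross pairs and `l_x`, `l_y` are the within-module
#' means ([l_block()]). Smaller s means topologically closer modules;
#' `s(x, x) = 0` identically, and s is symmetric.
#'
#' @inheritParams l_block
#' @param x,y `block_module`s or word vectors.
#' @return A `separation_score`: list with `s`, `b_xy`, `l_x`, `l_y`, `metric`.
#' @export
s_score <- function(x, y, net = NULL, metric = c("hops", "length"),
                    dist = NULL, on_disconnected = c("error", "drop_pairs")) {
  metric <- match.arg(metric)
  on_disconnected <- match.arg(on_disconnected)
  wx <- module_words(x); wy <- module_words(y)
  if (!length(wx) || !length(wy)) stop("cannot score an empty module")
  if (is.null(dist)) {
    all <- unique(c(wx, wy))
    dist <- net_distances(net, sources = all, to = all, metric = metric)
  }
  b <- mean_dist_policy(dist[wx, wy, drop = FALSE], on_disconnected)
  lx <- l_block(wx, dist = dist, metric = metric, on_disconnected = on_disconnected)
  ly <- l_block(wy, dist = dist, metric = metric, on_disconnected = on_disconnected)
  structure(list(s = as.numeric(b) - (as.numeric(lx) + as.numeric(ly)) / 2,
                 b_xy = as.numeric(b), l_x = as.numeric(lx), l_y = as.numeric(ly),
                 metric = metric),
            class = "separation_score")
}

#' @export
print.separation_score <- function(x, ...) {
  cat(sprintf("<s = %.4f (b = %.4f, l_x = %.4f, l_y = %.4f; %s)>\n",
              x$s, x$b_xy, x$l_x, x$l_y, x$metric))
  invisible(x)
}

# All pairwise s-scores between two module lists in one shot, via indicator
# matrices on a precomputed distance matrix: B = Zx' D Zy / (m n).
s_score_matrix <- function(modules_x, modules_y, dist) {
  nodes <- rownames(dist)
  ind <- function(mods) {
    M <- Matrix::sparseMatrix(
      i = unlist(lapply(mods, function(m) match(module_words(m), nodes))),
      j = rep(seq_along(mods), vapply(mods, function(m) length(module_words(m)), 0L)),
      x = 1, dims = c(length(nodes), length(mods)))
    M
  }
  Zx <- ind(modules_x); Zy <- ind(modules_y)
  nx <- Matrix::colSums(Zx); ny <- Matrix::colSums(Zy)
  DZy <- dist %*% Zy
  B <- as.matrix(Matrix::crossprod(Zx, DZy)) / outer(nx, ny)
  lx <- as.numeric(Matrix::diag(Matrix::crossprod(Zx, dist %*% Zx))) / nx^2
  ly <- as.numeric(Matrix::diag(Matrix::crossprod(Zy, DZy))) / ny^2
  B - outer(lx, ly, `+`) / 2
}

#' Mean set distance s-bar between two sets of modules
#'
#' `s_bar(A, B) = sum_{x in A, y in B} s(x, y) / (|A| |B|)`. With `A` a
#' single block `m` this is the classifier score `s_bar(m, ISSBs)`.
#'
#' @param A,B lists of `block_module`s (a single module is accepted).
#' @inheritParams l_block
#' @return A `set_distance`: list with `s_bar`, `u` (=|A|), `w` (=|B|),
#'   `metric`.
#' @export
mean_set_distance <- function(A, B, net = NULL, metric = c("hops", "length"),
                              dist = NULL) {
  metric <- match.arg(metric)
  if (inherits(A, "block_module") || is.character(A)) A <- list(A)
  if (inherits(B, "block_module") || is.character(B)) B <- list(B)
  if (!length(A) || !length(B)) stop("empty module set")
  if (is.null(dist)) dist <- net_distances(net, metric = metric)
  S <- s_score_matrix(A, B, dist)
  structure(list(s_bar = mean(S), u = length(A), w = length(B), metric = metric),
            class = "set_distance")
}

#' @export
print.set_distance <- function(x, ...) {
  cat(sprintf("<s_bar = %.4f over %d x %d module pairs (%s)>\n",
              x$s_bar, x$u, x$w, x$metric))
  invisible(x)
}

#' Degree-matched random reference sample of l values
#'
#' Draws random node sets matching the module's size and (log-binned) degree
#' profile and computes [l_block()] for each: the null distribution for the
#' modularity test. Degrees are binned at doubling edges (1, 2, 3-4, 5-8,
#' ...); an undersampled bin is widened to its neighbors with a warning.
#'
#' @param net an `affinity_network`.
#' @param degree_profile integer degrees of the module's words (use
#'   [module_degrees()]).
#' @param n_draws number of random sets (default 1000).
#' @param seed integer seed.
#' @inheritParams l_block
#' @return List with `l` (numeric vector), `mean`, `sd`, `n_draws`.
#' @export
reference_null <- function(net, degree_profile, n_draws = 1000, seed = 1,
                           metric = c("hops", "length"), dist = NULL,
                           on_disconnected = c("error", "drop_pairs")) {
  metric <- match.arg(metric)
  on_disconnected <- match.arg(on_disconnected)
  if (is.null(dist)) dist <- net_distances(net, metric = metric)
  deg <- igraph::degree(net$graph)
  node_bin <- pmax(ceiling(log2(pmax(deg, 1) + 1e-12)), 0)
  want_bin <- pmax(ceiling(log2(pmax(degree_profile, 1) + 1e-12)), 0)
  need <- table(want_bin)
  bins <- lapply(sort(unique(node_bin)), function(b) which(node_bin == b))
  names(bins) <- sort(unique(node_bin))
  # candidate pool per required bin, widened if too small
  pools <- list()
  for (bn in names(need)) {
    width <- 0
    repeat {
      sel <- as.character((as.integer(bn) - width):(as.integer(bn) + width))
      pool <- unlist(bins[intersect(sel, names(bins))], use.names = FALSE)
      if (length(pool) >= need[[bn]] || width > max(node_bin)) break
      width <- width + 1
    }
    if (width > 0)
      warning("degree bin ", bn, " widened by ", width, " to find enough candidates")
    pools[[bn]] <- pool
  }
  nodes <- rownames(dist)
  l <- withr::with_seed(seed, vapply(seq_len(n_draws), function(d) {
    idx <- unlist(lapply(names(need), function(bn)
      pools[[bn]][sample.int(length(pools[[bn]]), need[[bn]])]), use.names = FALSE)
    idx <- unique(idx)
    as.numeric(mean_dist_policy(dist[idx, idx, drop = FALSE], on_disconnected))
  }, 0))
  list(l = l, mean = mean(l), sd = stats::sd(l), n_draws = n_draws)
}

#' Degrees of a module's words in the network
#' @param module a `block_module` or word vector.
#' @param net an `affinity_network`.
#' @return Integer vector of degrees.
#' @export
module_degrees <- function(module, net) {
  as.integer(igraph::degree(net$graph, v = module_words(module)))
}

#' One-tailed modularity z-test for a block module
#'
#' Tests whether the module's observed mean internal distance ([l_block()])
#' is shorter than expected for random word sets of matching size and degree
#' profile. `z = (l_obs - null_mean) / null_sd`; the p-value is the lower
#' tail (alpha 0.05 by convention). A null spread below `1e-9` flags the
#' result degenerate.
#'
#' @param module a `block_module` or word vector.
#' @param net an `affinity_network`.
#' @param n_draws random reference sets (default 1000).
#' @param seed integer seed.
#' @inheritParams l_block
#' @return A `modularity_result`: list with `l_obs`, `null_mean`, `null_sd`,
#'   `z`, `p_one_tailed`, `n_draws`, `degenerate`.
#' @export
modularity_test <- function(module, net, n_draws = 1000, seed = 1,
                            metric = c("hops", "length"), dist = NULL,
                            on_disconnected = c("error", "drop_pairs")) {
  metric <- match.arg(metric)
  on_disconnected <- match.arg(on_disconnected)
  if (is.null(dist)) dist <- net_distances(net, metric = metric)
  l_obs <- as.numeric(l_block(module, dist = dist, metric = metric,
                              on_disconnected = on_disconnected))
  null <- reference_null(net, module_degrees(module, net), n_draws = n_draws,
                         seed = seed, metric = metric, dist = dist,
                         on_disconnected = on_disconnected)
  degenerate <- is.na(null$sd) || null$sd < SD_FLOOR
  sd_use <- max(null$sd, SD_FLOOR, na.rm = TRUE)
  z <- (l_obs - null$mean) / sd_use
  structure(list(l_obs = l_obs, null_mean = null$mean, null_sd = null$sd,
                 z = z, p_one_tailed = stats::pnorm(z), n_draws = n_draws,
                 degenerate = degenerate),
            class = "modularity_result")
}

#' @export
print.modularity_result <- function(x, ...) {
  cat(sprintf("<modularity: l_obs = %.3f vs null %.3f (SD %.3f), z = %.2f, p = %.4g%s>\n",
              x$l_obs, x$null_mean, x$null_sd, x$z, x$p_one_tailed,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Group modularity report over many blocks
#'
#' Runs [modularity_test()] per block and summarizes the group: mean/SD of
#' observed block compactness vs mean/SD of the pooled null draws, the
#' percent excess of the null over the observed, a two-sample one-tailed
#' group z, and the fraction of blocks individually significant at `alpha`.
#' All raw per-block values are emitted for audit.
#'
#' @param modules list of `block_module`s (>= 2; single-word modules are
#'   flagged degenerate).
#' @param net an `affinity_network`.
#' @param n_draws per-block null draws.
#' @param seed integer seed.
#' @param alpha significance level (default 0.05).
#' @inheritParams l_block
#' @return List with `per_block` (data.frame) and `group` (list).
#' @export
group_modularity_report <- function(modules, net, n_draws = 1000, seed = 1,
                                    alpha = 0.05, metric = c("hops", "length"),
                                    dist = NULL,
                                    on_disconnected = c("error", "drop_pairs")) {
  metric <- match.arg(metric)
  on_disconnected <- match.arg(on_disconnected)
  stopifnot(length(modules) >= 2)
  if (is.null(dist)) dist <- net_distances(net, metric = metric)
  res <- vector("list", length(modules))
  null_all <- numeric()
  for (k in seq_along(modules)) {
    mt <- modularity_test(modules[[k]], net, n_draws = n_draws,
                          seed = seed + k, metric = metric, dist = dist,
                          on_disconnected = on_disconnected)
    m <- modules[[k]]
    res[[k]] <- data.frame(
      session_id = m$session_id, block_index = m$block_index, label = m$label,
      n_words = m$n, l_obs = mt$l_obs, null_mean = mt$null_mean,
      null_sd = mt$null_sd, z = mt$z, p_one_tailed = mt$p_one_tailed,
      degenerate = mt$degenerate, stringsAsFactors = FALSE)
    null_all <- c(null_all, mt$null_mean)
  }
  per_block <- do.call(rbind, res)
  ok <- !per_block$degenerate
  m_obs <- mean(per_block$l_obs[ok]); s_obs <- stats::sd(per_block$l_obs[ok])
  m_null <- mean(per_block$null_mean[ok]); s_null <- stats::sd(per_block$null_mean[ok])
  n_ok <- sum(ok)
  group_z <- if (n_ok >= 2 && (s_obs > 0 || s_null > 0))
    (m_obs - m_null) / sqrt(s_obs^2 / n_ok + s_null^2 / n_ok) else NA_real_
  list(per_block = per_block,
       group = list(
         n_blocks = length(modules), n_scored = n_ok,
         mean_l_obs = m_obs, sd_l_obs = s_obs,
         mean_l_null = m_null, sd_l_null = s_null,
         percent_excess = 100 * (m_null - m_obs) / m_obs,
         group_z = group_z,
         group_p_one_tailed = if (is.na(group_z)) NA_real_ else stats::pnorm(group_z),
         prop_significant = mean(per_block$p_one_tailed[ok] < alpha),
         alpha = alpha, all_degenerate = n_ok == 0))
}

#' Ranked shortest-path explanations between a block and reference modules
#'
#' For every cross pair (word of `m`, word of any reference module) the
#' weighted shortest path (edge cost 1 - affinity) is found; the `top_n`
#' shortest are returned as word chains, the format a counselor-facing
#' report would show. Ties are broken lexicographically on the rendered
#' chain.
#'
#' @param m a `block_module` or word vector.
#' @param refs a `block_module`, word vector, or list of either.
#' @param net an `affinity_network`.
#' @param top_n paths to return (default 5).
#' @return data.frame with `rank`, `path` (words joined by em-dashes),
#'   `length`, `from`, `to`.
#' @export
explain_paths <- function(m, refs, net, top_n = 5) {
  wm <- module_words(m)
  if (inherits(refs, "block_module") || is.character(refs)) refs <- list(refs)
  wr <- unique(unlist(lapply(refs, module_words), use.names = FALSE))
  wr <- setdiff(wr, wm)
  if (!length(wm) || !length(wr))
    return(data.frame(rank = integer(), path = character(), length = numeric(),
                      from = character(), to = character()))
  D <- net_distances(net, sources = wm, to = wr, metric = "length")
  idx <- which(is.finite(D), arr.ind = TRUE)
  if (!nrow(idx))
    return(data.frame(rank = integer(), path = character(), length = numeric(),
                      from = character(), to = character()))
  cand <- data.frame(from = wm[idx[, 1]], to = wr[idx[, 2]],
                     length = D[idx], stringsAsFactors = FALSE)
  cand <- cand[order(cand$length, cand$from, cand$to), , drop = FALSE]
  cand <- utils::head(cand, max(top_n * 4L, top_n))
  chains <- character(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    sp <- igraph::shortest_paths(net$graph, from = cand$from[k], to = cand$to[k],
                                 weights = igraph::E(net$graph)$length,
                                 output = "vpath")
    chains[k] <- paste(names(sp$vpath[[1]]), collapse = "—")
  }
  cand$path <- chains
  cand <- cand[order(cand$length, cand$path), , drop = FALSE]
  cand <- utils::head(cand, top_n)
  data.frame(rank = seq_len(nrow(cand)), path = cand$path,
             length = cand$length, from = cand$from, to = cand$to,
             stringsAsFactors = FALSE, row.names = NULL)
}
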