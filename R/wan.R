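# Word affinity network construction: co-occurrence affinity, CBOW embedding
# similarity affinity, edge merging (max rule), largest-component restriction
# and GraphML / edge-list I/O.
#
# Affinity lives in (0, 1]; a path traversal cost ("length") is 1 - affinity,
# floored at a small epsilon so weighted shortest paths stay positive.

LENGTH_EPS <- 1e-6

# One token vector per message across the whole corpus. Accepts a list of
# session objects or a plain list of token vectors (each treated as a message).
corpus_message_tokens <- function(corpus, tokenizer = NULL) {
  if (length(corpus) && inherits(corpus[[1]], "session")) {
    unlist(lapply(corpus, function(s)
      lapply(s$messages$text, tokenize, tokenizer = tokenizer)),
      recursive = FALSE)
  } else {
    corpus
  }
}

#' Count word co-occurrences within a sliding window
#'
#' Two vocabulary words co-occur when they appear within `window` token
#' positions of each other inside the same message. Counts are symmetric and
#' accumulated per position pair (a pair of words appearing near each other
#' twice counts twice). Per-word corpus occurrence totals are returned
#' alongside.
#'
#' @param corpus list of [session] objects or of token vectors (one per
#'   message).
#' @param vocab a `vocabulary` (or character vector of words).
#' @param window window width in tokens (default 5).
#' @param tokenizer passed to [tokenize()] for session input.
#' @return A `cooc_counts` object: list with `pairs` (data.table `word_i`,
#'   `word_j`, `count`, with `word_i < word_j`), `occ` (named occurrence
#'   totals over the vocabulary) and the parameters.
#' @export
cooccurrence_counts <- function(corpus, vocab, window = 5, tokenizer = NULL) {
  stopifnot(window >= 1)
  words <- if (is.character(vocab)) vocab else vocab$word
  msgs <- corpus_message_tokens(corpus, tokenizer)
  tok <- unlist(msgs, use.names = FALSE)
  mid <- rep(seq_along(msgs), lengths(msgs))
  keep <- tok %in% words
  tok <- tok[keep]; mid <- mid[keep]
  occ <- table(factor(tok, levels = words))
  occ <- stats::setNames(as.integer(occ), words)
  pair_list <- vector("list", window)
  n <- length(tok)
  for (o in seq_len(window)) {
    if (n <= o) break
    i1 <- seq_len(n - o)
    ok <- mid[i1] == mid[i1 + o]
    if (!any(ok)) next
    a <- tok[i1][ok]; b <- tok[i1 + o][ok]
    swap <- a > b
    pair_list[[o]] <- data.table::data.table(
      word_i = ifelse(swap, b, a), word_j = ifelse(swap, a, b))
  }
  pairs <- data.table::rbindlist(pair_list)
  if (nrow(pairs)) {
    pairs <- pairs[word_i != word_j][, .(count = .N), by = .(word_i, word_j)]
    data.table::setorder(pairs, word_i, word_j)
  } else {
    pairs <- data.table::data.table(word_i = character(), word_j = character(),
                                    count = integer())
  }
  structure(list(pairs = pairs, occ = occ, window = window,
                 n_messages = length(msgs)),
            class = "cooc_counts")
}

#' Convert co-occurrence counts to affinities
#'
#' Jaccard-style normalization on occurrence contexts:
#' `affinity(i,j) = cooc(i,j) / (occ(i) + occ(j) - cooc(i,j))`, clipped into
#' (0, 1]. Pairs observed fewer than `min_count` times are dropped.
#'
#' @param counts a `cooc_counts` from [cooccurrence_counts()].
#' @param min_count minimum co-occurrence count to keep an edge (default 3).
#' @return data.table with `word_i`, `word_j`, `affinity`.
#' @export
cooccurrence_affinity <- function(counts, min_count = 3) {
  stopifnot(inherits(counts, "cooc_counts"))
  p <- counts$pairs[count >= min_count]
  occ <- counts$occ
  aff <- p$count / (occ[p$word_i] + occ[p$word_j] - p$count)
  data.table::data.table(word_i = p$word_i, word_j = p$word_j,
                         affinity = pmin(pmax(aff, 0), 1))[affinity > 0]
}

#' Train CBOW word embeddings
#'
#' Continuous-bag-of-words embeddings with negative sampling, trained on the
#' corpus restricted to the vocabulary (one sentence per message).
#' Single-threaded and fully deterministic under a fixed seed. Vocabulary
#' words absent from the corpus are reported in `missing` and excluded from
#' similarity edges.
#'
#' @param corpus list of [session] objects or of token vectors.
#' @param vocab a `vocabulary` or character vector.
#' @param dim embedding dimension (study default 128; small corpora are well
#'   served by 32).
#' @param window context window (default 5).
#' @param epochs training epochs (default 20).
#' @param negative negative samples per target (default 5).
#' @param alpha initial learning rate (default 0.025, linearly decayed).
#' @param seed integer seed.
#' @param tokenizer passed to [tokenize()].
#' @return An `embedding_model`: list with `vectors` (matrix, one row per
#'   present vocabulary word), `missing`, `params`.
#' @export
train_embeddings <- function(corpus, vocab, dim = 128, window = 5, epochs = 20,
                             negative = 5, alpha = 0.025, seed = 1,
                             tokenizer = NULL) {
  words <- if (is.character(vocab)) vocab else vocab$word
  msgs <- corpus_message_tokens(corpus, tokenizer)
  ids <- lapply(msgs, function(m) {
    v <- match(m, words)
    as.integer(v[!is.na(v)])
  })
  ids <- ids[lengths(ids) > 1]
  if (!length(ids)) stop("corpus contains no vocabulary words")
  counts <- tabulate(unlist(ids, use.names = FALSE), nbins = length(words))
  emb <- cbow_train_cpp(ids, length(words), as.numeric(counts),
                        as.integer(dim), as.integer(window), as.integer(epochs),
                        as.integer(negative), alpha, as.integer(seed))
  rownames(emb) <- words
  missing <- words[counts == 0]
  structure(list(vectors = emb[counts > 0, , drop = FALSE], missing = missing,
                 params = list(dim = dim, window = window, epochs = epochs,
                               negative = negative, alpha = alpha, seed = seed)),
            class = "embedding_model")
}

#' @export
print.embedding_model <- function(x, ...) {
  cat(sprintf("<embedding_model: %d words x %d dims (%d vocabulary words missing)>\n",
              nrow(x$vectors), ncol(x$vectors), length(x$missing)))
  invisible(x)
}

#' Derive similarity edges from embeddings
#'
#' Edge affinity is the cosine similarity between word vectors. An edge is
#' retained when cosine >= `theta_s` (default 0.6), or — when `top_k` is
#' given instead — when each word is among the other's `top_k` nearest
#' neighbors (mutual top-k). Non-positive cosines are never retained.
#' Supply only one of `theta_s` / `top_k`.
#'
#' @param model an `embedding_model`.
#' @param vocab optional restriction to these words.
#' @param theta_s cosine threshold.
#' @param top_k mutual nearest-neighbor count.
#' @return data.table with `word_i`, `word_j`, `affinity`.
#' @export
similarity_edges <- function(model, vocab = NULL, theta_s = 0.6, top_k = NULL) {
  stopifnot(inherits(model, "embedding_model"))
  V <- model$vectors
  if (!is.null(vocab)) {
    words <- if (is.character(vocab)) vocab else vocab$word
    V <- V[rownames(V) %in% words, , drop = FALSE]
  }
  if (nrow(V) < 2)
    return(data.table::data.table(word_i = character(), word_j = character(),
                                  affinity = numeric()))
  nrm <- sqrt(rowSums(V^2))
  nrm[nrm == 0] <- 1
  S <- tcrossprod(V / nrm)
  diag(S) <- 0
  if (is.null(top_k)) {
    sel <- which(S >= theta_s & S > 0 & upper.tri(S), arr.ind = TRUE)
  } else {
    k <- min(top_k, nrow(S) - 1)
    topk <- apply(S, 1, function(r) order(r, decreasing = TRUE)[seq_len(k)])
    inTop <- matrix(FALSE, nrow(S), ncol(S))
    inTop[cbind(rep(seq_len(nrow(S)), each = k), as.vector(topk))] <- TRUE
    sel <- which(inTop & t(inTop) & S > 0 & upper.tri(S), arr.ind = TRUE)
  }
  if (!nrow(sel))
    return(data.table::data.table(word_i = character(), word_j = character(),
                                  affinity = numeric()))
  w <- rownames(S)
  a <- w[sel[, 1]]; b <- w[sel[, 2]]
  swap <- a > b
  out <- data.table::data.table(word_i = ifelse(swap, b, a),
                                word_j = ifelse(swap, a, b),
                                affinity = pmin(S[sel], 1))
  data.table::setorder(out, word_i, word_j)
  out
}

#' Merge co-occurrence and similarity edges into a word affinity network
#'
#' The two affinity channels are combined by `max`; edge provenance is kept
#' (`cooccurrence`, `similarity` or `both`). Path length is `1 - affinity`,
#' floored at `1e-6` so affinity-1 edges remain traversable with positive
#' weight.
#'
#' @param cooc_edges,sim_edges data.tables (`word_i`, `word_j`, `affinity`);
#'   either may be empty. Order of the two arguments is immaterial apart
#'   from the provenance labels.
#' @param nodes optional full node set (e.g. the vocabulary) so that
#'   edge-less words still appear as isolated nodes.
#' @param meta named list of construction parameters recorded on the object.
#' @return An `affinity_network`: wraps an undirected igraph whose vertices
#'   carry `word` and whose edges carry `affinity`, `length`, `edge_type`.
#' @export
merge_edges <- function(cooc_edges, sim_edges, nodes = NULL, meta = list()) {
  empty <- data.table::data.table(word_i = character(), word_j = character(),
                                  affinity = numeric())
  ce <- if (is.null(cooc_edges) || !nrow(cooc_edges)) empty else data.table::as.data.table(cooc_edges)
  se <- if (is.null(sim_edges) || !nrow(sim_edges)) empty else data.table::as.data.table(sim_edges)
  ce_k <- ce[, .(word_i, word_j, aff_c = affinity)]
  se_k <- se[, .(word_i, word_j, aff_s = affinity)]
  m <- merge(ce_k, se_k, by = c("word_i", "word_j"), all = TRUE)
  m[, `:=`(
    affinity = pmax(data.table::fifelse(is.na(aff_c), -Inf, aff_c),
                    data.table::fifelse(is.na(aff_s), -Inf, aff_s)),
    edge_type = data.table::fifelse(!is.na(aff_c) & !is.na(aff_s), "both",
                 data.table::fifelse(!is.na(aff_c), "cooccurrence", "similarity")))]
  m[, length := pmax(1 - affinity, LENGTH_EPS)]
  if (is.null(nodes)) {
    nodes <- sort(unique(c(m$word_i, m$word_j)))
  } else {
    nodes <- if (is.character(nodes)) nodes else nodes$word
  }
  g <- igraph::graph_from_data_frame(
    m[, .(word_i, word_j, affinity, length, edge_type)],
    directed = FALSE, vertices = data.frame(name = nodes))
  igraph::V(g)$word <- igraph::V(g)$name
  structure(list(graph = g, meta = meta), class = "affinity_network")
}

#' @export
print.affinity_network <- function(x, ...) {
  g <- x$graph
  et <- table(igraph::E(g)$edge_type)
  cat(sprintf("<affinity_network: %d words, %d edges (%s)>\n",
              igraph::vcount(g), igraph::ecount(g),
              paste(names(et), as.integer(et), sep = "=", collapse = ", ")))
  invisible(x)
}

#' Network node words
#' @param net an `affinity_network`.
#' @return Character vector of node words.
#' @export
network_words <- function(net) igraph::V(net$graph)$name

#' Network edge table
#' @param net an `affinity_network`.
#' @return data.frame `word_i`, `word_j`, `affinity`, `length`, `edge_type`.
#' @export
network_edges <- function(net) {
  e <- igraph::as_data_frame(net$graph, what = "edges")
  names(e)[1:2] <- c("word_i", "word_j")
  e
}

#' Restrict a network to its largest connected component
#'
#' Shortest-path statistics need finite distances; analysis is therefore
#' confined to the largest connected component and the coverage loss is
#' reported.
#'
#' @param net an `affinity_network`.
#' @return The restricted network, with attribute `removed` listing the
#'   dropped words.
#' @export
restrict_to_lcc <- function(net) {
  g <- net$graph
  if (igraph::vcount(g) == 0) stop("empty network")
  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  removed <- igraph::V(g)$name[-keep]
  out <- net
  out$graph <- igraph::induced_subgraph(g, keep)
  out$meta$lcc_removed <- length(removed)
  attr(out, "removed") <- removed
  out
}

#' Build a word affinity network end to end
#'
#' Convenience wrapper: co-occurrence counting, CBOW training, similarity
#' edges, and the max-merge. The result is not yet restricted to its largest
#' component; call [restrict_to_lcc()] before shortest-path work.
#'
#' @param corpus list of [session] objects or token vectors.
#' @param vocab a `vocabulary`.
#' @param window co-occurrence and CBOW context window (default 5).
#' @param min_count minimum co-occurrence count (default 3).
#' @param dim,epochs,negative,alpha CBOW parameters (see [train_embeddings()]).
#' @param theta_s,top_k similarity retention rule (see [similarity_edges()]).
#' @param seed embedding seed.
#' @param tokenizer passed to [tokenize()].
#' @return An `affinity_network`.
#' @export
build_wan <- function(corpus, vocab, window = 5, min_count = 3, dim = 128,
                      epochs = 20, negative = 5, alpha = 0.025,
                      theta_s = 0.6, top_k = NULL, seed = 1, tokenizer = NULL) {
  counts <- cooccurrence_counts(corpus, vocab, window = window, tokenizer = tokenizer)
  ce <- cooccurrence_affinity(counts, min_count = min_count)
  emb <- train_embeddings(corpus, vocab, dim = dim, window = window,
                          epochs = epochs, negative = negative, alpha = alpha,
                          seed = seed, tokenizer = tokenizer)
  se <- similarity_edges(emb, vocab, theta_s = theta_s, top_k = top_k)
  merge_edges(ce, se, nodes = vocab,
              meta = list(window = window, min_count = min_count, dim = dim,
                          epochs = epochs, theta_s = theta_s, top_k = top_k,
                          seed = seed))
}

#' Write / read a network as GraphML
#'
#' Node attribute `word` and edge attributes `affinity`, `length`,
#' `edge_type` are preserved.
#'
#' @param net an `affinity_network`.
#' @param path file path.
#' @return `path` (write) or an `affinity_network` (read).
#' @export
write_wan_graphml <- function(net, path) {
  igraph::write_graph(net$graph, path, format = "graphml")
  invisible(path)
}

#' @rdname write_wan_graphml
#' @export
read_wan_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  if (is.null(igraph::V(g)$name)) igraph::V(g)$name <- igraph::V(g)$word
  structure(list(graph = igraph::as_undirected(g, mode = "collapse"),
                 meta = list(source = path)),
            class = "affinity_network")
}

#' Write the network edge list as TSV
#' @param net an `affinity_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wan_edgelist <- function(net, path) {
  data.table::fwrite(network_edges(net), path, sep = "\t")
  invisible(path)
}
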