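# Independent brute-force oracles used to pin down expected values.
# These deliberately share no code with the package internals.

# All-pairs shortest distances by Floyd-Warshall on a dense weight matrix
# (Inf = no edge, 0 diagonal).
fw_distances <- function(W) {
  n <- nrow(W)
  D <- W
  diag(D) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# Eq.-style block compactness by explicit double loop over ordered pairs.
l_block_oracle <- function(idx, D) {
  tot <- 0
  for (i in idx) for (j in idx) tot <- tot + D[i, j]
  tot / length(idx)^2
}

# Separation score by explicit loops.
s_oracle <- function(ix, iy, D) {
  b <- 0
  for (i in ix) for (j in iy) b <- b + D[i, j]
  b <- b / (length(ix) * length(iy))
  b - (l_block_oracle(ix, D) + l_block_oracle(iy, D)) / 2
}

# Concordance by exhaustive pair enumeration, ties = 1/2.
c_stat_oracle <- function(scores, labels) {
  pos <- scores[labels == "PISSB"]
  neg <- scores[labels == "NISSB"]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p < q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Best achievable sensitivity+specificity by scanning a dense candidate set
# built directly from the score values.
best_J_oracle <- function(scores, labels) {
  eps <- min(diff(sort(unique(scores))), 1) / 10
  cands <- sort(unique(c(scores - eps, scores + eps)))
  pos <- scores[labels == "PISSB"]; neg <- scores[labels == "NISSB"]
  max(vapply(cands, function(t) mean(pos < t) + mean(neg >= t), 0))
}

# A random undirected graph as an affinity_network plus its hop and weighted
# distance matrices from the oracle.
random_toy_net <- function(n, p = 0.45) {
  words <- sprintf("w%02d", seq_len(n))
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < p
  pairs <- pairs[keep, , drop = FALSE]
  if (!nrow(pairs)) pairs <- matrix(c(1, 2), 1)
  aff <- runif(nrow(pairs), 0.1, 0.9)
  edges <- data.frame(word_i = words[pairs[, 1]], word_j = words[pairs[, 2]],
                      affinity = aff)
  net <- merge_edges(edges, NULL, nodes = words)
  Wh <- matrix(Inf, n, n, dimnames = list(words, words))
  Ww <- Wh
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    Wh[i, j] <- Wh[j, i] <- 1
    Ww[i, j] <- Ww[j, i] <- 1 - aff[k]
  }
  list(net = net, words = words,
       D_hops = fw_distances(Wh), D_len = fw_distances(Ww))
}

# Tiny deterministic affinity network used across files:
# a chain a-b-c-d-e with uniform affinity, as hops-friendly scaffold.
path_net <- function(n = 5, affinity = 0.5) {
  words <- letters[seq_len(n)]
  edges <- data.frame(word_i = words[-n], word_j = words[-1], affinity = affinity)
  merge_edges(edges, NULL, nodes = words)
}

# A quick synthetic session for corpus tests.
toy_session <- function(id = "s1", n_h = 12, n_c = n_h, text_fn = function(i) paste("tok", i)) {
  n <- n_h + n_c
  roles <- rep(c("H", "C"), length.out = n)
  session(id, seq = seq_len(n), role = roles,
          text = vapply(seq_len(n), text_fn, ""))
}
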