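msgs_to_corpus <- function(...) lapply(list(...), function(x) strsplit(x, " ")[[1]])

test_that("co-occurrence counting respects window and message boundaries", {
  vocab <- c("a", "b", "c")
  cc <- cooccurrence_counts(msgs_to_corpus("a b c"), vocab, window = 2)
  expect_equal(nrow(cc$pairs), 3)
  expect_true(all(cc$pairs$count == 1))
  expect_setequal(paste(cc$pairs$word_i, cc$pairs$word_j),
                  c("a b", "b c", "a c"))

  cc1 <- cooccurrence_counts(msgs_to_corpus("a b c"), vocab, window = 1)
  expect_setequal(paste(cc1$pairs$word_i, cc1$pairs$word_j), c("a b", "b c"))

  cc2 <- cooccurrence_counts(msgs_to_corpus("a b", "a b"), vocab, window = 5)
  expect_equal(cc2$pairs$count, 2)
  expect_equal(unname(cc2$occ[c("a", "b")]), c(2, 2))

  # window never crosses messages: "a" and "b" in different messages
  cc3 <- cooccurrence_counts(msgs_to_corpus("a", "b"), vocab, window = 5)
  expect_equal(nrow(cc3$pairs), 0)

  # brute-force pair scan oracle on a random message set
  set.seed(21)
  msgs <- replicate(20, sample(vocab, sample(2:6, 1), replace = TRUE),
                    simplify = FALSE)
  w <- 3
  cc4 <- cooccurrence_counts(msgs, vocab, window = w)
  brute <- new.env()
  for (m in msgs) for (i in seq_along(m)) for (j in seq_along(m))
    if (i < j && j - i <= w && m[i] != m[j]) {
      key <- paste(sort(c(m[i], m[j])), collapse = "|")
      assign(key, (if (exists(key, brute)) get(key, brute) else 0) + 1, brute)
    }
  got <- setNames(cc4$pairs$count, paste(cc4$pairs$word_i, cc4$pairs$word_j, sep = "|"))
  expect_mapequal(as.list(got), as.list(brute))
})

test_that("co-occurrence affinity is Jaccard on occurrence totals", {
  # cooc=1, occ(i)=3, occ(j)=2 -> 1/4
  cc <- cooccurrence_counts(msgs_to_corpus("a b", "a", "a", "b"), c("a", "b"),
                            window = 5)
  expect_equal(cc$pairs$count, 1)
  aff <- cooccurrence_affinity(cc, min_count = 1)
  expect_equal(aff$affinity, 0.25)
  # words always and only co-occurring -> affinity 1
  cc2 <- cooccurrence_counts(msgs_to_corpus("x y", "x y", "x y"), c("x", "y"),
                             window = 5)
  expect_equal(cooccurrence_affinity(cc2, min_count = 1)$affinity, 1)
  # below min_count the edge is absent
  expect_equal(nrow(cooccurrence_affinity(cc2, min_count = 4)), 0)
})

test_that("CBOW embeddings are deterministic, sized, and learn shared contexts", {
  set.seed(5)
  mk_msg <- function(group) {
    ctx <- if (group == "A") c("ca1", "ca2", "ca3") else c("cb1", "cb2", "cb3")
    core <- if (group == "A") paste0("a", 1:4) else paste0("b", 1:4)
    sample(c(sample(ctx, 2), sample(core, 2)))
  }
  corpus <- c(replicate(300, mk_msg("A"), simplify = FALSE),
              replicate(300, mk_msg("B"), simplify = FALSE))
  vocab <- c(paste0("a", 1:4), paste0("b", 1:4),
             paste0("c", c("a1", "a2", "a3", "b1", "b2", "b3")))
  m1 <- train_embeddings(corpus, vocab, dim = 32, epochs = 10, seed = 7)
  m2 <- train_embeddings(corpus, vocab, dim = 32, epochs = 10, seed = 7)
  expect_identical(m1$vectors, m2$vectors)
  expect_equal(ncol(m1$vectors), 32)

  cosine <- function(V) {
    V <- V / sqrt(rowSums(V^2)); tcrossprod(V)
  }
  S <- cosine(m1$vectors)
  within_a <- S[paste0("a", 1:4), paste0("a", 1:4)]
  cross <- S[paste0("a", 1:4), paste0("b", 1:4)]
  expect_gt(mean(within_a[upper.tri(within_a)]), mean(cross))

  # vocabulary words absent from the corpus are marked missing
  m3 <- train_embeddings(corpus, c(vocab, "ghost"), dim = 8, epochs = 1, seed = 1)
  expect_equal(m3$missing, "ghost")
  expect_false("ghost" %in% rownames(m3$vectors))
})

test_that("similarity edges honor the threshold, positivity and mutual top-k", {
  V <- rbind(u = c(1, 0), v = c(1, 0), w = c(0, 1), x = c(-1, 0))
  model <- structure(list(vectors = V, missing = character(), params = list()),
                     class = "embedding_model")
  e <- similarity_edges(model, theta_s = 0.6)
  expect_equal(nrow(e), 1)  # only u-v (cosine 1); orthogonal/negative dropped
  expect_equal(e$affinity, 1)
  # boundary: cosine just below theta_s is dropped
  V2 <- rbind(p = c(1, 0), q = c(0.59, sqrt(1 - 0.59^2)))
  model2 <- structure(list(vectors = V2, missing = character(), params = list()),
                      class = "embedding_model")
  expect_equal(nrow(similarity_edges(model2, theta_s = 0.6)), 0)
  # raising theta_s never adds an edge
  set.seed(2)
  V3 <- matrix(rnorm(60), 10, dimnames = list(letters[1:10], NULL))
  model3 <- structure(list(vectors = V3, missing = character(), params = list()),
                      class = "embedding_model")
  prev <- Inf
  for (th in c(0.2, 0.5, 0.8)) {
    n_e <- nrow(similarity_edges(model3, theta_s = th))
    expect_lte(n_e, prev)
    prev <- n_e
  }
  # mutual top-k keeps reciprocal positive pairs only
  ek <- similarity_edges(model, top_k = 1)
  expect_equal(paste(ek$word_i, ek$word_j), "u v")
})

test_that("edge merging takes the max affinity, records provenance, sets lengths", {
  ce <- data.frame(word_i = c("a", "b"), word_j = c("b", "c"),
                   affinity = c(0.3, 0.79))
  se <- data.frame(word_i = c("a", "c"), word_j = c("b", "d"),
                   affinity = c(0.7, 1.0))
  net <- merge_edges(ce, se)
  ed <- network_edges(net)
  ab <- ed[ed$word_i == "a" & ed$word_j == "b", ]
  expect_equal(ab$affinity, 0.7)
  expect_equal(ab$edge_type, "both")
  bc <- ed[ed$word_i == "b" & ed$word_j == "c", ]
  expect_equal(bc$affinity, 0.79)
  expect_equal(bc$edge_type, "cooccurrence")
  expect_equal(bc$length, 0.21)  # one minus affinity
  cd <- ed[ed$word_i == "c" & ed$word_j == "d", ]
  expect_equal(cd$edge_type, "similarity")
  expect_equal(cd$length, 1e-6)  # affinity-1 edges keep positive length
  expect_true(all(abs(ed$length - pmax(1 - ed$affinity, 1e-6)) < 1e-12))

  # commutative in its inputs (up to provenance relabeling)
  net2 <- merge_edges(se, ce)
  ed2 <- network_edges(net2)
  key <- function(d) d[order(d$word_i, d$word_j), c("word_i", "word_j", "affinity")]
  swapped <- within(key(ed2), edge_type <- NULL)
  expect_equal(key(ed), swapped)
})

test_that("largest-component restriction keeps the biggest piece and reports", {
  edges <- data.frame(word_i = c("a", "b", "c", "d", "f"),
                      word_j = c("b", "c", "d", "e", "g"),
                      affinity = 0.5)
  net <- merge_edges(edges, NULL, nodes = c(letters[1:7], "iso"))
  lcc <- restrict_to_lcc(net)
  expect_setequal(network_words(lcc), letters[1:5])
  expect_setequal(attr(lcc, "removed"), c("f", "g", "iso"))
  # a connected network is unchanged
  p <- path_net(4)
  expect_setequal(network_words(restrict_to_lcc(p)), letters[1:4])
  expect_error(restrict_to_lcc(merge_edges(NULL, NULL, nodes = character())),
               "empty")
})

test_that("GraphML and edge-list round trips preserve the network", {
  net <- path_net(4, affinity = 0.79)
  f <- withr::local_tempfile(fileext = ".graphml")
  write_wan_graphml(net, f)
  back <- read_wan_graphml(f)
  expect_setequal(network_words(back), network_words(net))
  eb <- network_edges(back)
  eo <- network_edges(net)
  expect_equal(eb[order(eb$word_i), c("affinity", "length", "edge_type")],
               eo[order(eo$word_i), c("affinity", "length", "edge_type")])
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_wan_edgelist(net, f2)
  tsv <- read.delim(f2)
  expect_equal(nrow(tsv), 3)
  expect_true(all(c("word_i", "word_j", "affinity", "edge_type") %in% names(tsv)))
})
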