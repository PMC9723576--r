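test_that("network distances match a Floyd-Warshall oracle on random graphs", {
  set.seed(31)
  for (rep in 1:20) {
    toy <- random_toy_net(sample(5:12, 1))
    Dh <- net_distances(toy$net, metric = "hops")
    Dw <- net_distances(toy$net, metric = "length")
    expect_equal(Dh[toy$words, toy$words], toy$D_hops, tolerance = 1e-12)
    expect_equal(Dw[toy$words, toy$words], toy$D_len, tolerance = 1e-9)
    expect_true(all(diag(Dh) == 0))
  }
  expect_error(net_distances(path_net(3), sources = "zz"), "unknown word: zz")
})

test_that("block compactness follows the ordered-pair mean with n^2 denominator", {
  p5 <- path_net(5)
  expect_equal(as.numeric(l_block("a", p5)), 0)            # singleton
  expect_equal(as.numeric(l_block(c("a", "b"), p5)), 0.5)  # (0+1+1+0)/4
  expect_equal(as.numeric(l_block(c("a", "b", "c"), p5)), 8 / 9)
  # weighted metric: same pairs, 1-affinity lengths
  expect_equal(as.numeric(l_block(c("a", "b"), p5, metric = "length")),
               2 * 0.5 / 4)
})

test_that("module projection drops out-of-network tokens and counts them", {
  p5 <- path_net(5)
  s <- session("m", 1:2, c("H", "H"), c("a b unknown1", "c unknown2 a"))
  b <- segment_blocks(s)[[1]]
  mod <- block_module(b, p5)
  expect_setequal(mod$words, c("a", "b", "c"))
  expect_equal(mod$n, 3)
  expect_equal(mod$oov_dropped, 2)
})

test_that("s-score reproduces hand-enumerated values and Eq. identities", {
  p5 <- path_net(5)
  # x={a,b}, y={d,e}: b=(3+4+2+3)/4=3, l_x=l_y=0.5 -> s=2.5
  sc <- s_score(c("a", "b"), c("d", "e"), p5)
  expect_equal(sc$b_xy, 3)
  expect_equal(sc$l_x, 0.5)
  expect_equal(sc$s, 2.5)
  # overlapping modules on a path of 4
  p4 <- path_net(4)
  sc2 <- s_score(c("a", "b", "c"), c("b", "c", "d"), p4)
  expect_equal(sc2$b_xy, 11 / 9)
  expect_equal(sc2$s, 3 / 9)
  # disjoint singletons: s = d(a, b)
  expect_equal(s_score("a", "c", p5)$s, 2)
})

test_that("s-score is zero on itself, symmetric, and matches the loop oracle", {
  set.seed(77)
  n_checked <- 0
  for (rep in 1:100) {
    toy <- random_toy_net(sample(6:12, 1))
    D <- toy$D_hops
    # work inside one connected component to keep distances finite
    comp <- toy$words[is.finite(D[1, ])]
    if (length(comp) < 4) next
    ix <- sample(comp, sample(2:3, 1))
    iy <- sample(comp, sample(2:3, 1))
    got <- s_score(ix, iy, toy$net)
    expect_equal(got$s, s_oracle(match(ix, toy$words), match(iy, toy$words), D),
                 tolerance = 1e-12)
    expect_equal(as.numeric(l_block(ix, toy$net)),
                 l_block_oracle(match(ix, toy$words), D), tolerance = 1e-12)
    # symmetry and self-zero
    expect_equal(got$s, s_score(iy, ix, toy$net)$s, tolerance = 1e-12)
    expect_identical(s_score(ix, ix, toy$net)$s, 0)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 80)
})

test_that("disconnected pairs error by default and can be dropped by policy", {
  edges <- data.frame(word_i = c("a", "c"), word_j = c("b", "d"), affinity = 0.5)
  net <- merge_edges(edges, NULL)
  expect_error(l_block(c("a", "b", "c"), net), "infinite")
  l <- l_block(c("a", "b", "c"), net, on_disconnected = "drop_pairs")
  # finite ordered pairs: 3 self (0) + a-b both ways (1+1); divisor 5
  expect_equal(as.numeric(l), 2 / 5)
  expect_equal(attr(l, "dropped"), 4L)
})

test_that("mean set distance averages pairwise s and obeys the mean identity", {
  p5 <- path_net(5)
  A <- list(c("a", "b"), c("b", "c"))
  B <- list(c("d", "e"), c("c", "d"))
  sd_ <- mean_set_distance(A, B, p5)
  manual <- mean(c(s_score(A[[1]], B[[1]], p5)$s, s_score(A[[1]], B[[2]], p5)$s,
                   s_score(A[[2]], B[[1]], p5)$s, s_score(A[[2]], B[[2]], p5)$s))
  expect_equal(sd_$s_bar, manual, tolerance = 1e-12)
  expect_equal(sd_$u, 2); expect_equal(sd_$w, 2)
  # s_bar over the set equals the mean of per-block s_bar values
  per_block <- vapply(A, function(a) mean_set_distance(a, B, p5)$s_bar, 0)
  expect_equal(sd_$s_bar, mean(per_block), tolerance = 1e-12)
  # identical singleton sets: s_bar = 0
  expect_equal(mean_set_distance(list("a"), list("a"), p5)$s_bar, 0)
})

test_that("degree-matched null is seeded and centers where it should", {
  set.seed(12)
  net <- restrict_to_lcc(random_toy_net(12, p = 0.6)$net)
  words <- network_words(net)
  prof <- module_degrees(words[1:4], net)
  n1 <- reference_null(net, prof, n_draws = 50, seed = 3)
  n2 <- reference_null(net, prof, n_draws = 50, seed = 3)
  expect_identical(n1$l, n2$l)
  expect_length(n1$l, 50)

  # planted clique: observed compactness beats the degree-matched null
  cl <- expand.grid(i = 1:6, j = 1:6)
  cl <- cl[cl$i < cl$j, ]
  clique_edges <- data.frame(word_i = paste0("k", cl$i), word_j = paste0("k", cl$j),
                             affinity = 0.9)
  set.seed(99)
  bg <- random_toy_net(40, p = 0.08)
  bg_edges <- network_edges(bg$net)[, c("word_i", "word_j", "affinity")]
  hook <- data.frame(word_i = "k1", word_j = "w01", affinity = 0.5)
  planted <- restrict_to_lcc(merge_edges(rbind(clique_edges, bg_edges, hook), NULL))
  stopifnot(all(paste0("k", 1:6) %in% network_words(planted)))
  mt <- modularity_test(paste0("k", 1:6), planted, n_draws = 300, seed = 8)
  expect_lt(mt$l_obs, mt$null_mean)
  expect_lt(mt$p_one_tailed, 0.05)
})

test_that("modularity z-test follows the stated sign convention", {
  net <- restrict_to_lcc(path_net(8))
  D <- net_distances(net, metric = "hops")
  mod <- c("a", "b", "c")
  mt <- modularity_test(mod, net, n_draws = 200, seed = 4, dist = D)
  expect_equal(mt$z, (mt$l_obs - mt$null_mean) / max(mt$null_sd, 1e-9))
  expect_equal(mt$p_one_tailed, pnorm(mt$z))
  # a module equal to the whole (degenerate) graph: null collapses onto l_obs
  whole <- modularity_test(network_words(net), net, n_draws = 20, seed = 1, dist = D)
  expect_true(whole$degenerate)
  expect_equal(whole$l_obs, whole$null_mean)
})

test_that("the group modularity report aggregates and flags degenerate input", {
  net <- restrict_to_lcc(random_toy_net(15, p = 0.5)$net)
  words <- network_words(net)
  set.seed(41)
  mods <- lapply(1:4, function(i) block_module(sample(words, 4), net))
  rep_ <- group_modularity_report(mods, net, n_draws = 100, seed = 2)
  expect_equal(nrow(rep_$per_block), 4)
  expect_equal(rep_$group$n_scored, 4)
  expect_false(rep_$group$all_degenerate)
  expect_equal(rep_$group$percent_excess,
               100 * (rep_$group$mean_l_null - rep_$group$mean_l_obs) /
                 rep_$group$mean_l_obs)
  # all single-word modules -> degenerate everywhere
  singles <- lapply(words[1:3], function(w) block_module(w, net))
  rep2 <- group_modularity_report(singles, net, n_draws = 20, seed = 2)
  expect_true(rep2$group$all_degenerate)
})

test_that("path explanations rank weighted shortest paths with additive lengths", {
  # chain with known affinities: a-b 0.79 (len .21), b-c 0.9 (len .1), c-d 0.83 (len .17)
  edges <- data.frame(word_i = c("a", "b", "c"), word_j = c("b", "c", "d"),
                      affinity = c(0.79, 0.9, 0.83))
  net <- merge_edges(edges, NULL)
  ex <- explain_paths("a", "b", net, top_n = 5)
  expect_equal(ex$length[1], 0.21)
  expect_equal(ex$path[1], "a—b")
  ex2 <- explain_paths("b", "d", net, top_n = 5)
  expect_equal(ex2$length[1], 0.1 + 0.17)  # lengths add along the chain
  expect_equal(ex2$path[1], "b—c—d")

  # exhaustive enumeration oracle on a small random net
  set.seed(53)
  toy <- random_toy_net(8, p = 0.5)
  net8 <- restrict_to_lcc(toy$net)
  ws <- network_words(net8)
  m <- ws[1:3]; refs <- ws[4:6]
  ex3 <- explain_paths(m, refs, net8, top_n = 5)
  Dw <- net_distances(net8, metric = "length")
  oracle <- sort(as.vector(Dw[m, refs]))[1:5]
  expect_equal(ex3$length, oracle, tolerance = 1e-9)
  # every reported chain's edge lengths sum to the reported total
  eds <- network_edges(net8)
  elen <- function(u, v) {
    r <- eds[(eds$word_i == u & eds$word_j == v) | (eds$word_i == v & eds$word_j == u), ]
    r$length[1]
  }
  for (k in seq_len(nrow(ex3))) {
    chain <- strsplit(ex3$path[k], "—")[[1]]
    tot <- sum(mapply(elen, chain[-length(chain)], chain[-1]))
    expect_equal(tot, ex3$length[k], tolerance = 1e-9)
  }
})
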