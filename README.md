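# issnet

Network-based prediction of the transition point to disclosure of ideation
about self-harm and suicide (ISS) in text-based counseling.

In synchronous text counseling, the first explicit disclosure of self-harm
or suicide ideation is a critical moment, and a counselor handling several
concurrent chats benefits from advance warning. `issnet` is for researchers
and service analysts who want a *transparent* predictor of that transition:
instead of a black-box text classifier, it measures how close the
vocabulary of a conversation block sits to known disclosure vocabulary
inside a word affinity network (WAN).

## The method

Sessions are split into **blocks** of ten help-seeker messages. A
keyword-plus-filters annotator marks the first block with explicit ISS
(**ISSB**); the block just before it (**PISSB**) is the prediction target;
everything else is **NISSB**. The pipeline then:

1. builds a WAN from a construction corpus — nodes are the top-k TF-IDF
   words, edges carry an affinity in (0, 1] from co-occurrence (Jaccard on
   occurrence totals) and CBOW embedding cosine similarity, merged by max;
   the traversal length of an edge is 1 − affinity;
2. verifies the premise that block words form **modules**: the compactness
   `l_block = Σ d(v_i, v_j) / n²` (ordered pairs, self-pairs included) is
   tested one-tailed against random node sets of matching size and
   degree profile;
3. scores each candidate block by its mean separation from the ISSB set,
   using the s-score
   `s(x, y) = ⟨b(x,y)⟩ − (⟨l_x⟩ + ⟨l_y⟩)/2`,
   where `b` is the mean cross-module shortest-path distance;
4. trains the cutoff `t` maximizing sensitivity + specificity on an 80/20
   stratified split and classifies a block as PISSB iff `s̄ < t`, reporting
   the c-statistic over 50 replications with NISSB resampling.

Because the original counseling transcripts are private, the package ships
a synthetic corpus generator that plants the method's premise (a prodromal
block whose vocabulary is network-close to ISS vocabulary) and is the test
bed for the whole pipeline.

## Worked example

```r
library(issnet)
cfg   <- generator_config(seed = 101, n_wan_sessions = 300, n_labeled_sessions = 150)
corp  <- generate_corpus(cfg)
vocab <- select_vocabulary(corp$wan_corpus, k = 800)
net   <- restrict_to_lcc(build_wan(corp$wan_corpus, vocab, dim = 32,
                                   epochs = 10, seed = 101))
net
#> <affinity_network: 800 words, 250093 edges (both=13751, cooccurrence=6144, similarity=230198)>

ann <- annotate_corpus(corp$labeled_corpus, corp$annotation_lexicon)
table(ann$labels$label)
#>  ISSB NISSB PISSB
#>    75   519    75

issb  <- modules_by_label(ann$blocks, "ISSB",  net)
pissb <- modules_by_label(ann$blocks, "PISSB", net)
nissb <- modules_by_label(ann$blocks, "NISSB", net)

modularity_test(issb[[1]], net, n_draws = 500, seed = 1)
#> <modularity: l_obs = 1.294 vs null 1.394 (SD 0.025), z = -3.97, p = 3.616e-05>

s_score(pissb[[1]], issb[[2]], net)
#> <s = 0.0840 (b = 1.3589, l_x = 1.2590, l_y = 1.2909; hops)>

e <- run_experiment(net, issb, pissb, nissb, n_reps = 50, seed = 1)
e$summary$mean_test_c
#> [1] 1
```

Reading the output: the first ISS block is significantly more compact than
degree-matched random word sets (z = −3.97), confirming the word-module
premise on this corpus; the PISSB module sits close to an ISSB module
(s = 0.084 against within-module means around 1.3 hops); and across 50
replications the threshold classifier separates PISSB from NISSB perfectly —
the planted synthetic signal is much cleaner than real language, so treat
this as a correctness check, not a performance claim.
`explain_paths(pissb[[1]], issb, net)` lists the shortest weighted paths
(1 − affinity per edge) that justify a given alert.

A thin CLI wraps the same functions:

```sh
exec/issnet simulate --seed 1 --outdir sim/
exec/issnet run-all  --seed 1 --outdir run/ --n-reps 50
```

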