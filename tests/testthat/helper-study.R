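# The packaged default study conditions (synthetic stand-in for the private
# transcripts): built once per test run and shared across files.

.study_cache <- new.env(parent = emptyenv())

default_study <- function() {
  if (!is.null(.study_cache$res)) return(.study_cache$res)
  cfg <- generator_config(seed = 20220001)
  corp <- generate_corpus(cfg)
  vocab <- select_vocabulary(corp$wan_corpus, k = 800)
  net <- restrict_to_lcc(build_wan(corp$wan_corpus, vocab, dim = 32,
                                   epochs = 20, seed = 20220001))
  ann <- annotate_corpus(corp$labeled_corpus, corp$annotation_lexicon)
  dist <- net_distances(net, metric = "hops")
  res <- list(
    config = cfg, corpus = corp, vocab = vocab, net = net, ann = ann,
    dist = dist,
    issb = modules_by_label(ann$blocks, "ISSB", net),
    pissb = modules_by_label(ann$blocks, "PISSB", net),
    nissb = modules_by_label(ann$blocks, "NISSB", net))
  .study_cache$res <- res
  res
}
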