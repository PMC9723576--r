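---
title: "Predicting the transition to self-harm ideation disclosure with word-network separation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting the transition to self-harm ideation disclosure with word-network separation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In synchronous text counseling, the moment a help-seeker first discloses
ideation about self-harm and suicide (ISS) is a critical transition. A
counselor juggling several concurrent chats benefits from an alert *before*
the disclosure happens. `issnet` implements a transparent, network-based
predictor of that transition point: instead of a black-box classifier over
raw text, it measures how close the vocabulary of a conversation block lies
to known disclosure vocabulary inside a word affinity network (WAN).

The unit of analysis is the **block**: ten consecutive help-seeker messages
(a trailing shorter remainder is kept but flagged partial). Within a session,
keyword matching with false-alarm filtering marks blocks containing explicit
ISS; the first such block is the **ISSB**, the block immediately before it is
the **PISSB** (the prediction target), and everything else is **NISSB**.
Sessions with fewer than ten message exchanges, or whose first ISSB has no
prior block, are excluded.

## The model

**Step 1 — word affinity network.** Sessions from a construction corpus are
tokenized; the top-k words by TF-IDF (corpus term frequency times
`ln(N/df)`, document = session; k = 5000 in the original study, 800 at the
packaged synthetic scale) become nodes. Edges carry an *affinity* in (0, 1]
from two channels: co-occurrence within a 5-token window inside a message,
normalized Jaccard-style as `cooc/(occ_i + occ_j - cooc)` and thresholded at
3 observations; and cosine similarity between CBOW word embeddings (128
dimensions for a production corpus, 32 here), retained at cosine >= 0.6 (a
mutual top-k rule is available instead). The two channels are merged by
`max`, and each edge gets a traversal length of `1 - affinity` (floored at
1e-6). Analysis is restricted to the largest connected component so
shortest-path distances are finite.

**Step 2 — modularity test.** A block projected onto the network is a word
module. Its compactness is the mean shortest-path distance over all ordered
word pairs, self-pairs included:

$$l_{block} = \frac{\sum_{v_i, v_j \in block} d(v_i, v_j)}{n^2}$$

The denominator is taken literally as \(n^2\); the reference distribution
comes from random node sets of the same size whose degrees match the
module's profile within doubling (log2) degree bins. A one-tailed z-test at
alpha 0.05 asks whether the observed module is more compact than chance.

**Step 3 — separation.** The distance between two modules is the separation
s-score

$$s_{(x,y)} = \langle b_{(x,y)} \rangle - \frac{\langle l_x \rangle + \langle l_y \rangle}{2},$$

the mean cross-pair distance minus the average of the within-module means;
`s(x, x) = 0` and the score is symmetric. A candidate block's classifier
score is \(\bar{s}\), its mean s-score against the reference set of ISSBs.

**Step 4 — threshold.** PISSB and NISSB score records are split 80/20
(stratified), and the cutoff `t` maximizing sensitivity + specificity on the
training set is chosen from the midpoints between consecutive distinct
scores. A block is called PISSB iff \(\bar{s} < t\), strictly: a score
exactly at `t` is NISSB. Performance is the c-statistic — the probability
that a random PISSB scores below a random NISSB, ties one half — and the
whole experiment is replicated 50 times with NISSB counterparts resampled
each trial.

## Distance metrics: hops versus lengths

Two metrics live on the same network. The modularity test and the s-score
use unweighted **hops** ("number of steps"), consistent with typical
compactness magnitudes around 2 on a large corpus. Counselor-facing path
*explanations* use the weighted **1 − affinity** lengths, so that a direct
edge of affinity 0.79 reads as a path of length 0.21 and multi-edge lengths
add. Both are selectable everywhere via `metric =`; the package default
follows this split.

## The false-alarm filters

Keyword matching alone over-triggers. Five cue-driven filters demote
matches, in fixed precedence: **negation** (a negation cue within 6 tokens
before the term), **subject** (the nearest subject mention before the term
is a third party rather than first person), **tense** (a past-tense cue
within the window, or an inflected past form of the matched term itself —
this is how "I jumped of a building" is caught without parsing), **quoting**
(a reporting verb earlier in the message), and **dream** (a dream cue
anywhere in the message). The window width and the precedence are design
choices made for determinism; both are documented knobs rather than claims
about the optimal operationalization. The packaged English lexicon is a
small demonstration set; real deployments must supply their own lexicon
file, and a human-override TSV always takes precedence over the automatic
labels.

## What the synthetic generator emulates — and what it does not

The original transcripts are private, so the package ships a generator that
reproduces the *statistical premise* of the method: sessions of alternating
help-seeker/counselor messages; token frequencies Zipf-distributed
(exponent 1.1) over three disjoint lexicons (700 neutral, 60 prodromal, 40
ISS entries, a quarter of the ISS entries two-token phrases); half the
sessions carry, in order, neutral blocks, one *prodromal* block (35% of its
tokens from the prodromal lexicon), and one explicit-ISS block (40% ISS
tokens, with the remainder again mixing in prodromal words so that
prodromal vocabulary co-occurs with — and therefore sits network-close to —
disclosure vocabulary). Counselor messages are always neutral. That
prodromal-to-ISS lexical proximity is exactly the mechanism the s-score is
meant to detect, so the generator is a test bed for every downstream stage:
with the mixture set to zero the pipeline's c-statistic is calibrated near
0.5, and it rises monotonically with the mixture.

The generator does **not** imitate Cantonese morphology, code-switching,
topic drift, or conversational pragmatics, and its planted signal is far
cleaner than real prodromal language: near-ceiling c-statistics on synthetic
corpora demonstrate that the machinery recovers a planted signal, not that
real-world performance reaches that level.

## Problem sizes and numerical choices

The packaged study conditions are 2000 construction sessions and 600
labeled sessions (vocabulary k = 800, embedding dimension 32, 20 epochs),
chosen so a full end-to-end replication run completes in about a minute on
one CPU while leaving every stage non-trivial; the calibration checks use
600/200 sessions. Other fixed numerical choices: null draws default 1000
(200 in tests and reports), null-SD floor 1e-9 with degenerate flagging,
lexicographic tie-breaks for vocabulary rank boundaries and path
explanations, smallest-t tie-break for the threshold grid, and an error (or
explicit drop-pairs policy with an audit flag) on disconnected word pairs.
Single-word modules have `l = 0` by construction and are flagged degenerate
in modularity reports. CBOW training is single-threaded with its own seeded
generator, so every embedding — and hence the whole network — is a pure
function of (corpus, parameters, seed).

## Design choices where the design was open

* **Reference-set leakage.** A scored block's own session's ISSB is always
  excluded from its reference set, and by default the reference set is
  restricted to ISSBs of training-split sessions; `paper_naive = TRUE`
  restores the literal all-ISSBs reading.
* **Counselor language.** Block tokens are help-seeker only (the method
  does not model two tracks of language); the network construction corpus
  uses all messages. Both are configurable.
* **Affinity combination.** `max` of the two channels keeps affinity in
  (0, 1] and preserves the two-fold interpretation; provenance is recorded
  per edge.
* **Group modularity summary.** Rather than a single opaque statistic, the
  report emits per-block compactness, null means/SDs and z-scores plus a
  two-sample group z, so any aggregate can be audited from the parts.

## Limitations

Hop distances are coarse on small networks; s-score magnitudes are
scale-dependent and not comparable across networks built at different
vocabulary sizes. The keyword annotator is lexicon-bound and
language-dependent; the shipped lexicon is for demonstration. The threshold
rule optimizes sensitivity + specificity only — no cost asymmetry — and the
classifier is binary by construction. None of the numbers produced on
synthetic corpora are estimates of performance on real counseling data.
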