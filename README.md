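# phonofluency

Scoring and network analysis for **phonological verbal fluency** tasks, in
which speakers produce, for one minute per cue, as many syllables as possible
that differ from the cue by a single phonological edit. The package targets
Mandarin-style monosyllables represented in the five-slot **C_G_V_X_T**
schema — onset consonant (C), glide (G), nucleus vowel (V), coda (X), lexical
tone (T) — and turns transcribed response streams into graded fluency scores,
participant-level phonological networks, and analysis-ready cohort tables.

## The measures

Let `e(a, b)` be the number of differing slots among {C, G, V, X, T}, with an
empty slot comparable to a filled one (so addition, deletion and substitution
of one segment or tone all cost 1), and `U` the unit count (filled segmental
slots + 1) of the longer member of a pair. The graded weight of a pair is

```
w(a, b) = clip[0,1] (U − e(a, b)) / (U − 1)
```

which yields the schedule 1, 0.75, 0.50, 0.25, 0 for a 4-unit cue with 5-unit
responses, and 1, 0.50, 0 for a 3-unit cue with 2-unit responses. From a
classified response stream the package computes, per trial:

* **WE** (weighted edit) — `Σ w(stimulus, r)` over *correct* responses: a
  fluency score that discounts responses by their distance from the cue.
* **RE** (running edit) — mean of `w(r_i, r_{i+1})` over consecutive
  productions, errors included; 1 means every production was an immediate
  neighbour of its predecessor.
* **SN** — proportion of consecutive pairs sharing the same atonal syllable
  (tone-family moves); `SN > 0.50` marks a predominantly syllable-driven
  search strategy.
* **Error** — nonword plus repetition productions.
* Network measures over the undirected graph whose nodes are the trial's
  unique correct productions and whose edges join pairs at edit distance 1:
  number of components **NC**, and **component-weighted** mean clustering
  coefficient CC̄ and degree assortativity *M* — averaged across *all*
  components with node-count weights and isolates set to zero, so a
  fully-clustered 9-node component plus one isolate scores CC̄ = 0.9 rather
  than 1.

A synthetic-cohort generator with known ground-truth strategy mixtures
(segment-driven single-slot mutation vs syllable-driven tone-family
enumeration), outlier-exclusion QC, and descriptive reporting complete the
pipeline.

## Worked example

```r
library(phonofluency)

lex_words <- c("wai4", "wai1", "shuai4", "shuan4", "zai4", "zai1", "zai3")
resp <- tibble::tibble(
  participant_id = "p01", trial_id = "t1", stimulus = "wai4",
  response = c("shuai4", "shuan4", "zai4", "zai1", "zai2", "zai3", "zai1"))

cls <- classify_productions(resp, lex_words)
score_trials(cls)
#>   n_correct n_nonword n_repetition   WE    RE    SN Error
#> 1         5         1            1 3.08 0.917 0.667     2
```

`zai2` is not in the lexicon (a nonword) and the second `zai1` is a
repetition, so Error = 2; the five correct responses contribute weights
1 + 0.75 + 0.667 + 0.333 + 0.333 = 3.08 to WE; the successive pair weights
(1, 0.5, 1, 1, 1, 1, errors included) average to RE 0.917, and 4 of 6
successive pairs are tone-family moves (SN 0.667).

```r
net <- trial_network(resp$response[cls$is_correct], stimulus = "wai4")
glance(net)
#>   n_nodes n_edges    NC CC_bar     M
#> 1       5       4     2    0.6     0
hop_distribution(net)
#>   hop              n
#> 1 1                1
#> 2 2                1
#> 3 disconnected     3
```

The `zai` tone family forms a triangle, `shuai4–shuan4` a separate edge (two
components, clustering 1, 1, 1, 0, 0 → CC̄ 0.6; both components are
degree-regular so *M* is 0), and only `shuai4` is an immediate neighbour of
the cue — the `zai` cluster has no path back to it.

At cohort scale:

```r
coh <- generate_cohort(n_participants = 95, seed = 2024)
sc  <- score_cohort(coh)
fluency_descriptives(sc)
#>   variable     n    min    max   mean     sd
#> 1 WE         570  0     16.3    6.40  2.92
#> 2 RE         570  0.625  1      0.952 0.064
#> 3 SN         570  0      1      0.450 0.175
#> 4 Error      570  0     11      2.55  2.04
#> 5 CC_bar     570  0      1      0.258 0.182
#> 6 M          570 -1      0.538 -0.173 0.270
#> 7 NC         570  1      7      1.99  1.13
strategy_split(sc)
#> [1] 0.346
```

About a third of generated trials are predominantly syllable-driven, trials
with many jumps fragment into more components with lower successive
similarity (`correlation_table(sc)["RE", "NC"]` is negative), and higher
fluency goes with more assortative networks (`["WE", "M"]` positive).

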