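---
title: "Methods: graded fluency scoring and component-weighted networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graded fluency scoring and component-weighted networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phonofluency)
```

## The syllable schema and edit metric

Every syllable is represented in five slots: onset consonant (C), glide (G),
nucleus vowel (V), coda (X), and lexical tone (T). V and T are always filled;
C, G and X may be empty, so unit counts run from 2 (a bare tonal vowel such
as `wu2`) to 5 (a full CGVX syllable such as `shuai4`). Segmentation is
deliberately delegated to a lookup table rather than rules: orthographic
conventions like `w`/`y` spellings do not determine slots (`wu` is a bare
vowel, `ye` is glide + vowel), and resolving them is the job of whichever
syllable database the user trusts. The packaged table covers the syllables
used in the examples and fixtures; user tables in the same two-column format
drop in for full coverage. Neutral tone is representable (category 5) but
absent from the fixtures.

Edit distance is the number of differing slots, comparing empty against
filled as a difference. This is a Hamming distance over five symbols —
genuinely a metric — and it reproduces addition, deletion and substitution
of one segment or tone as distance 1. It is *not* unrestricted Levenshtein
over linearised segments: slot alignment is part of the phonological claim
(a glide is never compared against a coda), and worked pairs such as
`wai4`–`shuan4` = 2 are only consistent with the slot-wise reading.

The graded weight of a pair is `(U − e)/(U − 1)` clipped into [0, 1], with
`U` the unit count of the *longer* item: the proportion of edit steps still
available before the pair shares nothing. One general formula reproduces
both weight schedules that anchor the scale (1, 0.75, 0.50, 0.25, 0 at
U = 5; 1, 0.50, 0 at U = 3); taking the longer item's U is what puts a
4-unit cue with 5-unit responses on the 5-step schedule. Identical items
(e = 0) are clipped to weight 1 — full similarity, the top of the scale.

## Trial scoring

Productions are classified in trial order: a production is a *word* if its
tonal string is in the lexicon, a *repetition* if the same tonal syllable
occurred earlier in the trial, and *correct* if it is a word and not a
repetition. Tone variants are distinct legitimate responses, so repetition
means exact tonal match, and the three categories are mutually exclusive
(repetition takes precedence over nonword) so that counts stay additive. A
production identical to the stimulus is treated as an ordinary response the
first time — the stimulus itself is not a production — and as a repetition
only if produced twice.

WE sums stimulus weights over correct productions only; RE and SN are means
over consecutive production pairs *including* errors, because interruptions
are part of the search trajectory being measured. Exact repetitions share
their atonal base and so count as syllable neighbours in SN; that is the
natural reading of including repetitions, though it is a convention, not an
observed fact about the original scoring. On trials with fewer than two
productions RE and SN are reported as missing rather than zero, so outlier
screens downstream are not distorted by degenerate trials.

## Component-weighted network measures

The trial network has the unique correct productions as nodes and edit-1
pairs as edges. The stimulus is not a node of the scored graph — the graph
describes what the participant produced — but it is attached afterwards for
the hop distribution, where each response is binned by its shortest-path
distance from the cue and path-less responses count as "disconnected". Both
conventions are switchable (`include_stimulus`), since drawings of such
networks often include the cue.

Fragmented networks are the interesting failure mode here, so instead of
the usual giant-component-only convention, CC̄ and *M* are node-count-
weighted averages over *all* components with isolates set to zero. For
clustering, nodes of degree < 2 get CC = 0 (not undefined); under that
convention the component-weighted average equals the plain node average, and
the worked 10-node example — a fully connected 9-node component plus one
isolate — scores exactly 0.9. For assortativity, each component's value is
the Pearson correlation of endpoint degrees over its edges taken in both
orientations (orientation-independent by construction); components on which
the correlation is undefined — no edges, or zero degree variance as in a
single edge, a cycle, or a clique — contribute 0, the same neutral value as
isolates. This treats "uninformative about mixing" uniformly rather than
dropping such components, and it is why a trial made of one tone-family
clique reports *M* = 0, not NA.

Both measures are authored in package code (triangle counting via the
adjacency matrix; the explicit degree correlation); the test suite checks
them against igraph's independent implementations on an exhaustive sweep of
all labelled graphs with up to 5 nodes plus hundreds of random graphs up to
12 nodes. The exhaustive sweep stops at 5 nodes because the count of
labelled graphs grows as 2^(n(n-1)/2); beyond that, random sampling covers
the space.

## Exclusion procedures

Participant-level screening excludes anyone whose total nonword or
repetition count lies more than 2.5 SD *above* the group mean, thresholds
computed once on the full pre-exclusion distribution. Trial-level screens
are per-variable and directional: WE and SN above-only at 2.5 SD (implausibly
high scores), RE below-only (implausibly incoherent streams), and *M* with a
two-sided Tukey boxplot rule at 1.5 IQR — the boxplot coefficient is a
package default, as the conventional fence, since only "a boxplot" is
specified by the procedure this reproduces. All screens are single-pass and
therefore idempotent. A minimum-cell-count filter (default 2) removes
participants who are alone at a covariate level. Whether the error screen
runs before or after other participant removals is left to the caller: the
screens are plain functions over tables, composable in either order.

## The synthetic-data generator

The generator exists so the whole pipeline is testable without any real
participant data; its output is explicitly synthetic and must never be
presented as observed data. It emulates the two search signatures visible
in real trials:

* a **segment move** mutates one slot of the previous production, giving an
  immediate-neighbour chain (pure segment search with no jumps scores
  RE = 1 by construction);
* a **syllable move** continues enumerating the remaining tone variants of
  the current atonal base in ascending tone order — tone families are
  produced as runs, nonwords included, which is exactly what drives SN up
  and brings errors along with the syllable-driven strategy;
* **jumps** happen only at steps that are not mid-family (searchers finish
  the family they are in): with probability `p_anchor` (default 0.5) a jump
  returns to an unproduced immediate word neighbour of the stimulus —
  mental searches anchor on the cue, which is what makes hop-1 responses
  the largest bin — and otherwise restarts from a random word, which is
  what fragments the network and raises NC;
* **repetition slips** re-emit one of the last three productions, a
  working-memory failure mode that preserves tone-family runs when they
  happen inside one.

Defaults are chosen once to emulate the study conditions of a 95-participant
university cohort with six one-minute trials: production counts negative-
binomial with mean 14 and size 8 bounded to [2, 30] (roughly a dozen correct
responses per trial plus a couple of errors); `p_syllable` = 0.35 with a
participant-level logit SD of 0.6, putting roughly a third of trials past
the SN > 0.5 split; `p_jump` = 0.10; nonword and repetition slip rates 0.08
and 0.05. Covariates follow the reported cohort structure — English
proficiency on levels 5–8 centred near 6.7, number of Chinese
languages/dialects 1–3, an even monolingual/multilingual split — and act on
the strategy parameters through logit-linear links in the directions the
observed regressions report: higher English lowers tone-family reliance and
error rates, higher Num_Chinese lowers tone-family reliance and raises the
jump rate, multilingual status lowers error rates. The logit link keeps
every probability in (0, 1) by construction, so no clipping is ever needed.

The toy lexicon crosses small disjoint slot alphabets (7 onsets, 3 glides,
3 nuclei, 3 codas, 4 tones; 756 tonal syllables) and marks each tonal
syllable as a word with probability 0.7. Stimuli are picked as the words
densest in immediate word neighbours, one per tone family — the same logic
as choosing high-neighbourhood cues without family overlap.

What the generator does *not* emulate: response timing, phonotactic
realism of the toy inventory, homophone/character knowledge, frequency
effects, and fatigue across trials. Passing tests therefore show that the
pipeline measures what the generative model encodes — monotone SN recovery
across `p_syllable` levels, strategy classification at the SN split,
negative RE–NC and positive WE–*M* correlations — not that real cohorts
will show the same magnitudes.

## Numerical and design notes

* Problem sizes in the test suite are chosen to keep the default run around
  1–2 minutes: 9 recovery levels × 100 trials, a 95 × 6 cohort for the
  correlation-sign check, 500 random 12-node graphs in the oracle sweep.
* Oracle comparisons use a 1e-8 tolerance: igraph's moment-based
  assortativity and the explicit correlation differ by ~1e-15 in absolute
  terms, which a relative 1e-12 tolerance would spuriously flag near zero.
* `tu` carries the aspirated onset /tʰ/ in the packaged mapping, keeping it
  phonologically distinct from `du` /t/ and the slot table invertible for
  round-tripping; every printed weight example is unaffected.
* Correlations default to product-moment with pairwise-complete missing
  handling; rank correlation and participant-level averaging are switches,
  since either convention is defensible for trial-level tables.
* The strategy split uses strict inequality (SN > 0.50), so ties at the
  threshold fall on the segment-driven side.
* End-to-end determinism: lexicon, trial and cohort generation all run
  under a single user-supplied seed, and `simulate → score → report`
  produces byte-identical CSVs across runs.

## Limitations

Multivariate model fitting over the seven dependent variables (and smooth
interaction surfaces) is out of scope by design: `export_model_table()`
hands a documented one-row-per-trial table to whatever regression machinery
the analyst prefers. Polysyllabic items, feature-level (sub-segmental)
similarity, tone sandhi and homophone resolution are likewise out of scope;
the slot metric treats every syllable as an unanalysable five-tuple.
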