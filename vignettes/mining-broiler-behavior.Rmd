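---
title: "Mining sequential behaviour patterns in broiler flocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining sequential behaviour patterns in broiler flocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(broilerseq)
```

## The problem

Behavioural welfare assessment in poultry usually counts how often or how
long behaviours occur. That discards the *temporal order* of events, yet
order carries signal: a broiler that stretches (`St`) and then immediately
lies laterally (`Ll`) is exposing body surface to dissipate heat — a
thermoregulatory sequence, not two unrelated postures. `broilerseq`
implements the sequence-analysis side of this idea: it turns ethogram-coded
behaviour bouts into per-bird sequence databases, mines them for frequent
sequential patterns with a generalized sequential pattern (GSP) engine, and
reports how the pattern repertoire changes across housing (enriched versus
non-enriched) and temperature (thermoneutral versus heat stress) conditions.

## The data model

**Ethogram.** Thirteen behaviours, identified by short case-sensitive
acronyms (`Ld, P, F, W, Db, Wf, Sf, E, D, R, St, Ll, Ex`). Exactly one,
exploring enrichment objects (`Ex`), can only occur in enriched pens.
Acronyms are canonical identifiers everywhere; the registry row order fixes
the deterministic ordering of all outputs.

**Bouts and windows.** Raw annotations are bouts: bird, window, onset,
duration, behaviour. A behaviour registers as an *event* only when sustained
for at least 10 s (`min_bout_s`); shorter bouts are discarded, not merged
into neighbours, because a transition is only recognised after sustained
activity and the treatment of sub-threshold bouts is otherwise unspecified.
Bouts belong to the 5-min window containing their onset and are truncated at
the window boundary (windows are analysed independently); a truncated bout
still counts if its within-window duration reaches the floor. Consecutive
surviving bouts of the same behaviour merge into one occurrence, so window
elements never contain adjacent duplicate codes. Windows with no events are
retained so that transaction times stay aligned across birds; they simply
support nothing. Each assessment day (thermoneutral day 21, heat day 22) is
a separate database — condition tables are mined separately, never pooled.

**Sequences and patterns.** A bird's sequence is its chronological list of
window elements. A *pattern* is an ordered series of elements, each an
ordered run of codes. Containment has two levels:

* an element matches a window when its codes embed as an order-preserving,
  multiplicity-respecting subsequence (gaps allowed): `{P,F,P}` matches a
  window recording `P,F,F,P`;
* a pattern matches a sequence when its elements map to strictly increasing
  windows (one window per element, no reuse).

Within-element order matters: `<{Ld,P,F}>` and `<{Ld,F,P}>` are distinct
patterns. Set semantics would collapse them, which is inconsistent with
repertoires in which both orders are reported; gap-free element matching
would make long elements essentially unminable. No time constraints
(max-gap, min-gap, sliding windows) are applied.

**Support.** The support of a pattern is the fraction of database sequences
(birds) containing it; a bird counts once regardless of how many embeddings
exist. Supports are therefore multiples of `1/n`. A pattern is frequent when
`support >= minsup` — the comparison is closed, so with ten birds a pattern
carried by exactly two of them is frequent at the 20% threshold.

## The mining engine

`mine_gsp()` is a level-wise GSP miner. Pass one counts the support of every
single code. Each later pass joins the frequent patterns of the previous
level: seeds `s1` and `s2` join when dropping `s1`'s first code equals
dropping `s2`'s last code, and the joined candidate appends `s2`'s last code
either merged into the final element or as a new element, mirroring `s2`'s
structure. Candidates are Apriori-pruned before counting and the loop stops
when a pass yields nothing. Support counting, the join and the maximality
filter run in small C++ kernels; the R level drives the passes.

One design point deserves emphasis. Mined patterns never contain adjacent
duplicate codes within an element, matching the data invariant created by
the merge rule. Under gap-allowed element matching such patterns are *not*
automatically unsupported (`<{a,a}>` embeds in a window `a,b,a`), so this
exclusion defines the pattern *language* being mined rather than a lossless
optimisation. Both the engine and the brute-force oracle enumerate exactly
this language, and the Apriori prune skips single-code deletions that would
leave an out-of-language subpattern — those are absent from the frequent set
by construction, not because they are infrequent.

`brute_force_mine()` is the verification oracle: it enumerates the complete
pattern language over the codes present in the database up to a code budget
and tests every containment through an independent pure-R path. The test
suite asserts engine–oracle identity on one hundred randomized small
databases at thresholds 0.2, 0.5 and 1.0, plus anti-monotonicity, support
quantization and determinism.

## Sweep reporting

`sweep_minsup()` reproduces the presentation used in condition pattern
tables: thresholds descend over a grid (default `1.0, 0.9, ..., 0.2`) and
each level reports only what is new — the maximal frequent patterns at that
level, minus anything identical to or contained in a higher-level report.
Maximality is applied level-locally first, then cross-level suppression;
this ordering reproduces tables whose top row shows a motif like `<{Ld,P}>`
without its single-code subpatterns and whose lower rows omit everything
already shown. Levels at which nothing survives print `None`, and adjacent
levels with identical level-local maximal sets collapse into one labelled
row (`1.0, 0.9 and 0.8`) for display.

The package ships transcriptions of observed condition tables for the four
housing-by-temperature conditions (`read_sweep_fixture()`), so the tally
layer — totals per condition (27 / 29 under thermoneutral, 7 / 8 under heat
for non-enriched / enriched), size compositions, the four behaviours (`Db`,
`Wf`, `R`, `Ex`) absent from every reported pattern, and maximum reported
sizes 4 (thermoneutral) versus 2 (heat) — is verifiable without any raw
data. Two entries in the enriched thermoneutral table print no `(n = k)`
count; the fixtures keep them verbatim and the parser treats the count as
optional.

## The synthetic flock generator

No raw annotation data are distributable with the package, so
`simulate_flock()` generates flocks with the statistical structure the
analysis assumes, making every stage testable end to end:

* **Semi-Markov walks.** Within each window a bird draws its next behaviour
  from the current row of a transition weight matrix (self-transitions are
  zero — same-code runs are one bout) and holds it for an exponential dwell
  with a floor at the 10-s rule, so generator and windowing agree by
  construction. The last bout of a window is truncated; sub-floor remnants
  are discarded downstream.
* **Condition presets** encode the study's qualitative contrasts and only
  those: `Ex` has weight only in enriched presets; `Ll` has weight only
  under heat; the `St -> Ll` transition is strongly boosted only in the
  non-enriched heat preset; heat presets have a lower `activity_scale`,
  which lengthens dwells and thus reduces the number of behavioural events.
  Magnitudes are illustrative — real per-behaviour rates are not
  recoverable from summary tables, and no attempt is made to inversely
  reconstruct a database reproducing them exactly.
* **Individuality.** Each bird receives Gamma-distributed behaviour
  preference multipliers (shape 0.5, mean 1), and each bird-window an
  additional, more concentrated draw (shape 0.25) modelling short-term
  behavioural context: a window tends to be a resting spell or a feeding
  circuit, not a uniform sample of the repertoire. Poultry behaviour is
  known to follow individual rather than flock rhythms, and without such
  heterogeneity simulated flocks share combinatorially deep patterns that
  observed tables rule out (their maximal reported patterns stop at size 4).

**Event density.** Defaults produce roughly 1.5–2 events per 5-min window
(about 17–25 qualifying events per bird-day; heat lower than thermoneutral).
This is a deliberate design choice rather than a match to any nominal event
count: at densities of ~10 events per window, every common behaviour becomes
embeddable in 8–12 windows for at least one bird pair, and the complete
frequent set at a 20% threshold grows beyond any practical enumeration
(measured growth was roughly tenfold per item level). Observed condition
tables — whose maximal patterns stop at a handful of elements — are only
consistent with far sparser qualifying-event streams, and the defaults are
tuned once to that regime. Density is fully configurable through the preset
dwell means and `activity_scale`.

`plant_pattern()` splices a chosen pattern into a chosen fraction of birds
(elements inserted at the start of distinct, randomly chosen increasing
windows, displacing existing bouts), giving a known ground truth: planting
`<{St,Ll}>` into a thermoneutral flock — where `Ll` never occurs
spontaneously — yields a mined support of exactly the carrier fraction.

## Numerical and interface choices

* Frequency thresholds are compared as `support_count >= ceiling(minsup * n
  - 1e-9)`, avoiding floating-point edge effects while keeping the closed
  comparison exact.
* Output ordering is total code count, then element count, then
  lexicographic order over canonical ethogram code indices; two runs on the
  same database are byte-identical.
* Windows are 0-indexed in bout tables and internally, 1-indexed in printed
  transaction output.
* Text formats: bout CSVs
  (`broiler_id,condition,day,window_index,onset_s,duration_s,behavior`),
  tab-separated sequence databases (SID, transaction index, comma-joined
  codes; empty for event-free windows), the `<{A,B} {C}> (n = k)` pattern
  dialect (round-trip safe, whitespace tolerant), JSON-lines pattern
  exports, and a YAML preset registry.
* The analysis drivers under `analysis/` (simulate, build databases, mine,
  sweep, summarise reference tables) are thin orchestrations of the exported
  functions; every computation they perform is available — and tested — as
  a package function.

## Scales used by the shipped tests and drivers

Engine–oracle equivalence runs on one hundred randomized databases of up to
ten sequences, six windows, a six-code alphabet and four-code patterns;
condition-level direction checks use twenty simulated flocks per temperature
arm at the default ten birds and fourteen windows. These sizes were chosen
so the oracle's exhaustive enumeration stays exact and the full suite runs
in minutes while still exercising every code path at the study's own flock
dimensions.

## What passing tests do and do not show

The generator reproduces directions, not magnitudes: fewer reported
patterns under heat, `Ll` only under heat, `St -> Ll` concentrated in
non-enriched heat, `Ex` only under enrichment, and more active thermoneutral
flocks. It does not model diurnal structure, social interaction, spatial
position, thermoregulatory physiology, or annotation error, and simulated
pattern counts are an order of magnitude above the observed tables (real
flocks are more individual than any stationary preset). Conclusions about
real flocks should rest on the mining and reporting layers — which are
exact, oracle-verified algorithms — applied to real annotations, not on the
generator's presets.

## Known limitations

* The engine enumerates the complete frequent set; at very high event
  densities or low thresholds that set is genuinely exponential and mining
  will be slow or infeasible regardless of implementation. The sweep's
  lowest level and the generator's density defaults are set with this in
  mind.
* Reported "size" counts elements (the table convention) while the engine's
  level variable counts codes; both are exposed (`size`, `item_count`)
  because summary tables use the former and the algorithm the latter.
* Whether multiple in-window embeddings were deduplicated per bird in the
  original analyses is not stated; this implementation counts each bird
  once, which is what the support definition implies.
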