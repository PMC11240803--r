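# broilerseq

Sequential pattern mining of broiler chicken behaviour.

Welfare assessment in poultry usually scores how *often* behaviours occur.
`broilerseq` is for researchers in precision livestock farming who want the
*order* of behaviours instead: it converts ethogram-coded behaviour bouts
into per-bird sequence databases, mines them for frequent sequential
patterns with a generalized sequential pattern (GSP) engine, and reports how
the pattern repertoire differs between enriched and non-enriched pens under
thermoneutral and heat-stress conditions. Order is informative: stretching
(`St`) followed immediately by lying laterally (`Ll`) is a thermoregulatory
sequence — a behavioural signature of heat stress — while the same two
postures far apart in time are not.

## The model

A bird's observation day is a chronological series of 5-min windows; each
window holds the ordered run of behaviours the bird sustained for at least
10 s (thirteen ethogram codes; consecutive same-code bouts merge). A
*sequential pattern* `<{e1} {e2} ...>` is an ordered series of elements,
each an ordered run of codes. A sequence contains a pattern when the
elements embed into strictly increasing windows, each element matching as an
order-preserving subsequence within a single window. The support of pattern
`s` in database `D` is

    supp(s) = |{ birds whose sequence contains s }| / |D|   in [0, 1]

and `s` is *frequent* when `supp(s) >= minsup` for a user-set minimum
support (the study threshold of interest is 20%). The GSP engine finds the
complete frequent set level-wise: frequent single codes seed candidate
generation, each pass grows candidates by one code (join + Apriori prune),
and counting stops when nothing frequent remains. A brute-force enumeration
oracle verifies the engine on small databases, and a seeded semi-Markov
flock simulator with four condition presets (thermoneutral/heat x
plain/enriched) makes the whole pipeline testable without any data download.

## A worked example

The two-bird database used throughout the documentation: bird 1 eats, walks,
then drinks; bird 2 lies down, then preens.

```r
library(broilerseq)
db <- example_database()
sequence_size(db[["broiler_1"]])   # 3  (three windows -> size 3)
sequence_size(db[["broiler_2"]])   # 2
mine_gsp(db, minsup = 0.5)
```

```
10 frequent pattern(s)
      notation support_count support item_count size
        <{Ld}>             1     0.5          1    1
         <{P}>             1     0.5          1    1
         <{W}>             1     0.5          1    1
         <{E}>             1     0.5          1    1
         <{D}>             1     0.5          1    1
    <{Ld} {P}>             1     0.5          2    2
     <{W} {D}>             1     0.5          2    2
     <{E} {W}>             1     0.5          2    2
     <{E} {D}>             1     0.5          2    2
 <{E} {W} {D}>             1     0.5          3    3
```

At `minsup = 0.5` a pattern needs only one of the two birds, so every
subpattern of either sequence is frequent — ten in all, exactly what
exhaustive enumeration (`brute_force_mine()`) returns. At `minsup = 1.0` the
result is empty: the birds share no behaviour. Note `<{E} {D}>` is frequent
(walking may intervene between windows) but `<{Ld,P}>` is not contained in
bird 2's sequence — co-occurrence inside one element requires a single
window.

The presentation layer reproduces threshold-sweep tables — at each level
only the new maximal patterns are shown:

```r
sw <- sweep_minsup(db, levels = seq(1, 0.5, by = -0.1))
writeLines(format_sweep_text(sw))
```

```
MinSupport	Sequence Number	Sequence
1.0 to 0.6	None	
0.5	1 size 2, 1 size 3	<{Ld} {P}> (n = 1); <{E} {W} {D}> (n = 1)
```

The package also ships transcribed reference pattern tables for four
observed flock conditions; `read_sweep_fixture("heat_plain")` and friends
feed the tally layer (`total_patterns()`, `tally_sizes()`,
`behavior_coverage()`, `max_reported_size()`), which reproduces the
published totals (27 / 29 thermoneutral, 7 / 8 heat), the four behaviours
never reported at the 20% level (`Db, Wf, R, Ex`), and the collapse of
maximum pattern size from 4 to 2 under heat.

End-to-end drivers live in `analysis/` (`01_simulate_flocks.R` ...
`05_reference_tables.R`): simulate the four conditions, build databases,
mine at 20%, write sweep reports, and summarise the reference tables. Their
outputs go to `results/`.

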