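# cas13sg — structure-guided Cas13 guide design and cleavage analysis

Cas13 effectors (e.g. LshCas13a) are RNA-guided RNA endonucleases with a
strong preference for cleaving **single-stranded (SS)** regions of their
target transcript. Guides whose spacers land on stems (double-stranded,
DS) tend to fail; guides whose spacers complement loops work — and what
matters most is an 8-base **central seed** in the guide (positions 11–18
of a 28-mer) pairing with single-stranded target nucleotides. `cas13sg`
turns these rules into a design and analysis toolkit for anyone
knocking down transcripts (long non-coding RNAs especially) with Cas13:

* **Structure I/O** — read secondary structures from connectivity tables
  (`.ct`), extended dot-bracket strings (pseudoknot bracket alphabets
  `()[]{}<>Aa–Dd`), or PARS-style structure-probing score tracks
  (positive score ⇒ paired, negative ⇒ unpaired), into one validated
  pair-map model.
* **Region annotation** — per-nucleotide SS/DS calls, maximal region
  segmentation with stem–loop junctions, and pseudoknot annotation as
  crossing base pairs: pairs (i,j), (k,l) with i<k<j<l.
* **Guide design** — enumerate spacer windows (20–28 nt; default 28) and
  score each by its SS-complement count `s` and central-seed SS count:
  *poor* when `s ≤ 10` with a broken seed, *efficient* when the seed is
  fully single-stranded (8/8) or `s ≥ 18`, *intermediate* otherwise.
  Candidates carry protospacer-flanking sites (3′ G soft-flagged, never
  filtered), junction coverage, pseudoknot base counts, hairpin/dimer/
  homopolymer screens, an optional mismatch off-target scan, and
  BbsI-ready (GAAGAC) cloning oligos.
* **Cleavage analysis** — from treatment and no-guide control alignments
  (SAM or a simple TSV): keep reads with MAPQ > 30, build per-position
  coverage, call a nucleotide *cleaved* when its treatment coverage
  drops to ≤ 50 % of a well-covered control, and report per region

  `cleavage rate = cleaved nucleotides / total nucleotides × 100`,

  with aggregate SS and DS rates compared by an exact two-tailed
  rank-sum test (stars: \*p<0.05, \*\*p<0.01, \*\*\*p<0.001).
* **Synthetic data** — deterministic generators for structured
  transcripts, noisy probing tracks and read sets with planted cleavage,
  so the full workflow is testable end to end without external data.

## Worked example

```r
library(cas13sg)

# a 2-kb synthetic transcript: four 300-nt loops on 100-bp stems,
# probing track and reads with cleavage planted at the loop centres
b <- synthetic_experiment(seed = 7)
state <- state_from_structure(b$structure)

# design guides against it
cand <- enumerate_candidates(b$structure$sequence, state)
head(cand[, c("protospacer_start", "ss_complement_count",
              "central_seed_ss_count", "efficiency_class")])
#>   protospacer_start ss_complement_count central_seed_ss_count efficiency_class
#> 1               101                  28                     8        efficient
#> 2               102                  28                     8        efficient
#> ...
```

Top-ranked candidates are fully single-stranded 28-mers whose central
seed sits inside a designed loop.

```r
# quantify the planted cleavage
L   <- length(b$structure)
trt <- coverage_profile(filter_alignments(b$reads$treatment), L)
ctl <- coverage_profile(filter_alignments(b$reads$control), L)
rep <- cleavage_report(segment_regions(state)$regions,
                       call_cleavage(trt, ctl))
rep$aggregate
#>   cls cleaved_nucleotides total_nucleotides     rate n_regions
#> 1  DS                   0               800  0.00000         5
#> 2  SS                 284              1200 23.66667         4
rep$comparison$p_value
#> [1] 0.007936508
```

Cleavage concentrates in the single-stranded loops: SS aggregate rate
23.7 %, DS 0 %, exact rank-sum p ≈ 0.008 (\*\*) — the single-strand
preference the design rules are built on.

Shell use: `inst/scripts/cas13sg annotate|design|cleave|simulate …`
wraps the same functions (`run_annotate()`, `run_design()`,
`run_cleave()`, `run_simulate()`), each run writing a provenance record
with parameters, package version and input checksums.

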