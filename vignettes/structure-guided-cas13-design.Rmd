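---
title: "Structure-guided Cas13 guide design: models, parameters and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-guided Cas13 guide design: models, parameters and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cas13sg)
```

## The problem and the model

Cas13 ribonucleases cleave RNA wherever their guide's spacer can base-pair
with the target, but the target must be physically accessible: cleavage is
strongly biased toward single-stranded (SS) loops and away from
double-stranded (DS) stems. `cas13sg` encodes a small set of empirical
design rules on top of a per-nucleotide strand-state model of the target
transcript:

1. **Strand state.** Every position is SS, DS or unknown. From a
   secondary structure (CT or dot-bracket) the call is definitional —
   DS iff the position has a pairing partner. From a probing track
   (PARS sign convention: positive score ⇒ paired) the call is a
   threshold rule with a configurable dead zone; a score *at* the
   threshold is deliberately `unknown`, never silently SS, because
   unknown positions are excluded from every scoring numerator.
2. **Guide scoring.** A spacer of length $L$ (20–28 nt, default 28)
   targeting protospacer $[p_s, p_e]$ is scored by its SS-complement
   count $s$ = number of protospacer nucleotides called SS, and by the
   SS count inside the 8-base **central seed**, guide positions
   $\lfloor (L-8)/2 \rfloor + 1$ through $\lfloor (L-8)/2 \rfloor + 8$
   (positions 11–18 for $L=28$), mapped to the protospacer under
   antiparallel pairing (guide position $k$ ↔ transcript position
   $p_e - k + 1$).
3. **Efficiency classes.** *Efficient* iff the seed is fully SS (8/8)
   **or** $s \ge 18$; *poor* iff $s \le 10$ and the seed is broken;
   *intermediate* otherwise. Both efficient routes are kept and
   reported separately (`central_seed_ss_count`, `ss_complement_count`)
   so users can tighten to the seed-only rule. The class is monotone in
   $s$ at fixed seed count, and a full seed always wins.
4. **Cleavage statistic.** For a region $R$,
   $\text{rate}(R) = 100 \cdot \#\{\text{cleaved nucleotides in } R\} /
   |R|$; aggregate class rates are numerator/denominator sums, i.e. the
   length-weighted mean of member-region rates. SS and DS per-region
   rates are compared with a two-tailed rank-sum test.

Protospacer-flanking sites are annotated but never filtered: the 3′ G is
soft-flagged (slightly weaker knockdown for G-PFS, overall PFS effects
insignificant for LshCas13a in mammalian cells), and pseudoknot
participation is reported (`knot_base_count`) but not penalised, since
targeting pseudoknotted loops does not measurably change knockdown.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `spacer_length` | 28 | nt | longest well-tolerated spacer; 20–28 accepted |
| `poor_max_ss` / `efficient_min_ss` | 10 / 18 | nt | empirical class boundaries on the SS-complement count |
| probing `threshold`, `dead_zone` | 0, 0 | score units | sign convention boundary; dead zone trades coverage for confidence |
| `mapq_min` | 30 | Phred | reads kept when MAPQ is *strictly* greater |
| `drop_fraction` | 0.5 | — | treatment/control coverage ratio at or below which a position is cleaved |
| `min_control_depth` | 10 | CPM depth | evidence floor: positions with a thin control are uncallable, not cleaved |
| filter thresholds | stem 5 bp, loop 3 nt, dimer 8 nt, homopolymer 5 | nt | conventional oligo-screening scales; all configurable |

How a nucleotide was originally called "cleaved" from alignment files is
not recoverable from published material; the coverage-drop rule above is
this package's definition, stated in every output header
(`cleavage_definition` in the JSON summary) and fully parameterised.
Normalisation is counts-per-million over retained reads. The rank-sum
comparison enumerates the exact permutation null for total $n \le 16$
(midranks, valid under ties — frequent here because many DS regions have
rate 0) and uses the tie-corrected normal approximation beyond.

## What the synthetic generator emulates

`synthetic_experiment()` stands in for a structure-probed transcript and
a paired knockdown sequencing experiment:

* **Transcript** (default): 2 000 nt, four 300-nt loops on 100-bp stems —
  the scale of a large lncRNA's stem–loop domains, chosen so loops are
  several read lengths long. Stems are complementary by construction with
  uniform GC-balanced bases; the dot-bracket of the design is exactly the
  returned structure.
* **Probing track**: score $\pm 1$ by true pairing state plus Gaussian
  noise (default sd 0.5, i.e. per-position recovery
  $\Phi(1/0.5) \approx 0.977$) and 5 % missing data — a stylised PARS
  track, not a model of V1/S1 enzyme biases.
* **Reads**: 10 000 per sample, log-normal lengths (median 150 nt,
  truncated to [100, transcript length]) started uniformly — loosely
  Nanopore-like; MAPQ from a low/high mixture (15 % ≤ 30) so the filter
  is exercised. Cleavage is planted at each loop centre: a spanning read
  is truncated at the cut with probability 0.9 (3′ fragment lost). Under
  this truncation model the coverage deficit necessarily extends ~one
  read length 3′ of the cut, which is why loops are made ≫ read length:
  the deficit stays essentially within the loop, and with 4 SS + 5 DS
  regions the smallest achievable exact two-sided rank-sum p is
  $1/\binom{9}{4} \approx 0.008$. The alternative `model = "fragment"`
  retains both fragments and excises the cut nucleotide, giving a
  deficit confined to the locus — that model is used where planted loci
  must be recovered position-exactly.

What passing tests on these fixtures do **not** show: real probing noise
is not Gaussian or independent per position, real read starts are not
uniform (coverage decays 5′ in Nanopore dRNA-seq), collateral Cas13
activity can cleave far from the guide, and real structures are ensembles
rather than a single pair map. The generator validates the machinery and
the statistics, not the biology.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere internally (the CT
  convention); conversion to 0-based half-open happens only at BED
  export, covered by round-trip tests.
* `T` is normalised to `U` and case folded on every sequence input.
* Multi-structure CT files yield the first structure unless an index is
  requested (minimum-free-energy structure first, by convention).
* Dot-bracket writing assigns crossing pair sets greedily to successive
  bracket families; more than eight mutually crossing families is an
  error (never reached by realistic structures).
* Probing ties at the threshold → `unknown`. No minimum region length or
  smoothing is applied by default; an optional odd-window majority
  smoother (`smooth_state()`) is available.
* Candidate sorting is fully deterministic: class, then seed SS count,
  then total SS count (descending), then protospacer start.
* Rank-sum comparison requires ≥ 2 regions per class and errors
  otherwise; `cleavage_report()` returns `NULL` for the comparison when
  a class is missing rather than fabricating a p-value.
* Problem sizes in the shipped tests (2-kb transcripts, $10^4$ reads,
  200 random structures for the oracle suites) were chosen as the
  smallest at which the statistical assertions are stable across seeds.

## Known limitations

* Structures are consumed, never predicted — no folding,
  partition-function or pseudoknot-prediction step; the pseudoknot
  module classifies crossing pairs in structures supplied to it.
* The off-target scan is a local FASTA mismatch search (substitutions
  only, both strands), not a genome-index search; indels are not
  modelled.
* No thermodynamic duplex scoring and no learned efficiency model: the
  class boundaries are step rules, deliberately transparent.
* The cleavage caller sees only coverage; read-end pileup information
  (cut-site stacking) is not used.
* SS/DS region calls from probing inherit the track's threshold choice;
  the package exposes it rather than asserting a universal value.
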