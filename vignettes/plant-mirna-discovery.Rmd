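---
title: "Discovering plant miRNAs from small RNA sequencing reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering plant miRNAs from small RNA sequencing reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plantmir)
```

## The problem

Novel miRNA discovery from small RNA sequencing is well solved for animals,
where precursor hairpins are short (~70 nt): excise a small window around a
read pile-up, fold it, and test the hairpin.  Plant pre-miRNAs break this
recipe because the distance between the mature and star sequences is
commonly 100-200 bp.  A short excision window truncates the true hairpin (a
false negative); an indiscriminately long window invites spurious pairing
partners for the mature (a false positive).

plantmir addresses this with a *mature-anchored* excision strategy: the
highest-expressed read of each alignment cluster is taken as the putative
mature, and candidate precursor windows are laid out so that the mature sits
at the end of one arm, scanning both a 200 nt and a 100 nt mature-to-star
span under both arm hypotheses (star downstream of the mature, or upstream).
Anchoring guarantees the mature lies at an arm end if the locus is genuine;
the 100 nt rescue span catches short precursors that the 200 nt window would
misfold.

## Pipeline

1. **Preprocess** (`preprocess_reads()`): 3' adapter trimming (exact
   adapter-prefix suffix match), length filtering to 10-23 nt, mean-Phred
   quality filtering, removal of reads containing N, and collapsing of
   identical reads into unique sequences with copy counts.
2. **Map** (`map_reads()`): exact, mismatch-free placement of every
   collapsed read on both genome strands (the matching engine is
   Biostrings).  Reads with more than `max_loci` (default 20) placements are
   discarded entirely rather than randomly assigned, keeping runs
   deterministic.  Copy counts travel with each alignment and into SAM
   output as the `XS` integer tag.
3. **Cluster and excise** (`cluster_alignments()`, `excise_candidates()`):
   alignments on one chromosome and strand chain into a cluster when
   successive intervals are within `max_gap` (default 30 nt).  For the
   anchor read at `[s, e]` the 5'-arm hypothesis excises
   `[s - flank, e + L]` and the 3'-arm hypothesis `[s - L, e + flank]`, for
   each span `L` in `spans` (defaults 200 and 100; `flank` 20).
4. **Fold** (`fold()`): minimum-free-energy structure of each window under
   the nearest-neighbor model described below.
5. **Filter** (`parse_hairpin()`, `infer_star()`, `check_loop()`,
   `read_consistency()`): structural and read-level plant filters.
6. **Score, deduplicate, annotate** (`score_candidate()`,
   `deduplicate_predictions()`, `match_known()`): additive log-odds score,
   one prediction per locus, optional known-miRNA annotation.
7. **Report** (`write_results()`, `render_hairpin_text()`,
   `render_hairpin_svg()`): six result files plus hairpin-with-reads
   diagrams.

## The folding model

`fold()` minimizes free energy over nested structures by dynamic programming
in C++, with three deliberate restrictions:

* **No multibranch loops.** A closed pair may contain a hairpin loop or one
  interior pair (stack, bulge, or internal loop up to 30 unpaired nt); any
  number of stems may sit side by side at the exterior level.  Downstream
  filtering rejects multi-hairpin candidates anyway, and the restriction
  makes the exhaustive verification oracle tractable.
* **Turner-style parameters, not Turner-complete.** Stacking energies for
  the 36 Watson-Crick/G-U doublets and size-dependent hairpin/bulge/internal
  loop penalties (log-extrapolated beyond the tables), at fixed 37 degrees
  Celsius.  There are no dangling ends, coaxial stacks, or special
  tetraloops, and the two destabilizing G-U-on-G-U stack entries are floored
  at -0.3 kcal/mol so that every stack is stabilizing.  Energies therefore
  do **not** numerically match RNAfold; the contract is the structural
  decision (does this window form a plant-like hairpin), not the kcal value.
* **Integer energies.** All parameters are integer hundredths of a
  kcal/mol, so the DP and the enumeration oracle (`fold_oracle()`, below)
  can be compared for *exact* equality with no floating-point slack.

Ties during traceback are broken deterministically: prefer pairing `(i, j)`
with the smallest `i`, then the largest `j`; at equal energy an extra
interior pair is preferred over closing the hairpin.  `fold_oracle()`
enumerates every valid structure of sequences up to 25 nt, scores each with
an independent walk over its loops, and applies the same tie-break; the test
suite verifies exact agreement with the DP on 200 random sequences per run.

## Hairpin geometry and the star

`parse_hairpin()` locates the outermost base pair enclosing the mature; the
stem inside it must contain exactly one terminal loop (otherwise
`multibranch`), and the mature must lie within one arm, not overlapping the
terminal loop (`mature_position`).  Internal loops and bulges inside the
arms are unrestricted in number — plant stems are long and imperfect — but
at least `min_paired_fraction` (default 60%) of mature bases must pair
(`unpaired_mature`).

`infer_star()` maps the mature through the pairing table, bridging unpaired
mature bases by linear interpolation between flanking partners, and shifts
the result so each duplex strand carries a 2 nt 3' overhang — the DCL1
cleavage signature.  On a perfect stem the mapping is an involution: the
star of the star is the mature.

`check_loop()` measures the gap between the mature-proximal and
star-proximal duplex ends in precursor coordinates and requires at least
`min_loop` nt (default 25).  The span includes the distance from the loop
ends to the mature or star, and the default reflects the long terminal
loops of plant precursors.

## Read consistency and the star bonus

A cluster chained at `max_gap` 30 nt cannot contain both arms of a plant
precursor (the arms are 58-158 nt apart), so consistency is evaluated over
*all* alignments overlapping the candidate window, in precursor
coordinates.  A read is consistent when it lies entirely within the mature
or the star region, with up to `consistency_shift_tol` (default 3) nt of
positional drift for imprecise processing.  Reads in the terminal loop are
**inconsistent** — unlike the animal-miRDeep convention — because plant
loops are long enough to accumulate unrelated reads.  The candidate passes
when the copy-weighted inconsistent fraction is strictly below
`max_incon_ratio` (default 0.10; a ratio of exactly 10% fails).

Two related distinctions are worth noting:

* The **star bonus** in the score requires a *star-positioned* read — both
  ends within the shift tolerance of the inferred star's ends — because the
  bonus rewards evidence of duplex processing, which a short fragment
  merely lying inside the star region does not provide.
* A window whose star region out-expresses its mature region is rejected
  (`star_dominant`): with both arm hypotheses scanned, the mirrored
  star-anchored window of a genuine locus would otherwise be reported with
  mature and star swapped.  The anchoring model defines the mature as the
  higher-expressed arm.

## Scoring

Each surviving candidate receives a sum of four components (bits):

| component       | form                                               | default constants |
|-----------------|----------------------------------------------------|-------------------|
| `s_depth`       | `log2(1 + consistent copies)`, capped              | cap 5             |
| `s_star`        | bonus if a star-positioned read exists, else penalty | +3.9 / -1.3     |
| `s_energy`      | `clamp(slope * (-E/len - scale))`                  | scale 0.20 (kcal/mol)/nt, slope 10, clamp [-2, +3] |
| `s_consistency` | `log2(1 - ratio) - log2(1 - max_incon_ratio)`      | 0 at the threshold |

Predictions with totals below `min_score` (default 4, the conventional
reporting cutoff for this family of scores) are dropped.  The component
constants are fixed, documented surrogates chosen for this package: the
original probabilistic training data behind miRDeep-style scores is not
published, so the score is a deterministic contract of *this* artifact
rather than a numerical reproduction.  Among overlapping same-strand
windows only the highest-scoring prediction is kept (ties: longer
precursor, then leftmost).

## The simulator

`make_genome()` plants `n_hairpins` stem-loops in a uniform random genome:
mature (21 nt), spacer, and the reverse complement of the mature with
`stem_mismatches` substitutions (each substitution chosen so the base can no
longer pair, Watson-Crick or wobble, with its partner).  The mature-to-star
span is drawn per locus from `span` (default 100-200 nt, the plant
precursor range), and loci are placed at random offsets inside equal
non-overlapping genome blocks.  `simulate_reads()` draws per locus, with
largest-remainder rounding: 90% mature-positioned reads (start jitter up to
1 nt), 5% star-positioned, 5% mappable background noise (genuine genome
substrings of 10-23 nt on either strand), all at constant Phred 40.

What this emulates: the dominant-mature / sparse-star expression signature,
isomiR-like positional jitter, and mappable background that stresses
clustering and consistency.  What it does not: sequencing errors, realistic
expression distributions (e.g. heavy-tailed locus depths), RNA degradation
ladders, multi-locus miRNA families, or genomic repeats.  Passing the
recovery tests therefore demonstrates the pipeline's contracts under clean
plant-like geometry, not performance on real libraries.

Constant qualities are deliberate: quality filtering is exercised by
dedicated fixtures so that a recovery failure can only implicate the
identification stages.

## Numerical and design choices

* Coordinates are 1-based closed in memory (the IRanges/Biostrings
  convention used by every container in the package) and in the TSV
  reports; SAM output is 1-based per the standard, and BED/truth-table
  exports are 0-based half-open.
* Windows are clipped to chromosome bounds; a window left shorter than the
  mature is skipped.  Duplicate windows (same chromosome, strand, interval
  and anchor offset) are folded once.
* One anchor per cluster: secondary expression peaks do not re-anchor; a
  missed locus stays missed rather than triggering data-dependent
  reprocessing.
* The anchor tie-break (copy count, then leftmost start, then sequence) and
  the traceback tie-break make runs byte-reproducible: identical inputs and
  configuration give identical output files.
* Known-mature matching tolerates the usual isomiR variation: exact
  agreement over the aligned overlap with a start shift up to 3 nt and a
  length difference up to 2 nt.

Test and validation problem sizes were chosen to make the oracles airtight
and the suite quick: folding equivalence uses 200 random sequences of up to
18 nt against exhaustive enumeration; mapping completeness uses a 10 kb
genome against a naive all-positions scan; end-to-end recovery uses a 100 kb
genome with 20 planted loci at 100 reads per locus, which the pipeline
processes in well under a minute.

## Limitations

* The energy model is a simplification; borderline hairpins may fold
  differently than under full Turner 2004 parameters, and a locus whose
  window MFE structure buries the mature in a competing stem is lost (the
  100 nt rescue span recovers most such cases).
* Two isolated single-copy reads that happen to form a valid Dicer-like
  duplex can score above the reporting cutoff (~6 bits).  This is the
  log-odds model behaving as specified — two independent reads with the
  right geometry *are* evidence — but on deeply sequenced real libraries
  such loci warrant inspection of the read stack before being believed.
* No conservation, target-complementarity, or expression-distribution
  evidence is used; scores are per-locus and library-local.
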