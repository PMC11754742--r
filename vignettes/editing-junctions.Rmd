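---
title: "Junction profiling and pause-site detection for U-indel editing amplicons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Junction profiling and pause-site detection for U-indel editing amplicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editpause)
```

## The measurement problem

Kinetoplastid mitochondrial mRNAs are matured by uridine insertion/deletion
(U-indel) editing: guide RNAs direct the insertion (and less often deletion)
of U residues at defined positions, working generally from the 3' end of a
transcript towards the 5' end.  A steady-state population of a pan-edited
mRNA such as ATP synthase subunit 6 (A6) is therefore a mixture of
pre-edited molecules, fully edited molecules, and — mostly — partially
edited intermediates whose 3' portion is canonically edited and whose 5'
leading edge often carries a *junction*: a stretch matching neither the
pre-edited nor the canonical sequence, interpreted as a zone of ongoing or
mis-directed editing.

When an editing factor is depleted (for example by doxycycline-inducible
RNAi), editing can stall at specific sites.  Amplicon deep sequencing of a
transcript region, before and after knockdown, makes these stalls
measurable: the distribution of junction end sites shifts, and particular
editing sites accumulate reads whose editing stops there.  This package
implements that measurement end to end and ships a read simulator so that
every stage can be validated against a known ground truth.

## Coordinate system and read reduction

Because every difference between a pre-edited and a fully edited molecule is
confined to U's, both sequences share an identical *backbone* of non-T
residues.  The package aligns a reference pair by this backbone
(`build_scaffold()`), defining an **editing site (ES)** at each gap between
consecutive backbone residues.  ES are numbered 1..n from the 3' end,
following the direction of editing, so site windows quoted in the editing
literature (e.g. "ES121-126") carry over directly.  Each ES stores the
pre-edited and canonical U count; interleaving the backbone with either
vector reproduces the corresponding input exactly, and this round trip is
enforced by property tests.

Two conventions are applied on input: terminal T's (outside the first and
last backbone residue) are trimmed, since editing sites are defined between
residues and real amplicons are delimited by primers in never-edited
sequence; and `U`/lowercase are normalised while degenerate IUPAC codes are
rejected rather than guessed.

A read is reduced to its observed U-count vector by exact matching
(`align_read()`): both primers are located verbatim, and the non-T residue
string between their footprints must equal the reference backbone over the
amplicon window.  Reads failing this — a non-T SNP, an indel, a missing
primer, or a length below the configured minimum — are *excluded* with a
machine-readable reason rather than rescued by approximate alignment.  The
exclusion rule makes mismatch tolerance unnecessary by construction, keeps
per-sample exclusion tallies auditable, and mirrors how amplicon editing
data are conventionally filtered.  Primer matching is exact by default;
since primers are part of the amplicon chemistry, a read without intact
primers is not trustworthy evidence about editing state.  Primers must end
(forward) and start (reverse) on a non-T base so the boundary between
primer footprint and the first scored U-run is unambiguous.

## Read classes and junction boundaries

Over the amplicon window, a read is `FULLY_EDITED` if its U counts equal
the canonical counts at every ES ("fully edited up to the forward primer"),
`PRE_EDITED` if they equal the pre-edited counts everywhere, and
`PARTIALLY_EDITED` otherwise.  Sites where the two references agree
constrain neither call; a read compatible with both is reported
`FULLY_EDITED`, reflecting that editing has nothing left to do in the
window.

For partially edited reads two boundaries are called:

* **JSS (junction start site)** — the first ES, moving 3' to 5' (ascending
  ES index), whose U count fails the canonical sequence;
* **JES (junction end site)** — the 5'-most ES with any editing action,
  i.e. a U count differing from pre-edited, canonical or not.

`jes == jss - 1` is a legal *empty junction*: canonical editing up to `jes`
abutting pre-edited sequence directly.  Such reads still contribute their
JES to pause profiles, because a clean stall after a block of correct
editing is exactly what a pause site produces.  On scaffolds containing
sites with identical pre-edited and canonical counts, `jes` can fall more
than one site below `jss`; those never-edited-at-site positions can be
neither a JSS nor a JES.  Both callers are verified exhaustively against an
independent brute-force scan over all 625 U-count vectors (entries 0-4) of
a 4-ES toy scaffold.

## Normalization and differential pause detection

Each sample's non-excluded reads are weighted by `100000 / n` so that
samples of different depth are comparable (`normalize_sample()`).
Normalized counts are kept as non-integer weights internally — conservation
(class counts, per-sequence counts, and the JES histogram of partial reads
each summing to their expected totals) holds exactly pre-rounding — and
reports round to one decimal only at write time.

An ES is an **exacerbated junction end site (EJES)** — operationally an
editing pause site — when (`detect_ejes()`):

* mean normalized JES count in the induced condition is at least
  `fold_min` (default 3) times the uninduced mean, and
* at least `min_replicates` (default 2) induced replicates each carry at
  least `min_norm_reads` (default 100) normalized JES counts at that ES.

The defaults mirror the filters conventionally applied to per-sequence
pause tables (3-fold, 100 reads, duplicate RNAi experiments); all three are
exposed because other datasets may warrant stricter replication.  Whether
the fold criterion should use per-replicate folds or the means of
replicates is genuinely open; the package uses means of replicates, the
more stable choice at duplicate depth, and reports per-replicate floors
separately through the `n_induced_ge_min` column.  When the uninduced mean
is zero, a pseudocount of one normalized read is added to both means; this
keeps fold changes finite and monotone while leaving well-covered sites
untouched (the pseudocount is *not* applied otherwise, so reported folds
are plain ratios).  No multiple-testing correction is applied across ES:
the EJES rule is a thresholded effect-size filter, not a hypothesis test,
and is conventionally reported as such.

Two windowed statistics summarise a pause region (inclusive ES bounds on
both ends): `percent_jes_in_window()` gives the percentage of a sample's
reads pausing inside the window, computed over all non-excluded reads
(whether to restrict to non-pre-edited reads is not settled; all-reads is
the default because pre-edited molecules are part of the population whose
fate is being measured), and `compare_conditions()` applies a two-sample
Student's t-test to per-replicate percentages (Student's rather than
Welch's by default, matching convention for duplicate amplicon designs;
Welch's by flag).  With zero pooled variance the statistic is undefined and
is reported as degenerate rather than silently patched.
`filter_window_sequences()` gives the per-sequence view: distinct U-count
vectors with a JES in the window, at least `min_reads` mean normalized
counts in the induced condition, and at least a `fold_min` induced/uninduced
ratio.

## The simulator: what it emulates and what it does not

`simulate_reads()` draws, per read: a class (defaults: 20% pre-edited, 10%
fully edited, 70% partial, reflecting the dominance of intermediates in
steady-state pan-edited populations); for partial reads a JES from a
categorical distribution over the window — per-ES `pause_weights`
multipliers let a condition-specific pause site be planted — and a
geometric junction length with mean 2 ES (junctions at the leading edge are
typically short; length 0 yields an empty junction).  Junction sites
receive U counts drawn uniformly from `0..max(pre, can)+2` excluding the
canonical value; the count at the JES also excludes the pre-edited value so
the drawn pause position is an actual editing action.  If an empty-junction
draw lands on a site where pre-edited and canonical counts coincide, the
junction is grown to length 1, since a JES there would be undefined.  The
per-read truth table records the realised class/JSS/JES (recomputed from
the drawn U vector by the same definitions the callers implement — the
sequence rendering and parsing, not the definitions, are what the
truth-consistency tests exercise) together with the drawn pause target.

Sequencing error is modelled as independent per-base substitution at
`error_rate` (default 0.001, typical of Illumina amplicon data) with two
deliberately distinct consequences.  A hit on a backbone or primer base
substitutes a random different base, which forces exclusion downstream —
any substitution at a non-T position breaks either the primer match or the
backbone identity, so the exclusion fraction has the closed form
`1 - (1-e)^(primer + backbone length)`, which the tests check within
binomial error.  A hit inside a U-run instead lengthens or shortens that
run by one: this is the realistic failure mode that fabricates spurious
non-canonical calls, and it is modelled (rather than excluded) precisely so
tests can distinguish reads whose observed editing state is corrupted from
reads that are removed.  For reads with at least one backbone/primer hit a
single substitution is placed (placement is uniform over those positions);
since any one hit already determines exclusion, multiple hits per read are
not materialised.  Constant Q30 qualities are written because the pipeline
ignores quality by default.  PCR bias, chimeras, indel errors and
quality-score realism are out of scope.

`simulate_experiment()` derives per-replicate seeds from a master seed, so
a fixed seed reproduces FASTQ, truth and sample-sheet files byte for byte.

## Numerical and design choices

* ES indices are 1-based, inclusive, 3'-anchored everywhere, including all
  output files; nucleotide coordinates are never exposed.
* Window bounds are inclusive on both ends ("between ES121-126" is read as
  [121, 126]).
* Ties in the EJES table are not broken: the full table with fold changes
  and pass flags is returned and written, and consumers rank as they see
  fit.
* Classification precedence: a read matching both references (possible
  only when `pre == can` across the whole window) is `FULLY_EDITED`.
* Degenerate inputs fail with classed conditions
  (`editpause_backbone_mismatch`, `editpause_empty_sample`, ...) so
  callers and the command-line wrapper can map them to distinct exit
  codes.
* All tabular outputs are TSV with frozen column order; reruns on
  identical inputs are byte-identical, which is itself under test.

## Validation scales

The test suite validates the analysis at desk scale, with all inputs
generated in code: exhaustive oracle agreement on the 625-vector toy;
exact reconstruct-align round trips for 10,000 random U vectors on random
scaffolds; conservation of normalized totals; recovery of a planted 5x
pause site (2+2 replicates of 20,000 reads, 100 seeded runs, top
fold-change EJES) against a label-swap null (100 seeds of identical
conditions, 2+2 replicates of 4,000 reads, zero passes); and closed-form
checks of the windowed statistics.  `scripts/acceptance.R` re-runs the full
simulate-to-report pipeline at the same scale from a command-line seed.

Passing these tests shows the machinery is exact and well calibrated on
populations the simulator can express.  It does not certify behaviour on
real libraries, whose error structure (indels, chimeras, PCR bias,
position-dependent quality) the simulator intentionally omits; on real
data those reads are excluded by the backbone rule rather than modelled,
and exclusion tallies should be inspected before interpreting profiles.
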