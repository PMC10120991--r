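---
title: "Methods: scoring CRISPR off-targets from ssDNA-enrichment reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring CRISPR off-targets from ssDNA-enrichment reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossseq)
```

## The measurement model

RNA-guided editors open an R-loop wherever they engage the genome,
displacing the non-target strand as single-stranded DNA. An
ssDNA-enrichment library therefore over-represents engaged loci, and the
mechanics of each editor leave a distinct mark in the aligned reads:

* **Nuclease (SpCas9).** A blunt double-strand break 3 bp 5′ of the PAM.
  Enriched fragments terminate at the break, so forward-strand reads
  *start* at the cut position and reverse-strand reads *end* one base
  before it. This read-terminus pile-up, on both strands, is the
  cleavage signature.
* **Base editors (CBE/ABE).** A nickase plus a deaminase acting on the
  displayed non-target strand within an editing window near the
  PAM-distal end of the protospacer. The signature is reads carrying the
  programmed conversion (C→T or A→G, as seen on the non-target strand)
  at window positions; the nick additionally produces a one-strand
  truncation pile-up.
* **Prime editors.** A nick on the non-target strand followed by
  templated synthesis. The signature is an alignment insertion whose
  reference placement is exactly the nick junction (the inserted base
  following the nick is counted as position +1) and whose bases equal
  the programmed insert.

The pipeline assumes its input reads are already aligned (coordinate
conventions are 0-based half-open throughout, with the cut falling
between `cut_pos - 1` and `cut_pos`), single-end, and primary
alignments; mapping is treated as an upstream commodity step.

## The CROSS score and its gates

At each position the caller computes `F` (forward starts), `R` (reverse
ends at the preceding base) and `D` (both-strand depth), and scores
`1e6 * (F + R) / total_mapped` — cleavage-signal reads per million
mapped reads. Normalizing by library size rather than local depth makes
scores comparable across positions and libraries of different sizes; the
local end fraction `f = (F + R) / D` is kept as a gate instead of the
headline statistic because depth at an enriched locus is itself
signal-dependent. Note `f` can exceed 1: reverse-strand cleavage
products end *before* the scored position and do not contribute to `D`
there.

Candidate gates, all exposed in `caller_params()`:

| parameter | default | role |
|---|---|---|
| `m` | 3 reads | minimum per-strand end count; bidirectional support is the blunt-cut fingerprint and suppresses one-sided artifacts (random shear, repeat edges) |
| `f_min` | 0.2 | minimum end fraction; separates focal cleavage from diffuse background, which at uniform coverage concentrates only ~1–2% of local reads on any one terminus position |
| `c_max` | 1 read | control end count above which the control is considered occupied |
| `ratio_min` | 5× | treated/control score ratio that rescues positions with incidental control ends; the two-pronged control test removes endogenous ssDNA loci, which enrich in both libraries |
| `merge_window` | 10 bp | candidates closer than this merge to the strongest position, absorbing repair/resection fuzziness seen in cellular data |
| `require_bidirectional` | TRUE | set to FALSE for nickase-style data where repair blurs one strand; the gate then becomes a combined count of `2m` |
| `r_min` | 0.01 | minimum editing ratio for BE/PE candidacy |
| `pe_tolerance` | 0 bp | placement slack for the +1 insertion |

The mapping-quality filter defaults to 20 and duplicates are *not*
collapsed by default — enrichment protocols legitimately yield identical
fragments; a `dedup` flag exists for PCR-heavy libraries.

The exact published form of this score and its cutoffs are not part of
the package's sources; the formula above is this package's own, declared
reconstruction of a depth-normalized cleavage-read count, and all
constants are configuration, not reproductions.

## Cut geometry

SpCas9 is modeled as a blunt cut between protospacer positions 17 and 18
(`cut_offset = -3` from the PAM-proximal end), the canonical geometry.
Protospacer positions are numbered with 1 at the PAM-distal end, the
convention used for editing windows (default window 4–8; the published
window for the editors emulated here is not printed in accessible
sources, so the default is a conservative, configurable choice).
Nick-strand assignments follow the enzymes: D10A (BE) nicks the target
strand, H840A (PE) nicks the non-target strand. Because the modeled cut
is a single duplex coordinate, the nick junction used for insertion
placement is orientation-independent, while the inserted bases are
orientation-resolved (a `-`-oriented site expects the reverse
complement on the forward strand).

## Guide alignment and consensus

`align_guide()` anchors on the cut geometry: the PAM must sit
`-cut_offset` bases 3′ of the cut in the orientation under test. It
enumerates the ungapped placement, all single-base DNA-bulge placements
(one extra target base skipped) and all single-base sgRNA-bulge
placements (one spacer base skipped), each requiring an IUPAC-valid PAM,
and returns the best alignment *within* the search limits
(`max_mm = 6`, `max_bulge = 1`) by lexicographic `(bulges, mismatches)`.
Penalizing bulges first reflects their status as exceptional events in
off-target tables; limits are applied before minimization so that a
clean bulged alignment is preferred over an over-budget ungapped one.
Ties prefer the most PAM-proximal bulge, then the `+` orientation. Sites
with no in-budget alignment are reported unmatched rather than dropped,
keeping guide-independent background visible. A candidate context
shorter than `spacer - 1` is an error; the annotation step fetches
`spacer + PAM + 2` bases on each side of the cut.

`consensus_matrix()` projects aligned targets onto spacer coordinates —
a DNA-bulged target drops its extra base; an sgRNA-bulge leaves a gap
that contributes nothing to that column — and reports raw per-column
frequencies with information content `2 − H` bits (no pseudocounts, no
background correction, no small-sample correction: a plain sequence-logo
presentation). The projection convention for bulged sites is this
package's own choice. `g_content()` counts guanines on the displaced
non-target strand, since the ssDNA probe chemistry is guanine-reactive:
a target region without a single G on that strand is flagged
unlabelable.

## What the simulator emulates — and what it does not

`sim_config()` describes a complete planted-signal experiment. Its
defaults are the package's study conditions: a 100-kb contig at GC 0.41
(human-like), one exact on-target plus five off-targets with 2–4 spacer
mismatches, one of them additionally carrying a single-base bulge,
100-nt single-end reads at 200× mean depth, a matched no-guide control,
and two shared coverage hotspots (5×, 1 kb) mimicking endogenous ssDNA
loci so that control subtraction does real work.

Cleavage is modeled on the molecules: a background fragment covering a
planted cut is itself cut with probability `cleavage_fraction`, and its
read terminus is re-anchored to the cut. At saturation every
cut-covering read terminates at the cut — the pattern seen in enriched
libraries — and the default `cleavage_fraction = 0.5` encodes the
observation that most reads at a true site end at the cut while keeping
uncleaved, window-spanning molecules available to carry base-editor
conversions. `background_end_rate` (default 0.01) is the per-read
probability of truncation at a random internal position, a minimal model
of random breaks in endogenous ssDNA. Conversions are planted per read
(a selected window-spanning read converts every editable window
position), insertions per read exactly at the nick junction; bulged
sites receive cleavage signal but no conversion signal, since their
window coordinates are not well defined under a gap.

Deliberately not modeled: sequencing errors and quality scores, PCR
duplicates, paired-end geometry, structured (non-uniform) background
beyond hotspots, chromatin accessibility, and indel repair outcomes.
Consequently, passing the bundled tests demonstrates the *computational*
correctness and calibration of the callers on clean signatures — exact
terminus bookkeeping, unbiased ratio estimation, correct strand/bulge
handling — but not robustness to error-prone base calls, mappability
artifacts, or biological background structure in real libraries. The
no-candidate result on guide-free simulations calibrates the gates
against stochastic pile-ups only.

## Numerical and degenerate-input choices

* Scores and fractions at zero depth or an empty library are 0 (not
  NaN); editing ratios with zero spanning reads are reported missing
  (`NA`), never 0, to distinguish "no evidence" from "evidence of
  absence".
* `cut_pos = 0` has no position for reverse ends; the score uses
  `R = 0` and the record is flagged `edge`.
* Candidate merging groups positions whose consecutive gaps exceed the
  merge window, keeping the smallest position on score ties.
* Ranks are dense (ties share a rank), ordered by descending score then
  (chrom, position).
* All simulator stages draw from seeded, stage-separated RNG streams;
  identical configurations reproduce FASTA/SAM/TSV outputs byte for
  byte, and the global RNG state of the session is left untouched.

## Problem sizes used by the test suite

The suite runs entirely on simulated data sized for a desktop: pileup
exactness is verified on ten 10-kb read sets (50–200×) against a naive
per-read recount; recovery and null calibration use ten seeds each of
the 100-kb study conditions; estimator calibration uses twenty seeds of
20-kb/200× libraries (~200 window-spanning reads per site, checked
within three binomial standard deviations); the alignment search is
checked against exhaustive enumeration on 500 random spacer/target
pairs with up to four substitutions and one bulge, plus
reverse-complement symmetry on every pair. These sizes were chosen so a
full run completes in about a minute while keeping every binomial check
comfortably powered.

## Known limitations

* The score reconstruction is property-calibrated, not a reproduction of
  any published site list; absolute score values depend on library size.
* gRNA-independent editing (e.g. Cas-independent deamination) is
  invisible by design: the control subtraction removes anything present
  without a guide.
* Bulge search is limited to a single base, and bulges within the three
  PAM-proximal positions are not distinguished from geometry shifts.
* The caller reports no statistical significance — there is no error
  model for enrichment background — so candidate lists should be
  validated orthogonally (e.g. targeted amplicon sequencing).
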