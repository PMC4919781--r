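---
title: "Comparing full-length and truncated sgRNAs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing full-length and truncated sgRNAs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(truncguide)
```

## The problem

Truncating an SpCas9 single guide RNA (sgRNA) from the canonical 20
matched nucleotides down to 17 ("tru-gRNA") is a popular way to reduce
off-target cleavage. Evaluating that trade-off in a reporter-knockout
experiment involves a chain of small computational steps — protospacer
enumeration, guide-pair design under the U6 5'-G transcription rule,
mismatch profiling of candidate off-target sites, indel calling from
Sanger-sequenced amplicon clones, T7 endonuclease I (T7E1)
quantification, and knockout-efficiency statistics. `truncguide`
implements that chain as tested, reusable functions, together with
simulators that generate each input with known ground truth.

## Guide design rules

An SpCas9 protospacer is the window immediately 5' of an NGG PAM;
`find_pam_sites()` enumerates PAMs on both strands (a minus-strand PAM
appears as CCN on the sense strand) and `design_guides()` emits one
candidate per designable PAM. Three empirical rules from
truncated-guide work are encoded on each candidate:

* **5' G.** U6-driven transcription needs a 5' guanine. Policy
  `require_matched_G` keeps only protospacers whose genomic 5' base is
  G; `prepend_g` instead prepends a mismatched lowercase `g` (stored
  lowercase to distinguish it from matched sequence; all comparisons
  are case-insensitive).
* **Minimum length.** Guides with fewer than 17 matched nucleotides are
  flagged ineffective (16-mers show only residual activity), and a
  g-tagged guide needs at least 18 nt in total — 17 matched plus the
  mismatched g. `effective_flag` encodes exactly this rule, and nothing
  else: it is a length rule, not an activity score.
* **3' G/A preference.** A G or A at the PAM-proximal end is associated
  with better activity; since it is a preference rather than a rule, it
  is reported as the sort-key annotation `three_prime_pref`, never used
  as a filter.

`truncate_guide()` shortens a guide from its PAM-distal end, so a
17 nt guide is always the PAM-proximal suffix of its 20 nt partner —
the property that makes matched-pair comparisons meaningful.
`build_cloning_oligos()` emits the Gibson-assembly synthesis template
(two fixed 30 nt arms around the spacer minus its leading G, which the
upstream arm's trailing `...ACACCG` supplies) and the fixed PCR primer
pair.

### Coordinates and site labels

Internally all coordinates are 0-based, half-open, on the sense strand;
`start` is the leftmost sense-strand base of the protospacer for either
strand, and minus-strand spacers are reported 5'→3' (reverse
complement of the sense window). Published site names such as "site 42"
do not come with a stated convention, so `site_label` is simply
`start + site_offset` with a default offset of 1 (1-based position of
the first matched base); the offset is a parameter for anyone whose
naming convention anchors elsewhere (cut site, PAM).

Sites whose protospacer window or PAM overlaps an ambiguous base (N)
are skipped with a warning rather than failing the run; a genomic N is
never allowed to satisfy any PAM position.

## Off-target mismatch windows

Candidate off-target sites are compared to the guide by **ungapped
Hamming distance** over two windows aligned at the PAM-proximal end:
the full spacer (`m20`) and the 17 PAM-proximal positions (`m17`).
`m17 <= m20` always holds, and the PAM itself (including its degenerate
first base, printed lowercase in site tables) is never counted. Bulged
(gapped) off-target alignment is deliberately out of scope: the
published site lists this package mirrors are presented ungapped.

`scan_genome()` enumerates every NGG-adjacent window on both strands
within a mismatch budget. The default budget is 5 for 20 nt guides and
4 for 17 nt guides — the extremes under which off-target activity has
been observed for each length. NAG PAMs can be included behind a flag
but are off by default. The scanner is exact (it is tested against an
exhaustive brute-force scan), so its only scale limitation is time;
desk-scale synthetic genomes are its intended use here.

The bundled `table1_sites.tsv` fixture transcribes a published
on/off-target site table: four on-target rows and 29 candidate
off-target rows, each with the full site + PAM, the PAM-proximal
17 nt site + PAM, and measured indel percentages (or ND, not detected)
for three cell lines under both guide lengths. Two transcription
caveats are preserved as-is and surfaced by tests rather than silently
"fixed": one row's printed 20-mer differs from its guide at four
positions by direct Hamming count although five are typographically
annotated (suggesting the original site search used a gapped
alignment), and two rows grouped with the 4-mismatch category by the
source text score 3.

## Indel calling

Clones are aligned to the reference amplicon with a global
Needleman–Wunsch aligner with affine gap costs (a gap of length *k*
costs `gap_open + k * gap_extend`), implemented in C++ for speed.
Defaults — match +2, mismatch −4, gap open −8, gap extend −1 — make a
contiguous gap cheaper than scattered mismatches, which suits NHEJ
alleles where a single deletion or insertion is the expected signal.
Among co-optimal alignments, gaps are placed at their **leftmost**
reference position (the traceback prefers aligned columns on score
ties), making event coordinates deterministic in repeats. `N` scores 0
against anything and never counts as a match. The aligner's scores are
verified against an independent plain-R dynamic program in the test
suite.

Event extraction and classification follow three conventions:

* **Cut site.** SpCas9 cuts bluntly 3 bp 5' of the PAM (between
  protospacer positions 17 and 18 of a 20-mer). `guide_cut_site()`
  encodes this standard geometry; it is a default, overridable wherever
  a cut coordinate is accepted.
* **Window.** Only events whose left edge lies within ±20 nt of the cut
  are called (`window` parameter). Sanger clones occasionally carry
  distal polymorphisms that are not nuclease-induced; windowing keeps
  them out of the profile while `n_distal_events` records their
  existence.
* **Frame.** A clone with no windowed events is `unedited`; otherwise
  the net inserted-minus-deleted length modulo 3 decides `in_frame`
  versus `frameshift`. The call depends only on the net length, never
  on event order or decomposition.

Clones aligning below 80% identity are flagged `unalignable` and
excluded from cohort profiles instead of being mis-called.
`summarize_cohort()` bins event lengths as 1 bp / 2–8 bp / ≥9 bp; the
published binning ("1, 2–8, >9") leaves 9 bp unassigned, and this
implementation assigns it to the upper bin. Because sources differ on
whether indel counts refer to events or clones, the profile reports
both (`n_events`, `n_edited`), and both the median and mean event
length, since published summaries are inconsistent about which of the
two they show.

## T7E1 quantification

Reannealed heteroduplexes carrying an indel are cleaved by T7E1; with
indel fraction *p*, a random duplex is cleavable with probability
`1 − (1 − p)²`, giving the standard conversion

> % indel = 100 × (1 − √(1 − f~c~)),

where `f_c = Σcut / (uncut + Σcut)` is the cleaved fraction of gel
signal. The function is strictly increasing with slope 50 at 0 and is
undefined at `f_c = 1`, so an uncut intensity of zero returns 1 with a
warning and the conversion rejects it. `invert_indel_percent()` is the
algebraic inverse used by the simulator; the round-trip is exact to
numerical precision (tested at 1e−9). The default "not detected"
threshold is 2% indel: no threshold is published, positive published
readouts start around 11%, and 2% is well above the conversion's noise
floor at typical gel densitometry error; a measurement exactly at the
threshold counts as detected. Simulated noisy measurements are clamped
to `f_c ≤ 0.999999` before conversion; real inputs of 1 or more raise
an error instead.

## Knockout statistics

Knockout efficiency is the raw GFP-negative percentage of cells — no
background subtraction, matching how such readouts are defined. Because
steric hindrance of reporter transcription can inflate the raw value by
a few percent, an optional corrected estimator
`(raw − bg) / (1 − bg)` is available behind the `background` argument
but is never the default. Group summaries are mean ± SEM (sample
standard deviation over √n; a singleton reports SEM 0 with
`sem_defined = FALSE`). Paired comparisons (same site, 17 nt vs 20 nt)
use the paired Student's t-test or the Wilcoxon signed-rank test with
the exact permutation null for n ≤ 25 pairs; zero-variance differences
return a flagged degenerate result rather than an unstable statistic.
One-way ANOVA is provided for more-than-two-group comparisons. Star
notation (\*0.05, \*\*0.01, \*\*\*0.001) is formatting only.

## Simulators and what passing tests mean

Every generator takes an explicit integer seed and isolates its
randomness with `withr::with_seed`, so identical seeds reproduce
outputs byte-for-byte and the caller's RNG state is untouched.

* `simulate_edited_reads()` emulates Sanger clone sets: each read is
  edited with probability `edit_rate`, drawing one event from an
  `indel_spectrum()`. The default spectrum is deletion-dominated (80%)
  with a geometric-like length distribution (mean ≈ 5 nt, support
  1–30 nt) — emulation parameters chosen to reproduce the *shape* of
  published NHEJ profiles, not measured values. Deletion left edges are
  placed within 10 nt of the cut so every event falls inside the
  default calling window; insertions sit at the cut. A
  `complex_allele_rate` (default 5%) adds a 1–5 nt junction insertion
  to a deletion; exact-recovery tests use single-event spectra because
  a deletion-plus-junction-insertion allele has no unique event
  decomposition under any aligner (only its net length is
  identifiable).
* `plant_offtarget_genome()` embeds NGG-adjacent sites with exactly the
  requested PAM-proximal mismatch counts, on random strands, in uniform
  (configurable-GC) background. The default recovery experiment plants
  the published category sizes {1 mm: 3, 2 mm: 9, 3 mm: 2, 4 mm: 5}.
* `simulate_facs()` draws GFP-negative counts from
  Binomial(n, ko + (1 − ko) · bg) with a 0.5% default background (a
  99.5% GFP-positive reporter clone).
* `simulate_t7e1()` inverts the indel formula and adds Gaussian noise
  on the cleaved fraction.

Clone reads are error-free apart from their indel (clone Sanger
consensus sequences effectively are); there is no sequencing-error or
PCR-chimera model, no microhomology structure in deletion placement,
and planted genomes have uniform base composition. Passing the
parameter-recovery suites therefore demonstrates that the *callers and
scanners are correct and unbiased on inputs matching their assumptions*
— not that those assumptions hold for any particular real dataset.

## Problem sizes and numerical choices

The shipped tests run the aligner oracle on sequences up to 60 nt,
exact-recovery on 500 simulated clones against a 200 nt amplicon,
scanner-vs-brute-force on multi-kilobase genomes, planted-site recovery
on a 20 kb genome with 19 sites, and the FACS mixture-mean check over
200 seeds at 10⁴ cells — sizes at which every property is decisive yet
the whole suite runs in well under a minute. The scanner and aligner
have no size-specific logic, so conclusions transfer to larger inputs
at linear (scanner) or quadratic (aligner) cost.

Ties and degenerate inputs are resolved deterministically throughout:
leftmost gap placement, detection at the ND boundary counts as
detected, `p = threshold` stars at the lower bound, empty cohorts and
all-zero gel lanes raise errors rather than returning NaN.

## Known limitations

* Ungapped off-target comparison only; RNA/DNA-bulge sites are invisible.
* No on-target activity score beyond the length/5'-G rules.
* The indel caller assumes one amplicon per clone (no bulk-trace
  deconvolution) and does not call HDR or substitution alleles.
* The effectiveness flag is binary by design; real knockout efficiency
  varies continuously with site and cell type, and nothing here models
  cell-type differences such as nuclease expression levels.
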