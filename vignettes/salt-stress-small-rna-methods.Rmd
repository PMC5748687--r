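---
title: "Methods: small RNA, degradome and tasiRNA analysis for plant salt-stress libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA, degradome and tasiRNA analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saltSRNA)
```

# Scope

`saltSRNA` implements the computational core of a two-condition plant small
RNA-seq study: cleaning and collapsing sequencer reads into tag libraries,
separating structural RNA from miRNA candidates, discovering novel miRNAs by
hairpin evidence, testing differential expression between single libraries,
detecting Dicer-signature siRNA duplexes on repeat elements, validating miRNA
targets with degradome (PARE) data, and resolving the miR390/TAS3 two-hit
tasiRNA pathway. Every stage can run on synthetic data with planted ground
truth, so the whole pipeline is testable offline.

# Preprocessing model

Raw small-RNA reads are insert + 3' adapter (+ downstream filler). The
trimmer reports the insert before the left-most adapter match, where a match
requires at least 6 nt of the adapter prefix with at most one substitution.
This mirrors standard small-RNA trimmers while staying fully deterministic; a
tolerance of one substitution accommodates typical sequencer error without
inviting spurious matches (a 6-nt exact seed with one mismatch allowed across
a 21-nt adapter is a 20-of-21 match at early offsets). Reads whose adapter
starts at position one are adapter dimers. The quality rule drops reads with
any `N` or more than 10% of bases below Q20 (Phred+33); the insert window is
15-30 nt inclusive.

Annotation uses exact substring matching against per-class references with a
fixed priority (rRNA, tRNA, snRNA, snoRNA, then known-miRNA and repeat
classes, then polyA), so each tag gets exactly one class. The polyA rule
declares a tag polyA when its 3'-terminal A-run covers at least 80% of its
length. Degradome tags additionally apply the polyN rule: any single base
strictly over 70% of positions discards the tag.

# Novel miRNA discovery

A candidate is an unannotated tag of 18-25 nt with a pooled count above one
that maps exactly to a transcript. Candidate precursors are excised by
extending the tag by {20, 60, 100, 150} nt on each side (all 16
combinations, clipped to the transcript and to the 50-400 nt folding
window). Windows lacking any region antisense-pairable with the mature core
at all but at most five positions cannot contain a qualifying miRNA* and are
skipped before folding — a pure pre-filter implied by the mismatch rule, not
an extra threshold.

Folding is a pluggable contract. The default backend shells out to RNAfold
(ViennaRNA) in one batched call; a base-pair-maximisation fallback with a
simplified stacking energy (−3 kcal/mol G:C, −2 A:U, −1 G:U) keeps the
package self-contained when the binary is absent. The backend identity is
recorded in every result.

Duplex evaluation works on the MFE pairing table:

* The expected miRNA* is located through the helix register. In an
  antiparallel duplex `i + partner(i)` is constant; the median over the
  mature's paired positions is robust to bulges and terminal breathing, and
  the star 3' end is that register minus the mature start plus the canonical
  2-nt offset.
* Duplex mismatches are the mature positions (excluding its own 2-nt 3'
  overhang) unpaired in the fold; G:U wobbles pair and do not count; the rule
  is strictly fewer than six.
* The mature must not overlap the terminal loop between the arms. The
  mature's 2-nt 3' overhang may touch the loop boundary — that is canonical
  geometry, not loop overlap.
* Overhang geometry fails only when two or more overhang positions pair into
  the opposite strand (a blunt duplex); a single terminal pairing is
  tolerated because MFE folds routinely close one extra breathing pair at a
  helix end.
* The computed miRNA* sequence must be present in the sequencing tags.

Among passing windows the lowest-MFE one is kept. Because the duplex rules
are symmetric in mature and star, two calls on the same transcript with
overlapping precursor windows and disjoint matures are one duplex; the more
abundant strand is reported as the mature. Repeat-annotated tags (both
element strands) are excluded from prediction, which removes
repeat-derived inverted-repeat artifacts exactly as the annotation-priority
cascade intends.

Precursor statistics follow the standard definitions: AMFE = (−ΔG/L)×100 and
MFEI = AMFE / (G+C%), reported half-up at two decimals. No MFEI cutoff is
enforced; the index is reported so precursors can be compared against
tRNA/rRNA baselines (~0.6). The bundled 24-row reference table is used as a
regression fixture; two of its rows print an MFEI inconsistent with their own
printed ΔG, length and G+C% and are flagged (`mfei_consistent = FALSE`)
rather than silently corrected.

Conserved matching is end-to-end with at most two substitutions and a length
difference of up to 2 nt at the termini, eligibility being tags shorter than
24 nt with more than one copy; ties break by fewest mismatches then
lexicographic family name.

# Differential expression

Counts are normalised to tags per million clean reads (TPM). The
significance test is the Audic–Claverie conditional test, the standard exact
test for two-library digital expression: conditional on `x`, the second
count is negative binomial with size `x + 1` and probability
`n1/(n1 + n2)`, and the two-sided p-value doubles the smaller tail (capped
at one). Conditioning on one library makes the classic test asymmetric in
the pair of counts, which is undesirable for a two-library comparison with
no privileged direction; the reported p-value is therefore the smaller of
the two conditioning orientations, which restores exact symmetry while
keeping the simulated null type-I error near 0.01 at the nominal 1% level
(the discrete test remains slightly conservative). It is evaluated through
`pnbinom()`, stable to counts of 10^7, and sits behind an interface so a
binomial alternative can be swapped. No
multiple-testing correction is applied, matching the raw `p < 0.01`,
`|log2 ratio| > 1` (strict) decision rule; features observed in only one
library with at least two reads are reported as library-specific rather than
given a pseudo-count ratio, and the two-read floor suppresses singleton
artifacts. Both-zero features are dropped. The `2^-ddCt` helper converts
qRT-PCR Ct differences to relative expression.

# siRNA duplexes

The Dicer signature is a perfectly complementary core with exactly a 2-nt
3' overhang on each strand. Under ungapped complementarity this forces equal
strand lengths, so the finder indexes tags by core sequence and pairs tag
`b` with tag `a` whenever `core(a) = revcomp(core(b))`; the quadratic
all-pairs oracle is the correctness reference in tests. Duplexes map to a
repeat element only when both strands match it perfectly on opposite
strands; coverage accumulates over matched spans, and the length histogram
uses the longer strand.

# Degradome analysis

Degradome tags (20-21 nt) are mapped sense-only and exactly; a multi-mapping
tag contributes its full count to every matched transcript (no fractional
weighting — the simplest defensible rule). Alignment scoring counts non-G:U
mispairs as 1, G:U as 0.5, and gap positions as 1, minimised over ungapped
or single-gap antisense alignments (length difference up to 2). The cleavage
site is the transcript position pairing miRNA nucleotide 10, i.e. alignment
end − 9. The default score threshold is 4.5: reported target tables in this
literature include 4.5-scoring sites even when prose states "fewer than 4",
so the permissive value is the default and the threshold is configurable.
Events require degradome abundance of at least one read at the predicted
site; cleavages guided by different miRNAs are distinct events.

Categories follow the standard five-category convention relative to the
transcript's profile: 0 = unique maximum (> 1 read); 1 = shared maximum
(> 1 read); 2 = above the median of non-zero positions; 3 = at or below the
median (> 1 read); 4 = exactly one read. T-plot tables expose the raw
per-position abundances with the site marked; rendering is left to
`plot_tplot()` or external tools.

# tasiRNA phasing

Trigger sites are scored with the same aligner. A two-hit locus is the
closest compliant pair of non-overlapping sites on one transcript
(overlaps resolved by discarding the higher-scoring site, ties keeping the
5'-most); spacing counts nucleotides strictly between the spans and
`phase_count = round(spacing/21)` — the only rule consistent with both
published examples (174 nt → 8 phases, 261 nt → 12), whose spacings are not
exact multiples of 21. The phase register anchors by default at the
3'-proximal site's predicted cleavage position, counting 21-nt windows
toward the 5' site (the canonical two-hit model in which the 3' site is
cleaved); a 5'-anchored register is a configuration switch because which
site is cleaved is an empirical question. Windows report (+)-strand
sequences with exact-match tag abundances, zero-supported windows included,
and truncated windows flagged. tasiRNA targets require one or two antisense
sites at score ≤ 2.0; "fewer than 2 mismatches" is implemented as score
≤ 2.0 with G:U = 0.5 — a strict reading would exclude exactly 2.0, but the
inclusive default favours recall, with degradome confirmation downstream.
Expression anti-correlation uses Pearson r over condition series
(length ≥ 3), classed negative below −0.5 and positive above 0.5.

# Synthetic data generator

The generator emulates the statistical structure the analysis assumes; its
defaults are the package's study conditions:

* three libraries (control plus two treatment time points), 50,000 reads
  each, drawn multinomially so totals are exact;
* tag abundance is log-normal (miRNAs `meanlog = log(150)`, `sdlog = 1`),
  reproducing the heavy skew of real libraries where counts span single
  digits to millions;
* background read lengths mix a 21-nt mode (weight 0.55) and a 24-nt mode
  (weight 0.30), the two canonical plant small-RNA classes;
* 30 planted hairpins (mature + 15-nt loop + near-revcomp star with 2-nt 3'
  overhang geometry and up to two planted duplex mismatches), embedded in
  host transcripts among 120 background transcripts;
* differential expression on 30% of miRNAs at |log2 fc| = 2, with up/down
  directions assigned mass-balanced (greedy) so the treatment library's
  total expected mass matches the control's and realized TPM ratios centre
  on the planted effect instead of absorbing a compositional shift;
* miRNA* tags at 10% of their mature's abundance;
* three repeat elements, each in two transcript copies, with 25 planted
  duplex pairs per element, 24-nt biased (weight 0.6);
* two TAS3-like loci with two perfect antisense trigger sites spaced an
  integer number of phases (8-12) apart and planted D7/D8 content, the 3'
  site degradome-cleaved;
* ten planted miRNA target sites (half with one G:U wobble) whose cleavage
  positions dominate (~85% expected mass) their transcript's degradome tags;
* substitution errors at 0.5% per base, reassigning whole reads to mutated
  tags (indels are not modelled at tag scale);
* each stage and library draws from its own RNG stream derived from the
  master seed, so adding a library does not perturb earlier ones.

What the generator does **not** emulate: real genome sequence and its k-mer
composition, ligation and PCR bias, multi-locus miRNA families, isomiR
heterogeneity, or degradome background structure. Passing the planted
recovery benchmarks therefore demonstrates correctness of the detectors'
logic under the stated statistical assumptions, not performance on real
tissue libraries.

# Numerical choices and degenerate inputs

* Table rounding is half-up at 2 dp, matching how such tables are printed;
  internal values stay unrounded.
* Empty libraries are valid but flagged unusable for normalisation; a
  constant series makes correlation an error rather than NA.
* Folding rejects windows outside 50-400 nt or with more than 10% `N`.
* Output tables are deterministically ordered (count descending then
  lexicographic for tags; name/position orders elsewhere) since downstream
  diffing relies on byte-identical reruns.
* Problem sizes in the shipped tests (120 transcripts, 50,000 reads per
  library, 10,000-feature null simulations) were chosen as the smallest
  sizes at which the planted-recovery statistics are stable.

# Known limitations

* Novel-miRNA discovery is transcript-based; genome-based precursor
  discovery (and genome mapping generally) is out of scope.
* One library per condition: no replicates, hence no dispersion estimation —
  the exact test's assumptions are those of digital tag counting.
* The two printed reference rows with inconsistent MFEI are flagged, not
  resolved; their underlying precursor records cannot be reconstructed from
  the printed statistics alone.
* Cleavage-site arithmetic assumes the end − 9 convention; published tables
  contain a minority of rows following a different (undocumented)
  convention for 22-nt queries, which this package does not attempt to fit.
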