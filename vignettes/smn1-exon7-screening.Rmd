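---
title: "Calling homozygous SMN1 exon 7 deletions from targeted sequencing reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling homozygous SMN1 exon 7 deletions from targeted sequencing reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smascreen)
```

## The screening problem

Spinal muscular atrophy (SMA) is an autosomal recessive motor-neuron disease
caused in the large majority of cases by homozygous loss of *SMN1* exon 7.
Its paralog *SMN2* is nearly identical in sequence, so short reads from the
locus co-map to both genes and naive depth or variant calling cannot tell
them apart. The screen implemented here resolves the paralogs at a handful of
**paralog-specific variant (PSV) positions** — bases that differ between
*SMN1* and *SMN2* in otherwise identical sequence — and asks one qualitative
question per newborn sample: *is SMN1 exon 7 absent on both alleles?*
Carriers (one *SMN1* copy) are deliberately screen negative; the assay is a
screen for the disease genotype, not a carrier test.

## The model

All reads over the SMN capture region are taken in SMN1-anchored coordinates,
i.e. we assume the upstream aligner co-maps *SMN2*-derived reads onto the
*SMN1* reference. Three consequences drive the design:

1. **Mapping position does not discriminate the paralogs; PSV bases do.**
   Each read's base at each covered PSV site is compared with the configured
   *SMN1* and *SMN2* alleles (after a Phred >= 20 base-quality gate; `N`
   bases are dropped).
2. **MAPQ is never used to filter SMN-region reads.** Multi-mapping makes
   MAPQ ~ 0 *expected* at this locus; filtering on it would remove exactly
   the evidence the method needs.
3. **Ungapped offset arithmetic** maps a genomic position to a read offset.
   Reads whose CIGAR carries indels or clipping over a PSV are skipped with a
   warning rather than mis-read; at this locus the screened variant is a
   whole-exon deletion, not a small indel, so the loss is negligible.

Per-read classification is a **majority vote** across the covered PSV sites:
`SMN1` when more sites match the *SMN1* allele, `SMN2` for the converse,
`AMBIGUOUS` on a tie (ties never contribute *SMN1* evidence — the
conservative direction for a deletion screen), and `UNINFORMATIVE` when no
usable observation remains. The per-site pileup counts
(`smn1_count`, `smn2_count`, `other_count`) feed the score; the per-read
classes are exposed for reporting and inspection.

### The coverage score

For PSV site $i$ the per-site score is

$$s_i = \frac{c_i}{\bar d_{\mathrm{ctrl}} / 2},$$

where $c_i$ is the quality-passing *SMN1*-supporting depth at site $i$ and
$\bar d_{\mathrm{ctrl}}$ the sample's mean depth over the control-gene
intervals. Control genes are diploid, so half their depth is one
copy-equivalent; $s_i$ estimates the *SMN1* copy number directly. The
sample's **coverage score** is the mean of the per-site scores: ~0 for a
homozygous exon 7 deletion, ~1 for a carrier, ~2 for two intact copies.
A sample is called `POSITIVE` when the score falls below the deletion
cutoff, `NEGATIVE` otherwise.

Normalising by control genes (rather than by total SMN1+SMN2 depth) was a
genuinely open choice; we chose the control-gene denominator because it keeps
the score interpretable in copy-equivalents regardless of the sample's
*SMN2* copy number, and we expose the per-site scores so an alternative
normalisation can be layered on without touching the pileup.

### Thresholds

| parameter | default | units | rationale |
|---|---|---|---|
| `min_control_depth` | 20 | fold-coverage | samples below 20X mean control depth fail QC; boundary is *strictly below*, so exactly 20.0X passes |
| `min_uniformity` | 0.95 | fraction | fraction of control bases at >= 0.2 x mean depth; guards against ragged capture |
| `min_base_quality` | 20 | Phred | standard pileup hygiene on PSV observations |
| `deletion_score_cutoff` | 0.5 | copy-equivalents | midpoint between 0 and 1 copy: maximal margin against both error-driven false *SMN1* support (pushing a deletion up) and depth noise (pushing a carrier down) |
| `min_psv_total_depth` | 20 | reads | refuses to call a deletion from sheer dropout at the PSV sites, symmetric with the control-gene rule |

The numeric value of the deletion cutoff is a design decision of this
package: the assay it models draws the same line on a score scatter without
printing the number, and 0.5 is the maximal-margin choice for a score in
copy-equivalents. It is configurable in the locus YAML.

QC precedence is absolute: a failed sample is reported `FAIL` with a reason
naming the first failing rule and never receives a POSITIVE/NEGATIVE call.
An optional `library_failed` flag carries the wet-lab "insufficient
pre-capture library" failure mode; no concentration model is attempted.

## The simulator

`simulate_sample()` emulates the *post-alignment* view of a capture library,
which is the input boundary of the screen — no FASTQ, no aligner:

* Two templates over the SMN capture region, identical except at the PSV
  positions, carry the *SMN1* and *SMN2* alleles; a sample with
  `smn1_copies = a, smn2_copies = b` draws reads from them in proportion
  `a : b`. Control intervals are sequenced from their own templates at
  diploid depth.
* Fragment count is Poisson with mean
  `copies x haploid_depth x (region_len + fragment_mean - 1) / (2 x read_length)`,
  fragment starts uniform over every position overlapping the interval and
  fragment lengths normal (300 +/- 30, truncated). This makes interior
  per-base depth exactly `copies x haploid_depth` in expectation, with flat
  coverage across interval edges (fragments overhang the target, as captured
  libraries do).
* Reads are 2 x 150 bp pairs by default; each base is substituted to a
  uniformly chosen different base with probability `error_rate` (default
  0.001). Base qualities are constant Q30; errors are *silent* (they keep
  Q30), so the quality gate is exercised separately via
  `low_qual_fraction`, which injects Q10 bases.
* SMN-region reads get MAPQ 0 and control reads MAPQ 60, mirroring paralog
  co-mapping; read ids are prefixed with the template of origin so tests can
  check per-read classification against ground truth.
* Everything is deterministic given the seed; `simulate_cohort()` uses
  `base_seed + sample_index` per sample.

The default `haploid_depth = 50` puts diploid control genes at ~100X — the
same order as the assay the simulator emulates, and comfortably clear of the
20X failure line, which is why the simulated failure rate is 0%.

**What the simulator does not model:** capture efficiency and GC bias,
indels, duplicate reads, gene-conversion/hybrid *SMN1–SMN2* alleles, and
real base-quality profiles. Passing the simulation experiments therefore
demonstrates the *bioinformatic* correctness of paralog assignment, scoring
and QC under a clean coverage model — not robustness to every artefact of
real dried-blood-spot libraries.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive (SAM/VCF convention) throughout.
* Tie-breaks: equal PSV support is `AMBIGUOUS`, never assigned; a read with
  only third-allele bases is likewise ambiguous.
* A sample with zero control depth fails QC before the score (whose
  denominator would be undefined) can be computed; computing the score on
  such a sample is an error, not a silent zero.
* Sensitivity is undefined (reported `NA`, not 0) when the truth contains no
  positives, and symmetrically for specificity.
* Unreadable or malformed SAM input fails that sample (`unreadable input`)
  without aborting the batch.

## Experiment sizes

The validation experiments shipped with the package are sized for a desktop:
a blinded panel of 12 homozygous-deletion positives plus 4 negatives run
through the full SAM batch pipeline, a 2,552-sample population cohort for
specificity, parameter recovery over 100 seeds per genotype, and
deletion-versus-carrier score separation over 1,000 seeds per genotype, all
at haploid depth 50 and error rate 0.001. These sizes were chosen to match
the cohort sizes of the validation design the package reproduces while
keeping the whole suite runnable in minutes on one CPU.

## A worked example

```{r example}
cfg <- default_locus_config()
cfg

params <- simulation_params(haploid_depth = 50, error_rate = 0.001)
sim <- simulate_sample(list(sample_id = "NB01", smn1_copies = 0,
                            smn2_copies = 2), params, cfg, seed = 11)
screen_sample(sim$reads, cfg, sample_id = "NB01")
```

A deletion sample scores essentially zero and is called `POSITIVE`; rerunning
with `smn1_copies = 1` gives a score near 1 and a `NEGATIVE` call.

## Known limitations

* The three packaged PSV base pairs are only partially documented in public
  annotation (the exon 7 c.840C>T site is canonical; the other two are
  placeholders) — a deployment must set the panel's validated alleles in the
  locus YAML.
* *SMN2* copy number is not reported, carriers are not detected, and SNVs in
  *SMN1* are invisible to the screen by design.
* Hybrid *SMN1/SMN2* gene structures violate the two-template model and are
  expected to be resolved downstream by an orthogonal assay (e.g. MLPA).
* Screen calls are machine calls; clinical review and confirmatory testing
  sit outside the package.
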