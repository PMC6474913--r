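---
title: "Mapping regional CpG methylation from ancient-DNA damage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping regional CpG methylation from ancient-DNA damage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleometh)
```

## The problem

Ancient DNA accumulates post-mortem hydrolytic deamination of cytosine.
Unmethylated C deaminates to uracil, read as T; 5-methyl-C deaminates
directly to thymine, and does so *faster*. In sequencing data from an
ancient specimen this leaves an excess of apparent C→T substitutions at
CpG dinucleotides that were methylated in the living tissue — a natural,
bisulphite-free methylation assay, provided one can separate that signal
from sequencing errors, mapping errors, true sequence variants, and
deamination of *unmethylated* cytosines.

paleometh estimates regional methylation in two steps, both by maximum
likelihood on the raw read data rather than on mismatch counts.

## Step 1: position-specific deamination rates

Deamination is concentrated in the single-stranded overhangs near fragment
ends, so rates are modelled per read position `k` (distance from the
nearer terminus, 0-based) and terminus `v` (5′/3′), separately for
methylated and unmethylated cytosines: a matrix `D[M, k, v]` with a
configurable depth `K_max` (default 20 positions; damage has plateaued in
the fragment interior, and deeper positions are clamped to the last
modelled one).

The likelihood multiplies per-observation probabilities over all read
bases covering a reference cytosine (canonicalised to C-strand space:
reference-C positions observed by forward-strand reads, reference-G
positions by reverse-strand reads with bases complemented), using equal
numbers of CpG-context and non-CpG-context observations. A non-CpG
cytosine deaminates at the unmethylated rate. A CpG cytosine has unknown
methylation state, so its effective rate is the mixture
`F_global * D[1,k,v] + (1 - F_global) * D[0,k,v]`, where `F_global` is the
assumed genome-wide methylated fraction (default 0.75, the typical
mammalian somatic value — in mammals 70–80% of CpGs are methylated). This
single assumed constant is what makes the two rates separately
identifiable. Each observation also carries a sequencing-error
probability `eps` from its Phred base quality (misread to each other base
with `eps/3`) and a mapping-error probability `Q` from MAPQ (a mismapped
read emits bases uniformly); `Q` is capped at 0.99 so no read is treated
as certainly mismapped.

Because each observation touches exactly one `(k, v)` bin, the likelihood
factorises and each bin is a two-parameter problem, maximised with
box-constrained quasi-Newton (L-BFGS-B, start `(0.01, 0.1)`, bounds
`[1e-8, 1 - 1e-8]`, relative tolerance ~1e-8). Identical observations are
aggregated into counts first, so runtime is independent of coverage.
Standard errors come from the observed Fisher information by central
finite differences (`h = 1e-5`); boundary MLEs get `NA`. An optional
guard drops cytosine sites where more than 20% of observations are
neither C nor T — likely A/G polymorphisms, which step 1 does not model.

## Step 2: the methylated fraction f in a window

For a window of CpG sites (50 consecutive CpGs by default, or user BED
regions), the likelihood of `f` — the fraction of methylated CpG copies,
equivalently of methylated cells — multiplies site terms. Each site term
marginalises over an unobserved diploid dinucleotide genotype

`L(f) = prod_sites sum_g p(G = g) * prod_reads p(X | g, f, D)`

with seven genotype states: the unordered diploid pairs over alleles
{CG, TG, CA} plus an aggregate OTHER state. TG and CA are exactly the
alleles confoundable with strand-specific deamination (a TG allele mimics
a fully deaminated forward-strand C; its reverse-strand reading CA mimics
the reverse signal), which is why true variants inflate naive mismatch
statistics. The prior draws two alleles independently (CG: `1 - 3*theta`,
each alternative: `theta`, default `theta = 0.001`); genotypes containing
any other allele collapse into OTHER, which emits uniformly.

Per read, with probability `Q` the read is mismapped (uniform emission);
otherwise it samples one of the two allele copies. A CG copy is
methylated with probability `f` — one independent Bernoulli per read,
since distinct reads are distinct molecules from distinct cells — and its
strand-deaminable cytosine (position 1 for forward reads, position 2 for
reverse reads, bases being the sequenced strand's bases at the two
reference positions) converts C→T at the methylated or unmethylated rate
for its `(k, v)`. A CA copy's cytosine is a non-CpG cytosine (unmethylated
rate); a TG copy has no deaminable position. Bases missing from a read
(not covered, below the base-quality threshold, or N) are marginalised.

Because each read carries at most one Bernoulli(`f`) draw, every
per-read probability is affine in `f`; the implementation precomputes the
two coefficients per read and genotype once per window, making the
likelihood cheap to evaluate anywhere in `[0, 1]`.

**Optimisation and CI.** `f` is maximised by a dense 101-point grid
followed by bounded scalar refinement (tolerance 1e-6); the grid pass
guards against multimodality, and a property test checks agreement with a
10,001-point grid. The 95% confidence interval is the profile-likelihood
set `{f : 2(l(f_hat) - l(f)) <= 3.841}` (the 0.95 quantile of chi-squared
with 1 df), found by bisection on each side and clipped to `[0, 1]`.
Windows with no observations return `NA` flagged `no_data`; windows whose
likelihood is numerically flat (e.g. all reads effectively mismapped)
return `NA` flagged `flat_likelihood`. A trailing partial window is
emitted only if it holds at least `max(5, n_cpg/5)` sites, and is flagged
`partial`.

## Filters and conventions

Reads below the mapping-quality or fragment-length thresholds and
secondary/supplementary/duplicate/unmapped alignments are skipped; bases
below the base-quality threshold are skipped (step 1) or treated as
missing (step 2); N bases in read or reference are ignored. Defaults
(base quality ≥ 13, MAPQ ≥ 25, length ≥ 30 bp) follow common ancient-DNA
practice and are user-overridable. Fragment length is the read query
length, appropriate for adapter-trimmed, merged ancient-DNA reads.
Low-mappability regions can be masked (BED) and individual sites excluded
(2-column TSV) before estimation. Terminal distance ties (exact fragment
midpoint) are assigned to the 5′ terminus. All output coordinates are
0-based half-open; estimation is per chromosome, and chromosomes can be
processed in parallel by the caller.

## The simulator

The simulator provides ground truth for end-to-end validation. It draws
DNA fragments from `n_genomes` (default 100) diploid genomes representing
cells of one individual: one shared diploid genotype, with each CpG
flagged methylated per genome with probability equal to the site's map
level (one Bernoulli per genome per site, symmetric across strands and
haplotype copies — granularity the data cannot resolve further, fixed
here as a design choice). Optional true variants replace the CG on one or
both haplotypes (het:hom odds 2:1 by default) with TG or CA at equal
odds. Fragments have truncated-lognormal lengths (default
`meanlog = log(70)`, `sdlog = 0.25`, truncated to 30–150 bp, typical of
ancient libraries), uniform genome/haplotype/strand/start, and are drawn
until the target coverage is met. On the sequenced strand every cytosine
deaminates at the methylated rate if it belongs to a CpG flagged
methylated in the fragment's genome and the unmethylated rate otherwise;
uniform sequencing errors are added at the configured Phred quality
(default 30), and reads are emitted as a coordinate-sorted indexed BAM at
their *true* positions (MAPQ 37), which keeps tests hermetic — no
aligner in the loop. FASTQ output with adapter read-through is available
for users who want a real mapping step. Double- versus single-stranded
library chemistry is expressed purely through the supplied rate matrices:
a 5′-only C→T profile reproduces the familiar 3′ G→A signal of
double-stranded libraries automatically, because reverse-strand fragments
are sampled uniformly.

Three built-in decay-shaped profiles (`ds_high`, `ds_mid`, `ss_low`)
span high/medium/low damage and both library chemistries, with the
methylated rate always above the unmethylated one.

**What the simulator does not emulate:** microbial contamination,
nick-ligation chemistry, polymerase-specific error spectra, realistic
per-cycle quality strings, indels, or mapping bias. Passing recovery
tests therefore demonstrates correctness of the estimator under its own
generative assumptions — not robustness to every artefact of real data.

## Validation design and problem sizes

The test suite validates, at sizes chosen to keep a full run to a few
minutes on one core:

* the window likelihood against exhaustive latent-state enumeration on
  hundreds of small random piles (agreement to 1e-10);
* step-1 recovery on a 1 Mb synthetic chromosome at 5× for all three
  presets (mean absolute error at positions k ≤ 10 well under 0.02);
* step-2 recovery in 50-CpG windows at 5–40× and true f in
  {0.1, 0.5, 0.9}: RMSD non-increasing in coverage, small pooled bias at
  40× — accuracy increases with depth, and confident single-window
  estimates need the higher coverages;
* empirical coverage of the 95% CI at 20× (≥ 0.90 required; observed
  ~0.95–0.99, i.e. slightly conservative);
* robustness to heterozygous CG→TG/CA variants at 10% of CpGs: with the
  genotype prior the bias is essentially unchanged, while a
  variant-blind run (`theta = 0`) on the same data is biased upwards by
  an order of magnitude more;
* the closed-form limit `f_hat = (T fraction)/d` when only methylated
  cytosines can deaminate and errors are off;
* the emitted damage spectrum against the configured matrices (binomial
  z-screen per position/terminus/methylation bin).

`scripts/acceptance.R` re-runs this whole design from scratch at a given
seed and writes the resulting numbers as JSON.

## Known limitations

* Step 1 marginalises methylation per observation with the constant
  `F_global`; a mis-specified `F_global` tilts the estimated methylated
  rate and propagates into step 2's scale.
* Symmetric CpG methylation only; asymmetric plant-style contexts are out
  of scope.
* One pooled deamination profile per sample (no per-read-group
  profiles); samples mixing libraries with very different damage should
  be split upstream.
* Single-window estimates below ~20× have wide intervals; the likelihood
  is honest about this (the CI reflects it), but users should prefer
  larger windows or higher depth, and the boundary clipping of `f` into
  `[0, 1]` induces a small inward bias at extreme methylation levels and
  low depth.
* The genotype prior treats sites independently with a constant `theta`;
  linked variation and indels are not modelled.
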