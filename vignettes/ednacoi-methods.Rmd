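---
title: "Methods: a simulation-backed COI eDNA metabarcoding pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a simulation-backed COI eDNA metabarcoding pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`ednacoi` re-implements a coastal eDNA metabarcoding workflow for metazoan
biodiversity surveys built on two mitochondrial COI amplicons (a 313 nt
insert, `COI1`, and a 325 nt insert, `COI2`): paired-read quality trimming,
overlap merging, degenerate-primer demultiplexing, curation of a BOLD-style
barcode reference, species assignment at a 97% identity threshold with
multiple-hit handling, OTU-based profiling of reference completeness, an
in-silico audit of primer coverage over species checklists, and the
community statistics used downstream (Hellinger transformation, PCoA,
PERMANOVA, SIMPER, Shannon diversity, rarefied accumulation curves, Chao
abundance-based similarity, and blocked group comparisons).

Raw survey data of this kind live in sequence archives and change with
every reference-database snapshot, so the package is built and validated
against a synthetic amplicon generator with complete per-read ground truth.
Every stage is exercised end to end on reads whose true species, marker and
error count are known.

# The synthetic survey

## Species pool and barcodes

`make_species_pool()` draws a pool of mock species (defaults: 897 native
taxa, 130 potential invaders, a handful of terrestrial decoys) across ten
metazoan phyla. Each species carries a 640 nt COI-like barcode with a fixed
layout: a 5' flank, the COI2 forward site, the COI2 insert region, the COI1
forward site, the shared insert core, the reverse-primer sites and a 3'
flank. Within the layout the two amplicons overlap, as the real primers do
on the Folmer region, and every species carries exactly one binding site
per primer.

Sequence relatedness is modelled with a two-level scaffold: a shared core
sequence, per-phylum scaffolds diverged from it (12% per site), and species
diverged from their phylum scaffold (10% per site, primer sites kept
intact). This gives within-phylum barcode identities around 0.84 —
comparable to congeneric/confamilial COI divergence — and cross-phylum
identities below the 0.80 profiling floor. Rejection sampling enforces the
documented upper bound: no two distinct species exceed 0.90 identity.
Optional "sister pairs" are planted at a configurable identity (0.95–1.0);
identical twins guarantee equal-best hits and exercise the multiple-hit
machinery deterministically.

One deviation from the published primer set is deliberate: the published
internal COI2 reverse primer binds the same conserved motif as the COI1
forward primer, so on a synthetic barcode its binding site would coincide
with the COI1 forward site and the one-site-per-primer invariant could not
hold. The default set therefore uses an orthogonal degenerate stand-in of
the same length and degeneracy for the COI2 reverse primer; real runs
supply their own primer sequences through the run configuration.

## Communities, reads and controls

`community_design()` describes the sampling layout (subtidal sites at
surface/mid/deep, tide pools, a shore transect sampled in summer `S20` and
fall `F20`, one negative control per ten samples) and the abundance model:
a log-normal base abundance per species (default sdlog 1.5, a typical
species-abundance skew) times planted multipliers for chosen factor levels
— e.g. a ×3 boost of ten species in tide pools. Freshwater species receive
non-zero probability only in river-influenced surface samples. Sample
counts are multinomial draws of `reads_per_sample` reads (so read depth is
fixed, composition varies).

`synthesize_reads()` cuts each read pair from one amplicon copy: forward
primer, insert, reverse-complemented reverse primer. Substitution errors
(default rate 0.005 per base, within the range of post-filter Illumina
error) are applied to the amplicon copy *before* the mates are cut, so a
copy's error count is Binomial(amplicon length, rate) — analytic for tests
— and the two mates agree over their overlap, as consensus-corrected real
pairs largely do after merging. Indels default to zero (a config knob), so
identity arithmetic stays exact. Qualities follow a fixed high profile
(Q38) with an optional degraded 3' tail; the trimming stage is exercised by
constructed records in the tests. Negative controls receive 0–5 stray
reads. All outputs (gzipped FASTQ, reference FASTA, checklist TSVs) are
byte-identical under a fixed seed.

What the generator does not emulate — and therefore what passing tests do
not certify on real data: PCR chimeras, primer-template amplification bias,
tag jumping, indel sequencing error, eDNA transport/decay, or taxonomic
mislabelling in the reference. The generator shows the pipeline is correct
and calibrated; field accuracy also depends on these unmodelled effects.

# Read processing

* **Trimming** keeps the longest read prefix in which every sliding window
  (default 4 bases) has mean quality ≥ 20; reads shorter than 100 nt after
  trimming are dropped. For prefixes shorter than one window the
  whole-prefix mean is used.
* **Merging** reverse-complements the reverse mate and scans overlaps from
  the longest down to 30 nt, choosing the overlap with the smallest
  mismatch fraction (ties to the longer overlap); pairs above the mismatch
  ceiling (default 10%) stay unmerged and are excluded downstream. At each
  overlap disagreement the higher-quality base wins.
* **Demultiplexing** requires the forward primer anchored at the 5' end and
  the reverse-complemented reverse primer at the 3' end (±2 nt slack),
  IUPAC-aware, each within `max_mismatches` (0 by default; 2 in the
  analysis scripts, since universal primers are expected to tolerate
  mismatch). An `N` in a read never satisfies a primer code unless
  explicitly allowed. Inserts shorter than 270 nt are rejected; the length
  filter is interpreted on the primer-stripped insert (both true inserts,
  313 and 325 nt, exceed it; the alternative — total merged length — is a
  documented configuration). Reads whose flanks identify two different
  markers are rejected as ambiguous.

Every input pair ends in exactly one bin (assigned per marker, unmerged,
rejected, trim-discarded), and the pipeline manifest carries the tally.

# Identity and assignment

`pairwise_identity()` is a semiglobal alignment with free terminal gaps on
the reference, so a short amplicon contained in a full-length barcode
scores 1.0 when exact. Identity is matches over aligned columns, excluding
the free reference overhangs; internal gaps and query overhangs count
against it. Scoring is match +1, mismatch −1, gap −1.5.

Bulk search (`assign_reads()`, `assignability_profile()`) dereplicates
inserts and uses exact k-mer seeding (k = 14) with ungapped diagonal
extension and early abandonment below a reporting floor. On
substitution-only data the best diagonal *is* the optimal semiglobal
alignment, and a read within 3% of a reference is guaranteed to share a
30 nt exact run (pigeonhole), hence a sampled seed at step 10; the
OTU-profiling search samples seeds at every position because it must
resolve identities down to 0.80. Agreement between the seeded search and
the full alignment is asserted in the tests.

A read is assigned to the single species of its best hit when the best
identity is ≥ 0.97. Reads whose equal-best hits span more than one species
are held out of the community matrix and tallied per species set in the
multiple-hit report — the workflow's resolution is reference curation
(exclude the implausible species, re-run for top hits), not fractional
apportionment. Sub-threshold reads are counted unassigned. Assignment is
monotone in the threshold and conserves reads
(assigned + multi-hit + unassigned = input).

OTU clustering is abundance-sorted greedy centroid clustering at 97%
identity (ties broken lexicographically; a sequence joins the first
qualifying centroid in founding order; the centroid is the representative).
Single-read OTUs are removed as likely error. A single-linkage-style
clusterer would differ in edge cases, but the completeness profile only
needs representatives, for which a percent-identity criterion is the
natural reading of a "97% similarity" threshold. The profile reports, per
phylum of the best reference, the fraction of OTUs in the species-level
band [0.97, 1.0] among those at or above the lower bound — 0.80 by
default, with 0.85 available as the common alternative; OTUs below the
bound are reported separately.

# Coverage audit

`coverage_report()` matches checklist species to reference records by exact
name after case/whitespace normalisation (synonym resolution is out of
scope) and checks each record for both primer sites in consistent
orientation with spacing within ±10% of the expected insert. Because
"species has a record" and "species has an amplifiable record" differ, the
report carries both counts; the headline covered fraction is the
primer-site one. The per-primer mismatch tolerance defaults to 2 and is
reported with the output. Coverage is monotone under database growth.

# Community statistics

All statistics are implemented from their definitions and cross-checked in
the tests against independent references (vegan, closed forms, exhaustive
enumeration):

* Hellinger transformation $y'_{ij} = \sqrt{y_{ij} / y_{i+}}$; all-zero
  samples are dropped with a warning (or a hard error on request).
* Distances: Euclidean on Hellinger-transformed counts (the Hellinger
  distance) is the default for PERMANOVA and PCoA, the standard pairing
  for transformed count communities; SIMPER uses Bray–Curtis, its defining
  base. Both choices are configurable and logged.
* PCoA by Gower double-centering and eigendecomposition; axes are scaled
  eigenvectors for positive eigenvalues, negative eigenvalues are reported
  and their axes dropped.
* PERMANOVA: $SS_T = \frac{1}{N}\sum_{i<j} d_{ij}^2$, within-group sums
  analogous, pseudo-$F = \frac{SS_A/(a-1)}{SS_W/(N-a)}$,
  $R^2 = SS_A/SS_T$, and $p = (\#\{F^\pi \ge F\} + 1)/(n_\pi + 1)$ from raw
  label permutations (not residual permutations). `exact = TRUE`
  enumerates all $N!$ permutations for small $N$. Calibration is checked
  by simulation: the size at $\alpha = 0.05$ under an exchangeable null
  stays within its binomial band, and power against the documented planted
  habitat effect (10 species ×3, 8 + 8 samples, 10⁴ reads) exceeds 0.9.
* SIMPER averages the per-pair Bray–Curtis species contributions over all
  between-group pairs; the averages sum to the mean between-group
  dissimilarity (conservation asserted at 1e-10) and ranking ties break by
  species name.
* Shannon $H$ uses the natural log (the common convention; base is a
  parameter); zero-read samples yield NA.
* Accumulation curves use the exact hypergeometric forms for sample- and
  read-based expected richness, with 95% envelopes from resampling (100
  replicates by default); curves are monotone and end at observed pooled
  richness.
* Chao abundance-based Jaccard/Sørensen follow the shared-species
  probability corrections: $U$ adds to the observed shared-read share of
  assemblage 1 a term driven by shared species that are singletons or
  doubletons in assemblage 2 (with the doubleton count floored at 1 when
  zero), symmetrically for $V$; both are clamped to 1. Classic
  incidence-based Jaccard/Sørensen are reported alongside.
* Group comparisons: with exactly two groups and no blocks, a
  pooled-variance Student's t; with blocks crossed with groups, a
  randomized-block ANOVA (`y ~ block + group`); with blocks *nested* in
  groups (sites within habitats), a split-plot ANOVA
  (`y ~ group + Error(block)`) so the factor is tested against
  between-site variation. These are fixed-effect stand-ins for a
  site-random mixed model; REML fitting is deliberately out of scope, and
  for balanced designs the nested-stratum F equals the mixed-model test.
  Read abundances can be log10-transformed first.

# Numerical and reproducibility choices

Seeds are explicit everywhere randomness exists (generation, permutations,
envelopes); a pipeline rerun with the same config and seed is hash-stable,
and the manifest records the config hash and per-stage tallies. Identity
comparisons use a 1e-9 tie tolerance; PERMANOVA treats permuted F values
within 1e-12 of the observed one as ties in its favour. Degenerate inputs
have defined behaviour: empty pools, empty checklists, all-zero samples,
zero-length mates, singleton-only OTU inputs and no-control summaries all
either error with a named cause or return a well-formed empty result.

Problem sizes in the test-suite and acceptance runs are chosen to keep a
complete run on one CPU in minutes while leaving no stage untested at
realistic depth: the headline recovery checks use 20 samples × 10⁴ reads
(two markers, 60 species), calibration uses 500 null and 200 power
simulations at 999 permutations, and the completeness recovery runs 20
independent seeds at 4 × 1500 reads. The analysis scripts use a fuller
layout (13 subtidal sites × 3 depths, 12 tide pools, 2 × 10 shore samples,
7 controls at 4000 reads per sample).

# Known limitations

Assignment treats the reference as ground truth — mislabelled or
non-monophyletic reference sequences (a known failure mode of public
barcode data) surface only as multiple-hit cases when they are exact
duplicates. The greedy OTU clusterer is order-dependent by construction.
The error model omits indels and chimeras, so observed error-tolerance
rates are an upper bound on what indel-rich platforms would achieve. The
coverage audit's exact name matching understates coverage where synonyms
differ between checklist and database.
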