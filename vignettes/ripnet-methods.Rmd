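---
title: "Methods: from AGO2 pileups to differential TF networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from AGO2 pileups to differential TF networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ripnet` chains seven analysis stages that together ask what a deleted
miRNA was doing: which transcripts it held in the silencing complex,
which of those are de-repressed, how the TF co-expression fabric rewires
without it, which expression trajectories respond, what developmental
state the cells reach, and which other miRNAs absorb the freed RISC
capacity. This vignette explains each stage's model, its tunable
parameters, the numerical choices, and what the bundled synthetic data
do and do not establish.

## Binding-site definition

AGO2-RIP coverage is summarized per base as read pileups. The caller is
deliberately threshold-based rather than model-based: the original
analysis calibrated cutoffs on known targets instead of fitting a null
model, and this package keeps that contract.

* A *candidate region* is a maximal run of non-zero depth at consecutive
  positions. The choice of where splitting starts is not uniquely
  determined by a threshold description; maximal non-zero runs are the
  simplest deterministic option and the one implemented here.
* A candidate whose summit is below `tau_background = 10` reads is
  background and discarded.
* Every base strictly below `f_primary = 0.20` of the candidate summit
  is cut; cut bases belong to no site, and ties with the threshold stay
  inside sites. Emerging sub-sites whose own summit reaches both
  `0.20 * S` and 10 reads are recursively split at `f_sub = 0.05` of
  their own summit.
* With `f_sub < f_primary` every base surviving the primary cut already
  exceeds the recursive threshold, so the recursion's role is to
  *preserve* sub-sites with weak signal relative to the primary summit
  rather than to fragment them further; the machinery still applies its
  rule recursively, and the package's independent brute-force oracle
  walks the identical contract. A useful corollary, covered by tests, is
  idempotence: re-splitting an emitted site returns it unchanged.
* An alternative reading of "sliding window starting from the summit"
  would walk outward and cut only at the first crossing; the linear-scan
  contract was fixed on purpose and is stated here rather than asserted
  as the original authors' exact code.

Consensus requires an overlapping site (at least one shared base; no
reciprocal-fraction rule) in *every* replicate; consensus `depth_sum` is
the replicate mean of the overlapping sites' sums, because downstream
signal comparisons are per-condition means. WT-specific sites are WT
consensus sites with no overlapping knockout site. Site signal is summed
only within annotated 3'UTRs -- the dominant location of miRNA-guided
repression -- and divided by the gene's mean whole-cell expression in
the matching condition, so IP enrichment is read relative to transcript
abundance. Genes with zero whole-cell expression get an undefined
normalized signal and are excluded downstream.

## The DE stage is pluggable

The built-in differential-expression test is a Welch two-sample test on
`log2(count + 1)` with Benjamini-Hochberg adjustment across genes. The
published analysis used negative-binomial machinery; re-implementing it
is out of scope here, and any external DE table with columns `gene_id`,
`log2fc`, `pvalue`, `padj` plugs into every consumer (`intersect_targets`,
`persistent_de_tfs`, `top_de_genes`). The log2 fold change is the ratio
of group means with a 0.5 pseudocount added only when a mean is zero, so
noise-free doubling gives exactly one log2 unit. "Upregulated" means
`log2fc > 0` and `padj < 0.05`; no fold-change floor is applied anywhere
in the intersection, mirroring the significance-only published filter.

## Signed wTO and the bootstrap filter

For nodes i, j and all expressed genes u (expressed = mean RPKM at or
above 5 on at least one day; a gene is removed only when below the floor
on *every* day):

$$\omega_{ij} = \frac{\sum_{u \ne i,j} a_{iu} a_{uj} + a_{ij}}
  {\min(k_i, k_j) + 1 - |a_{ij}|}, \qquad k_i = \sum_{u \ne i} |a_{iu}|$$

with $a$ the signed Pearson correlation, computed on `log2(RPKM + 1)`
(correlations on the linear scale attenuate negative relationships
between log-normal expression profiles, which matters because repressive
TF links are as informative as activating ones). The sums run over every
expressed gene except the pair itself, including fellow node-set
members; whether the original analysis included fellow nodes in $k_i$ is
not recoverable from its description, and the two choices differ by one
term. Zero-variance genes get zero correlations with a logged warning,
so a fully degenerate structure yields $\omega = 0$ everywhere.

Link confidence: the samples of one condition-day (biological
replicates) are resampled with replacement B = 1000 times and
$\omega$ recomputed; the reported probability is the two-sided
sign-crossing frequency $2 \min(\#\{\omega^* \le 0\}, \#\{\omega^* \ge
0\})/B$, and links above 0.10 are flagged as not kept. The published
description says only "the probability of the relationship being
random"; the sign-crossing reading is an interpretation, recorded as
such.

A calibration caveat the package measures rather than hides: with only
seven samples the n-out-of-n bootstrap underestimates sampling spread by
roughly $\sqrt{n/(n-1)}$, so on fully independent Gaussian data the
retained-link fraction sits near 0.13 instead of the nominal 0.10 (the
acceptance script recomputes this number on every run; the same
implementation at 30 or 60 samples retains *fewer* than 10 %). At the
pipeline's operating point this mild anti-conservativeness only admits a
thin extra margin of background links, which the distance filter of the
differential stage then removes.

## Differential network classification

Each network's weights are scaled by that network's maximum absolute
weight before comparison, so the distance filter is scale-free across
networks of different density -- the normalization of the link distance
is not printed in the method's description and this choice is recorded
as an interpretation. Categories: present in all networks with one sign
is common (alpha); a sign change between networks is different (beta);
presence in exactly one network is specific (gamma), labeled with its
owning network. A same-sign link confined to a proper subset of three or
more networks is treated as specific to that subset; with the two
networks compared here the case does not arise. "Similar strength" for
alpha links carries no printed tolerance, so similarity is enforced only
through the common-sign rule plus the distance filter
$\lVert \tilde w \rVert / \sqrt{m} > 0.5$.

Nodes take the modal category of their kept links when a chi-squared
goodness-of-fit test against a uniform 1/3 split (df = 2) rejects at
p < 0.05; modal ties and non-rejections are "undefined". Expected counts
below 5 are still tested but flagged, since no small-degree rule is
printed.

## SOM trajectory clustering

TFs significant on every day 1..4 enter with their per-day log2 fold
change, z-scored across the qualifying TFs within each day ("normalized
fold change" is otherwise undefined; per-day standardization keeps days
with large global shifts from dominating the shape). The SOM is the
standard online algorithm -- rectangular grid, Gaussian neighborhood,
learning rate decaying linearly 0.5 to 0.01, radius from half the larger
grid dimension to 0.5, 100 updates per trajectory -- followed by a
radius-zero quantization pass run to convergence and a best-of-three
restart over derived seeds, which stabilizes the local optimum. The grid
grows through near-square layouts (1x2, 1x3, 2x2, 2x3, ...; strongly
elongated strips are skipped because they quantize poorly) until the
average distortion, the mean squared distance of trajectories to their
best-matching unit, falls below `distortion_cut = 10`. Per-unit
quantization errors are reported but not individually thresholded: the
published stopping description is not fully specified, and this is the
operationalization chosen. The distortion cut's units depend on the nFC
scaling, which is why it is exposed as a parameter; on z-scored
trajectories the first grid usually already satisfies 10, and the cut
only binds when set deliberately tighter.

Cluster summaries are loess smooths (span 1, degree 2, direct surface)
of member trajectories per unit; degree-2 local regression reproduces
exactly any trajectory that is polynomial of degree at most two, so
linear cluster trends pass through unchanged and single-member clusters
are interpolated up to that degree.

## Atlas correlation profiling

The query is a cell-line expression profile; the reference is a genes x
(region, age) matrix. Both sides are `log2(x + 1)` transformed (standard
variance stabilization; the source description is silent) and correlated
over the top 1000 genes ranked by DE significance against day 0 within
the same cell line, ties broken by |log2fc| then gene id so the ranking
is deterministic even when nothing changes. A (region, age) call is
significant when its correlation exceeds the mean of the *other* regions
at the same age by more than twice the standard deviation of
correlations among similar-age columns -- similar meaning the age plus
its immediate ordered neighbors, a window exposed as a parameter because
"similar age" is not defined in the source. Whether that rule compared
correlations or expression means is ambiguous in its one-sentence
description; the correlation reading is implemented and flagged here.
Regions with non-overlapping sampled ages can be merged by column
averaging at shared ages and union of ages elsewhere (the treatment the
published analysis applied to the two cerebellar region labels).

## miRNA quantification and activity

Raw digital counts are divided by each sample's mean housekeeping count
(arithmetic mean; the geometric alternative is not stated in the
source), which makes values exactly invariant to lane depth. Abundance
requires a raw count strictly above 200 in at least one sample.
Takeover candidates are the intersection of abundant species
upregulated in the knockout in both the AGO2-IP and the whole-cell
compartment; the pipeline runs its Welch stage on normalized counts
rescaled by the grand housekeeping mean (restoring count scale so the
log transform stabilizes variance while staying depth-invariant) and
tests only the abundant panel, the set the published intersection is
framed on. Activity is IP over whole-cell signal per species -- how
strongly a miRNA is engaged in the silencing complex relative to its
abundance -- with dense descending ranks per condition; zero whole-cell
signal makes activity undefined and the species is excluded with a
warning.

## What the synthetic data emulate, and what they do not

The generators (`gen_pileups`, `gen_expression`, `gen_mirna_counts`,
`gen_atlas`, plus `gen_annotation`/`gen_target_list`) emit every input
the pipeline consumes, each with a machine-readable ground truth. The
default configuration is the study design the pipeline is meant for:
two conditions, five days, seven expression replicates and three pileup
replicates per condition, 24 TFs among 260 genes, knockout effects of
1.5 log2 units starting at day 1 with day 0 identical by construction.
Choices a user should know about, fixed once and for all:

* *Pileups*: Poisson background (2 reads/base) plus deterministic
  isoceles-triangular bumps (width 60, summit 40); the triangle makes
  the 20 %/5 % thresholds correspond to analytically known positions.
  Some regions carry a shared site, and some carry an 8-read decoy so
  callers are exercised on both sides of the 10-read rule. No read-level
  simulation, no mappability structure, no strand information.
* *Expression*: two TF modules (five TFs + ten members each) driven by a
  per-replicate latent factor with loadings of both signs; log-normal
  noise with sigma 0.25 gives within-module |r| near 0.94, satisfying
  the design requirement of exceeding 0.9. Counts are negative binomial
  (dispersion = sigma squared) around scaled RPKM. Knockout rewiring
  flips one module-1 TF's loading sign (expected beta links) and
  decouples one module-2 TF (expected WT-specific gamma links). Two
  groups of five non-module TFs carry rising and fading fold-change
  trajectories, both significant on every day -- two shapes, matching
  what a first grid of two SOM units can represent. A block of genes
  drifts with time identically in both conditions, standing in for the
  differentiation program that dominates change against day 0.
* *miRNA counts*: 50 species plus five housekeeping rows over the
  12-sample layout (2 conditions x 2 days x 3 replicates). The dominant
  species reaches 80 % of the WT count mass at the final day and is zero
  in the knockout throughout. Dispersion is 0.15 -- digital
  hybridization counting replicates more tightly than sequencing. The
  three takeover species are planted abundant with a 2 x effect-size
  log2 knockout jump: with three replicates a Welch test has essentially
  no power against more modest jumps, and a large jump is what freeing
  ~80 % of RISC capacity implies.
* *Atlas*: four regions by three ordered ages around a shared gene
  baseline, each cell with an essentially independent signature, and the
  template block planted in the middle age. Real developmental atlases
  drift smoothly with age; independence is deliberate so the planted
  match is unambiguous. The small age range keeps the two-SD rule well
  posed at desk scale: any column whose similar-age window excludes the
  template column has an unguarded t-tail of a few percent for chance
  calls, and with many such columns a unique planted call would be a
  coin flip rather than a property.

Consequently, passing tests show that the chain recovers planted
structure of realistic effect size under idealized noise; they do not
show robustness to mappability artifacts, batch effects, dispersion
misspecification, or atlas age-drift, none of which the generators
emulate.

Recovery of the decoupled-TF (gamma) links is the noisiest metric in the
chain: with seven replicates a decoupled gene's chance correlation with
its former module has a standard deviation near 0.4, so occasional
seeds re-couple it spuriously. This reflects the replicate budget, not
an implementation defect.

## Problem sizes and determinism

Default synthetic scale: 40 regions x 500 bases x 12 tracks for
pileups; 260 genes x 70 samples for expression; B = 1000 bootstraps per
network; the full chain runs in well under a minute on one CPU, and the
test suite's heaviest cases (1000-track oracle comparison, 10,000
random-structure bound checks, a 200-repeat null calibration) each stay
within a few minutes. One master seed derives all stage seeds, every
generator is byte-identical under a fixed seed, and rerunning the
pipeline with one configuration reproduces the manifest except for its
timestamp.
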