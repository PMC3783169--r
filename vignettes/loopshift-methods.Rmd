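---
title: "Chromatin complexes, gene transitions and pausing: methods behind loopshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromatin complexes, gene transitions and pausing: methods behind loopshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopshift)
```

`loopshift` decides how genes sit inside higher-order chromatin interaction
complexes, infers from before/after interaction maps whether those
complexes were disrupted by a treatment, and quantifies nascent
transcription (pausing, initiation, metagene shape) from strand-specific
read-start coverage. This vignette records the models, the parameters that
matter, the numerical choices, and what the synthetic test bed does and
does not demonstrate.

## Coordinates and windows

All intervals are 0-based, half-open (`[start, end)`), the BED convention;
1-based inputs are converted at read time. `[a,b)` and `[b,c)` never
overlap. The distance from a point to an interval is the distance to the
nearest *contained* base (0 inside, `min(|p - start|, |p - end + 1|)`
outside), so a TSS one base past the right edge is at distance 1, not 0.

Window rules ("TSS within ±5 kb of an anchor", "promoter within ±20 kb of a
stand-alone site") are **boundary-inclusive**: a gene exactly 5,000 bp from
an anchor edge is an anchor gene. The plain reading of "within ±5 kb" is
inclusive, and pinning it lets tests assert the boundary exactly. The TSS
of a minus-strand gene is `tx_end - 1` — the first transcribed base — which
makes every ±window rule an exact mirror image of the plus-strand case;
TSS-centred signal windows are likewise strand-mirrored
(`[tss - w, tss + w)` on `+`, `[tss - w + 1, tss + w + 1)` on `-`).

Chromosome names match as exact strings. No silent `chr` repair is
attempted (mixing assembly naming styles should fail loudly);
`normalize_chrom_names()` converts explicitly when the caller decides to.

## Complex assembly and gene categories

A ChIA-PET experiment reports pairs of anchor regions. `assemble_complexes()`
treats anchors overlapping by ≥1 bp as one node and each pair as an edge;
a **complex** is a connected component, its anchors the merged nodes, its
span the interval from first anchor start to last anchor end. Connected
components are the standard cluster-to-complex construction and are what
make "multiple loops and anchor regions per complex" well defined.
Inter-chromosomal pairs are read and flagged but excluded from assembly:
the analysis concerns local looping. Complex ids are assigned by
(chromosome, span start), so output is deterministic.

`categorize_genes()` applies, in order of precedence: *anchor* (TSS within
`anchor_window`, default 5,000 bp, of any anchor), *loop* (TSS inside a
complex span), *outside*. "Loop gene" is read as "otherwise, among genes
inside the complex" — loop DNA is by construction the part of the span away
from anchors. A TSS near anchors of two complexes is assigned to the
nearest anchor, ties broken by smallest complex id; the choice is arbitrary
but deterministic, and at the default window it affects only genes sitting
in the rare overlap of two complex neighbourhoods.

## Transition classification and disruption inference

For every gene that was an anchor gene in the *before* condition,
`classify_transitions()` determines its status against the *after*
complexes: `anchor` → `anchor-to-anchor`; else `loop` → `anchor-to-loop`;
else, if the TSS is within `standalone_window` (default 20,000 bp) of a
binding site external to every after-complex anchor, `anchor-to-stand-alone`;
else `anchor-to-none`. The fourth category is deliberate: the three named
outcomes do not exhaust the anchor genes (some have no post-treatment
complex or site anywhere near), and an exhaustive partition is what makes
the category counts add up and the chi-squared test well posed.

**Disruption is an inference, not an observation**: a complex is called
disrupted exactly when its gene's transition is not anchor-to-anchor. The
package encodes that inference and nothing more. The stand-alone rule
measures from the TSS point by default; `promoter_flank` widens it to a
promoter interval, which only shrinks distances.

Class differences are tested with the Pearson statistic
$X^2 = \sum (O - E)^2 / E$ on the response-class × transition table (or the
collapsed disrupted/retained 2×2 — both shapes are available because the
choice is not forced by the inference), with expected counts from the
margins and no continuity correction. An empty expected cell is an error
advising collapse rather than a silently degenerate statistic. Group-mean
comparisons default to the Welch unequal-variance t-test — the safer choice
when only "t-test" is specified — with pooled-variance Student behind
`var_equal = TRUE`; paired comparisons are the one-sample t on differences.
Degenerate inputs follow explicit conventions: identical groups give
`p = 1`; a constant non-zero shift with zero variance gives `p = 0` with a
`degenerate` flag rather than an error mid-pipeline.

## Signal metrics

Coverage is stored as strand-specific per-base **read-start counts** with a
library size; RPM is `count × 10⁶ / library_size`. Read 5′ ends are the
standard GRO-seq tag convention and make the ±300 bp initiation window well
defined. When no library size is supplied it defaults to the total count
across both strand files, which keeps RPM self-contained on synthetic data.

The **pause ratio** of a gene is the sense-strand density near the TSS over
the density in the gene body:

$$\mathrm{PR} = \frac{\mathrm{RPM}(\mathrm{TSS} \pm 300\,\mathrm{bp}) / 0.6\,\mathrm{kb}}
                    {\mathrm{RPM}(\mathrm{TSS}+300 \to \mathrm{TES}) / L_\mathrm{body}\,\mathrm{kb}}.$$

Totals over regions three orders of magnitude apart in length are only
comparable as densities, so per-kb normalisation is the default; the raw
total ratio survives behind `per_kb = FALSE`. One pseudocount read is added
to each region before forming densities (default `pseudocount = 1`):
it keeps the ratio defined for genes with empty bodies at the cost of a
small attenuation that vanishes at realistic depth. With `pseudocount = 0`
an empty body yields `NA` plus a flag, never an Inf that propagates.
Genes too short to hold the TSS window plus 300 bp of body are skipped and
flagged.

**Metagene profiles** average signal in gene-oriented coordinates: per-bp
RPM over `[TSS - flank, TSS + flank)` and around the TES (flank 500 bp for
Pol II ChIP profiles, 1,000 bp for GRO-seq), and a gene body rescaled to a
common length by fitting a **natural cubic spline** over base index and
evaluating it at 1,000 equally spaced points (endpoints included), averaged
into 100 bins of 10. Natural boundary conditions are the common default
where none is specified; the spline is exact on constant and linear signal,
which the tests pin (flat coverage reproduces the flat level to 1e-6
relative; a linear ramp matches closed-form bin means to 1%). Negative
spline excursions are clipped at 0 — RPM cannot be negative. Genes with
transcripts shorter than `min_gene_length` (default 2,000 bp) are excluded
and counted: interpolating a near-empty body is ill-posed.

## Consensus cistromes and spatial statistics

`consensus_cistrome()` pools peaks from all studies, clusters them
transitively by ≥1 bp overlap, counts *distinct studies* per cluster
(site-level support: a study supports a cluster if any of its peaks touches
it), and emits the merged span of clusters with support ≥ `min_studies`
(default 2). The merged span, not the intersection, is kept: intersecting
would shrink sites asymmetrically depending on which study happened to call
the narrowest peak. Base-level voting would be the alternative reading; it
yields ragged sub-intervals and was rejected for this default.

`permutation_enrichment()` measures association between two interval sets
by the base-level Jaccard index (or mean nearest distance for
promoter–marker proximity) against a null in which every query interval is
independently re-placed uniformly on its own chromosome, lengths preserved,
overlaps among relocated intervals allowed. This is the simplest
length-preserving null and is stated openly; a gap-preserving circular
shift (`null_model = "shift"`) is available when preserving the query's
internal spacing matters. P-values use the add-one rule
`p = (1 + #extreme)/(n_perm + 1)`, are one-sided with the direction
declared by the caller, and are bit-reproducible given a seed (the caller's
RNG state is saved and restored). Promoters on chromosomes carrying no
marker contribute the chromosome length as a maximal distance rather than
an infinity that would poison the mean. The default `n_perm = 500`
resolves p-values down to ~0.002, enough for the "< 0.01" claims this kind
of analysis makes; no multiple-testing correction is applied across
factor/marker pairs — the number of tests is the caller's to correct.

## The synthetic study generator

`simulate_study()` builds a fully labelled miniature of the real inputs'
*joint* structure: genes with a single TSS; one chromatin complex per
responsive gene whose anchors either cover the TSS (probability
`p_tss_in_anchor = 0.9`) or flank it beyond the 5 kb window (loop truth);
per-complex disruption drawn with class-specific probabilities
(`d_repressed = 0.86`, `d_induced = 0.49`) realised as retained /
loop-geometry / stand-alone-site / nothing outcomes (0.4/0.4/0.2 among
disrupted); binding sites enriched in anchors (3 per complex) over a sparse
background (1 per 500 kb); three pseudo-studies with 20% peak dropout and
±150 bp edge jitter; and Poisson read-start coverage with class-specific
pre-treatment pause ratios (induced ~ LogNormal(ln 8, 0.4), repressed ~
LogNormal(ln 2, 0.4)) and post-treatment multipliers (induced body ×3,
repressed TSS ×0.4 and antisense ×0.5) at 2×10⁶ reads per library.
Nonresponsive genes get LogNormal(ln 4, 0.4) pause ratios — between the two
responsive classes, so rank-recovery checks cannot lean on class
separation alone.

Construction is **truth-first**: labels are drawn, then geometry and signal
are placed to match them. Each gene owns a *territory* — its transcript
plus margins (18 kb for responsive genes, which must also host their
complex; 2 kb otherwise) — and territories never overlap. Complex anchors
stay within ±14 kb of their gene's TSS, emitted stand-alone sites within
6–12 kb, and background binding sites are rejection-sampled to stay >21 kb
from every TSS. These margins are chosen so that no window rule can reach
across territories: an anchor of one gene's complex can never fall within
5 kb of another gene's TSS, and no stray site can fake stand-alone
evidence for an `anchor-to-none` gene. That is what licenses the strongest
test in the suite: on noiseless settings (jitter 0, dropout 0,
`p_tss_in_anchor = 1`) categorisation and all four transition labels must
match the truth for 100% of genes, not merely most.

Two generator defaults are the package's own choices. Each responsive gene
gets its *own* complex: disruption probabilities are class-specific, so
complexes are kept class-pure (real complexes can enclose several genes —
the categoriser handles that, the generator just does not produce it), and
`n_background_complexes` adds gene-free complexes for realism. The default
chromosome length is 2×10⁷ bp × 4 chromosomes: 800 non-overlapping genes
with mean transcript ~16 kb plus their territories demand ~40 Mb, and the
80 Mb genome keeps placement occupancy below ~50% so rejection sampling
terminates comfortably (the generator errors with advice if asked to pack
an impossible genome).

What the generator does **not** emulate — and hence what passing tests do
not show about real data: peak shape (reads are uniform within regions),
mappability and copy-number structure, multi-gene complexes,
inter-chromosomal interactions, isoform-resolved TSS ambiguity, and
sequencing error. Conclusions about estimator calibration transfer;
conclusions about robustness to those artefacts do not.

## Problem sizes used in the tests

The shipped suite runs the generator at 60–800 genes on 5–80 Mb genomes,
the oracle-equivalence checks on 200 random instances per operation
(chromosomes ≤ 100 kb, ≤ 100 intervals or pairs, compared exactly against
per-base masks and a BFS component search), permutation calibration on 200
replicate null datasets at `n_perm = 199` (type-I error within
[0.02, 0.08] at α = 0.05), detection power on 100 replicates, and the
disruption-recovery check at the study's class sizes (144 repressed, 213
induced anchor genes, seed 7), asserting the estimates land within 3
binomial standard errors of the configured probabilities. These sizes give
each stochastic assertion comfortable margins while keeping the whole suite
in a few minutes.

## Known limitations

* Gene categorisation is TSS-point based; a gene body can cross many
  complexes but only the TSS decides its category.
* The disruption call is the positional inference only; a complex that
  re-formed with different anchors beyond the windows is
  indistinguishable from one that dissolved.
* `consensus_cistrome()` treats studies symmetrically; no weighting by
  study quality or peak score.
* The relocation null ignores chromatin accessibility structure; enrichment
  against an accessibility-matched background would need a user-supplied
  candidate set.
* `mean_nearest_distance` summarises proximity by the mean, which a few
  marker-free promoters on large chromosomes can dominate; the capped
  distance bounds, but does not remove, that influence.
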