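# loopshift

Genes do not respond to a nuclear-receptor ligand in isolation: many sit
inside higher-order chromatin complexes — sets of genomic *anchor* regions
held together by a protein machine (Pol II, ERα), with looped DNA in
between. `loopshift` is an R package for asking, before and after a
treatment such as estrogen stimulation of breast-cancer cells, **where a
gene sits relative to those complexes and what happened to its complex**:

* **Gene categorisation.** A gene is an *anchor gene* if its TSS lies within
  ±5 kb of an anchor region of a complex, a *loop gene* if its TSS falls
  inside the complex span but away from anchors, and *outside* otherwise.
  Complexes are assembled from ChIA-PET-style anchor pairs as connected
  components of the anchor-overlap + interaction graph.
* **Chromatin-reconfiguration inference.** Each pre-treatment anchor gene is
  classified by its position relative to the post-treatment complexes:
  `anchor-to-anchor`, `anchor-to-loop`, `anchor-to-stand-alone` (promoter
  within ±20 kb of a binding site external to any complex), or
  `anchor-to-none`. A complex is inferred *disrupted* exactly when the
  transition is not anchor-to-anchor; class differences are tested with a
  Pearson chi-squared test.
* **Nascent-transcription metrics from GRO-seq-like tags.** Per-gene pause
  ratio (pausing index)
  `PR = (RPM/kb in TSS ± 300 bp, sense strand) / (RPM/kb in gene body, TSS+300 → TES)`,
  sense/antisense initiation rates, and metagene profiles with fixed flanks
  and a 100-bin gene body rescaled through a natural cubic spline evaluated
  at 1000 points.
* **Consensus cistromes.** Binding sites merged across studies, keeping
  clusters supported by ≥ *k* studies (site-level support, merged spans).
* **Permutation spatial statistics.** Base-level Jaccard enrichment of sites
  in complex anchors and promoter–marker proximity, against a
  length-preserving uniform-relocation null (a circular-shift null is
  available), with `p = (1 + #extreme) / (n_perm + 1)`.
* **A synthetic-study generator** (`simulate_study()`) that emits genes,
  complexes, pseudo-study cistromes, strand-specific coverage and
  ground-truth labels, constructed so that on noiseless settings the
  analysis must reproduce the truth exactly — the package's own test bed.

Everything is tidyverse-native: interval sets, genes, annotations and
results are tibbles (BED-style 0-based half-open coordinates), functions
compose with the pipe, fitted objects have `tidy()`/`glance()` methods, and
result types have `autoplot()`/`plot_*()` companions.

## Worked example

```r
library(loopshift)
library(dplyr)

sim <- simulate_study(sim_config(seed = 42, n_genes = 240, n_chromosomes = 2,
                                 chrom_length = 1e7, n_background_complexes = 50,
                                 library_size = 5e5))

complexes <- assemble_complexes(sim$pairs_pre)
annot     <- categorize_genes(sim$genes, complexes, condition = "pre")
count(annot, category)
#>   category     n
#> 1 anchor     113
#> 2 loop        19
#> 3 outside    108
```

113 genes have a TSS within 5 kb of a pre-treatment anchor; those are the
genes whose complexes we can follow across treatment.

```r
er_cx      <- assemble_complexes(sim$pairs_post)
annot_post <- categorize_genes(sim$genes, er_cx, condition = "post")
standalone <- standalone_sites(sim$er_sites_post, er_cx)
transitions <- classify_transitions(sim$genes, annot, annot_post, standalone,
                                    response = sim$response)
transition_contingency(transitions, collapse_to_disruption = TRUE)
#> Pearson chi-squared test
#>            col
#>             disrupted retained
#>   repressed        47        9
#>   induced          20       37
#> X-squared = 27.92, df = 1, p-value = 1.27e-07
```

Complexes holding repressed genes were inferred disrupted far more often
(47/56 = 84%) than those holding induced genes (20/57 = 35%) — the generator
planted class-specific disruption probabilities and the pipeline recovers
the contrast with a decisive chi-squared test.

```r
pause_pre  <- pause_ratio(sim$genes, sim$coverage_pre,  condition = "pre")
pause_post <- pause_ratio(sim$genes, sim$coverage_post, condition = "post")
induced <- sim$response$gene_id[sim$response$label == "induced"]
compare_conditions(filter(pause_pre,  gene_id %in% induced),
                   filter(pause_post, gene_id %in% induced), "pause_ratio")
#>        metric  n median_before median_after direction  statistic      p_value
#> 1 pause_ratio 72      8.022798     2.634528  decrease  -19.31973 5.499224e-30
```

Induced genes start highly paused (median pause ratio ≈ 8) and the
simulated 3× elongation increase drops the ratio to ≈ 2.6; the paired
t-test is unambiguous. `plot_pause_ratios()`, `plot_transitions()` and
`autoplot()` on metagene or enrichment objects draw the matching figures,
and `run_pipeline()` executes the whole chain from one config (YAML or
list) into a deterministic `report.json`.

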