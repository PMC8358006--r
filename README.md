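# gsdtools — grand H3K27me3 silencer domain analysis

H3K27me3 is the Polycomb-associated repressive histone mark. While most
H3K27me3 peaks span a few kilobases, a small class of merged domains
extends over tens to hundreds of kilobases. The broadest of these — the
**grand silencer domains (GSDs)**: the top 5% broadest merged domains that
also exceed 50 kb — mark developmentally critical, evolutionarily
constrained genes, sit preferentially across entire TADs, interact with
each other through chromatin loops, and are widely *lost* in carcinoma,
de-repressing a catalog of activated genes. `gsdtools` implements that
entire analysis as a tested, reusable R pipeline:

1. **Domain calling** — SICER-style peak BED in; peaks merged within 2 kb;
   input-subtracted RPKM signal
   (`RPKM = reads / (length_kb × millions_mapped)`, floored at 0);
   breadth-quantile classification into grand / typical / narrow plus a
   seeded random control set.
2. **Gene association** — genes marked by domains overlapping the gene
   body ± 2 kb; rank-sum tests of missense *Z* and dN/dS for grand-marked
   vs other marked genes; Spearman trend of expression across 20
   breadth-quantile bins.
3. **3D-genome integration** — TAD overlap/anchor/"spans ≥ 90% of a TAD"
   census, normalized TAD position profiles, within-class loop
   connectivity and multiplexity (1 / 2 / ≥3 partners), and a permutation
   null that relocates each grand domain uniformly on its own chromosome
   (length preserved), with the add-one empirical p
   `p = (1 + #{null ≥ obs}) / (1 + n_perm)`.
4. **Two-condition loss/gain** — per-gene
   `log2((RPKM_tumor + 0.25)/(RPKM_normal + 0.25))`, loss/gain at |log2FC|
   > 1; integration with a DE table (log2FC > 1, FDR < 0.05) into
   activated / silenced / loss-only / gain-only / stable calls; mark and
   methylation profiles (TSS − 5 kb … TES + 10 kb) for the activated set,
   splitting promoter (TSS ± 2 kb) from gene-body methylation.
5. **Synthetic epigenome generator** — a paired normal/tumor genome with a
   lognormal + Pareto breadth law, breadth-linked signal and repression,
   TAD-segregated loops and planted loss/gain/activation truth, so every
   stage is testable offline with a recovery oracle.

## Worked example

```r
library(gsdtools)
res <- gsd_demo("run", seed = 7)   # simulate + full pipeline, ~30 s
```

`run/report.md` from this exact call (abridged):

```
Seed: 7; domains called: 1000 (grand 50, narrow 50, control 50)
Grand breadth cut-off: 52.7 kb (floor 50 kb)
- marked genes: 587 (grand-marked: 142)
- missense Z grand vs other marked: p = 1.82e-21 (grand_greater)
- dN/dS grand vs other marked: p = 4.41e-31 (grand_less)
- breadth-expression Spearman r = -0.708, p = 0.000475
- grand domains overlapping TADs: 50/50; marking anchors: 50; spanning a TAD: 15 (30%)
- connectivity (grand/narrow/control): 1 / 0 / 0
- permutation test: observed 50 connected grand domains, p = 0.002 (500 shuffles)
- grand-marked genes: 142; loss 93 (65.5%), gain 28 (19.7%)
- activated (loss + up): 27 of 93 (29%); silenced (gain + down): 5 of 28 (17.9%)
- methylation delta (activated genes): body 0.146, promoter -0.004
  (body hypermethylation without promoter hypomethylation: TRUE)
```

Reading this: the caller recovers all 50 planted grand domains; grand-marked
genes are more constrained (higher missense Z, lower dN/dS); expression
falls with mark breadth (negative Spearman r over breadth bins); grand
domains span TADs and interconnect far more than narrow/control domains
(permutation p at the floor); in the simulated tumor, about two thirds of
grand-marked genes lose H3K27me3, a third of those are transcriptionally
activated, and activated genes gain gene-body (not promoter) methylation —
the same qualitative signature the real-data analysis reports.

Stages are also available individually (`merge_peaks`,
`quantify_domain_signal`, `classify_domains`, `map_domains_to_genes`,
`breadth_expression_trend`, `tad_overlap_summary`,
`permutation_interaction_test`, `assign_target_genes`,
`classify_h3k27me3_change`, `integrate_expression_changes`,
`region_mark_profiles`, ...) and behind a CLI:

```sh
Rscript inst/cli/gsd demo --out run --seed 7 --n-perm 500
Rscript inst/cli/gsd call-domains --peaks peaks.bed --treatment chip.bedgraph \
    --input input.bedgraph --total-mapped 20000000 --merge-gap 2000 \
    --grand-quantile 0.95 --min-breadth 50000 --out out
```

## Documentation

The methods vignette (`vignettes/gsd-methods.Rmd`) describes the model,
every tunable parameter with its default and rationale, what the synthetic
generator does and does not emulate, and the package's numerical and
design choices.
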