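# sargtype

Comparative mitogenomics and molecular typing of the three holopelagic
*Sargassum* forms of the western Atlantic: *S. fluitans III*, *S. natans I*
and *S. natans VIII*.

The three forms drive the Caribbean "golden tide" strandings and are easily
confused morphologically, yet their complete mitochondrial genomes are
collinear, 34,727 bp long, and nearly identical: the two *natans* forms
differ at 7 nucleotide sites, and each differs from *S. fluitans III* at 93
and 96 sites. `sargtype` packages that comparison as a tested pipeline for
algal molecular ecologists: it ships the 98-site variant panel (position,
locus, per-form plus-strand allele, amino-acid chain) and the diagnostic
cox2/cox3 primer panel, and provides

- a **constraint-solving simulator** that builds three synthetic reference
  mitogenomes realizing the panel exactly (codon constraints solved per gene
  for strand, frame and context; primer footprints embedded variant-free),
- **fixed-difference scanning** of collinear genomes and per-locus summaries
  (`scan_variants()`, `count_differences()`, `locus_summary()`),
- **codon-aware effect annotation** reproducing the panel's amino-acid
  chains (`annotate_effects()`, `effect_summary()`),
- **in-silico PCR and specimen typing** into the three forms
  (`insilico_pcr()`, `derive_diagnostic_profiles()`, `type_cohort()`),
- a **distance-based phylogeny**: p-distances, neighbour joining with
  three-point branch lengths, column-resampling bootstrap (`nj_tree()`,
  `bootstrap_support()`).

For a pair of collinear sequences the package works with the p-distance
`d = m / n` (m differing columns of n compared, N pairwise-excluded); NJ
branch lengths for three taxa follow the three-point formulas
`v_a = (d_ab + d_ac - d_bc) / 2`. A confident typing call requires a single
form consistent with *every* observed diagnostic allele across assays —
majority voting is deliberately rejected because the diagnostic sites are
fixed within forms.

## Worked example

```r
library(sargtype)
report <- run_pipeline(generator_config(seed = 4727), bootstrap_replicates = 100)
print(report)
```

```
Holopelagic Sargassum comparative mitogenomics report
  genome length: 34727 bp; variant sites: 98
  pairwise differences: natans I/VIII 7, fluitans/natans I 93, fluitans/natans VIII 96
  natans pair amino-acid differences in 5 genes: rpl5, rps19, rps13, cox3, nad6
  typing summary: fluitans_III=5, natans_I=13, natans_VIII=53, unknown=0, conflict=0 
  label mismatches: 0
  tree: (fluitans_III:0.002620439428,natans_I:5.759207533e-05,natans_VIII:0.0001439801883)1;
```

Reading the output: the simulator rebuilt the three references from the
packaged panel (98 sites over 34,727 bp); the whole-genome scan recovers the
7/93/96 pairwise difference counts; the amino-acid annotation finds the five
protein-coding genes separating the two *natans* forms; in-silico PCR typing
assigns all 71 simulated specimens (53 *natans VIII*, 13 *natans I*,
5 *fluitans III*) to their true forms with no unknown or conflicting calls;
and the NJ tree places the two *natans* forms together (terminal branch
lengths 2/34727 and 5/34727 substitutions per site against 91/34727 for
*fluitans*), with bootstrap support as the internal node label.

Individual stages are exposed directly:

```r
refs     <- build_references(layout_genes(sarg_variants(), generator_config()))
profiles <- derive_diagnostic_profiles(refs)
typing   <- type_cohort(generate_cohort(refs), profiles)
```

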