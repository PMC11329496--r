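# editclust

Edit-cluster analysis for antibody-directed RNA base-editing experiments.

## The problem

Antibody-directed cytidine deaminase profiling localises an RNA-binding
protein (RBP) on the transcriptome without immunoprecipitation: a deaminase
coupled to the RBP-bound antibody deposits C-to-U edits on nearby
transcript positions, which sequencing reads report as C>T mismatches
(G>A on minus-strand genes). The analytical problem is to turn noisy
per-site mismatch counts — contaminated by artifact editing, SNPs and
nonspecific enzyme activity — into a confident map of binding sites, and to
quantify how specific that map is. `editclust` implements the full chain for
analysts working with such data:

1. **Edit-site calling.** Every covered sense-strand C with at least one
   edited read is scored with the posterior probability that its true edit
   rate exceeds the background, under a Jeffreys prior with binomial
   likelihood: `score = P(p > p_bg | alt, ref) = 1 − I(p_bg; alt+½, ref+½)`,
   where `I` is the regularised incomplete Beta function. Sites with
   score ≤ 0.5, edit fraction ≥ 0.8 (likely SNPs), or a known-SNP overlap
   are discarded.
2. **Cluster detection.** Sliding windows (50 nt, step 10) over annotated
   exons, introns and UTRs are tested with a Poisson model on edit-site
   counts: for a window with `k` edit sites and `n` covered C positions in a
   region class with background site rate `λ₀`, `p = P(Pois(λ₀·n) ≥ k)`.
   Window p-values are Benjamini–Hochberg adjusted genome-wide; windows with
   `q < 0.1` are merged when ≤ 15 nt apart and trimmed to their outermost
   edit sites.
3. **Confident clusters.** Clusters present (≥ 1 nt same-strand overlap) in
   all replicates and absent from buffer-only controls, via strand-aware
   anchored intersection and whole-interval subtraction.
4. **Specificity statistics.** Motif containment of clusters versus 20
   length- and feature-preserving within-exon/intron shuffles
   (`z = (obs − mean(perm)) / sd(perm)`, `enrichment = obs / mean(perm)`),
   nearest-motif distance distributions, reference peak overlap, and an
   editing-radius estimate from case-versus-control distance CDFs.
5. **Isoform-level quantification** from long reads: read filtering
   (mapped, primary, quality ≥ 20, correct strand), removal of putative
   SNPs (positions edited in every sample), per-isoform
   `editsC = Σ edited C / Σ total C` over exons and UTRs, and selection of
   case-elevated isoforms by residuals (> 1.5 sd) of an OLS fit of case on
   control editsC.

A fully seeded synthetic-data generator (`sim_config()`,
`generate_reference()`, `simulate_site_counts()`, `simulate_long_reads()`)
emulates the whole experiment — planted UGCAUG binding sites with a 200 nt
editing radius, uniform background and artifact editing, replicates,
condition-invariant SNP confounders — so every stage can be validated
against a known truth.

## Worked example

The `analysis/` directory holds the complete workflow as numbered drivers.
`01_simulate.R` writes a ~1 Mb toy transcriptome bundle (100 stranded genes,
30 planted motifs, 50 SNPs, 3 replicates of case / enzyme-only /
buffer-only counts) under `results/sim/`; the later steps consume the
previous step's files:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_call_edits.R
Rscript analysis/03_call_clusters.R
Rscript analysis/04_confident_clusters.R
Rscript analysis/05_enrichment.R
Rscript analysis/06_isoform_edits.R
```

Output of steps 03–05 at the default seed:

```
case_rep1               2795 clusters (median width 44 nt)
buffer_only_rep1           0 clusters (median width - nt)
case          2795 clusters in the anchor replicate ->   441 intersected ->   441 confident (84.2% removed)
enzyme_only   2839 clusters in the anchor replicate ->   382 intersected ->   382 confident (86.5% removed)
case         motif fraction 0.082 vs permuted 0.035 +/- 0.006 -> z = 7.58, enrichment = 2.32
enzyme_only  motif fraction 0.024 vs permuted 0.022 +/- 0.007 -> z = 0.19, enrichment = 1.06
planted motifs within 200 nt of a confident case cluster: 100%
editing radius estimate: 178 nt (planted: 200 nt)
```

Reading the numbers: each case replicate carries ~2800 clusters, mostly
nonspecific enzymatic editing above the artifact baseline; replicate
intersection plus buffer subtraction removes ~85% of them. Of the surviving
confident case clusters, 8.2% contain the UGCAUG motif — a 2.3-fold,
z = 7.6 enrichment over within-feature shuffles — while the enzyme-only
control shows none (z = 0.2). All 30 planted binding sites are recovered
within 200 nt, and the case-versus-control distance curves converge at
178 nt, recovering the planted 200 nt editing radius. The long-read step
(`06_isoform_edits.R`) selects 14 confident isoforms, exactly the planted
bound set, with a replicate editsC correlation of r = 0.985.

The same computations are available programmatically through
`run_pipeline(pipeline_config(sim = sim_config(seed = 1)))`.

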