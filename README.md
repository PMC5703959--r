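# pleiocfdr

Pleiotropy-informed conditional false discovery rate (cFDR) analysis for
paired GWAS summary statistics.

Genome-wide association studies of related traits — the shipped worked
example concerns body-mass index (BMI) and type 2 diabetes (T2D) — leave
many true, modest-effect variants below genome-wide significance. The cFDR
leverages the second trait as a conditioning variable: for SNP *i* with
p-values *p₁* (principal trait) and *p₂* (conditioning trait),

    cFDR_i = min(1, p1_i * n_cond_i / n_joint_i)

where `n_cond = #{j : p2_j <= p2_i}` and
`n_joint = #{j : p1_j <= p1_i and p2_j <= p2_i}` (both self-inclusive, ties
counted), i.e. *p₁* divided by the conditional empirical cdf of *p₁* given
*P₂ ≤ p₂*. The **conjunction FDR** — a conservative FDR for association
with *both* traits — is the per-SNP maximum of the two conditioning
directions. Loci are called at `conj_fdr < 0.05` (the Manhattan line at
−log₁₀ 0.05 ≈ 1.3).

The package covers the full pipeline: harmonizing two summary-statistic
tables, sliding-window LD pruning (window 50 / step 5 / r² > 0.2 /
smaller-MAF removal) against a genotype reference panel, cFDR in both
directions, conjunction calls, conditional Q-Q / fold-enrichment /
Manhattan diagnostics, SNP-to-gene annotation, and a two-trait simulator
with known pleiotropic architecture so everything is testable without
external downloads.

## Worked example

The numbered drivers under `analysis/` run the whole study on synthetic
data (20,000 SNPs, 90% null / 4% per-trait / 2% pleiotropic, |z| effect
3, 500-sample panel with 10-SNP LD blocks at ρ = 0.9):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_prune.R
Rscript analysis/03_cfdr_conjunction.R
Rscript analysis/04_enrichment_diagnostics.R
Rscript analysis/05_worked_example.R
```

which prints (abridged):

```
Merged 20000 shared SNPs; 3369 survive LD pruning ( 16631 removed ).
cFDR < 0.05 calls: trait A given B: 120 ; trait B given A: 96 ; conjunction (both traits): 29
conjunction empirical FDR 0.034, power 0.077
Fold enrichment of the p2<=0.001 stratum:
  at -log10 p = 4   pleiotropic: 4.08  | negative control: 0.38
Reproduced the printed conjunction FDR for all 23 loci (max of the directional cFDRs).
Example: rs9930506 conj FDR = 1.9e-10
```

Reading: after pruning, conditioning on the second trait calls 29
conjunction loci of which ~3% are false against the simulation truth
(within the nominal 5% target); the strongly conditioned stratum is
several-fold enriched in small principal p-values while the matched
independent-trait control is not. Stage 5 re-derives, with the package's
own conjunction rule, the conjunction-FDR column of the 23 published
BMI/T2D pleiotropic loci shipped in `inst/extdata/` (e.g. rs9930506 in
*FTO*: max(1.01e−123, 1.90e−10) = 1.90e−10).

Programmatic use mirrors the drivers:

```r
library(pleiocfdr)
cfg   <- sim_config(seed = 1)
sim   <- simulate_two_trait_stats(cfg)
panel <- simulate_reference_panel(cfg)
m     <- merge_common_snps(validate_summary_stats(sim$stats_a),
                           validate_summary_stats(sim$stats_b))
pruned <- ld_prune(m, panel)
conj   <- conjunction_fdr(cfdr_estimate(pruned, "A|B"),
                          cfdr_estimate(pruned, "B|A"))
call_significant(conj, 0.05, "conj_fdr")
```

Real data enter through `read_summary_stats()` (header-bearing TSV with
SNP/CHR/BP/P columns, remappable), `read_reference_panel()` (dosage TSV)
and `read_gene_intervals()` (BED-like); `run_pipeline()` orchestrates a
whole run from a single config with per-stage outputs and a MANIFEST.

## Method notes

See `vignettes/conditional-fdr-methods.Rmd` for the estimator's
derivation and properties, the pruning conventions and tie-breaks, what
the simulator does and does not emulate, and known limitations.
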