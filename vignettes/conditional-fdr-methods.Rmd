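---
title: "Conditional and conjunction FDR for cross-trait GWAS pleiotropy: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional and conjunction FDR for cross-trait GWAS pleiotropy: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Two genome-wide association studies (GWAS) of related traits — the shipped
worked example concerns body-mass index (BMI) and type 2 diabetes (T2D) —
each provide per-SNP association p-values. Many variants with true but
modest effects on both traits sit below genome-wide significance in either
study alone. The conditional false discovery rate (cFDR) borrows strength
across the two studies: a SNP whose p-value is small in *both* traits is
more likely to be a true association than its marginal p-value suggests.

For SNP $i$, let $p_1$ be its p-value in the principal trait and $p_2$ in
the conditioning trait. Over the $N$ analyzed SNPs the conditional
empirical cumulative distribution function of $p_1$ given $P_2 \le p_2$ is

$$\hat F(p_1 \mid P_2 \le p_2)
  = \frac{\#\{j : p_{1j} \le p_{1i},\ p_{2j} \le p_{2i}\}}
         {\#\{j : p_{2j} \le p_{2i}\}}
  = \frac{n_{\text{joint}}}{n_{\text{cond}}},$$

and the cFDR estimate is

$$\widehat{\mathrm{cFDR}}_i
  = \min\!\left(1,\ \frac{p_{1i}\, n_{\text{cond},i}}{n_{\text{joint},i}}\right).$$

This is the conditional analogue of the empirical Bayes reading of the
Benjamini–Hochberg quantity: under the null, $p_1$ is uniform, so
$p_1 / \hat F(p_1 \mid \cdot)$ estimates the fraction of nulls among SNPs
at least as extreme in both coordinates. When the conditioning trait is
uninformative ($p_2 \equiv 1$), the estimator reduces exactly to
$\min(1,\ p_1 N / \mathrm{rank}(p_1))$, the unconditional empirical FDR.

Both counts are *self-inclusive* (SNP $i$ counts itself, ties counted with
$\le$ on both sides), so $n_{\text{joint}} \ge 1$ always: the estimate is
defined for every SNP and, since $\hat F \le 1$, satisfies
$\widehat{\mathrm{cFDR}}_i \ge p_{1i}$ — the estimator never claims more
significance than the nominal p-value.

The **conjunction FDR** — a conservative FDR for association with *both*
traits — is the per-SNP maximum of the two directional estimates,
$\max(\widehat{\mathrm{cFDR}}_{A|B}, \widehat{\mathrm{cFDR}}_{B|A})$.
Loci are called at a strict threshold (`field < alpha`, default
$\alpha = 0.05$; the Manhattan significance line sits at
$-\log_{10} 0.05 \approx 1.3$).

The method consumes p-values only, so it is blind to effect direction and
needs no allele harmonization; it assumes the input statistics were already
genomic-control corrected upstream, and no further correction is applied.

A deliberate design choice: the estimator is the *direct per-SNP empirical
form* above. Interpolated two-dimensional lookup-table variants of cFDR
exist; they smooth the surface at the cost of a model component, and this
package intentionally does not implement one. On the shipped table of 23
published BMI/T2D pleiotropic loci the direct conjunction rule reproduces
the printed conjunction FDR column exactly, and every printed directional
cFDR respects the $\mathrm{cFDR} \ge p$ bound.

## Data preparation

* **Harmonization.** Two summary tables are inner-joined on SNP id; only
  shared SNPs enter the analysis. Coordinates come from the principal
  table; chromosome labels are normalized by stripping a leading `chr`.
* **P-value domain.** cFDR needs $p \in (0, 1]$. Exact zeros (underflow in
  downloaded files) are clamped to $10^{-300}$ with a warning; negative,
  $>1$, or non-numeric values are dropped with a count. Duplicate rs ids
  keep the first occurrence — the original analyses do not state their
  duplicate policy, so this is a documented convention, not a reproduction
  claim.
* **LD pruning.** Within each chromosome a window of 50 surviving SNPs is
  scanned; for every pair with dosage $r^2 > 0.2$ (squared Pearson
  correlation of 0/1/2 genotype dosages from a reference panel — composite
  LD, since the panel is unphased) the smaller-MAF member is removed,
  removals taking effect immediately in pair order $(i, j)$ by position;
  the window then slides 5 surviving SNPs forward, and whole-chromosome
  passes repeat until nothing is removed. Equal MAFs remove the
  larger-position member (deterministic tie-break; the source analyses are
  silent). SNPs absent from the panel are retained unconditionally and
  pairs involving them are skipped, because their $r^2$ cannot be
  evaluated. `verify_pruned()` re-scans every window-length run of
  survivors as a postcondition. Whether the original analyses rescanned
  after each single removal or each window pass is unstated; the
  convention here is fixed, documented, and oracle-tested, not asserted as
  theirs.

## Diagnostics

* **Conditional Q-Q curves.** For each conditioning level
  $t \in \{1, 0.1, 0.01, 0.001\}$ (the conventional decade strata; the
  figures in the motivating analyses do not print their cutoffs), the
  stratum $S_t = \{i : p_{2i} \le t\}$ is sorted by $p_1$ and plotted as
  empirical cdf position $k/|S_t|$ against $-\log_{10} p_{1(k)}$. Within a
  curve $y$ is non-increasing in $x$ by construction. Pleiotropic
  enrichment appears as the strongly conditioned strata lifting above the
  all-SNPs curve.
* **Fold enrichment.** $\mathrm{fold}(t, x) = $ proportion of $S_t$ with
  $-\log_{10} p_1 \ge x$ divided by the same proportion among all SNPs,
  on a grid $x = 0, 0.1, \dots, 10$; $x = 7.3$ is the genome-wide
  significance point ($p = 5 \times 10^{-8}$). Grid points with an empty
  denominator are omitted, and the underlying counts are returned so
  callers can judge estimability: the ratio is statistically meaningful
  only where the stratum tail holds a reasonable count (the stability
  checks in the test suite require at least 50 stratum SNPs above $x$).
* **Separation measure.** `qq_separation()` reports both the maximum and
  the mean vertical gap between two strata over a grid of cdf positions.
  In small strata (a $t = 10^{-3}$ stratum of a 20,000-SNP null screen
  holds ~20 SNPs) the *max* gap is dominated by order-statistic noise —
  single points can deviate by half a $-\log_{10}$ unit or more under
  perfect independence — so systematic enrichment is judged on the *mean*
  gap, which stays well below 0.3 under independence at this scale.

## The simulator

`simulate_two_trait_stats()` draws each SNP's component from the mixture
(null / A-only / B-only / pleiotropic), defaults
$\pi = (0.90, 0.04, 0.04, 0.02)$; causal z-scores are
$\mathcal{N}(\pm\mu, 1)$ with random sign (defaults $\mu_A = \mu_B = 3$,
chosen so true effects straddle the genome-wide threshold rather than
separate cleanly), nulls are $\mathcal{N}(0,1)$, and
$p = 2\Phi(-|z|)$. SNPs are laid out as rs1..rsM in contiguous chunks on
22 chromosomes, 10 kb apart. The default screen size is 20,000 SNPs — big
enough that empirical-cdf estimates are stable and the full pipeline still
runs in seconds.

`simulate_reference_panel()` builds genotypes per LD block of 10
consecutive SNPs: two haplotypes per sample from a Gaussian copula with
exchangeable latent correlation $\rho = 0.9$, each SNP thresholded at the
quantile of its MAF (drawn uniformly from $[0.05, 0.5]$), summed to a
0/1/2 dosage; blocks and chromosomes are independent. Note that
thresholding bounds the attainable dosage correlation below the latent
$\rho$ when the pair's MAFs differ strongly — a property of real
genotypes too — so "high LD" fixtures in the tests use narrowed MAF
ranges. The panel consumes the RNG stream at `seed + 1` so statistics and
panel draws never interleave.

The matched negative control (`negative_control_config()`) keeps each
trait's marginal causal rate (0.06) but assigns the two traits' causal
labels independently, mimicking conditioning on a genetically unrelated
trait; chance label overlap (~0.36% of SNPs) is genuinely pleiotropic and
is labelled as such in the truth table.

**What the simulator does not emulate:** LD-induced correlation among the
*test statistics* (effects are independent across SNPs; the panel carries
all LD, so pruning is exercised structurally but the cFDR stage sees
exchangeable statistics), sample-overlap correlation between the two
traits' z-scores, and MAF–effect-size coupling. Passing tests therefore
demonstrate the estimator's arithmetic, calibration, and qualitative
enrichment behaviour — not robustness to correlated statistics or
overlapping cohorts.

## Calibration and test design

Simulation-backed checks in the test suite use seeds 1–10 (controls pair
seed $s$ with $s + 1000$), fixed once:

* Under the default pleiotropic architecture, conjunction calls at
  $\alpha = 0.05$ exceed the matched control's in every seed pair (~200
  vs ~17), and the empirical conjunction FDR among calls averages ~0.08,
  within the $2\alpha$ soft bound expected of this conservative
  estimator.
* The fold-enrichment check at the genome-wide point uses $\mu = 4$ and
  pools counts over the ten seeds: at $\mu = 3$ the stratum tail above
  7.3 has Poisson mean near 1, so any single-seed fold there is mostly
  noise (the expectation, ~5.4, is nearly the same at both $\mu$; only
  the counts differ).
* These stochastic checks run the cFDR stage on the merged, unpruned
  simulated set: the statistics are independent across SNPs by design, so
  pruning would only subsample them. Pruning has its own exact
  oracle-equivalence and postcondition checks, plus the end-to-end
  pipeline run.

Numerical details: the table-wide dominance counts
$n_{\text{joint}}$ are computed exactly (ties included) with a Fenwick
tree over dense $p_1$ ranks swept in $p_2$-tie groups, $O(N \log N)$, and
are verified against an $O(N^2)$ double-loop oracle on random tied
instances up to $N = 2000$; results are independent of input row order.
Written tables serialize doubles at 17 significant digits so a read
round-trip is bit-identical. Constant dosage rows are treated as unlinked
(correlation undefined); $-\log_{10}$ values are capped at 300 for plot
data only.

## Limitations

* The per-SNP empirical estimator is conservative and, like all cFDR
  variants, inherits any sample overlap between the two GWAS as
  anti-conservative pressure it cannot see; with truly overlapping
  cohorts the conjunction calls should be read qualitatively.
* "Independent loci" are equated with post-pruning SNPs; no secondary
  clumping of the called set is performed.
* Annotation is interval logic only (`within_gene` / `intergenic` with up
  to two flanking genes inside 1 Mb, smallest enclosing interval wins,
  alphabetical tie-break): sub-genic roles (intronic, UTR) need
  transcript models and are out of scope, as are GO-term enrichment and
  protein-interaction lookups, which depend on live external databases.
* Real reference panels (e.g. HapMap-derived) must be exported to the
  documented dosage TSV contract; no PLINK/VCF parsing is included.
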