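---
title: "Rare-variant cis discovery with rarecis: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-variant cis discovery with rarecis: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Whole-genome sequencing of population biobanks makes it possible to ask
whether *rare noncoding* variants — singletons included — affect
quantitative molecular traits such as circulating protein levels.
`rarecis` implements a complete cis-locus discovery procedure for this
setting: per-genotype quality filtering, variant classification and
annotation masks, single-variant association with conditional-joint lead
selection, rare-variant aggregate testing under layered conditioning, a
stepwise aggregate-independence procedure, sequencing-coverage QC, and
regulatory-region enrichment with empirical significance thresholds. A
synthetic-locus simulator generates every input the pipeline consumes, so
the whole chain is testable without controlled-access cohort data.

## Statistical model

For each protein, the phenotype is rank-inverse normalized at analysis
time, $\tilde y_i = \Phi^{-1}\!\big((r_i - c)/(n - 2c + 1)\big)$ with the
Blom offset $c = 3/8$ and average ranks for ties. All models are ordinary
least squares with covariates $X$ (here: age, sex, four PC-like
covariates, assay batch; the full epidemiological covariate set of a real
cohort is a drop-in replacement). Covariates are projected out of the
phenotype and the dosages once (Frisch–Waugh), which is exactly
equivalent to refitting them in every model and is asserted as a test.

**Single variants.** Every variant with minor allele count (MAC) of at
least 5 is tested by OLS of $\tilde y$ on dosage. Two-sided P values are
computed entirely in log space,
$\log_{10} P = \log_{10}(e)\,\big(\texttt{pt}(-|\beta/\mathrm{se}|,
\nu, \log{=}\mathrm{TRUE}) + \log 2\big)$,
so extreme statistics never underflow. The degrees of freedom default to
the residual $n - k - 2$ inside the scan; the standalone helper defaults
to $\nu = n - 2$ with a switch, since summary-level tools conventionally
ignore the covariate count.

**Conditional-joint selection.** Lead variants are selected by a
forward–backward stepwise procedure (threshold $2.95\times10^{-10}$).
Because the LD reference *is* the discovery sample, we implement the
conditional steps by residualization on individual-level data: the
conditional statistics are then exactly the corresponding
multiple-regression statistics, and the final joint estimates equal a
direct all-in-one regression (tested to $10^{-8}$). The
variance-explained-ratio collinearity filter found in summary-statistic
implementations is deliberately absent — with a matched LD panel it
removes genuine large-effect signals — and is replaced by a pairwise
dosage $r^2 > 0.99$ guard that keeps joint fits non-singular. Forward
ties break by smaller P, then larger MAC, then position. The `diff_freq`
argument is retained as an interface no-op: panel and sample frequencies
are identical by construction here.

**Aggregate tests.** Rare variants (MAF < 0.1%) are grouped into units:
gene-centric coding and proximal units, active regulatory regions,
constraint windows ($z \ge 4$), conserved windows (phastCon 99th
percentile, exon-free) and 2-kb sliding windows advancing 1 kb (coding
variants never enter noncoding units; the trailing partial window at the
3' edge is emitted so edge variants stay covered). Per unit and mask we
run:

* **Burden** — OLS on the weighted carrier score
  $b_i = \sum_j w_j g_{ij}$, $w_j = \mathrm{Beta}(\mathrm{MAF}_j; 1, 25)$,
  assuming shared direction;
* **SKAT** — $Q = \sum_j w_j^2 S_j^2$ with per-variant scores $S_j$; the
  null is the mixture of $\chi^2_1$ variables whose weights are the
  eigenvalues of the projected, weighted genotype cross-product times the
  residual variance, rescaled to the exact permutation mean and variance
  of the statistic for multi-variant kernels (with sparse carriers the
  plain Gaussian mixture overstates the null variance by $O(1/n)$;
  single-variant units skip the rescaling so they reduce exactly to the
  score test). Tail probabilities come from numerical inversion of the
  characteristic function in the body of the distribution, a log-space
  saddlepoint approximation below $10^{-5}$ — beneath the quadrature's
  absolute noise floor — and a permutation fallback for numerics that
  fail;
* **ACAT-V** — Cauchy combination
  $T = \sum_j \tilde w_j \tan\big((0.5 - p_j)\pi\big)$; the combined p is
  the standard-Cauchy upper tail, evaluated as $\arctan(1/T)/\pi$ for
  $T > 0$ to retain full relative precision (p values are clipped to
  $[10^{-300}, 1 - 10^{-16}]$ so the tangent stays finite);
* **ACAT-O** — equal-weight Cauchy combination of the three;
* **Singleton** — the burden test restricted to MAC = 1 members;
* **All-mask** — Cauchy combination of the per-mask omnibus p values,
  never mixing coding and noncoding masks.

The weight scheme is the Beta(1, 25) convention; the published analysis
this procedure follows does not state its internal weights, so the
reduction laws (every test on a single-variant unit equals the
corresponding single-variant test) and a permutation oracle define
correctness instead.

**Layered conditioning.** Noncoding discovery adjusts for (1) the common
joint leads (MAF > 0.1%) plus *every* coding variant of the cognate gene
regardless of significance; (2) a forward stepwise pass that repeatedly
records the most significant aggregate (by omnibus p; ties by smaller
span, then position), adds all of its member variants to the
conditioning set and re-tests the remaining significant aggregates until
none passes $8.71\times10^{-9}$; (3) per-aggregate flags counting member
lead variants and study-wide-significant members; and (4) a sensitivity
re-test conditioning on all identified pQTLs. Conditioning is
implemented by projection, so aggregate statistics are exactly
conditional; conditioning on a unit's causal variants drives its
rejection rate back to the nominal level (tested).

**Coverage QC.** From a per-base track of the number of samples with
depth > 8 (strict), a base passes when more than 90% of samples do, and
a protein passes when both the UTR-to-UTR gene body and the full
cis-window have strictly more than 99.5% of bases passing. Proteins
whose maximum marginal-vs-joint $|\Delta\beta|$ exceeds the empirical
90th percentile (type-7 quantile, strictly greater) are excluded.
Exclusion is modelled against problematic-region overlap counts by
logistic regression adjusting for window length, with a Firth-penalized
refit under separation (written in-package; no penalized-logistic
dependency is declared).

**Enrichment and thresholds.** Consequence-category enrichment uses
exact two-sided Fisher tests with a Bonferroni flag at $0.05/k$.
Regulatory-region enrichment draws `n_sim` random signal sets of the
observed size from the tested candidate pool (without replacement, a
flag switches to with-replacement) and reports the plus-one empirical p
$(1 + \#\{\mathrm{sims} \ge \mathrm{obs}\})/(1 + n_\mathrm{sim})$, which
can never be zero. Significance thresholds are reproduced procedurally:
20 standard-normal null traits are scanned end-to-end and the minimum
single-variant and aggregate P values become the thresholds; the
pipeline's defaults are the published constants
($2.95\times10^{-10}$, $8.71\times10^{-9}$).

## The simulator and what it does (not) emulate

`simulate_locus()` draws variant sites with an allele-frequency spectrum
specified as mixture weights over five bins (singleton, MAC 2–5,
MAF < 0.1%, 0.1–1%, > 1%); alt alleles are placed on randomly chosen
haplotypes so each variant's MAC is exact and genotypes are
Hardy–Weinberg. Variants are independent by default — which keeps the
analytic oracles exact — with an optional block-LD mode that re-places
rare alleles onto a common background haplotype to exercise conditional
analysis. Consequences follow position in a two-transcript gene model
(UTRs, exons, introns, 5-kb proximal flanks); GERP/CADD/JARVIS/SpliceAI
scores come from simple parametric distributions; regulatory regions,
constraint and conservation tracks are drawn uniformly.

Phenotypes are $y = \sum_j \beta_j g_j + X\gamma + \varepsilon$. Causal
effect magnitudes are half-normal, scaled so rare noncoding effects
average $|\beta| = 1.15$ s.d. with 65.2% decreasing, and coding effects
average 1.55 s.d. (set from the reported ratio of noncoding to missense
effect sizes) with 86.3% decreasing. At reduced sample sizes where
MAF < 0.1% is unattainable, the MAC ≤ 5 bins stand in for the rare
class. Raw calls attach mixture-Poisson depths split into allelic depths
by genotype, genotype qualities below 10 at a configurable
per-component rate, and a per-base pass-count track exactly consistent
with the per-genotype depths at variant sites.

The simulator does **not** model coalescent haplotype structure,
realistic LD decay, batch covariance of the assay, sequencing reads or
structural variants. Passing tests therefore demonstrate the
correctness and calibration of the statistical machinery under the
stated generative model, not robustness to every pathology of real
cohort data.

## Numerical choices and defaults

* Intervals are 0-based half-open internally; VCF/GFF positions convert
  at the I/O boundary. A variant at a window's half-open end belongs to
  the next window only.
* All score-mask thresholds are strict (> 2 GERP, > 25 CADD, > 0.99
  JARVIS, > 50 SpliceAI); constraint $z \ge 4$ and the phastCon 99th
  percentile are inclusive; a single base of exon overlap excludes a
  conserved window.
* Genotype calls go missing when sum(LAD) < 8 *or* GQ < 10 (strict);
  variants with missingness strictly above 10% are dropped; missing
  dosages are mean-imputed for regression only, frequencies always come
  from observed calls.
* The cis-window uses the union of transcript UTR extremes by default
  with a longest-transcript mode available (`define_cis_window(mode=)`);
  the two conventions differ and both are supported rather than
  asserting either as canonical.
* Empirical p values are plus-one corrected; bootstrap draws are without
  replacement; aggregate-interval overlap counts any-overlap per region
  set.
* Default problem sizes (2,000 samples, 3,000 variants in a 200-kb
  window for the end-to-end fixture; 5,000 samples for power studies)
  are the package's reduced-scale study conditions; the acceptance
  script and tests state the sizes they use.
* All randomness flows from one integer seed through a splittable
  sub-seed helper, making every stage and the whole pipeline
  reproducible byte-for-byte.

## Known limitations

Mixed-model association (whole-genome ridge, relatedness) is out of
scope: samples are modelled as unrelated and fixed-effects OLS is used
throughout. Multi-allelic splitting and indel normalization are assumed
done upstream. The mask catalogue implements the explicitly specified
masks plus an unscored all-noncoding mask; a cohort-specific catalogue
can be supplied as configuration. ACAT-type combinations of dependent
tests are only asymptotically exact at small significance levels; their
empirical size at $\alpha = 0.05$ is verified by simulation in the test
suite rather than by theory.
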