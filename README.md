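# isodiet

Reconstructs what a consumer ate — proportionally, by diet category — from
carbon, nitrogen and sulfur stable-isotope ratios measured in bone
collagen, and tests how diet composition changed across historical
periods. It is written for isotope ecologists and archaeozoologists who
have: consumer collagen measurements (δ¹³C, δ¹⁵N, δ³⁴S with elemental
%C/%N/%S) spanning periods and regions, diet-item measurements with
elemental concentrations, and literature trophic discrimination factors
(TDFs).

The pipeline, in the order the functions are meant to be used:

1. **Quality control** (`run_qc`): excludes diagenetically altered
   collagen (atomic C:N ∉ [2.9, 3.6], C:S ∉ [300, 900], N:S ∉ [100, 300],
   %S ∉ [0.15, 0.35]) and nursing-age or unknown-age animals.
2. **Source pooling** (`pairwise_source_tests`, `merge_sources`): a
   K-nearest-neighbour randomisation test decides which diet categories
   are isotopically distinguishable; indistinguishable ones are pooled
   (Bonferroni-adjusted threshold derived from the pair count).
3. **Temporal correction** (`correct_sources_for_period`): places modern
   diet-item δ¹³C (optionally δ¹⁵N) on a historical period's isotopic
   scale (Suess effect); δ³⁴S is never corrected.
4. **Mixing model** (`fit_mixing_model`): a concentration-dependent
   Bayesian mixing model. For consumer *i*, channel *j*:

   X_ij ~ N( Σ_k p′_jk (μ_jk + λ_j),  Σ_k p′²_jk (ω²_jk + τ²_j) + σ²_j ),
   p′_jk = p_k q_jk / Σ_l p_l q_jl

   with a Dirichlet(1) prior on the diet proportions **p**, Uniform(0, 20‰)
   priors on the residual SDs σ_j, TDF means λ ± SD τ (defaults
   5.0±1.5, 3.0±1.5, 1.0±0.5 ‰ for C/N/S collagen), and source
   concentrations q weighting the mass balance. Sampled by adaptive
   random-walk Metropolis on the additive-log-ratio transform
   (1,000,000-iteration reference configuration; diagnostics: split-R̂,
   ESS, acceptance).
5. **Summaries and comparisons**: posterior modes, 50/75/95% highest
   density regions, HDR-overlap letter displays (`summary`, `hdr`,
   `hdr_overlap_letters`); Kruskal–Wallis, Steel–Dwass and Wilcoxon period
   comparisons (`kruskal_wallis`, `steel_dwass`, `wilcoxon_rank_sum`);
   period assignment, time-series binning and a change-point readout
   (`assign_period`, `binned_series`, `change_point`); all orchestrated by
   `run_pipeline`.

A synthetic-data module (`scenario`, `study_scenario`,
`generate_sources`, `generate_consumers`) generates datasets with known
true diet proportions, planted QC failures and temporal drift, so the
whole pipeline is verifiable without access to any original specimens.

## Worked example

Reconstruct the pre-development ("Period 1") diet on the packaged
synthetic scenario — 30 consumers whose true diet is 64% terrestrial
animals, 19% salmon, 12% C₃ herbs, 5% C₃ fruits (corn is excluded from
Period 1: it postdates that period's agriculture):

```r
library(isodiet)
sc        <- study_scenario(n_consumers = 30, seed = 1)
sources   <- generate_sources(sc)
consumers <- generate_consumers(sc, "period1")

qc   <- run_qc(consumers)                                  # collagen + age QC
pw   <- pairwise_source_tests(sources, n_perm = 999, seed = 1)
part <- merge_sources(pw, sources)                         # pool if needed
avail <- setdiff(part$groups$names, "corn")                # corn: not in Period 1
corrected <- correct_sources_for_period(                   # Suess +1.6 permil
  isodiet:::subset_source_groups(part$groups, avail), "period1",
  correction_config())

fit <- fit_mixing_model(qc$clean[, c("d13C", "d15N", "d34S")], corrected,
                        config = mixing_config(n_iter = 1e5,
                                               burn_in = 2e4, seed = 1))
summary(fit)
```

```
Diet proportions (posterior):
             source  mean  mode          hdr95      ess  rhat
           C3_fruit 0.074 0.035 [0.000, 0.166]  337.000 1.000
            C3_herb 0.046 0.008 [0.000, 0.106]  270.714 1.009
             salmon 0.195 0.198 [0.170, 0.219] 1082.000 1.000
 terrestrial_animal 0.685 0.689 [0.620, 0.749] 1280.946 1.002
Residual SD (permil):
 channel  mean    sd
    d13C 0.691 0.371
    d15N 0.975 0.424
    d34S 0.749 0.199
```

Reading this: the posterior puts terrestrial animals at a mean 68.5%
(truth 64%), salmon at 19.5% (truth 19%) with a tight 95% HDR because
salmon's δ³⁴S/δ¹⁵N signature is distinctive, and the two plant groups
jointly near 12% (truth 17%) — plants share similar elemental
concentrations so their split is the least-informed direction. `rhat`
near 1 and effective sizes in the hundreds-to-thousands indicate the
chains mixed. `plot(fit)` draws the nested 95/75/50% HDR boxes per
source; `hdr_overlap_letters` letters periods whose 95% HDRs overlap.

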