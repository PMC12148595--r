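# aesthsim

Can a mental image move you the way a painting in front of your eyes
does? `aesthsim` is an R package for studying whether aesthetic
experiences evoked by **visual perception** and by **mental imagery** are
behaviorally equivalent, and how strongly stimulus modality, evoked
experience and stimulus type are encoded in multivoxel fMRI patterns. It
is aimed at cognitive neuroscientists and psychologists who want a fully
verifiable version of this two-track analysis: every stage is driven by a
synthetic-data generator that plants *known* effects and *known*
representational geometries, so the whole pipeline can be validated by
parameter and model recovery without any raw study data.

## What the package computes

**Behavioral track.** Subjects rate stimuli (artworks and faces) on
7-point scales (pleasure, beauty, being moved), once while viewing and
once while imagining each stimulus, reporting imagery vividness `v` on
each imagery trial. The package:

* fits a hierarchical Bayesian **cumulative probit** model per rating
  dimension,
  `P(Y <= k) = Phi(tau_k - (beta_mod * imagery + beta_type * face + u_subj + u_stim))`,
  with flexible ordered thresholds `tau`, `normal(0, 1)` coefficient
  priors, `student_t(3, 0, 2.5)` threshold priors and half-t random
  intercept SDs. The latent residual SD is fixed at 1, so coefficients
  are standardized effects (`beta_stand`). Sampling is by an adaptive
  Metropolis-within-Gibbs scheme with interweaved moves along the weakly
  identified directions; split-R-hat and ESS are attached to every fit;
* computes the per-stimulus **cross-modality dissimilarity score**
  `S = sum_d (rating_perception,d - rating_imagery,d)^2` (0 = identical
  experiences, theoretical maximum 108), and regresses it on vividness
  with a Student-t hierarchical model (standardized slope);
* runs **ROPE equivalence tests**:
  `BF01 = [P_post(|beta| < 0.1) / P_post(|beta| > 0.1)] / [P_prior(...) / P_prior(...)]`,
  with the prior mass computed analytically.

**Neural track.** Per subject, 8 condition patterns (high/low moving
experience x perception/imagery x art/face; canonical order HPA, LPA,
HPF, LPF, HIA, LIA, HIF, LIF) are z-scored and converted to a **neural
RDM** of squared Euclidean distances. Nine theory-derived candidate RDMs
(Independent; Modality; Experience; Type; Mod|Exp|Type; Mod|(Exp|Type)/2
and /3; Exp|(Mod|Type)/2 and /3; optionally the partial Exp|Type model)
are compared to each subject's RDM with **whitened cosine similarity**
`s = d1' V^-1 d2 / sqrt((d1' V^-1 d1)(d2' V^-1 d2))`, where `V` is the
covariance structure of squared-distance estimates under isotropic noise
(`V` proportional to the elementwise square of `C C'`, `C` the pairwise
contrast matrix; an identity mode gives the plain cosine). Uncertainty
comes from resampling subjects 2000 times; performance is bracketed by a
leave-one-out **noise ceiling**; models are compared pairwise (paired t,
BH-FDR q < 0.01), against zero, and against the lower ceiling bound
(Bonferroni).

**Generator.** `generate_ratings()` plants ordinal effects with
subject/stimulus intercepts and a vividness-coupled divergence term;
`generate_patterns()` plants any weighted modality/experience/type
geometry by embedding the double-centered distance matrix in voxel space
per subject (plus Gaussian channel noise and between-subject geometry
variability). Everything is seeded and reproducible.

## Worked example

```r
library(aesthsim)
res <- run_pipeline(modifyList(default_config(),
                               list(out_dir = "demo-run", seed = 7)))
res$evaluation
```

With the default study conditions (34 subjects, 20 artworks + 20 faces,
a planted modality effect of -0.29, and a planted pure-modality neural
geometry at 200 voxels) this prints:

```
Model evaluation (distance-covariance whitening, 2000 bootstrap resamples)
            model   mean    sem  ci_lo  ci_hi
      Independent 0.3883 0.0047 0.3808 0.3986
         Modality 0.9940 0.0050 0.9833 0.9999
       Experience 0.0137 0.0070 0.0024 0.0293
             Type 0.0172 0.0161 0.0006 0.0503
     Mod|Exp|Type 0.5917 0.0071 0.5802 0.6074
 Mod|(Exp|Type)/2 0.8242 0.0033 0.8185 0.8311
 Mod|(Exp|Type)/3 0.9084 0.0016 0.9055 0.9118
 Exp|(Mod|Type)/2 0.4240 0.0068 0.4122 0.4383
 Exp|(Mod|Type)/3 0.3173 0.0068 0.3057 0.3316
```

The planted Modality model wins (0.994) and reaches the noise ceiling
(`res$ceiling`: lower 0.9939, upper 0.9942) — the generator's geometry is
recovered exactly as a well-specified model should be, while every
misspecified candidate sits significantly below the ceiling. On the
behavioral side, the ordinal fit of "moving" returns
`beta_modality = -0.149 [-0.223, -0.068]` on the full data (the planted
-0.29 attenuated by the vividness-coupled noise, which deliberately
violates the equal-variance probit assumption) and
`-0.269 [-0.374, -0.159]` in the high-vividness subset, and the
standardized vividness slope on the dissimilarity score is
`-0.285 [-0.335, -0.234]`: less vivid imagery diverges more from
perception. The ROPE Bayes factor for the subset modality effect is
0.004 — evidence *against* equivalence, correctly so, because this
generator plants a modality effect that persists at high vividness;
planting `beta_modality = 0` flips BF01 far above 3 (see the acceptance
tests).

`run_pipeline()` also writes the full dataset (TSV ratings, NIfTI
patterns + JSON sidecar, manifest), posterior summaries, evaluation and
comparison tables, RDM heatmap and model bar plot, and a Markdown report
under `out_dir`. A shell wrapper lives at
`inst/scripts/run_pipeline.R`.

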