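# serogp — additive Gaussian process modelling of longitudinal serum proteomes

`serogp` is for proteomics and biostatistics practitioners who follow serum
(or plasma) protein levels in young children — or any small longitudinal
cohort — and need to know *which* covariates drive each protein's trajectory:
age, sampling season, gender, living environment, or simply the individual.
Parametric mixed models force a functional form on the age trend; `serogp`
instead fits each protein with an additive Gaussian process and selects
covariates by cross-validated predictive density.

## The model in brief

For one protein's standardised log2 trajectory,

    y = f_age(a) + f_season(s) + f_gender(g) + f_location(l) + f_id(u)
        + f_age×id(a, u) + ε,     ε ~ N(0, σ²)

with independent GP priors: a squared-exponential kernel on age, a periodic
kernel (period 12 months) on season, block-constant categorical kernels for
gender/location/subject, and an SE × subject product kernel giving each child
its own smooth age deviation. The 2⁴ = 16 subsets of {age, season, gender,
location} (always keeping the subject and noise terms, with age × id tied to
age) are scored by mean log predictive density — exact closed-form
leave-one-out CV for time-varying covariates, leave-subject-out stratified CV
for subject-constant ones — and a covariate is called significant when its
ΔMLPD ≥ 0.05 nats and its variance share in the best model is ≥ 1%.

Around the model sits the full pipeline: MaxQuant-style `proteinGroups`
filtering (decoy/site-only removal, <2 unique peptides, <25% of runs;
replicate medians; <50% of samples; no imputation, ever), child-specific
Z-score summaries with age-bin averages and trajectory clustering, paired
fold changes between batch-mates, a paired rank-product test with
permutation-based pfp plus BH-adjusted Spearman correlations for comparing
cord-blood and follow-up proteomes, SRM normalisation against A1BG, and a
synthetic-data generator reproducing the cohort design with known ground
truth.

## A worked example

```r
library(serogp)

ann  <- simulate_design(study_design(n_subjects = 8), seed = 42)
prot <- simulate_protein(ann, effect_config(age = 1, id = 0.5), seed = 7)
df   <- data.frame(y = prot$value, age = ann$age_months, id = ann$subject_id)
df   <- df[!ann$is_cord, ]

fit <- agp(y ~ age + id + age:id, df, seed = 1)
summary(fit)
#> Additive Gaussian process fit
#>   call: agp(formula = y ~ age + id + age:id, data = df, seed = 1)
#>   n = 48; response mean 28.81, sd 1.257 (log2 scale)
#>
#>  component kind  variance lengthscale     share
#>        age   se 0.2527000       5.718 1.819e-01
#>         id  cat 0.0000132          NA 4.481e-10
#>     age:id prod 0.3587000      46.880 2.933e-01
#>   noise variance 0.4584 (share 0.5249)
#>   log marginal likelihood -60.61
```

The summary reads: of this protein's variance (on the standardised scale),
about 18% is attributed to the shared age trend (lengthscale ≈ 5.7 months, so
most change happens early), 29% to child-specific smooth deviations, and the
rest to noise; the subject-offset term collapsed to nothing. Covariate
selection over all 16 candidates:

```r
select_effects(prot$value, ann, seed = 1)
#> Additive GP covariate selection (16 candidate models)
#>   best model: age+location
#>  covariate delta_mlpd   share significant
#>        age  1.608e-01 0.19670        TRUE
#>     season  1.904e-07 0.00000       FALSE
#>     gender  1.143e-06 0.00000       FALSE
#>   location  1.250e-02 0.02883       FALSE
```

Age is flagged (ΔMLPD = 0.16 nats, well above the 0.05 threshold, with a 20%
variance share); location rides along in the best model but falls short of
both thresholds and is correctly not flagged — this protein was simulated
with an age effect and individual variation only.

The whole pipeline (ingest → select → summarize → cordcompare) runs off one
configuration:

```r
cfg <- pipeline_config(outdir = "run", seed = 7)
run_pipeline(cfg)            # TSV reports + manifest.json under run/
```

or from the shell via `inst/exec/serogp-pipeline all --outdir run --seed 7`.

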