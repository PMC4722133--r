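# svhdecay

Tools for characterising the time course of short-term vestibular
forgetting.

## The problem

Accelerating a seated subject in a swing-out gondola centrifuge creates a
conflict inside the organ of balance: the semicircular canals register a
large roll displacement (66° at 2.5G) while the otolith organs keep
signalling "upright".  The resulting sensation of tilt — recorded as the
subjective visual horizontal (SVH), the orientation a subject gives a
luminous line in darkness, in degrees, right tilt positive — fades over
minutes.  Whether that fading follows an exponential or a power law is the
classic open question of the forgetting-curve literature, and the answer is
easily distorted by *how* data are pooled: averaging truly exponential
decays with heterogeneous rates produces group curves that a power function
fits almost as well.

`svhdecay` implements the full analysis for anyone working with this
paradigm (vestibular psychophysicists, memory researchers, biostatisticians):

* per-run unweighted least-squares fits of the two candidate retention
  functions, SVH(t) = *A*·e^(−*bt*) + *C* and SVH(t) = *A*·t^(−*b*) + *C*,
  via a deterministic multistart variable-projection search
  (`fit_decay()`), with the time constant *T* = 1/*b*;
* run → individual → group aggregation with the run-averaging convention
  (`average_runs()`, `individual_summaries()`, `group_summary()`) and the
  RMS model contest with a paired t-test (`model_contest()`,
  `contest_from_rms()`);
* group pooling by time-binning or by concatenating all settings
  (`pool_binned()`, `pool_all_points()`) plus data-set discriminability
  diagnostics (`discriminability_check()`);
* a study-conformant synthetic cohort generator with returned generating
  truth (`sample_cohort()`), multi-trace sum-of-exponentials series
  (`multi_trace_series()`), and the end-to-end aggregation-artifact
  experiment (`aggregation_experiment()`);
* centrifuge stimulus kinematics (`centrifuge_kinematics()`) and settings
  file I/O / study-style table rendering (`read_settings()`,
  `render_tables()`).

The reported per-run tables of the original 27-subject 2.5G study ship with
the package (`study_exponential_fits()`, `study_power_fits()`,
`study_rms()`) as reference inputs.

## Worked example

```r
library(svhdecay)

coh <- sample_cohort(cohort_config(seed = 42))   # 27 subjects, 44 runs
s <- coh$series[[1]]
s
#> <setting_series> subject S01 run 1: 22 settings, t in [12.3, 348.0] s, SVH in [-5.5, 24.0] deg (2.5G)

fit_decay(s, "exponential")
#> <decay_fit> subject S01 run 1, exponential: A = 29.42, b = 0.01311, C = -0.7147 | RMS = 2.150 deg (n = 22)
fit_decay(s, "power")
#> <decay_fit> subject S01 run 1, power: A = 144.7, b = 0.07821, C = -93.28 | RMS = 2.417 deg (n = 22)
```

The exponential fit recovers the generating parameters of that run
(A = 26.8, b = 0.0136, C = 1.2, noise SD 2.1) within sampling error, and its
RMS beats the power fit; note the power family's characteristically
unphysiological asymptote (−93°).  The same comparison across the whole
cohort, at every pooling level:

```r
aggregation_experiment(cohort_config(seed = 42))
#> <aggregation_report> 44 runs; exponential wins 91% per run
#>   mean per-individual RMS gap ratio (power/exp): 1.173
#>   binned k=15: gap ratio 0.990
#>   binned k=5: gap ratio 0.717
#>   all points: gap ratio 1.001
```

Per individual run the exponential wins in 91 % of cases, but once all
settings are pooled the RMS gap ratio collapses to 1.00 — the aggregation
artifact.  The reported study tables give the empirical analogue:

```r
contest_from_rms(study_rms())
#> <model_contest> 44 runs; power RMS smaller in 4
#>   mean RMS (run-averaged individuals): exponential 2.416, power 3.160 (+30.8%)
#>   paired t = 5.133, df = 26, p = 2.4e-05
```

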