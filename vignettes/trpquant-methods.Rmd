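---
title: "Methods: quantifying light-dependent TRP channel phosphorylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying light-dependent TRP channel phosphorylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trpquant)
```

## Scope and design

The *Drosophila* TRP channel, the major light-activated cation channel of
the photoreceptor, is phosphorylated at many C-terminal sites, and the
phosphorylation state of several of these sites depends on illumination.
`trpquant` implements the quantitative procedures needed to characterize
such regulation from four kinds of measurements:

1. **Label-free LC-MS phosphopeptide quantification** (`filter_charge()`,
   `normalize_runs()`, `select_quantifiable()`, `quantify_sites()`,
   `classify_sites()`): relative phosphopeptide abundance between
   light- and dark-adapted flies across replicate LC-MS runs.
2. **Quantitative Western-blot densitometry** (`normalize_lane()`,
   `linearity_check()`, `relative_phosphorylation()`,
   `timecourse_normalize()`): phosphospecific-antibody signals normalized
   to total-protein signals of the same lane.
3. **Phosphate occupancy** (`occupancy()`, `apparent_occupancy()`,
   `invert_occupancy()`): the fraction of channel subunits phosphorylated
   at a site, estimated from immunoprecipitation signal quadruples,
   together with a binomial model of the tetramer co-precipitation bias.
4. **Candidate-screen hit calling** (`call_initial_hits()`,
   `confirm_hits()`, `summarize_screen()`): fold-change screening of
   kinase/phosphatase mutant panels with rescreen confirmation.

No raw mass spectra or blot images are consumed: inputs are post-alignment
feature tables and integrated band densities, as TSV. Because the original
biological raw data are not publicly deposited, correctness is established
on synthetic data with known ground truth; every generator in the
`simulate_*` family exists so that each analysis stage has a
parameter-recovery test surface.

## Label-free quantification

### The feature table and charge filtering

A feature is an LC-MS signal defined by m/z and retention time whose
summed peak area serves as a peptide's abundance; the table holds one
abundance column per run with `NA` for "not detected". Before
quantification the features are reduced to charge states +2 through +5
(`filter_charge()`): singly charged ions are dominated by non-peptide
background, and charges above +5 are rare for tryptic/chymotryptic
peptides of this size.

### Run normalization

Run-level differences in loading and ionization are removed by a
median-of-log-ratios estimator. For each run, log abundance ratios
against a reference run are computed over the features observed in both
runs; the normalization factor is `exp(m)` where `m` is a robust location
estimate of that distribution. The estimate rests on the assumption that
most features do not change between runs — the changing minority
(genuinely regulated phosphopeptides) then has bounded influence on the
median.

The default estimator is a *recursive median*: starting from the median
of all log ratios, the median is recomputed over the subset of ratios
within `1.48 * MAD` of the current estimate until it moves by less than
`tol` (default 1e-10) or `max_iter` (50) is reached. The trimming
constant 1.48 makes the MAD a consistent scale estimate under normality.
A plain (non-recursive) median is available via `method = "median"`. The
commercial software used for this kind of alignment output describes its
normalization only as "a recursive median approach", so equivalence with
any vendor implementation cannot be asserted; the recursive trimmed
median implemented here is one standard robust realization of that idea,
and both options are recorded in the result object. The reference run
defaults to the first run id in lexicographic order and is stored in the
result.

### Eligibility and variant selection

A phosphosite is quantifiable when at least one of its peptide variants
(i) carries exactly one phosphate, (ii) has an unambiguous site
assignment, and (iii) is present in *all* runs of at least one light
condition. Requiring complete presence in one condition — rather than a
fraction of runs overall — keeps strongly light-regulated peptides (which
may be undetectable in the other condition) quantifiable while excluding
sporadically detected features. Among eligible variants, the one with the
highest mean normalized abundance over its non-missing runs is chosen;
ties break deterministically to the smallest feature id. Missing values
are never imputed: the presence rule replaces imputation.

### Relative abundance and significance

Per condition, the mean normalized abundance of the chosen variant is
computed over that condition's runs (nine per condition in the default
design) and the higher condition is set to 100%. A two-sided unpaired
Student t-test (pooled variance; Welch available via `test = "welch"`)
compares the conditions; significance is coded `*` (p < 0.05), `**`
(p < 0.01), `***` (p < 0.001), `n.s.`, or `n.d.` when not quantifiable.
Sites are classified light-elevated or dark-elevated at p < 0.05, else
not light-dependent. Technical replicates enter the test as runs — the
nine runs per condition pool biological and technical replication, which
reproduces the original analysis convention faithfully but overstates
independence; an analysis on biological means only is possible by
aggregating the design before quantification. When the run design
contains more than one digestion enzyme, quantification is performed per
enzyme by default (each enzyme yields its own peptide panel), matching
the convention of reporting tryptic and chymotryptic results separately.

Degenerate inputs are resolved by the limit of the t statistic: two
zero-variance samples give p = 1 when their means agree and p = 0
otherwise. Fewer than two observations in a condition make the site not
quantifiable rather than producing an unstable test.

## Densitometry

Each lane's phosphospecific-antibody signal is divided by the
total-protein (generic antibody) signal of the same sample, cancelling
loading differences. Quantitative use of a blot requires the signal to be
linear in the loaded amount; `linearity_check()` fits ordinary least
squares of signal on head equivalents (intercept included by default —
forcing through zero is optional because film/CCD backgrounds need not
vanish) over the dilution design 3, 1.5, 0.75, 0.375 head equivalents
with constant total protein, and passes at r² ≥ 0.95. A zero-variance
signal is scored r² = 0: a flat signal carries no linearity information.

Relative phosphorylation expresses each test lane's ratio as a percentage
of a control lane **on the same membrane** (control = 100%), then averages
over replicate membranes with SEM. Same-membrane anchoring is essential
because antibody and detection gains are membrane-specific constants; the
percentage is exactly invariant to them. Percentages may exceed 100 (e.g.
mutants with enhanced phosphorylation) and are not clipped. Time courses
are scaled the same way to an anchor timepoint (e.g. 4 h of light
adaptation = 100%); the anchor is applied per replicate, and a pooled
variant (anchoring the timepoint means) is reported alongside because the
original convention does not disambiguate the two.

## Phosphate occupancy and the tetramer co-capture bias

Occupancy (OC) — the fraction of channel protein phosphorylated at a site
— is estimated from four signals: phosphospecific and generic antibody on
the input extract, and the same two antibodies on the immunoprecipitate
obtained with the phosphospecific antibody:

    OC = (pTRP_input / TRP_input) x (TRP_IP / pTRP_IP) x 100%.

The input ratio measures phospho-epitopes per subunit up to the two
antibody gains; the IP ratio cancels those gains under the assumption
that everything in the immunoprecipitate is phosphorylated. That
assumption fails for a tetramer: a channel with even one phosphorylated
subunit can be captured whole, and its unphosphorylated subunits inflate
the generic-antibody IP signal, biasing OC upward.

`apparent_occupancy()` formalizes this. Subunits are phosphorylated
i.i.d. Bernoulli(p); a channel with k phospho-subunits is captured with
probability `1 - (1 - capture_eff)^k` (independent capture per epitope;
an all-or-nothing threshold variant would be a plausible alternative but
is not needed for the qualitative conclusion). With full capture
efficiency the expectation reduces to the closed form

    OC_app = 100 x (1 - (1 - p)^n),

so a per-subunit probability of p = 0.2 on a tetramer already appears as
59.04% occupancy. For a monomer (n = 1) the estimate is unbiased. The
general case is computed by exact binomial enumeration over k, and
`invert_occupancy()` recovers p from a measured OC — closed form when
`capture_eff = 1`, otherwise monotone bisection to 1e-10. Residual
phosphantibody signal in unphosphorylated material (dark-condition
background) is modelled as an additive `cross_reactivity` fraction,
default 0. All p estimates from this inversion are model-based: the
binomial capture model is one consistent formalization of the co-capture
argument, not a measured property of the antibodies, so inverted values
should be reported as "at most" style bounds alongside the raw OC.

`simulate_ip()` draws channels explicitly and exposes per-channel state,
and `occupancy_from_simulation()` attaches Monte-Carlo standard errors by
recomputing both OC and p over 10 channel blocks; with 10^6 channels the
measured OC at p = 0.2 matches the closed form within ~0.05%.

## Candidate screen

Mutants are screened per phosphosite antibody and light condition against
a wild-type control lane on the same membrane. The initial screen uses a
single experiment: a mutant is a hit when its relative phosphorylation is
at least 2-fold up (boundary inclusive) or below 0.5-fold down (boundary
exclusive) in any site x condition — the boundary semantics are read
literally from the screening rule. Hits are retested so that three
experiments are available, and a hit is *confirmed* when the fold
criterion holds on the mean of the three replicates and, in the default
`"ttest"` mode, a one-sample two-sided t-test of the replicate
percentages against 100% gives p < 0.05.

Two statistical choices deserve comment:

* **The confirmation t-test runs on log percentages.** Blot noise is
  multiplicative, so on the raw scale the test is severely asymmetric —
  in simulation its power for a 4-fold *increase* is roughly half its
  power for a 4-fold *decrease* at the same noise. On the log scale the
  two directions are symmetric. `log_scale = FALSE` restores the raw
  test.
* **With n = 3 the t-test is fragile by construction.** At two degrees
  of freedom the critical value is 4.30, and the variance estimate is
  itself so variable that even 5-fold effects fail confirmation in a few
  percent of cases — no effect size escapes this. The `"threshold"` mode
  (fold criterion on the mean alone) is therefore used for the planted-
  effect recovery benchmark, while `"ttest"` remains the default and the
  more conservative choice for null specificity. Which reading of
  "significant effects" the original screen used cannot be resolved from
  its description; both are shipped.

Under a null panel, the rescreen strictly reduces the hit count: an
initial false positive must reproduce its extreme fold in the mean of
three experiments (the initial experiment counts as the first of the
three, as in "tested two more times").

## The synthetic-data generators

All generators derive their RNG substreams deterministically from one
master seed, so identical configuration and seed give byte-identical
outputs, including through `run_pipeline()`.

* `simulate_feature_table()` emulates aligned LC-MS output: per-run
  abundance = base x condition effect x run scale factor x multiplicative
  log-normal noise with unit mean and CV `noise_cv`, reported missing
  with probability `1 - detect_prob` (missing at random, independent per
  run; an abundance-dependent detection function can be supplied but the
  default is constant). Background features carry no condition effect
  except a configurable minority (default fraction 0.1, folds 2–8),
  which anchors — and stress-tests — the normalization assumption.
  Charge states are sampled from 1–6 so the charge filter has work to
  do; each site emits ≥ 1 peptide variants plus optional
  multiply-phosphorylated or ambiguous-localization variants that the
  eligibility rules must reject.
* `simulate_blot_panel()` gives each lane total = gain x amount x noise
  and phospho = gain x amount x fraction x noise, with per-membrane
  gains, and supports the dilution-series design for linearity QC.
* `simulate_ip()` is described above.
* `simulate_screen_panel()` builds one membrane (wild-type + mutant
  lane) per mutant x site x condition x replicate, with per-membrane
  gains and per-signal noise.

Default study conditions: nine LC-MS runs per condition (the number of
runs entering each per-condition mean in the original analysis), MS
feature noise CV 0.2, blot signal noise CV 0.15, 200 background features
in the demonstration pipeline, 85 screen mutants with three experiments
each. The dark-elevated demonstration site is labelled S936 and the
light-elevated set includes the two antibody sites T849 and T864, at
4-fold condition effects. The blot noise default is a placeholder
magnitude chosen as a realistic chemiluminescence CV, not an estimate of
any particular assay. The planted screen effects (folds 0.15–0.2 down,
5 up; all ≥ 4-fold) echo the magnitude of the strongest reported
kinase-mutant effect (a 6.7-fold reduction).

What the generators deliberately do **not** emulate: retention-time
drift and alignment errors (tables arrive aligned), abundance-dependent
censoring by default, correlated noise across features, ion suppression,
membrane stripping artefacts, and antibody affinity kinetics. Passing
recovery tests on this synthetic data therefore demonstrates that the
*procedures* are implemented correctly and are well-calibrated under
their own assumptions — not that those assumptions hold for any given
real dataset.

## Numerical conventions

* Ratios are computed in natural log internally; factors are reported on
  the linear scale.
* Normalization convergence tolerance 1e-10 on the median of log ratios;
  bisection tolerance 1e-10 on p.
* Ties in variant selection break to the smallest feature id; all
  tabulations are deterministic.
* A zero phospho input signal gives OC = 0 even though the IP ratio is
  then 0/0 (nothing was phosphorylated, so nothing was captured).
* Zero or negative total signals, missing same-membrane controls,
  missing anchors, and runs sharing no features with the reference are
  hard errors naming the offending lane/run, never silent drops.

## Problem sizes used by the test-suite benchmarks

Fold-change recovery uses 200 simulated datasets per run (3 sites each at
2/4/8-fold, 9 runs per condition, noise CV 0.2); the type-I calibration
uses 2000 null sites; the site-map recovery scenario (13 light-elevated +
1 dark-elevated) and the screen recovery benchmark (85 mutants, 4 + 4
planted effects) use 100 simulated datasets each; the occupancy
Monte-Carlo uses 10^6 channels. These sizes give the medians and rates
reported by `scripts/acceptance.R` Monte-Carlo errors well below the
tolerances being checked.

## Known limitations

* The vendor normalization algorithm is not public; only the recursive
  median family implemented here is exercised.
* Pooling technical with biological replicates reproduces the original
  convention and therefore also its pseudo-replication.
* The occupancy correction depends on the binomial capture model;
  capture efficiency is a model input, not estimated from data.
* The screen confirmation with n = 3 has intrinsically limited power in
  `"ttest"` mode (see above).
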