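# misogate

Predicting multi-input transcriptional logic gates from single-input data.

## What it is for

Synthetic biologists building Boolean decision-making into cells from
engineered LacI-family transcription factors face a combinatorial wall:
with 5 regulatory core domains (RCDs — which ligand a factor senses),
8 DNA recognition functions (ADRs — which operator it binds) and 2
operator positions, there are already 80 putative BUFFER (repressor) and
80 putative NOT (antirepressor) single-input gates, and hundreds of ways
to pair them on a shared operator into two-input AND, NOR and NIMPLY
gates. `misogate` implements the alternative to brute-force screening:
measure the single-input (SISO) gates once, then predict every two-input
(MISO) gate from those measurements.

The core model is deliberately coarse-grained. With digitized inputs
I ∈ {0, 1}, a single-input gate is

    Ω = ε + σ Λ(I),   Λ(I) = I (repressor) or 1 − I (antirepressor)

where ε is leakiness (OFF output) and σ the ON-minus-OFF increment on a
0–1 fluorescence scale. A two-input SE-PA gate composed of members X and Y
is the quadratic corner-state model

    Ω = α0 + α1 S_X + α2 S_Y + α3 S_X S_Y

with α0 = min(ε_X, ε_Y), α1 = ε_Y − α0, α2 = ε_X − α0, and
α3 = min(ε_X+σ_X, ε_Y+σ_Y) − (α0+α1+α2); the gate type (AND, NOR,
A NIMPLY B, B NIMPLY A) only selects which state functions S are
repressor- or antirepressor-polarity. Around that model the package
provides:

* plate-reader processing (blank correction, per-well OD600
  normalization, 75,000-RFU unit scaling, replicate summaries);
* SISO metrology: Welch t-test phenotype classification (repressor /
  antirepressor / super-repressor / nonfunctional), ε/σ extraction, fold
  induction, repression strength and traceability scores;
* design-space enumeration (SISO spaces, nonsynonymous SE-PA pairs,
  networked bin counts) and two-tier compatibility screening;
* validation statistics: ANOVA + Tukey–Kramer objective-logic calls and
  measured/predicted fold-error metrology;
* a synthetic plate-data generator with known ground truth, so the whole
  pipeline is testable at desk scale.

## Worked example

Fit two repressor (BUFFER) gates from replicate unit-scale measurements,
check their compatibility, and predict the AND gate they would compose:

```r
library(misogate)

x <- siso_fit(uninduced = c(0.049, 0.052, 0.050, 0.051, 0.048, 0.050),
              induced   = c(0.83, 0.86, 0.85, 0.84, 0.86, 0.85),
              gate_id = "I_YQR_PROXIMAL")
x
#> Single-input gate fit: I_YQR_PROXIMAL
#>   phenotype : REPRESSOR (p = 8.5e-11, Cohen's d = 95.9)
#>   epsilon = 0.05, sigma = 0.7983, ON state = 0.8483, fold change = 16.97

y <- siso_fit(uninduced = c(0.098, 0.101, 0.100, 0.102, 0.099, 0.100),
              induced   = c(0.79, 0.81, 0.80, 0.78, 0.82, 0.80),
              gate_id = "R_YQR_PROXIMAL")

check_pair(x, y)
#> Pair I_YQR_PROXIMAL | R_YQR_PROXIMAL: tier1 TRUE, tier2 TRUE -> COMPATIBLE

miso_gate(x, y, "AND", gate_id = "AND_I.R_YQR_PROXIMAL")
#> Two-input AND gate model: AND_I.R_YQR_PROXIMAL (SE_PA-parameterized)
#>   alphas: alpha0 = 0.05, alpha1 = 0.05, alpha2 = 0, alpha3 = 0.7
#>   predicted truth table:
#>     (IX=0, IY=0) -> 0.05
#>     (IX=0, IY=1) -> 0.05
#>     (IX=1, IY=0) -> 0.1
#>     (IX=1, IY=1) -> 0.8  [ON corner]
```

The gates are operational (t-test p ≪ 0.001) and mutually compatible
(every ON state clears every OFF state), and the predicted AND gate is ON
only when both inducers are present, with leakiness set by the smaller
member leakiness and ON level by the weaker member.

The full pipeline — simulate a SISO library, process plates, classify,
screen pairs, predict and validate the resulting two-input gates — runs
from one seeded configuration:

```r
run <- run_pipeline(run_config(seed = 17))
run
#> Transcriptional logic gate pipeline run (seed 17 )
#>   SISO designs : 80 BUFFER, 80 NOT
#>   phenotypes   : ANTIREPRESSOR 76, NONFUNCTIONAL 7, REPRESSOR 74, SUPER_REPRESSOR 3
#>   AND        : 160 putative pairs, 136 passed screening
#>   NOR        : 160 putative pairs, 144 passed screening
#>   validation   : mean fold error 1.048, 100.0% corners within 2-fold, 100.0% objective logic
```

At the generator's default 10% replicate CV, model-faithful two-input
gates are predicted with a mean fold error of ~1.05 and every gate shows
objective logic by the Tukey test. Real plate data enter the same way via
`read_plate_csv()` (a small synthetic example lives in
`inst/extdata/synthetic_siso_plate.csv`).

See the vignette (`vignettes/predicting-logic-gates.Rmd`) for the model's
assumptions, the compatibility rule, and what the synthetic conditions do
and do not emulate.

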