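# amylokin

Chemical-kinetics analysis of amyloid-β42 (Aβ42) aggregation dominated by
**monomer-dependent secondary nucleation**, for biophysicists who study how
small molecules modulate amyloid self-assembly with thioflavin-T (ThT)
plate-reader assays and AFM/TEM fibril imaging.

Aβ42 fibrils form through three microscopic steps: primary nucleation of new
aggregates from monomer (rate constant *k*ₙ), elongation of fibril ends
(*k*₊), and secondary nucleation of new aggregates on existing fibril
surfaces (*k*₂), which dominates proliferation once a small amount of fibril
mass exists.  The total fibril mass *M*(*t*) obeys the integrated rate law

```
M(t)/M(∞) = 1 − (m₀/m_tot) ·
            [ (B₊+C₊)/(B₊+C₊e^{κt}) · (B₋+C₊e^{κt})/(B₋+C₊) ]^{k∞²/(κ·k̃∞)} ·
            e^{−k∞ t}
```

where the composite parameters *B*±, *C*±, κ, *k*∞, *k̃*∞ depend on the
microscopic constants only through the products *k*₊*k*₂ and *k*₊*k*ₙ (plus
initial monomer *m*₀, seed mass *M*₀ and seed number *P*₀).  In particular
κ = √(2 *k*₊*k*₂ *m*₀^(n₂+1)) is the secondary-pathway proliferation rate.
The package also integrates the underlying moment equations

```
dP/dt = kₙ mⁿᶜ + k₂ mⁿ² M ,   dM/dt = 2 k₊ m P ,   dm/dt = −2 k₊ m P
```

as a numerical oracle, and exploits their exact first integral
(2*k*₊*P* d*P* = −(*k*ₙ*m*^(nc−1) + *k*₂*m*^(n₂−1)(*m*_tot−*m*)) d*m*) for a
machine-accurate analytical solution of seeded reactions (see the methods
vignette).

A modulator that perturbs one microscopic step multiplies its rate constant
by a fold-change per dose.  Global fitting of unseeded and seeded dose
series attributes the perturbation to a specific step; competing mechanistic
hypotheses (primary vs. secondary pathway) are ranked by AIC.  Because the
mean fibril length scales as √(*k*₊/*k*₂) under secondary-nucleation
dominance, a fitted *k*₂ enhancement also predicts a fibril-length change
that can be confronted with AFM/TEM morphometry, using the field's
total-error convention (SEM + instrument sensitivity floor) and a
sensitivity-aware Welch test.

Wet-lab inputs are replaced by a deterministic synthetic generator with
planted ground truth, so the whole pipeline is testable end to end.

## Worked example

Simulate the canonical dose series (2 µM Aβ42-like peptide, modulator at
10:1, 5:1, 1:1 peptide-to-modulator ratios, planted secondary-pathway
enhancements of 2, 4.5 and 5), then recover the mechanism by global fitting:

```r
library(amylokin)
fx <- make_paper_fixture(seed = 1)

halftime_dose_response(fx$traces$unseeded)
#>   condition modulator_ratio n t50_mean t50_sem n_excluded
#> 1      ctrl             0.0 3     2.11 0.00816          0
#> 2 tro_10to1             0.1 3     1.59 0.00326          0
#> 3  tro_5to1             0.2 3     1.14 0.00589          0
#> 4  tro_1to1             1.0 3     1.08 0.00831          0

fit <- fit_global(fx$traces$unseeded,
                  perturbation_hypothesis("secondary_product"),
                  fit_config(seed = 0, n_hops = 5))
fit
#> Global kinetic fit (hypothesis: secondary_product)
#>   rss = 0.772289 over 1812 points, 5 parameters; AIC = -14050.18; converged
#>   base products: k+k2 = 1.622, k+kn = 0.0001832
#>   fold-changes: tro_10to1 = 1.99, tro_5to1 = 4.52, tro_1to1 = 4.99
```

The half-time falls dose-dependently, and the fit recovers the planted
fold-changes (2, 4.5, 5) to a few percent: at the equimolar ratio the
apparent secondary-pathway rate constant *k*₊*k*₂ is enhanced five-fold.
That enhancement predicts shorter fibrils, which the (synthetic) morphometry
confirms:

```r
predicted_length_scale(factor_k2 = fit$fitted_factors[["tro_1to1"]])
#> [1] 0.448

lr <- length_ratio(fx$morphometry$length_treated, fx$morphometry$length_control)
#> observed length ratio: 0.401 +/- 0.040
scaling_consistency(lr$ratio, factor_k2 = 5)$consistent
#> [1] TRUE
```

A command-line interface over the same functions is available as a thin
script (`inst/cli/amylokin.R`, subcommands `simulate`, `fit`, `halftime`,
`compare`, `morph`), or directly as `amylokin::cli()`.

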