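# swerf

Estimate the **size-weighted relevant fine fraction** (SWeRF) of a bulk
powder — the mass fraction that, if made airborne and inhaled, would reach
the lungs' unciliated airways — and derive the GHS/CLP **STOT RE** hazard
classification for products containing crystalline silica.

The package is for occupational-hygiene and product-stewardship scientists
who must classify mineral powders (quartz and cristobalite flours, barite,
diatomaceous earth, carbonates, ...) under the EU CLP regulation, where the
generic concentration limits for the fine fraction of crystalline silica
(CS) are: >= 10% w/w → STOT RE 1, 1–10% → STOT RE 2, < 1% → no
classification.

## The method

"Respirable" is defined for airborne dust, but classification applies to
the powder in the bag. SWeRF bridges the two by weighting the powder's
particle size distribution with the EN 481 respirable convention

$$R(D) = \tfrac12\left(1 + e^{-0.06 D}\right)
 \left[1 - \Phi\!\left(\frac{\ln(D/4.25)}{\ln 1.5}\right)\right],
 \qquad \mathrm{SWeRF} = \sum_b P(b)\,R(D_b),$$

where $D$ is aerodynamic diameter in µm ($D = d\sqrt{SG}$ for
spherical-equivalent diameter $d$ and specific gravity $SG$) and $P(b)$ the
mass fraction in size bin $b$. The curve passes through 97.1% at 1 µm and
1.3% at 10 µm.

Alternatively SWeRF is **measured** by sedimentation: a gravimetric
protocol whose survival function $S(D) = \max(0, 1-(D/D_c)^2)$ is matched
to the convention by equating integrals, giving the cut diameter
$D_c = \tfrac32 \int_0^\infty R\,dD \approx 6.42$ µm and, via Stokes' law,
the settling time $t = 18\,\eta\,h\,\rho_p \,/\,
(g(\rho_p-\rho_l)\rho_0 D_c^2)$. The supernatant residue then yields
$\mathrm{SWeRF} = mH/(Mh)$ and, with the CS fraction of the residue from
FT-IR/XRD, $\mathrm{SWeRF}_{CS} = \mathrm{SWeRF} \times f_{CS}$.

## Worked example

```r
library(swerf)

quartz <- material("quartz flour", specific_gravity = 2.66,
                   cs_mass_fraction = 1)
flour  <- lognormal_psd(median = 3, gsd = 2)   # D50 3 um, typical fine flour

swerf_from_psd(flour, quartz) |>
  swerf_cs_calculated(quartz) |>
  tidy()
#> # A tibble: 1 × 5
#>   material     method     swerf_percent swerf_cs_percent stot_re
#>   <chr>        <chr>              <dbl>            <dbl> <chr>
#> 1 quartz flour calculated          39.4             39.4 STOT_RE_1
```

A fine quartz flour with a median diameter of 3 µm has a SWeRF of 39.4%:
39.4% of its mass lies in the respirable-equivalent fraction. Being pure
quartz, its fine-fraction CS content equals the SWeRF, far above the 10%
generic concentration limit, so the product classifies as STOT RE 1.

Planning the equivalent sedimentation experiment:

```r
sedimentation_plan(quartz, extraction_height_m = 0.05,
                   column_height_m = 0.20)
#> sedimentation plan (EN 481 respirable equivalent)
#>   liquid: water (eta 0.001002 Pa s, rho 998 kg/m^3)
#>   particle density: 2660 kg/m^3
#>   extraction height h: 0.05 m of 0.2 m column
#>   cut diameter D_c: 6.422 um aerodynamic
#>   settling time t: 3568 s (00:59:28)
```

i.e. settle for just under an hour, then pipette the top 50 mm of the
200 mm column. Evaluating a weighing record (5 g dispersed, 120 mg residue,
62% of the residue identified as quartz):

```r
swerf_from_measurement(
  data.frame(M_mg = 5000, m_mg = 120, H_mm = 200, h_mm = 40, f_cs = 0.62)
) |> tidy()
#> # A tibble: 1 × 5
#>   material method        swerf_percent swerf_cs_percent stot_re
#>   <chr>    <chr>                 <dbl>            <dbl> <chr>
#> 1 unnamed  sedimentation            12             7.44 STOT_RE_2
```

A command-line interface wrapping these functions is installed with the
package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/swerf.R", package="swerf"))')" \
  sediment-plan --sg 2.66 --h 50 --H 200
```

See `vignettes/swerf-method.Rmd` for the model, its assumptions and the
numerical choices.

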