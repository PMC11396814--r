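# windfirm

Mechanistic assessment of coniferous-tree resistance to wind-induced
uprooting, for forest managers and researchers who need a rapid, per-tree
hazard screen from standard inventory measurements (DBH, height, crown
dimensions) plus root-plate geometry detectable non-destructively with
ground-penetrating radar (GPR).

## The model

A standing conifer is treated statically as three parts. The wind exerts an
overturning moment about the stem base through the conical crown:

    S_tc = R (H − H0)                       frontal area
    W_c  = 0.5 ρ_a C_d R (H − H0) v²        wind load
    M_w  = W_c L,   L = (H + 2 H0) / 3      overturning moment

Resisting it are the elastic stem moment `M_s = a D³ H` (D, H in metres;
`a` = 3.315 for spruce, 3.589 for Korean pine) and the weight of the root
plate — a half-ellipsoid of coarse roots plus enclosed soil — acting through
its centroid lever arm `L_r = 4 D_rp / (3π)`:

    V_r = (π/6) D_rp H_rp W_rp              plate volume (or measured)
    M_r = f_r L_r (G_cr + ρ_s V_r) g        plate resistive moment

with anchorage fraction `f_r` (0.20 spruce, 0.30 Korean pine), coarse-root
biomass `G_cr` from species allometries, and effective soil bulk density
`ρ_s`. The resistance coefficient is `R_m = (M_s + M_r) / M_w`; factoring
out the wind constant `μ = ρ_a C_d v² / 6` leaves the wind-independent
index

    Δ′ = μ R_m = [3π a D³ H + 4 f_r D_rp (G_cr + ρ_s V_r) g]
                 / [3π R (H + 2H0)(H − H0)]

Thresholds calibrated from uprooted reference trees (mean + z·sd of their
Δ′, z at the 95% and 99% two-sided normal levels) band standing trees into
High (Δ′ ≤ t95), Moderate (t95 < Δ′ < t99) and Low (Δ′ ≥ t99) uprooting
hazard. Defaults are spruce (1.31, 1.51) and Korean pine (1.20, 1.44).

Supporting tools: GPR coarse-root densities per transect/depth bin with
one-way ANOVA and Tukey HSD compact letter displays, soil physical
properties (gravimetric water content, bulk density, porosity), packaged
reference tables, a CLI, and a seeded synthetic stand generator.

## Worked example

```r
library(windfirm)
tree  <- data.frame(tree_id = "S1", species = "spruce", dbh_cm = 26.7,
                    height_m = 7.8, crown_base_m = 3.7,
                    crown_ew_m = 5.2, crown_ns_m = 5.8)
plate <- data.frame(tree_id = "S1", depth_m = 0.5, length_m = 1.2,
                    width_m = 1.1, volume_m3 = 0.28)   # measured volume
res <- run_assessment(tree, plate, soil = 1087.5)      # rho_s in kg/m^3
t(res$report)
```

prints (default wind: ρ_a = 1.226, C_d = 0.29, v = 10 m/s, so μ ≈ 5.926):

```
crown_radius_m         2.75        # (5.2 + 5.8)/4
frontal_area_m2        11.275      # R (H − H0)
wind_load_n            200.4357
overturning_nm         1015.541    # W_c × 5.0667 m lever
stem_moment            0.4921664   # 3.315 × 0.267³ × 7.8
coarse_root_kg         38.23891    # spruce allometry
soil_mass_kg           304.5       # 1087.5 × 0.28
root_moment_nm         142.6991
delta_prime            0.8355192
resistance_coefficient 0.141
hazard_level           High        # 0.836 ≤ 1.31
```

Δ′ = 0.836 is below the spruce 95% band (1.31), so this small-crowned but
slender, light-plated tree is classified as High uprooting hazard. Note
that halving the wind speed would rescale `R_m` but leave `delta_prime`
and the hazard level unchanged.

Command-line equivalents:

```sh
exec/windfirm simulate  --seed 7 --out stand/
exec/windfirm calibrate --reference inst/extdata/table3_uprooted_reference.csv \
                        --out thresholds.json
exec/windfirm assess    --trees stand/trees.csv --plates stand/rootplates.csv \
                        --bulk-density 1087.5 --thresholds thresholds.json \
                        --out hazard.csv
exec/windfirm density   --scans stand/scans.csv --letters
```

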