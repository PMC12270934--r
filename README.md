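# cryocurve

Freezing thermodynamics of aqueous anti-freeze-agent solutions — the
model systems behind frozen desserts such as ice cream and sorbet.
`cryocurve` is aimed at food physical chemists and product developers
who need to predict how much ice a sugar, polyol, alcohol or salt
solution holds at a given storage temperature, how concentrated the
unfrozen serum phase becomes, and how those properties connect to the
hardness and melting behaviour measured on real samples.

## The model

For a solute of molecular weight *M* at mass *m*ₛ per 100 g of sample,
the ideal (colligative) freezing-point depression is

    ΔT_f = K_k · i · m_s / (M · m_water[kg])

with *K*ₖ = 1.86 K·kg·mol⁻¹ the cryoscopic constant of water and *i* the
degree of dissociation. Below the freezing point the unfrozen serum
phase must hold the equilibrium solute mole fraction

    x_s(T) = 1 − exp(a − b/T),   a = b / 273.15 = 2.646,   b = ΔH_fus/R = 722.8 K

(*T* absolute). Solutes additionally bind water in hydration shells —
*h* mol of water per mol of solute, the **effective hydration number** —
and bound water cannot freeze. The ice content (% of total sample mass)
follows by bookkeeping the water moles:

    %ice = 100·MW_w/basis · [ n_w − (1/x_s − 1)·n_s − n_s·h ]

where *n*\_w and *n*ₛ are total water and solute moles. The expression
inverts in closed form, so a single measured ice content at a known
temperature yields the effective hydration number directly — this is how
*h*(T, c) surfaces are extracted from DSC measurements, in which the
melting enthalpy of a partially frozen sample divided by the enthalpy of
fusion of pure ice (334 J/g) gives the ice fraction.

Around this core the package provides serum-phase freeze concentration
(`serum_concentration()`, `unfrozen_water()`), DSC endotherm integration
(`integrate_endotherm()`, `ice_content_from_enthalpy()`),
hydration-surface fitting and ice-curve prediction
(`fit_hydration_table()`, `predict_ice_curve()`), melting-test and
penetration-test descriptors (`extract_melting_parameters()`,
`hardness_from_penetration()`), and seeded synthetic-data generators
that emulate the instruments for end-to-end validation
(`generate_ice_dataset()`, `generate_melting_curve()`,
`generate_dsc_trace()`).

## Worked example

```r
library(cryocurve)

# Colligative freezing point of 11.5 % glucose
freezing_point(solution("glucose", 11.5))
#> [1] -1.34275          # degC; prints as -1.34

# Ice curve of 15 % glucose with effective hydration number 10.5
ice_content(solution("glucose", 15), h = 10.5, temperature_C = c(-18, -12, -8))
#>   temperature_C  ice_pct valid
#> 1           -18 61.92225  TRUE
#> 2           -12 57.62576  TRUE
#> 3            -8 51.17405  TRUE

# Freeze concentration: 15 % sucrose at 70 % ice -> 50 % serum phase
serum_concentration(solution("sucrose", 15), 70)
#> sucrose
#>      50

# Melting parameters from a synthetic thaw test (lag 15 min, 1.5 %/min)
mc <- generate_melting_curve(15, 1.5, cfg = generator_config(seed = 7))
extract_melting_parameters(mc)
#> Melting parameters:
#>   lag time            14.99 min
#>   total melting time  81.33 min
#>   melting rate        1.500 %/min
#>   onset temperature   -0.96 degC
#>   temperature rate    0.210 degC/min
```

At −18 °C the 15 % glucose sample is 62 % ice: of its 85 g of water,
the serum phase keeps the equilibrium free water and 10.5 water
molecules per glucose stay bound in hydration shells. The same
machinery run in reverse (`hydration_number()`) turns measured ice
contents into effective hydration numbers.

A command-line entry point with the same functionality ships in
`exec/cryocurve` (subcommands `freezing-point`, `serum`,
`fit-hydration`, `predict`, `melt-params`, `hardness`, `simulate`).

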