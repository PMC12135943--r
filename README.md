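# atroposcan

Atropisomerism — axial chirality from hindered rotation about a single bond —
is easy to miss in large, flexible drug molecules, and expensive to discover
late: a "Class 2" axis (interconversion over minutes to months at 37 °C) can
frustrate crystallization, split NMR spectra into rotamer signal sets, and
turn one nominal compound into a slowly equilibrating mixture. `atroposcan`
is an R toolkit for flagging and quantifying such axes in beyond-rule-of-5
molecules (PROTACs, linear peptidomimetics), for two complementary routes:

1. **Torsion-profile screening** — detect the non-terminal rotatable bonds of
   a molecule, carve a capped fragment around each, embed it in 3D, and drive
   a restrained 36-point torsion scan (10° steps; staged harmonic dihedral
   restraints with k = 10^5 then 10^6 kJ/mol) against a pluggable energy
   backend. Each profile V(θ) is reduced to the screening features
   ΔΔV_min (spread of the minima), max(V_max) and min(V_max) (highest and
   lowest barrier), and flagged *of interest* when max(V_max) > 13 kcal/mol
   with ≥ 2 clear minima.
2. **Variable-temperature NMR kinetics** — compute rotational barriers from
   coalescence data via the modified Eyring equation

   ΔG‡ = R·T_coal·[22.96 + ln(T_coal/δν)]   (J/mol, reported in kcal/mol)

   where δν is the slow-exchange Larmor frequency difference in Hz (ppm
   separation × spectrometer MHz) and T_coal the coalescence temperature —
   observed, linearly extrapolated from the separation-vs-temperature trend,
   or supplied as candidate values when coalescence is out of range.

Barriers from either route are placed on the LaPlante scale via the Eyring
racemization half-life at 37 °C: Class 1 (t½ < 60 s, ΔG < 20 kcal/mol),
Class 2 (60 s–4.5 y, 20–30 kcal/mol), Class 3 (> 4.5 y, > 30 kcal/mol).

The two tool compounds of the underlying study are shipped as curated
structures: **ACBI1** (a VHL-recruiting SMARCA2/4 PROTAC degrader) and
**BI201335** (faldaprevir, an HCV NS3 protease inhibitor; transcription
verified by its empirical formula C40H49BrN6O9S), together with the printed
slow-exchange chemical shifts of their rotameric signal pairs at 400.13 MHz.

## Worked example

```r
library(atroposcan)

## --- torsion screening of butane with the threefold analytic backend -----
mol   <- fixture_mol("butane")
bonds <- detect_rotatable_bonds(mol)
frag  <- embed_3d(fragment_around_bond(mol, bonds[1, ]), seed = 1)
prof  <- scan_torsion(frag, scan_settings(backend_id = "cosine3"),
                      get_backend("cosine3", barrier = 3))
extract_features(prof)
#> <profile_features> 3 clear minima | ddV_min 0.00 | max(V_max) 3.00 |
#>   min(V_max) 3.00 kcal/mol | not flagged
```

Three equivalent staggered minima separated by 3 kcal/mol barriers: a free
rotor, far below the 13 kcal/mol screening threshold, hence "not flagged".

```r
## --- VT-NMR barrier for the PROTAC's hindered amide axis ------------------
est <- barrier_report(fixture_vt_pair("acbi1_pair1"),
                      T_coal = 453.15,                 # plausible coalescence
                      candidates_K = c(393.15, 423.15, 453.15))
est
#> <barrier_estimate> acbi1_pair1: dG = 22.4 kcal/mol [estimated]
#>   (T_coal 453.1 K, dnu 64.02 Hz), t1/2(37C) = 694 s, Class 2
#>   candidate coalescence temperatures:
#>     T = 393.1 K -> dG = 19.4 kcal/mol (Class 1)
#>     T = 423.1 K -> dG = 20.9 kcal/mol (Class 2)
#>     T = 453.1 K -> dG = 22.4 kcal/mol (Class 2)
```

The 0.16 ppm rotamer pair (4.53/4.69 ppm at 303 K) gives δν = 64.02 Hz; at a
coalescence temperature of 453 K the modified Eyring equation yields a
22.4 kcal/mol barrier — a Class 2 atropisomer with a racemization half-life
of minutes at 37 °C. The equally shipped BI201335 pair (4.46/4.76 ppm),
which coalesces at 393 K, gives 18.9 kcal/mol: Class 1.

A thin command-line wrapper is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("cli","atroposcan",package="atroposcan"))') \
    nmr --series bi201335_pair1 --t-coal 393.15 --out out/
```

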