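Package: atroposcan
Title: Atropisomerism Screening by Torsion Profiles and Variable-Temperature NMR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing hindered rotation (atropisomerism) in drug-like
    small molecules. Screens the non-terminal rotatable bonds of a molecule by
    fragment-based, restrained 36-point torsion scans against pluggable energy
    backends, extracts profile features (minima spread, maximal and minimal
    barrier heights), flags torsions of interest, and assigns LaPlante
    atropisomer classes. Independently computes rotational barriers from
    variable-temperature NMR coalescence data via the modified Eyring equation,
    including coalescence-temperature extrapolation, racemization half-lives and
    class assignment. Ships embedded structures of the two beyond-rule-of-five
    tool compounds ACBI1 (a SMARCA2/4 PROTAC) and BI201335 (faldaprevir) plus a
    synthetic variable-temperature series generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
SystemRequirements: OpenBabel (obabel on the PATH for 3D embedding)
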