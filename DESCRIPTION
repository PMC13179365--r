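Package: petkit
Title: Quantitative Analytics for PET Hydrolase Engineering
Version: 0.1.0
Authors@R:
    person("petkit", "developers", email = "petkit@example.org", role = c("aut", "cre"))
Author: petkit developers [aut, cre]
Maintainer: petkit developers <petkit@example.org>
Description: Tools for the quantitative workflows used when engineering
    poly(ethylene terephthalate) (PET) hydrolases: equivalent-circuit
    (Randles) fitting of electrochemical impedance spectra of degrading PET
    films and conversion of film capacitance to thickness and degradation
    rates; inverse Michaelis-Menten kinetics for interfacial catalysis;
    pH-stat titration stoichiometry converting NaOH consumption to
    depolymerized PET mass; nanoDSF two-state melt-curve simulation and
    first-derivative melting-point extraction; variant mutation-set
    accounting including formal net-charge deltas; geometric classification
    of enzyme-substrate trajectory frames into catalytic sub-states,
    hydrogen-bond and salt-bridge geometry, dihedrals, water radial
    distribution functions, and Kabsch superposition; plus seeded synthetic
    generators for every input so each analysis is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
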