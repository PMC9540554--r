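Package: prudentweb
Title: Evolution of Prudent Predation in Assembling Food Webs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulator and analysis toolkit for two-level Lotka-Volterra
    food-web assembly in which consumer base attack rates evolve under
    biased mutation. Provides the full ODE formulation (adaptive stiff
    integration with extirpation thresholds) and a deconstructed,
    condition-based formulation in which closed-form invasibility,
    exploitative-competition, overexploitation, apparent-competition and
    Pyrrhic-competition criteria replace population dynamics. Includes a
    single-consumer model of serial resource extirpation, metacommunity
    fitness-landscape diagnostics factorising lifetime reproductive success
    into establishment rate and population lifetime, and stock-recruitment
    steepness calculations for Lotka-Volterra stocks under fishing
    mortality.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    zoo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
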