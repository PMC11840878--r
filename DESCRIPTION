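Package: orsched
Title: Operating-Room Surgery Scheduling with Metaheuristic Solvers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the surgical scheduling problem: assigning
    waiting-list surgeries to operating-room shifts over a planning
    horizon under capacity, specialty and turnover constraints. Provides
    a deadline/priority penalty objective, a first-fit initial-solution
    constructor ordered by priority and waiting-list longevity, and
    three metaheuristic solvers (hill climbing, simulated annealing,
    particle swarm) sharing a swap/relocate neighbourhood. Includes a
    synthetic instance generator emulating an overloaded hospital
    waiting list, with a planted-feasible mode whose optimal penalty is
    zero by construction, plus CSV/YAML readers and writers and
    comparison reports against a manual-scheduling baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
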