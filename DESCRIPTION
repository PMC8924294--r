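Package: boolpop
Title: Continuous-Time Boolean Network Simulation with Cell Population
    Updates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Stochastic simulation of Boolean signalling networks as
    continuous-time Markov processes (Gillespie-style exact jumps with
    state-dependent rate_up/rate_down transition rates), alternated with
    synchronous population updates that account for cell death, cell
    division and ligand-receptor coupling through population-probability
    dependent rates.  Reads and writes MaBoSS-style network (bnd),
    configuration (cfg) and population-update (upp) text files, imports
    bnet logical models, and provides in-silico mutant screening and
    sequential treatment schedules over the population loop.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
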