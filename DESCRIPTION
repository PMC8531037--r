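Package: swirlkit
Title: Reinforcement-Learning Models of Swirling, Escort Pursuit and
    Energy-Optimal Group Locomotion
Version: 0.1.0
Authors@R:
    person("swirlkit", "developers", email = "swirlkit@example.org",
           role = c("aut", "cre"))
Description: Agent-based simulator of collective animal motion under
    severely limited perception, trained with the EPISODIC REINFORCE
    policy gradient. Implements one-to-one escort pursuit (velocity-,
    acceleration- and force-controlled scenarios), spontaneous swirling
    (milling) of a swarm quantified by a mean angular-velocity order
    parameter, resistance of trained swarms to stretched-exponential
    external forces, and energy-optimal group locomotion in viscous
    fluid via Rotne-Prager hydrodynamics, both by direct minimisation
    of the dissipated power and by reinforcement learning.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    numDeriv,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
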