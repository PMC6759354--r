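Package: balspike
Title: Efficient Balanced Spiking Networks with Population Adaptation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation toolkit for networks of leaky integrate-and-fire
    neurons derived from a greedy minimization of a cost-accuracy objective.
    The derived networks combine spike-frequency adaptation with tightly
    balanced recurrent inhibition so that a fixed linear decoder remains
    accurate while activity is redistributed across the population. Includes
    builders for a random LIF baseline, dual-ring and random-gain orientation
    networks, synthetic stimulus generators (seven-segment digit sequences,
    constant pulses, oriented drives), linear decoder training, and scripted
    protocols for digit encoding, population adaptation, orientation tuning
    curves and the tilt aftereffect.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
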