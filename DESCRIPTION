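Package: hillphos
Title: Hill-Type Muscle Model with ATP Phosphate Kinetics and Exhaustion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward simulation of a muscle-tendon unit (MTU) whose Hill-type
    contraction and Hatze-type calcium activation dynamics are coupled to a
    model of ATP hydrolysis/condensation kinetics. Accumulation of inorganic
    phosphate lowers the relative chemical potential of ATP, which scales the
    muscle activity and produces short-term force decay (exhaustion) during
    sustained stimulation. Includes creatine-kinase and adenylate-kinase
    equilibrium bookkeeping with strict pool conservation, bounded
    least-squares parameter estimation against multi-length isometric
    force-time traces, local parameter sensitivity time courses, steady-state
    force and decay-rate relations, and exhaustion-time maps over muscle
    length and stimulation level. Ships fitted parameter presets for rabbit
    gastrocnemius and plantaris preparations and a seeded synthetic-trace
    generator emulating the isometric experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    graphics,
    grDevices,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
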