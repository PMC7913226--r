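Package: malnpbpk
Title: Whole-Body PBPK Simulation of Drug Exposure in Malnourished Children
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A whole-body physiologically-based pharmacokinetic (PBPK)
    simulator with a physiological-scaling layer that translates
    non-malnourished virtual individuals into defined states of mild,
    intermediate or severe malnutrition. Includes tissue:plasma partition
    coefficient prediction (Rodgers-Rowland, tissue-composition and
    Schmitt-type methods), a 12-segment gastrointestinal absorption model
    with Weibull and particle-dissolution kinetics, stochastic virtual
    pediatric populations with enzyme ontogeny, WHO-style growth z-scores,
    a library of six worked drug models, and virtual-trial tooling to
    compare flat versus body-weight-adjusted dosing between malnourished
    and non-malnourished populations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
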