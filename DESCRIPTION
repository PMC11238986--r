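Package: fmloop
Title: Multistable Neuroendocrine Loop Models of Fibromyalgia Pathogenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic dynamical-systems toolkit for a multistable
    neuroendocrine account of fibromyalgia pathogenesis.  Implements a
    three-node thalamocortical firing-rate loop (ventroposterolateral
    nucleus, somatosensory cortex, thalamic reticular nucleus) with
    equilibrium enumeration, Jacobian stability classification and
    saddle-node bifurcation location over the GABAergic coupling strength;
    a two-component Hill map from brain allopregnanolone concentration to
    GABAergic strength together with its full calibration chain; a mutually
    inhibitory HPG-HPA endocrine system with basin-of-attraction mapping;
    and a coupled scenario layer that propagates the endocrine steady state
    into the thalamocortical regime and computes the predicted gender
    prevalence.  Hill-function primitives, least-squares dose-response
    fitting, packaged reference tables and a synthetic dose-response
    generator support fit-recovery testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
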