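Package: foldkin
Title: Discrete Kinetic Models of Protein Folding from Foldon Macrobasins
Version: 0.1.0
Authors@R:
    person("foldkin", "maintainers", email = "foldkin@example.org",
           role = c("aut", "cre"))
Description: Builds discrete kinetic models of protein folding on funneled
    energy landscapes. Residues are grouped into contiguous foldons; a
    Gaussian native-contact similarity coordinate Q measures the foldedness
    of each foldon, and thresholding the per-foldon Q values maps every
    simulation frame onto a binary macrobasin label such as "0101".
    Macrobasin free energies over a range of temperatures are estimated
    from umbrella-sampled windows with the multistate Bennett acceptance
    ratio (MBAR). A locally connected master equation with a universal
    downhill rate turns the free energies into a rate matrix, which is
    solved spectrally to predict relaxation rates, thermal chevron plots,
    and cumulative net fluxes from which dominant folding pathways are
    read off and exported as GraphViz DOT diagrams. A synthetic Ising-like
    landscape generator with exactly enumerable free energies provides
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
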