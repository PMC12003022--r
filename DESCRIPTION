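Package: granuleco
Title: Physico-Chemical Gradients and Niche-Based Community Ecology of
    Anaerobic Granular Sludge Size Fractions
Version: 0.1.0
Authors@R:
    person("Granule", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for anaerobic granular sludge studied across
    sieved size fractions.  Derives settling velocity and Stokes'-law particle
    density from drop-column measurements, total/volatile solids from
    loss-on-ignition masses, extracellular polymeric substance (EPS)
    composition proportions, and specific methanogenic activity (SMA) rates
    from headspace pressure time series.  Implements the taxon-centric
    community ecology stack used on the accompanying amplicon count tables:
    rarefaction, alpha diversity (richness, Shannon, Pielou), Bray-Curtis and
    unweighted UniFrac beta diversity with NMDS and PERMANOVA, ensemble
    quotient optimisation (a genetic-algorithm search for small genus subsets
    whose summed relative abundance tracks a covariate or is maximally
    stable), a permutation-null specificity score, Levins' and Hurlbert's
    niche breadth with generalist/specialist classification, and asymmetric
    Levins' niche overlap.  A structured synthetic-data generator with planted
    ground truth makes every stage testable without access to the original
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    vegan
Suggests:
    biomformat,
    phyloseq,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
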