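Package: betascape
Title: Continental-Scale Beta-Diversity Modeling from Occurrence Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping compositional turnover (beta diversity) from
    georeferenced species occurrence records. Records are grouped into
    geographic sample sites by Markov clustering of coordinate distances,
    filtered, and tallied into a site-by-species community matrix. Pairwise
    Horn-Morisita dissimilarity is modeled against geographic and
    environmental distances by multiple regression on distance matrices
    (MRM) with permutation inference, and by generalized dissimilarity
    modeling (GDM): monotone I-spline transforms of each predictor fitted
    under a negative-exponential link by non-negative deviance minimization,
    with richness-weighted site pairs. Fitted models transform environmental
    rasters to biological space and render predicted beta-diversity maps via
    PCA of the transformed layers. A synthetic-world generator provides
    niche-structured communities with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    pracma,
    splines,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    png,
    optparse
Config/testthat/edition: 3
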