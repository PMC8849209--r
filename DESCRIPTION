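Package: nutribalance
Title: Global Food-System Mass Balance and Nutrient Availability Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A global food-system mass-balance model in the food balance
    sheet (FBS) tradition.  Commodity-level supply ledgers (production,
    trade, feed, seed, processing, losses, other uses) are resolved into
    food available for human consumption; inedible portions and in-home
    waste are subtracted to approximate food consumed; consumed mass is
    converted into the availability of 29 nutrients via per-100 g
    composition tables, with bioavailability coefficients applied to
    protein and seven indispensable amino acids.  The package decomposes
    global nutrient availability into food-group contribution
    percentages, computes per-capita daily availability, and evaluates
    counterfactual scenarios (food-group removal, production scaling)
    including per-nutrient supply gaps against reference values and
    replacement multipliers.  A seeded synthetic-world generator and an
    independent brute-force oracle make every pipeline stage testable
    without external data downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite, withr, optparse
Config/testthat/edition: 3
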