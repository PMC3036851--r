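Package: markord
Title: Marker Ordering for Genetic Linkage Maps by Simulated Annealing
    and Rapid Chain Delineation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for ordering molecular markers within linkage groups
    when constructing genetic maps. Marker ordering is cast as an open
    traveling-salesman problem over pairwise map distances, minimizing the
    sum of adjacent recombination fractions (SARF). Two orderers are
    provided and can be compared head to head: a Metropolis-type simulated
    annealing search and the deterministic rapid chain delineation greedy
    with double/triple window inversions ("ripple"). The package also
    simulates F2 co-dominant populations over a user-specified genome,
    estimates pairwise recombination fractions by EM with LOD scores,
    converts between centimorgans and recombination fractions (Haldane,
    Kosambi), includes an exhaustive brute-force orderer as a ground-truth
    oracle for small marker sets, and reads and writes genotype (CSV,
    MAPMAKER raw) and distance-matrix (TSV) files.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    graphics,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
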