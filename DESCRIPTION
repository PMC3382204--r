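Package: topocand
Title: Candidate Disease Gene Prioritization from Combined Network Topological Features
Version: 0.1.0
Authors@R:
    person("PKG", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Prioritizes candidate disease genes on a protein-protein
    interaction network by combining disease-set-relative topological
    features (degree, disease-neighbor count and ratio, betweenness,
    clustering coefficient, mean shortest-path length to disease genes).
    Features are screened by Wilcoxon rank-sum disparity and by repeated
    balanced support-vector-machine cross-validation, all non-empty feature
    subsets are evaluated to pick an optimal combination, and candidates are
    called as the (configurable) intersection of positive predictions over
    many randomized balanced training rounds. Includes a synthetic-data
    generator (scale-free background with a planted disease module, plus
    expression matrices with planted differential expression) so the whole
    pipeline is testable without external databases, and a small
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
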