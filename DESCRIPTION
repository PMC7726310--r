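Package: petmsm
Title: Shared Diabetes Risk in Owner-Pet Pairs via Weibull-Markov Multistate Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for register-based studies of shared diabetes risk between
    pet owners and their dogs or cats. Provides a synthetic registry generator
    with known ground-truth transition intensities, diabetes phenotyping from
    ICD-10 / ATC / veterinary claim code streams, owner-pet pair cohort
    assembly with an auditable exclusion cascade, and maximum-likelihood
    fitting of a four-state Weibull-Markov multistate model with
    transition-pair covariate constraints, restricted cubic spline age
    effects, and household-cluster robust (sandwich) standard errors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
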