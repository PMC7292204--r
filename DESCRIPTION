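Package: fruitcarbon
Title: Carbon Balance Modelling and Rate Inversion for Tomato Fruit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying carbon allocation in developing tomato fruit
    with a simplified three-pool carbon-balance model (soluble sugar, starch
    and structural carbon). Provides forward simulation of the pool balance
    driven by fruit growth and temperature, with growth and Q10-responsive
    maintenance respiration; inversion of observed pool trajectories by local
    polynomial smoothing and derivative estimation to recover the time-varying
    conversion rates k3(t), k5m(t), the respiration coefficient k6(t) and the
    phloem carbon supply flux; a seeded synthetic-data generator emulating a
    four-level water deficit by two-level potassium factorial experiment;
    experimental-design arithmetic (irrigation amounts, potassium dosing); and
    the treatment statistics used in such studies (balanced three-way ANOVA,
    Fisher's LSD compact letter display, Kruskal-Wallis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
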