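Package: adjointpm
Title: Adjoint Source Attribution of Chronic PM2.5 Mortality Burden
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reduced gridded Eulerian chemical-transport model with an exact
    discrete adjoint, used to attribute the chronic-PM2.5 mortality burden of a
    receptor population back to emission sources resolved by location, sector,
    season, and emitted species. The backward model is driven by the derivative
    of a GEMM (Global Exposure Mortality Model) mortality cost function, or by
    its VSL-monetized twin, yielding mortality sensitivities (deaths per kton)
    and benefits per ton (USD per ton) for primary PM2.5 and precursor (SO2,
    NOx, NH3) emissions. Includes seeded synthetic-world generators, brute-force
    finite-difference verification of the adjoint gradients, regional and
    sectoral burden roll-ups for fractional emission reductions, and a
    stage-based pipeline with text-format gridded I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
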