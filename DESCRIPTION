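Package: prestinmem
Title: Electro-Viscoelastic Modeling of Prestin-Containing Cell Membranes
Version: 0.1.0
Authors@R:
    person("prestinmem", "maintainers", email = "prestinmem@example.org",
           role = c("aut", "cre"))
Description: Constitutive modeling of electrically active viscoelastic cell
    membranes that contain the motor protein prestin, such as the cochlear
    outer hair cell wall and the plasma membrane of prestin-transfected
    cells. Couples power-law (springpot) viscoelastic relaxation and creep
    kernels to a first-order RC-type prestin charge-transfer kernel, and
    derives the measurable responses: the normalized amplitude and phase of
    the isometric active force under harmonic electrical stimulation, and
    the time course of the electric charge generated by step pressure,
    constant-rate pressure, and constant-rate axial strain under voltage
    clamp. Includes numerical inverse Laplace transforms (fixed Talbot and
    Gaver-Stehfest), a generalized exponential integral of real order,
    least-squares estimation of the viscoelastic parameters from
    force-frequency sweeps and of the prestin time constant from filter
    amplitude surfaces, synthetic-data generators, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
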