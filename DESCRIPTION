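Package: spinscape
Title: NMR Spin Relaxation and Dynamic Landscapes from Bond-Vector Trajectories
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts NMR spin relaxation observables (15N T1, T2 and
    heteronuclear NOE; 2H T1 and T2) from molecular-dynamics bond-vector
    trajectories. Computes second-order Legendre (P2) rotational
    autocorrelation functions, fits them with a non-negative
    multi-exponential spectral model on a fixed logarithmic timescale grid,
    evaluates the analytic spectral density, and applies Redfield theory for
    dipolar, chemical-shift-anisotropy and quadrupolar relaxation
    mechanisms. Also provides per-residue dynamic-landscape summaries,
    micelle geometry analyses (distance-cutoff membership, radius of
    gyration, Stokes-Einstein rotational timescales, principal-axis angles,
    rotation removal), secondary-structure helicity correlations, and a
    synthetic rotational-diffusion generator with known ground truth for
    validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
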