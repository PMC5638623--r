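Package: gridforge
Title: Grid-Cell Pattern Formation from Spike-Rate Adaptation and STDP
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and analysis of a single-cell model in which
    grid-cell firing patterns emerge from spike-rate adaptation and
    spike-timing dependent plasticity (STDP) acting on spatially tuned
    Poisson inputs. Provides the stochastic spiking simulator, the
    deterministic averaged weight dynamics with its input-correlation
    operator, the Turing-type eigenvalue spectrum obtained by Hankel
    transforms (critical spatial frequency, largest eigenvalue,
    structure-formation time, parameter sweeps, and the attenuation
    factor for multi-field irregular inputs), correlated random-walk
    trajectories with optional Ornstein-Uhlenbeck speed modulation,
    and grid-pattern metrics (spatial autocorrelogram, gridness score,
    grid scale, orientation, and phase).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
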