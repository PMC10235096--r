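Package: reefcontext
Title: Environmental Context, Thermal History and Flow Diagnostics for
    Coral-Reef and Open-Ocean Sampling Stations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize the environment of coral-reef and
    open-ocean sampling stations. Computes historical sea-surface
    temperature climatologies and CoRTAD-style heat and cold
    thermal-stress indices (thermal stress anomalies, degree heating and
    cooling weeks, exceedance frequencies, site summaries); Eulerian and
    Lagrangian surface-flow diagnostics (kinetic energy, divergence,
    vorticity, Okubo-Weiss, finite-time Lyapunov exponents, Lagrangian
    divergence, retention time, flow-network betweenness) over
    stadium-shaped station regions; multi-source environmental-context
    aggregation with lag bookkeeping, satellite match-up buffer
    extraction, regression bias correction and priority merging;
    sampling-design provenance labels and station/island assignment; and
    normalized biovolume size spectra for plankton-net validation. A
    synthetic-data module generates every input with known ground truth
    so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    geosphere,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
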