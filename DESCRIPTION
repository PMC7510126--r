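Package: cpasl
Title: Multi-Delay Arterial Spin Labeling Quantification of Choroid Plexus Perfusion
Version: 0.1.0
Authors@R: person("cpasl", "maintainers", email = "cpasl@example.org", role = c("aut", "cre"))
Description: Kinetic modeling and quantification of choroid plexus and gray
    matter perfusion from multi-delay pseudo-continuous arterial spin
    labeling (pCASL) MRI. Implements the single-compartment dynamic ASL
    signal model with labeling duration and post-labeling delay schedules,
    proton-density based M0 calibration, constrained nonlinear
    least-squares estimation of apparent blood flow, arterial transit time
    and tissue T1 (voxelwise and region-of-interest), total and
    weight-corrected choroid plexus blood flow, exact paired Wilcoxon
    signed-rank group comparisons, and a synthetic digital phantom with
    CSF-filled lateral ventricles and a sheet-like choroid plexus for
    end-to-end validation. Includes a minimal NIfTI-1 volume reader/writer
    and a simulate/fit/report command-line pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
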