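# Shared fixtures: a unit calibration and a canonical step profile used by
# several background-rule tests.

unitCal <- function(A = 1, ...) surfaceDensityCalibration(A = A, ...)

# [1]*15, 9, [3]*15 -- rect background (1+3)/2 = 2, peak-minus-background 7
stepProfile <- function() intensityProfile(c(rep(1, 15), 9, rep(3, 15)))

# Quick scene renders used across files (small frame for speed)
quickScene <- function(...) renderScene(SyntheticScene(...))
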