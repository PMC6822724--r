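# Shared fixtures: short, fast runs used across test files.

musician_1hz <- function() sappa_params("musician", f = 1)
nonmusician_1hz <- function() sappa_params("nonmusician", f = 1)

drive_on <- function(fs = 1) {
  stimulus_spec("sinusoid", fs = fs, feedback_mode = "constant_self")
}
drive_off <- function(fs = 1) stimulus_spec("sinusoid", fs = fs)

# steady-state mean asynchrony (ms) for a one-oscillator configuration
quick_asynchrony <- function(params, spec, duration = 20, dt = 1e-3) {
  glance(measure_asynchrony(sappa_integrate(params, spec, duration, dt = dt)))
}
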