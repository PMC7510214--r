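# Shared fixtures: all synthetic, built in code.

# Fully deterministic configuration: no curve noise, no MLPA noise.
noiseless_config <- function(...) {
  sim_config(curve_noise_sd = 0, mlpa_cv = 0, mlpa_scale_sdlog = 0,
             mlpa_probe_sdlog = 0, ...)
}

# One-row sample specification with controlled DNA input and blood load.
make_spec <- function(smn1, smn2, id = "W1", input_dna_ng = 10,
                      blood_load = 1, tm_shift_c = 0, role = "SPECIMEN") {
  tibble::tibble(sample_id = id, role = role,
                 smn1_copies = as.integer(smn1),
                 smn2_copies = as.integer(smn2),
                 smn1_functional_copies = as.integer(smn1),
                 input_dna_ng = input_dna_ng, blood_load = blood_load,
                 tm_shift_c = tm_shift_c)
}

# A noiseless single logistic transition on the default grid.
single_transition_curve <- function(A, w, tm, cfg = noiseless_config(),
                                    id = "T1", step = NULL) {
  temps <- seq(cfg$temp_min_c, cfg$temp_max_c, by = step %||% cfg$temp_step_c)
  tibble::tibble(sample_id = id, temperature_c = temps,
                 fluorescence = cfg$baseline_fluorescence +
                   A * stats::plogis((tm - temps) / w))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Simulate a small plate (controls + given specimens) and return the pieces
# most tests need.
simulate_plate_run <- function(specimens, cfg = noiseless_config(),
                               seed = 1) {
  layout <- build_plates(specimens, cfg)
  curves <- simulate_melt_curves(layout, cfg, seed = seed)
  peaks <- call_peaks(curves, cfg)
  list(layout = layout, curves = curves, peaks = peaks,
       qc = qc_plates(peaks, layout),
       calls = classify_wells(peaks, layout))
}
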