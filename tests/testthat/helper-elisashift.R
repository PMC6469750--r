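# Shared fixtures, all built in code.

# The increasing-curve reading of the published reference parameters:
# lower asymptote -0.01 OD, upper 3.20, midpoint 1300 pg/mL, inverse
# slope 1/1.3, symmetric.
ref_params <- function() {
  curve_params(a = -0.01, d = 3.2, xmid = log(1300), scal = 1 / 1.3, g = 1)
}

# Noiseless standards data frame (x = log conc, od) for a given curve.
noiseless_standards <- function(p, levels = 8000 / 2^(0:7), reps = 3) {
  x <- rep(log(levels), each = reps)
  data.frame(x = x, od = logistic(x, p))
}

# A single synthetic plate as an elisa_plate-shaped CSV row block.
plate_csv_lines <- function() {
  c("plate_id,batch,run_date,operator,well,role,sample_id,conc,od",
    "P1,lot1,2017-10-11,MT,A1,standard,S1,1000,1.25")
}

write_tmp_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Small simulated dataset shared by several tests.
small_spec <- function(shifts = c(lot1 = 0, lot2 = 0.07, lot3 = 0.55),
                       plates = 2, noise = 0, seed = 11, ...) {
  sim_spec(batch_shifts = shifts, plates_per_batch = plates,
           od_noise_sd = noise, seed = seed, ...)
}
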