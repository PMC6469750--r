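# Synthetic plate generator with known truth.
#
# Generative model: the assay chemistry (OD versus *real* concentration)
# is the reference curve for every batch; a batch with shift S carries
# mislabelled standards, so a standard labelled c really contains
# c * e^{-S}. Its measured curve against the nominal labels is therefore
# the reference curve with midpoint xmid + S. Control and unknown wells
# respond at their true concentration on the reference curve — their ODs
# do not depend on the batch, only the labels of the standards do.
# Well noise is additive homoscedastic Gaussian on OD.

#' Specification for a synthetic ELISA experiment
#'
#' Defaults reproduce the validation testbed: a reference curve on the
#' scale of a real sandwich ELISA (lower asymptote -0.01 OD, upper 3.20,
#' midpoint 1300 pg/mL, inverse slope 1/1.3, symmetric), five kit lots
#' with true shifts (0, 0.07, 0.55, 0.65, 0.70) and (28, 19, 8, 4, 9)
#' plates, eight two-fold standard levels from 8000 pg/mL in triplicate,
#' OD noise sd 0.02, and one spiked control at 500 pg/mL on every plate.
#'
#' @param true_params [curve_params()] of the generating curve.
#' @param batch_shifts Named numeric vector of true shift factors; the
#'   first entry is the reference batch and must be 0.
#' @param standard_levels Standard concentrations (pg/mL), strictly
#'   positive and strictly decreasing.
#' @param n_replicates Wells per standard level (default 3).
#' @param plates_per_batch Plates per batch; scalar or one value per batch.
#' @param od_noise_sd Additive Gaussian OD noise sd (>= 0).
#' @param controls Data frame with `sample_id` and `conc` (true pg/mL), or
#'   `NULL` for no controls.
#' @param seed Integer RNG seed; simulation is bitwise reproducible.
#' @return A `"sim_spec"` list.
#' @export
sim_spec <- function(true_params = curve_params(a = -0.01, d = 3.2,
                                                xmid = log(1300),
                                                scal = 1 / 1.3, g = 1),
                     batch_shifts = c(lot1 = 0, lot2 = 0.07, lot3 = 0.55,
                                      lot4 = 0.65, lot5 = 0.70),
                     standard_levels = 8000 / 2^(0:7),
                     n_replicates = 3,
                     plates_per_batch = c(28, 19, 8, 4, 9),
                     od_noise_sd = 0.02,
                     controls = data.frame(sample_id = "C1", conc = 500),
                     seed = 20190417) {
  stopifnot(inherits(true_params, "curve_params"))
  if (is.null(names(batch_shifts)) || any(names(batch_shifts) == ""))
    es_stop("batch_shifts must be a fully named vector",
            "elisashift_validation_error")
  if (batch_shifts[[1]] != 0)
    es_stop("the first (reference) batch must have true S = 0",
            "elisashift_validation_error")
  if (any(standard_levels <= 0) || any(diff(standard_levels) >= 0))
    es_stop("standard_levels must be strictly positive and strictly decreasing",
            "elisashift_validation_error")
  if (od_noise_sd < 0)
    es_stop("od_noise_sd must be >= 0", "elisashift_validation_error")
  if (n_replicates < 1 || any(plates_per_batch < 1))
    es_stop("n_replicates and plates_per_batch must be >= 1",
            "elisashift_validation_error")
  if (length(plates_per_batch) == 1L)
    plates_per_batch <- rep(plates_per_batch, length(batch_shifts))
  if (length(plates_per_batch) != length(batch_shifts))
    es_stop("plates_per_batch must be scalar or one value per batch",
            "elisashift_validation_error")
  if (!is.null(controls)) {
    controls <- as.data.frame(controls)
    if (!all(c("sample_id", "conc") %in% names(controls)) ||
        any(controls$conc <= 0))
      es_stop("controls need sample_id and positive conc",
              "elisashift_validation_error")
  }
  structure(list(true_params = true_params, batch_shifts = batch_shifts,
                 standard_levels = standard_levels,
                 n_replicates = n_replicates,
                 plates_per_batch = plates_per_batch,
                 od_noise_sd = od_noise_sd, controls = controls,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

#' @export
print.sim_spec <- function(x, ...) {
  cat(sprintf("Synthetic ELISA spec: %d batch(es), %s plate(s), %d standard levels x %d reps, OD noise sd %g, seed %d\n",
              length(x$batch_shifts), sum(x$plates_per_batch),
              length(x$standard_levels), x$n_replicates, x$od_noise_sd,
              x$seed))
  print(x$batch_shifts)
  invisible(x)
}

#' Simulate ELISA plates with known truth
#'
#' Standard wells of batch *i* are drawn as
#' `od = logistic(x_nominal; xmid + S_i) + e`, `e ~ N(0, od_noise_sd^2)` —
#' the labels carry the nominal concentrations, so a nonzero shift models
#' mislabelled standards. Control wells are drawn on the reference curve
#' at their true log concentration, independent of batch. Standards occupy
#' plate columns 1–3 (rows A–H), controls column 4.
#'
#' @param spec A [sim_spec()].
#' @return An `"elisa_plates"` collection.
#' @export
simulate_plates <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  with_seed(spec$seed, {
    plates <- list()
    date0 <- as.Date("2017-09-01")
    operators <- c("MT", "BT", "JK")
    plate_no <- 0L
    for (bi in seq_along(spec$batch_shifts)) {
      batch <- names(spec$batch_shifts)[bi]
      S <- spec$batch_shifts[[bi]]
      shifted <- spec$true_params
      shifted$xmid <- shifted$xmid + S
      for (pi in seq_len(spec$plates_per_batch[bi])) {
        plate_no <- plate_no + 1L
        lv <- seq_along(spec$standard_levels)
        std <- data.frame(
          well = paste0(rep(LETTERS[lv], each = spec$n_replicates),
                        rep(seq_len(spec$n_replicates), length(lv))),
          role = "standard",
          sample_id = paste0("S", rep(lv, each = spec$n_replicates)),
          conc = rep(spec$standard_levels, each = spec$n_replicates),
          stringsAsFactors = FALSE)
        std$od <- logistic(log(std$conc), shifted) +
          stats::rnorm(nrow(std), 0, spec$od_noise_sd)
        wells <- std
        if (!is.null(spec$controls)) {
          ctl <- do.call(rbind, lapply(seq_len(nrow(spec$controls)),
                                       function(ci) {
            data.frame(
              well = paste0(LETTERS[seq_len(spec$n_replicates)], 3 + ci),
              role = "control",
              sample_id = spec$controls$sample_id[ci],
              conc = NA_real_,
              od = logistic(log(spec$controls$conc[ci]),
                            spec$true_params) +
                stats::rnorm(spec$n_replicates, 0, spec$od_noise_sd),
              stringsAsFactors = FALSE)
          }))
          wells <- rbind(wells, ctl)
        }
        plates[[plate_no]] <- new_plate(
          sprintf("%s_P%02d", batch, pi), batch,
          date0 + 7 * (plate_no - 1),
          operators[(plate_no - 1) %% length(operators) + 1], wells)
      }
    }
    structure(plates, class = "elisa_plates")
  })
}

#' Shift-recovery experiment: simulate, fit, compare to truth
#'
#' @param spec A [sim_spec()] with at least two batches.
#' @param mode Estimation mode passed to [fit_shift_model()].
#' @param model `"4pl"` or `"5pl"`.
#' @return Data frame with one row per batch: `batch, true_S, est_S, se_S`.
#' @export
recovery_experiment <- function(spec, mode = c("fixed_reference", "joint"),
                                model = c("4pl", "5pl")) {
  mode <- match.arg(mode)
  model <- match.arg(model)
  if (length(spec$batch_shifts) < 2L)
    es_stop("recovery experiment needs >= 2 batches",
            "elisashift_precondition_error")
  plates <- simulate_plates(spec)
  fit <- fit_shift_model(plates,
                         reference_batch = names(spec$batch_shifts)[1],
                         model = model, mode = mode)
  idx <- match(names(spec$batch_shifts), fit$shifts$batch)
  data.frame(batch = names(spec$batch_shifts),
             true_S = as.numeric(spec$batch_shifts),
             est_S = fit$shifts$S[idx], se_S = fit$shifts$se_S[idx],
             stringsAsFactors = FALSE)
}

#' Read a simulation spec from a key-value config file
#'
#' Plain-text format, one `key = value` per line; `#` starts a comment.
#' Keys: `a, d, xmid, scal, g` (curve), `batch_shifts` (e.g.
#' `lot1:0, lot2:0.07`), `standard_levels` (comma list, pg/mL),
#' `n_replicates`, `plates_per_batch` (comma list or scalar),
#' `od_noise_sd`, `controls` (e.g. `C1:500`), `seed`. Omitted keys take
#' the [sim_spec()] defaults.
#'
#' @param path Config file path.
#' @return A `"sim_spec"`.
#' @export
read_sim_spec <- function(path) {
  if (!file.exists(path))
    es_stopf("elisashift_io_error", "config file not found: %s", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[trimws(lines) != ""])
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, function(z) paste(z[-1], collapse = "="), ""))
  get1 <- function(k, default) if (k %in% keys) vals[keys == k][1] else default
  num <- function(k, default) as.numeric(get1(k, default))
  pairs <- function(txt) {
    items <- strsplit(strsplit(txt, ",")[[1]], ":")
    stats::setNames(vapply(items, function(z) as.numeric(trimws(z[2])),
                           numeric(1)),
                    vapply(items, function(z) trimws(z[1]), ""))
  }
  defaults <- sim_spec()
  bs <- if ("batch_shifts" %in% keys) pairs(get1("batch_shifts", "")) else
    defaults$batch_shifts
  ctl <- if ("controls" %in% keys) {
    cp <- pairs(get1("controls", ""))
    data.frame(sample_id = names(cp), conc = as.numeric(cp),
               stringsAsFactors = FALSE)
  } else defaults$controls
  lv <- if ("standard_levels" %in% keys)
    as.numeric(trimws(strsplit(get1("standard_levels", ""), ",")[[1]]))
  else defaults$standard_levels
  ppb <- if ("plates_per_batch" %in% keys)
    as.numeric(trimws(strsplit(get1("plates_per_batch", ""), ",")[[1]]))
  else defaults$plates_per_batch
  sim_spec(true_params = curve_params(num("a", defaults$true_params$a),
                                      num("d", defaults$true_params$d),
                                      num("xmid", defaults$true_params$xmid),
                                      num("scal", defaults$true_params$scal),
                                      num("g", defaults$true_params$g)),
           batch_shifts = bs, standard_levels = lv,
           n_replicates = num("n_replicates", defaults$n_replicates),
           plates_per_batch = ppb,
           od_noise_sd = num("od_noise_sd", defaults$od_noise_sd),
           controls = ctl, seed = num("seed", defaults$seed))
}
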