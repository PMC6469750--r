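# Reference-curve and shift-factor estimation.
#
# Statistical model: standard curves from every batch share (a, d, scal, g)
# and differ only in the midpoint, xmid_i = xmid + S_i, with the reference
# batch pinned at S = 0. S_i is the natural-log fold difference between a
# batch's nominal standard concentrations and their reference-scale values
# (relabelling a batch's standards by a factor N moves its S by ln N).

#' Fit the reference standard curve
#'
#' One pooled least-squares fit over every standard well of every supplied
#' plate (a single shared curve, no per-plate parameters). The plates given
#' here define the reference batch, whose standard concentrations are
#' treated as accurate.
#'
#' @param plates Plates of the designated reference batch.
#' @param model `"4pl"` or `"5pl"`.
#' @return A [curve_params()] object with the pooled fit attached as
#'   attributes `fit` (the `"curve_fit"`) and `n_curves`.
#' @export
fit_reference <- function(plates, model = c("4pl", "5pl")) {
  model <- match.arg(model)
  plates <- as_plate_list(plates)
  std <- standard_wells(plates)
  fit <- fit_curve(std, model)
  out <- fit$params
  attr(out, "fit") <- fit
  attr(out, "n_curves") <- length(plates)
  out
}

# RSS of a batch's standard wells against the reference curve with the
# midpoint displaced by S; used by the 1-D estimator and its oracle tests.
shift_rss <- function(S, std, reference) {
  shifted <- reference
  shifted$xmid <- reference$xmid + S
  sum((std$od - logistic(std$x, shifted))^2)
}

# Analytic derivative of the shifted-curve mean response with respect to S.
dmu_dS <- function(S, x, p) {
  u <- exp((p$xmid + S - x) / p$scal)
  -(p$d - p$a) * p$g * u / (p$scal * (1 + u)^(p$g + 1))
}

#' Estimate the shift factor of one batch against a reference curve
#'
#' One-dimensional least squares in `S` only: every curve parameter is held
#' at its reference value and the midpoint becomes `xmid + S`. The search
#' starts from the best point of a coarse grid over `[-6, 6]` and is
#' polished by Levenberg–Marquardt. The standard error comes from the
#' linearized curvature at the optimum,
#' `se = sqrt(rss/(n-1) / sum((dmu/dS)^2))`.
#'
#' @param plates Plates of a single batch (or any collection of plates to
#'   be treated as one batch).
#' @param reference A [curve_params()] reference curve.
#' @param batch Batch label for the result; defaults to the plates' label.
#' @return A one-row data frame (class `"batch_shift"`) with columns
#'   `batch, S, se_S, adjusted_xmid, n_curves, n_points, rss`.
#' @export
estimate_shift <- function(plates, reference, batch = NULL) {
  stopifnot(inherits(reference, "curve_params"))
  plates <- as_plate_list(plates)
  std <- standard_wells(plates)
  if (length(unique(std$x)) < 4L)
    es_stop("shift estimation requires >= 4 distinct standard levels",
            "elisashift_precondition_error")
  if (is.null(batch)) batch <- std$batch[1]

  asym <- sort(c(reference$a, reference$d))
  if (all(std$od <= asym[1]) || all(std$od >= asym[2]))
    es_stop(sprintf("batch %s: all ODs outside the reference asymptotes; shift not estimable",
                    batch),
            "elisashift_estimation_error")

  grid <- seq(-6, 6, by = 0.1)
  rss_grid <- vapply(grid, shift_rss, numeric(1), std = std,
                     reference = reference)
  s0 <- grid[which.min(rss_grid)]
  lm_fit <- tryCatch(
    minpack.lm::nls.lm(par = c(S = s0), fn = function(par) {
      shifted <- reference
      shifted$xmid <- reference$xmid + par[[1]]
      std$od - logistic(std$x, shifted)
    }, control = es_lm_control()),
    error = function(e) NULL)
  if (is.null(lm_fit) || !lm_fit$info %in% 1:4)
    es_stop(sprintf("shift estimation for batch %s did not converge", batch),
            "elisashift_convergence_error", best = lm_fit)
  S <- lm_fit$par[[1]]
  rss <- sum(lm_fit$fvec^2)
  n <- nrow(std)
  jac <- dmu_dS(S, std$x, reference)
  se_S <- if (n > 1 && sum(jac^2) > 0)
    sqrt((rss / (n - 1)) / sum(jac^2)) else NA_real_
  structure(data.frame(batch = batch, S = S, se_S = se_S,
                       adjusted_xmid = reference$xmid + S,
                       n_curves = length(plates), n_points = n, rss = rss,
                       stringsAsFactors = FALSE),
            class = c("batch_shift", "data.frame"))
}

#' Per-plate shift factors against a reference curve
#'
#' Applies [estimate_shift()] to each plate separately — the granularity
#' used to monitor individual standard curves for quality control.
#'
#' @param plates Plates from any number of batches.
#' @param reference A [curve_params()] reference curve.
#' @return Data frame with one row per plate: `plate_id, batch, S, se_S,
#'   n_points`.
#' @export
plate_shifts <- function(plates, reference) {
  plates <- as_plate_list(plates)
  rows <- lapply(plates, function(p) {
    s <- estimate_shift(p, reference, batch = p$batch)
    data.frame(plate_id = p$plate_id, batch = p$batch, S = s$S,
               se_S = s$se_S, n_points = s$n_points,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Joint estimation of the shared curve and all shift factors
#'
#' Simultaneous least squares over the shared logistic parameters and one
#' `S_i` per non-reference batch (the reference batch's shift is identically
#' 0). This is the full statistical model; [fit_shift_model()] with
#' `mode = "fixed_reference"` is the two-stage operational variant.
#'
#' @param batches Named list of plate collections, as from
#'   [group_by_batch()].
#' @param reference_batch Name of the batch pinned at `S = 0`.
#' @param model `"4pl"` or `"5pl"`.
#' @return A `"shift_model"` object; see [fit_shift_model()].
#' @export
fit_joint <- function(batches, reference_batch, model = c("4pl", "5pl")) {
  model <- match.arg(model)
  if (!reference_batch %in% names(batches))
    es_stopf("elisashift_value_error",
             "reference batch '%s' not among batches (%s)",
             reference_batch, paste(names(batches), collapse = ", "))
  if (length(batches) < 2L)
    es_stop("joint fitting requires at least 2 batches",
            "elisashift_precondition_error")
  for (b in names(batches)) {
    nb <- length(unique(standard_wells(batches[[b]])$x))
    if (nb < 4L)
      es_stopf("elisashift_data_error",
               "batch %s has only %d distinct standard levels (need >= 4)",
               b, nb)
  }

  # two-stage estimates as starting values
  start_model <- fit_fixed_reference(batches, reference_batch, model)
  other <- setdiff(names(batches), reference_batch)
  std <- do.call(rbind, lapply(names(batches), function(b) {
    w <- standard_wells(batches[[b]])
    w$batch <- b
    w
  }))
  batch_idx <- match(std$batch, c(reference_batch, other))

  n_curve_par <- if (model == "5pl") 5L else 4L
  par0 <- c(cp_to_par(start_model$reference, model),
            stats::setNames(start_model$shifts$S[match(other, start_model$shifts$batch)],
                            paste0("S_", other)))
  lower <- c(rep(-Inf, 4), if (model == "5pl") log(0.1),
             rep(-Inf, length(other)))
  upper <- c(rep(Inf, 4), if (model == "5pl") log(10),
             rep(Inf, length(other)))

  resid_fn <- function(par) {
    p <- par_to_cp(par[seq_len(n_curve_par)], model)
    S_all <- c(0, par[-seq_len(n_curve_par)])[batch_idx]
    shifted_xmid <- p$xmid + S_all
    std$od - (p$a + (p$d - p$a) /
                (1 + exp((shifted_xmid - std$x) / p$scal))^p$g)
  }
  lm_fit <- tryCatch(
    minpack.lm::nls.lm(par = par0, fn = resid_fn, lower = lower,
                       upper = upper, control = es_lm_control()),
    error = function(e) NULL)
  if (is.null(lm_fit) || !lm_fit$info %in% 1:4)
    es_stop("joint shift-model fit did not converge",
            "elisashift_convergence_error", best = lm_fit)

  reference <- par_to_cp(lm_fit$par[seq_len(n_curve_par)], model)
  S_other <- lm_fit$par[-seq_len(n_curve_par)]
  rss <- sum(lm_fit$fvec^2)
  n <- nrow(std)
  p_eff <- length(par0)

  # covariance from a forward-difference Jacobian of the residuals
  se_other <- rep(NA_real_, length(other))
  jac <- tryCatch({
    eps <- 1e-6
    base <- resid_fn(lm_fit$par)
    vapply(seq_along(lm_fit$par), function(j) {
      pj <- lm_fit$par
      pj[j] <- pj[j] + eps
      (resid_fn(pj) - base) / eps
    }, numeric(n))
  }, error = function(e) NULL)
  if (!is.null(jac) && n > p_eff) {
    cv <- tryCatch(solve(crossprod(jac)) * rss / (n - p_eff),
                   error = function(e) NULL)
    if (!is.null(cv))
      se_other <- sqrt(diag(cv))[-seq_len(n_curve_par)]
  }

  shifts <- batch_shift_table(batches, reference_batch, reference,
                              S = stats::setNames(c(0, S_other),
                                                  c(reference_batch, other)),
                              se = stats::setNames(c(NA_real_, se_other),
                                                   c(reference_batch, other)))
  new_shift_model(reference, shifts, model, reference_batch, rss,
                  mode = "joint", data = std,
                  df_residual = n - p_eff, converged = TRUE)
}

batch_shift_table <- function(batches, reference_batch, reference, S, se) {
  rows <- lapply(names(batches), function(b) {
    std <- standard_wells(batches[[b]])
    data.frame(batch = b, S = S[[b]], se_S = se[[b]],
               adjusted_xmid = reference$xmid + S[[b]],
               n_curves = length(batches[[b]]), n_points = nrow(std),
               x_lo = min(std$x), x_hi = max(std$x),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

fit_fixed_reference <- function(batches, reference_batch, model) {
  reference <- fit_reference(batches[[reference_batch]], model)
  ref_fit <- attr(reference, "fit")
  other <- setdiff(names(batches), reference_batch)
  est <- lapply(other, function(b)
    estimate_shift(batches[[b]], reference, batch = b))
  S <- stats::setNames(c(0, vapply(est, function(e) e$S, numeric(1))),
                       c(reference_batch, other))
  se <- stats::setNames(c(NA_real_, vapply(est, function(e) e$se_S,
                                           numeric(1))),
                        c(reference_batch, other))
  shifts <- batch_shift_table(batches, reference_batch, reference, S, se)
  std <- do.call(rbind, lapply(names(batches), function(b) {
    w <- standard_wells(batches[[b]])
    w$batch <- b
    w
  }))
  rss <- ref_fit$rss + sum(vapply(est, function(e) e$rss, numeric(1)))
  p_eff <- (if (model == "5pl") 5L else 4L) + length(other)
  new_shift_model(strip_attrs(reference), shifts, model, reference_batch,
                  rss, mode = "fixed_reference", data = std,
                  df_residual = nrow(std) - p_eff, converged = TRUE)
}

strip_attrs <- function(p) curve_params(p$a, p$d, p$xmid, p$scal, p$g)

new_shift_model <- function(reference, shifts, model, reference_batch, rss,
                            mode, data, df_residual, converged) {
  structure(list(reference = reference, shifts = shifts, model = model,
                 reference_batch = reference_batch, rss = rss, mode = mode,
                 data = data, df_residual = df_residual,
                 converged = converged),
            class = "shift_model")
}

#' Fit a shift-factor batch-correction model
#'
#' The package's central fitting function. A reference standard curve
#' (4PL/5PL) is estimated together with one shift factor `S` per batch;
#' the reference batch has `S = 0` exactly. Two estimation modes:
#'
#' * `"fixed_reference"` (default, the operational workflow): the curve is
#'   fitted once, pooled over the reference batch's plates, then each other
#'   batch's `S` is a one-dimensional least-squares fit against it.
#' * `"joint"`: all shared parameters and all shifts are estimated
#'   simultaneously from every batch.
#'
#' In the noiseless limit the two modes coincide. "Batch" is whatever the
#' plates' `batch` labels say — a kit lot, or a single plate if per-plate
#' correction is wanted.
#'
#' @param plates An `"elisa_plates"` collection (e.g. from [read_plates()]
#'   or [simulate_plates()]).
#' @param reference_batch Batch treated as accurately labelled; defaults to
#'   the first batch label encountered.
#' @param model `"4pl"` or `"5pl"`.
#' @param mode `"fixed_reference"` or `"joint"`.
#' @return An object of class `"shift_model"` with components `reference`
#'   ([curve_params()]), `shifts` (data frame: `batch, S, se_S,
#'   adjusted_xmid, n_curves, n_points, x_lo, x_hi`), `model`,
#'   `reference_batch`, `rss`, `mode`, `data` (standard wells used),
#'   `df_residual`, `converged`. Supports `print()`, `summary()`,
#'   `coef()`, `predict()`, `fitted()`, `residuals()`, `plot()` and
#'   `simulate()`.
#' @examples
#' spec <- sim_spec(batch_shifts = c(lot1 = 0, lot2 = log(2)),
#'                  plates_per_batch = 2, od_noise_sd = 0, seed = 1)
#' fit <- fit_shift_model(simulate_plates(spec), reference_batch = "lot1")
#' fit$shifts[, c("batch", "S")]   # recovers ln 2 for lot2
#' @export
fit_shift_model <- function(plates, reference_batch = NULL,
                            model = c("4pl", "5pl"),
                            mode = c("fixed_reference", "joint")) {
  model <- match.arg(model)
  mode <- match.arg(mode)
  batches <- group_by_batch(plates)
  if (is.null(reference_batch)) reference_batch <- names(batches)[1]
  if (!reference_batch %in% names(batches))
    es_stopf("elisashift_value_error", "reference batch '%s' not found",
             reference_batch)
  out <- if (mode == "joint")
    fit_joint(batches, reference_batch, model)
  else
    fit_fixed_reference(batches, reference_batch, model)
  out
}

#' @export
print.shift_model <- function(x, digits = 4, ...) {
  cat(sprintf("Shift-factor model (%s, %s mode)\n", x$model, x$mode))
  cat(sprintf("Reference batch: %s (S = 0)\n", x$reference_batch))
  cat("Reference curve: ")
  cat(paste(sprintf("%s = %s", names(unclass(x$reference)),
                    signif(unlist(x$reference), digits + 2)),
            collapse = ", "), "\n")
  cat("Shift factors:\n")
  print(data.frame(batch = x$shifts$batch,
                   S = round(x$shifts$S, 4),
                   se_S = signif(x$shifts$se_S, 3),
                   n_curves = x$shifts$n_curves), row.names = FALSE)
  cat(sprintf("Residual sum of squares: %s on %d degrees of freedom\n",
              format(x$rss, digits = digits), x$df_residual))
  invisible(x)
}

#' @export
summary.shift_model <- function(object, ...) {
  sigma <- sqrt(object$rss / max(object$df_residual, 1))
  structure(list(model = object, sigma = sigma), class = "summary.shift_model")
}

#' @export
print.summary.shift_model <- function(x, ...) {
  print(x$model)
  cat(sprintf("Residual standard deviation (OD): %.4g\n", x$sigma))
  sh <- x$model$shifts
  sh <- sh[sh$batch != x$model$reference_batch & is.finite(sh$se_S), ,
           drop = FALSE]
  if (nrow(sh) > 0) {
    z <- sh$S / sh$se_S
    cat("Approximate z-statistics for non-reference shifts:\n")
    print(stats::setNames(round(z, 2), sh$batch))
  }
  invisible(x)
}

#' @export
coef.shift_model <- function(object, ...) {
  p <- unlist(unclass(object$reference))
  sh <- object$shifts
  c(p, stats::setNames(sh$S, paste0("S_", sh$batch)))
}

#' @export
fitted.shift_model <- function(object, ...) {
  if (is.null(object$data)) return(NULL)
  S <- object$shifts$S[match(object$data$batch, object$shifts$batch)]
  p <- object$reference
  p$a + (p$d - p$a) /
    (1 + exp((p$xmid + S - object$data$x) / p$scal))^p$g
}

#' @export
residuals.shift_model <- function(object, ...) {
  if (is.null(object$data)) return(NULL)
  object$data$od - fitted(object)
}

#' Predict from a shift-factor model
#'
#' @param object A `"shift_model"`.
#' @param newdata Data frame. For `type = "od"`: columns `conc` (pg/mL) and
#'   `batch` — returns the fitted OD on each batch's shifted curve. For
#'   `type = "conc"`: columns `od` and `batch` — inverse prediction,
#'   returning raw (batch-scale) and adjusted (reference-scale)
#'   concentrations; ODs outside the asymptotes give `NA`.
#' @param type `"conc"` (default) or `"od"`.
#' @param ... Unused.
#' @return For `"od"` a numeric vector; for `"conc"` a data frame with
#'   columns `raw_conc` and `adjusted_conc`.
#' @export
predict.shift_model <- function(object, newdata, type = c("conc", "od"),
                                ...) {
  type <- match.arg(type)
  newdata <- as.data.frame(newdata)
  S <- object$shifts$S[match(newdata$batch, object$shifts$batch)]
  if (any(is.na(S)))
    es_stopf("elisashift_lookup_error", "unknown batch '%s'",
             newdata$batch[is.na(S)][1])
  if (type == "od") {
    p <- object$reference
    return(p$a + (p$d - p$a) /
             (1 + exp((p$xmid + S - log(newdata$conc)) / p$scal))^p$g)
  }
  raw_log <- vapply(seq_len(nrow(newdata)), function(i) {
    shifted <- object$reference
    shifted$xmid <- shifted$xmid + S[i]
    tryCatch(inverse_logistic(newdata$od[i], shifted),
             elisashift_range_error = function(e) NA_real_)
  }, numeric(1))
  data.frame(raw_conc = exp(raw_log), adjusted_conc = exp(raw_log - S))
}

#' Simulate standard-well ODs from a fitted shift model
#'
#' Draws new OD values at the fitted model's own design points (the
#' standard wells it was fitted to), from the batch-shifted curves plus
#' Gaussian noise at the residual standard deviation — the parametric
#' bootstrap generator for this model.
#'
#' @param object A `"shift_model"` with its fitting data attached.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return A data frame with `nsim` columns (`sim_1`, ...), one row per
#'   standard well in `object$data`.
#' @export
simulate.shift_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(object$data))
    es_stop("model carries no data to simulate from",
            "elisashift_value_error")
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  sigma <- sqrt(object$rss / max(object$df_residual, 1))
  out <- as.data.frame(replicate(nsim, mu + stats::rnorm(length(mu), 0, sigma)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot a shift-factor model
#'
#' Standard-well ODs against log concentration, coloured by batch, with the
#' reference curve (solid) and each batch's shifted curve (dashed).
#'
#' @param x A `"shift_model"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.shift_model <- function(x, ...) {
  if (is.null(x$data))
    es_stop("model carries no data to plot", "elisashift_value_error")
  batches <- x$shifts$batch
  cols <- grDevices::hcl.colors(max(3L, length(batches)), "Dark 3")
  col_of <- stats::setNames(cols[seq_along(batches)], batches)
  graphics::plot(x$data$x, x$data$od, col = col_of[x$data$batch],
                 xlab = "log concentration (ln pg/mL)",
                 ylab = "optical density", pch = 16, cex = 0.6, ...)
  xx <- seq(min(x$data$x) - 1, max(x$data$x) + 1, length.out = 200)
  graphics::lines(xx, logistic(xx, x$reference), lwd = 2)
  for (i in seq_along(batches)) {
    shifted <- x$reference
    shifted$xmid <- x$shifts$adjusted_xmid[i]
    graphics::lines(xx, logistic(xx, shifted), lty = 2,
                    col = col_of[batches[i]])
  }
  graphics::legend("topleft", legend = batches, col = col_of[batches],
                   pch = 16, bty = "n")
  invisible(x)
}

#' Persist a shift model to a flat key-value text file
#'
#' The file stores the mode, model, reference batch, curve parameters and
#' one line per batch (`batch, S, se_S, n_curves, n_points, x_lo, x_hi`)
#' with full double precision, so [read_shift_model()] reproduces the
#' stored numbers bit-exactly. The fitting data are not persisted.
#'
#' @param model A `"shift_model"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_shift_model <- function(model, path) {
  stopifnot(inherits(model, "shift_model"))
  p <- model$reference
  lines <- c(
    "format = elisashift/shift_model/1",
    paste("model =", model$model),
    paste("mode =", model$mode),
    paste("reference_batch =", model$reference_batch),
    paste("a =", fmt_num(p$a)), paste("d =", fmt_num(p$d)),
    paste("xmid =", fmt_num(p$xmid)), paste("scal =", fmt_num(p$scal)),
    paste("g =", fmt_num(p$g)), paste("rss =", fmt_num(model$rss)),
    paste("df_residual =", model$df_residual),
    vapply(seq_len(nrow(model$shifts)), function(i) {
      s <- model$shifts[i, ]
      paste("batch =", paste(s$batch, fmt_num(s$S), fmt_num(s$se_S),
                             s$n_curves, s$n_points, fmt_num(s$x_lo),
                             fmt_num(s$x_hi), sep = "\t"))
    }, character(1)))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) es_stopf("elisashift_io_error", "cannot write to %s", path)
  invisible(path)
}

#' @rdname write_shift_model
#' @export
read_shift_model <- function(path) {
  if (!file.exists(path))
    es_stopf("elisashift_io_error", "model file not found: %s", path)
  lines <- readLines(path)
  kv <- strsplit(lines, " = ", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, function(z) paste(z[-1], collapse = " = "), "")
  get1 <- function(k) {
    v <- vals[keys == k]
    if (length(v) != 1)
      es_stopf("elisashift_format_error", "model file lacks field '%s'", k)
    v
  }
  if (get1("format") != "elisashift/shift_model/1")
    es_stop("unrecognized model file format", "elisashift_format_error")
  num <- function(s) if (s %in% c("NA", "NaN")) NA_real_ else as.numeric(s)
  reference <- curve_params(num(get1("a")), num(get1("d")),
                            num(get1("xmid")), num(get1("scal")),
                            num(get1("g")))
  shift_rows <- vals[keys == "batch"]
  shifts <- do.call(rbind, lapply(shift_rows, function(r) {
    f <- strsplit(r, "\t", fixed = TRUE)[[1]]
    data.frame(batch = f[1], S = num(f[2]), se_S = num(f[3]),
               adjusted_xmid = reference$xmid + num(f[2]),
               n_curves = as.integer(f[4]), n_points = as.integer(f[5]),
               x_lo = num(f[6]), x_hi = num(f[7]),
               stringsAsFactors = FALSE)
  }))
  new_shift_model(reference, shifts, get1("model"), get1("reference_batch"),
                  as.numeric(get1("rss")), mode = get1("mode"), data = NULL,
                  df_residual = as.integer(get1("df_residual")),
                  converged = TRUE)
}
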