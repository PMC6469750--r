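# Four- and five-parameter logistic calibration curves: evaluation,
# closed-form inversion, self-start heuristic, and least-squares fitting.

#' Logistic curve parameters
#'
#' Container for the parameters of the five-parameter logistic (5PL)
#' calibration function
#' \deqn{Y = a + \frac{d - a}{\left(1 + e^{(xmid - x)/scal}\right)^g}}
#' where \eqn{x} is natural-log analyte concentration and \eqn{Y} the
#' optical density (OD). With \eqn{g = 1} this is the familiar 4PL.
#'
#' @param a Lower asymptote (OD), approached at low concentration for an
#'   increasing curve (`scal > 0`).
#' @param d Upper asymptote (OD). Must differ from `a`.
#' @param xmid Natural-log concentration at the inflexion point.
#' @param scal Inverse slope at the inflexion; nonzero. Positive `scal`
#'   with `d > a` gives a strictly increasing curve.
#' @param g Asymmetry factor, strictly positive; `g = 1` recovers the 4PL.
#' @return An object of class `"curve_params"`.
#' @examples
#' p <- curve_params(a = -0.01, d = 3.2, xmid = log(1300), scal = 1/1.3)
#' logistic(log(1300), p)  # midpoint OD = (a + d)/2 for g = 1
#' @export
curve_params <- function(a, d, xmid, scal, g = 1) {
  vals <- c(a = a, d = d, xmid = xmid, scal = scal, g = g)
  if (!is.numeric(vals) || length(vals) != 5L || any(!is.finite(vals)))
    es_stop("curve parameters must be finite numbers", "elisashift_value_error")
  if (d == a)
    es_stop("asymptotes 'a' and 'd' must differ", "elisashift_value_error")
  if (scal == 0)
    es_stop("'scal' must be nonzero", "elisashift_value_error")
  if (g <= 0)
    es_stop("asymmetry 'g' must be positive", "elisashift_value_error")
  structure(list(a = a, d = d, xmid = xmid, scal = scal, g = g),
            class = "curve_params")
}

#' @export
print.curve_params <- function(x, digits = 6, ...) {
  cat("Logistic curve parameters (", if (x$g == 1) "4PL" else "5PL", "):\n",
      sep = "")
  print(signif(unlist(x), digits))
  invisible(x)
}

#' @export
as.list.curve_params <- function(x, ...) unclass(x)

#' Evaluate the logistic calibration curve
#'
#' @param x Numeric vector of natural-log concentrations.
#' @param p A [curve_params()] object.
#' @return OD values, same length as `x`. Total function: values beyond the
#'   asymptotes are never produced; infinite `x` map to the asymptotes.
#' @export
logistic <- function(x, p) {
  stopifnot(inherits(p, "curve_params"))
  p$a + (p$d - p$a) / (1 + exp((p$xmid - x) / p$scal))^p$g
}

#' Invert the logistic calibration curve
#'
#' Closed-form inverse prediction:
#' \eqn{x = xmid - scal\,\ln\!\big(((d-a)/(y-a))^{1/g} - 1\big)}.
#'
#' @param y OD value(s), strictly inside the open asymptote interval.
#' @param p A [curve_params()] object.
#' @return Natural-log concentration(s).
#' @details An OD at or beyond the low-concentration asymptote raises an
#'   error of class `"elisashift_range_error"` with `side = "below_range"`;
#'   at or beyond the high-concentration asymptote, `side = "above_range"`.
#' @export
inverse_logistic <- function(y, p) {
  stopifnot(inherits(p, "curve_params"))
  increasing <- (p$d > p$a) == (p$scal > 0)
  # the asymptote reached as x -> -Inf is always `a`
  lo_side_a <- if (p$a < p$d) y <= p$a else y >= p$a
  hi_side_d <- if (p$a < p$d) y >= p$d else y <= p$d
  if (any(lo_side_a))
    es_stop(sprintf("OD %g at or beyond the low-concentration asymptote (a = %g)",
                    y[lo_side_a][1], p$a),
            "elisashift_range_error",
            side = if (increasing) "below_range" else "above_range")
  if (any(hi_side_d))
    es_stop(sprintf("OD %g at or beyond the high-concentration asymptote (d = %g)",
                    y[hi_side_d][1], p$d),
            "elisashift_range_error",
            side = if (increasing) "above_range" else "below_range")
  p$xmid - p$scal * log(((p$d - p$a) / (y - p$a))^(1 / p$g) - 1)
}

#' Heuristic starting values for a logistic fit
#'
#' Self-start rule: asymptotes padded 5% beyond the observed OD range,
#' `xmid` from linear interpolation of the level means at the half-height,
#' `scal` from the central slope (the 4PL slope at the inflexion is
#' `(d - a) / (4 scal)`), and `g = 1`.
#'
#' @param standards A data frame with numeric columns `x` (log
#'   concentration) and `od`.
#' @return A [curve_params()] object inside the basin of attraction of the
#'   least-squares optimum for well-behaved sigmoid data.
#' @export
initial_params <- function(standards) {
  standards <- as.data.frame(standards)
  x <- standards$x; od <- standards$od
  if (length(unique(x)) < 4L)
    es_stop("at least 4 distinct standard levels are required",
            "elisashift_precondition_error")
  rng <- max(od) - min(od)
  if (rng == 0)
    es_stop("all OD values are equal; curve is degenerate",
            "elisashift_degenerate_error")
  a <- min(od) - 0.05 * rng
  d <- max(od) + 0.05 * rng
  mx <- sort(unique(x))
  mo <- vapply(mx, function(v) mean(od[x == v]), numeric(1))
  slope <- stats::coef(stats::lm(mo ~ mx))[[2]]
  ymid <- (a + d) / 2
  xmid <- tryCatch(stats::approx(mo, mx, xout = ymid, ties = mean)$y,
                   error = function(e) NA_real_, warning = function(w) NA_real_)
  if (!is.finite(xmid)) xmid <- mx[which.min(abs(mo - ymid))]
  # slope of the central portion estimates (d - a)/(4 scal)
  mid_band <- mo > min(mo) + 0.25 * (max(mo) - min(mo)) &
              mo < max(mo) - 0.25 * (max(mo) - min(mo))
  b <- if (sum(mid_band) >= 2)
    stats::coef(stats::lm(mo[mid_band] ~ mx[mid_band]))[[2]] else slope
  scal <- if (is.finite(b) && b != 0) (d - a) / (4 * b) else sign(slope) * 1
  if (!is.finite(scal) || scal == 0) scal <- if (slope < 0) -1 else 1
  curve_params(a = a, d = d, xmid = xmid, scal = scal, g = 1)
}

# Map an unconstrained optimizer vector to curve_params. g is carried on
# the log scale so the bound g in [0.1, 10] is a box constraint.
par_to_cp <- function(par, model) {
  g <- if (model == "5pl") exp(par[[5]]) else 1
  curve_params(a = par[[1]], d = par[[2]], xmid = par[[3]],
               scal = par[[4]], g = g)
}

cp_to_par <- function(p, model) {
  out <- c(a = p$a, d = p$d, xmid = p$xmid, scal = p$scal)
  if (model == "5pl") out <- c(out, lg = log(p$g))
  out
}

# Optimizer contract shared by fit_curve() and fit_joint().
es_lm_control <- function() {
  minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10, gtol = 0,
                             maxiter = 500)
}

MULTISTART_SEED <- 20190417L

#' Fit a logistic standard curve by nonlinear least squares
#'
#' Levenberg–Marquardt least squares on individual replicate wells (never
#' replicate means). `model = "4pl"` fixes `g = 1`; `model = "5pl"`
#' estimates `g` on the log scale within `[0.1, 10]`. If the fit from the
#' heuristic start does not converge, up to 10 restarts are attempted from
#' log-normally perturbed starts (factor 1.2, fixed internal seed).
#'
#' @param standards Data frame with columns `x` (natural-log concentration,
#'   pg/mL) and `od`; an optional `well` column is used in error messages.
#' @param model `"4pl"` or `"5pl"`.
#' @param start Optional [curve_params()] starting values (default:
#'   [initial_params()]).
#' @return An object of class `"curve_fit"`: a list with `params`
#'   ([curve_params()]), `rss`, `n_points`, `converged`, `n_iter`.
#' @examples
#' p <- curve_params(0, 3.2, log(1300), 1/1.3)
#' std <- data.frame(x = log(rep(8000 / 2^(0:7), each = 3)))
#' std$od <- logistic(std$x, p)
#' fit <- fit_curve(std, "4pl")
#' unlist(fit$params)
#' @export
fit_curve <- function(standards, model = c("4pl", "5pl"), start = NULL) {
  model <- match.arg(model)
  standards <- as.data.frame(standards)
  if (!all(c("x", "od") %in% names(standards)))
    es_stop("standards must have columns 'x' and 'od'",
            "elisashift_value_error")
  bad <- which(!is.finite(standards$od) | !is.finite(standards$x))
  if (length(bad) > 0) {
    label <- if ("well" %in% names(standards))
      paste(standards$well[bad], collapse = ", ") else
      paste("row", paste(bad, collapse = ", "))
    es_stopf("elisashift_value_error",
             "non-finite OD or concentration at %s", label)
  }
  n_distinct <- length(unique(standards$x))
  need <- if (model == "4pl") 4L else 5L
  if (n_distinct < need)
    es_stopf("elisashift_precondition_error",
             "%s fit requires >= %d distinct standard levels, got %d",
             model, need, n_distinct)

  if (is.null(start)) start <- initial_params(standards)
  x <- standards$x; od <- standards$od
  resid_fn <- function(par) od - logistic(x, par_to_cp(par, model))
  lower <- c(-Inf, -Inf, -Inf, -Inf)
  upper <- c(Inf, Inf, Inf, Inf)
  if (model == "5pl") { lower <- c(lower, log(0.1)); upper <- c(upper, log(10)) }

  run_lm <- function(par0) {
    tryCatch(
      minpack.lm::nls.lm(par = par0, fn = resid_fn, lower = lower,
                         upper = upper, control = es_lm_control()),
      error = function(e) NULL)
  }
  as_fit <- function(lm_fit) {
    if (is.null(lm_fit)) return(NULL)
    structure(list(params = par_to_cp(lm_fit$par, model),
                   rss = sum(lm_fit$fvec^2),
                   n_points = length(od),
                   converged = lm_fit$info %in% 1:4,
                   n_iter = lm_fit$niter),
              class = "curve_fit")
  }

  fit <- as_fit(run_lm(cp_to_par(start, model)))
  if (is.null(fit) || !fit$converged) {
    best <- fit
    restarts <- with_seed(MULTISTART_SEED, {
      lapply(seq_len(10), function(i)
        cp_to_par(start, model) * stats::rlnorm(length(lower), 0, log(1.2)))
    })
    for (par0 in restarts) {
      cand <- as_fit(run_lm(par0))
      if (is.null(cand)) next
      if (is.null(best) || (cand$converged && !best$converged) ||
          (cand$converged == best$converged && cand$rss < best$rss))
        best <- cand
      if (!is.null(best) && best$converged) break
    }
    fit <- best
    if (is.null(fit) || !fit$converged)
      es_stop("logistic fit failed to converge after multi-start",
              "elisashift_convergence_error", best = fit)
  }
  fit
}

#' @export
print.curve_fit <- function(x, digits = 6, ...) {
  cat("Logistic curve fit (", if (x$params$g == 1) "4PL" else "5PL",
      "), ", x$n_points, " wells\n", sep = "")
  print(signif(unlist(x$params), digits))
  cat("RSS:", format(x$rss, digits = digits),
      " converged:", x$converged, " iterations:", x$n_iter, "\n")
  invisible(x)
}

#' @rdname to_exp_form
#' @export
from_exp_form <- function(ep) {
  stopifnot(inherits(ep, "exp_form_params"))
  if (ep$C <= 0)
    es_stop("'C' (midpoint concentration) must be positive",
            "elisashift_value_error")
  curve_params(a = ep$A, d = ep$D, xmid = log(ep$C), scal = -1 / ep$B,
               g = ep$g)
}

#' Exponential-form parameterization of the logistic curve
#'
#' Converts between the log-form parameters \eqn{(a, d, xmid, scal, g)} and
#' the non-log ("plate reader") form
#' \eqn{Y = A + (D - A)/\big(1 + (x'/C)^B\big)^g} with \eqn{x' = e^x}. The
#' mapping is \eqn{C = e^{xmid}}, \eqn{B = -1/scal}, \eqn{A = a},
#' \eqn{D = d}, which preserves the curve's orientation.
#'
#' @param p A [curve_params()] object.
#' @param ep An `"exp_form_params"` object.
#' @return `to_exp_form()` returns an `"exp_form_params"` object (fields
#'   `A, D, C, B, g`); `from_exp_form()` returns [curve_params()]. The two
#'   are exact inverses.
#' @export
to_exp_form <- function(p) {
  stopifnot(inherits(p, "curve_params"))
  structure(list(A = p$a, D = p$d, C = exp(p$xmid), B = -1 / p$scal,
                 g = p$g),
            class = "exp_form_params")
}

#' @export
print.exp_form_params <- function(x, digits = 6, ...) {
  cat("Logistic curve, exponential form:\n")
  print(signif(unlist(x), digits))
  invisible(x)
}
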