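# Inverse prediction of sample concentrations and the shift adjustment.
#
# Two-step correction: a sample's OD is first read off its own batch's
# shifted curve (midpoint xmid + S), giving the raw log concentration
# x_hat on the batch's nominal scale; the adjusted value is x_hat - S,
# which places every batch on the reference scale.

#' Aggregate replicate wells
#'
#' @param od Numeric vector of replicate OD readings (>= 1).
#' @return List with `mean_od` and `cv_pct` (100·sd/mean with the sample
#'   standard deviation; 0 for a single well).
#' @export
aggregate_replicates <- function(od) {
  if (length(od) < 1L || any(!is.finite(od)))
    es_stop("need at least one finite OD", "elisashift_value_error")
  m <- mean(od)
  if (m == 0)
    es_stop("mean OD is zero; CV undefined", "elisashift_value_error")
  cv <- if (length(od) == 1L) 0 else 100 * stats::sd(od) / m
  list(mean_od = m, cv_pct = cv)
}

#' Estimate raw and adjusted concentrations for one aggregated OD
#'
#' @param mean_od Aggregated OD of a sample.
#' @param model A `"shift_model"`.
#' @param batch Batch label (must be present in the model).
#' @return List with `raw_log_conc`, `adjusted_log_conc`, `raw_conc`,
#'   `adjusted_conc` (pg/mL), `S` and `flags` (character vector). ODs
#'   outside the open asymptote interval yield `below_range`/`above_range`
#'   and absent concentrations.
#' @export
estimate_concentration <- function(mean_od, model, batch) {
  stopifnot(inherits(model, "shift_model"))
  i <- match(batch, model$shifts$batch)
  if (is.na(i))
    es_stopf("elisashift_lookup_error",
             "batch '%s' not present in the shift model", batch)
  S <- model$shifts$S[i]
  shifted <- model$reference
  shifted$xmid <- shifted$xmid + S
  flags <- character(0)
  raw_log <- tryCatch(inverse_logistic(mean_od, shifted),
                      elisashift_range_error = function(e) {
                        flags <<- e$side
                        NA_real_
                      })
  adj_log <- raw_log - S
  list(raw_log_conc = raw_log, adjusted_log_conc = adj_log,
       raw_conc = exp(raw_log), adjusted_conc = exp(adj_log),
       S = S, flags = flags)
}

#' Flag concentrations outside the quantification range
#'
#' LLOQ/ULOQ are operationalized as the lowest/highest standard level of
#' the sample's batch: adjusted log concentrations outside `[x_lo, x_hi]`
#' are flagged `below_lloq`/`above_uloq` but the value is retained (only
#' asymptote violations censor the value).
#'
#' @param result A list as returned by [estimate_concentration()].
#' @param standards_range Numeric length-2, `c(x_lo, x_hi)` in log pg/mL.
#' @return `result` with flags appended.
#' @export
apply_range_gates <- function(result, standards_range) {
  x <- result$adjusted_log_conc
  if (!is.na(x)) {
    if (x < standards_range[1])
      result$flags <- c(result$flags, "below_lloq")
    else if (x > standards_range[2])
      result$flags <- c(result$flags, "above_uloq")
  }
  result
}

#' Quantify control and unknown samples on all plates
#'
#' Replicate wells are aggregated per (plate, sample), concentrations are
#' read off the plate's batch-shifted curve and adjusted by its shift
#' factor. Samples with replicate CV above `cv_limit` are flagged
#' `high_cv` but still reported.
#'
#' @param model A `"shift_model"`.
#' @param plates Plates carrying `control`/`unknown` wells; every batch
#'   label must be known to the model.
#' @param cv_limit Replicate CV acceptance gate in percent (default 15).
#' @return A `"quant_results"` data frame, one row per (plate, sample):
#'   `plate_id, batch, sample_id, role, n_wells, mean_od, cv_pct,
#'   raw_log_conc, adjusted_log_conc, raw_conc, adjusted_conc, S, flags`
#'   (semicolon-joined tokens).
#' @export
quantify <- function(model, plates, cv_limit = 15) {
  stopifnot(inherits(model, "shift_model"))
  plates <- as_plate_list(plates)
  rows <- list()
  for (p in plates) {
    i <- match(p$batch, model$shifts$batch)
    if (is.na(i))
      es_stopf("elisashift_lookup_error",
               "batch '%s' (plate %s) not present in the shift model",
               p$batch, p$plate_id)
    rng <- c(model$shifts$x_lo[i], model$shifts$x_hi[i])
    w <- p$wells[p$wells$role %in% c("control", "unknown"), , drop = FALSE]
    if (nrow(w) == 0) next
    for (sid in unique(w$sample_id)) {
      ws <- w[w$sample_id == sid, , drop = FALSE]
      agg <- aggregate_replicates(ws$od)
      res <- estimate_concentration(agg$mean_od, model, p$batch)
      res <- apply_range_gates(res, rng)
      if (agg$cv_pct > cv_limit) res$flags <- c(res$flags, "high_cv")
      rows[[length(rows) + 1L]] <- data.frame(
        plate_id = p$plate_id, batch = p$batch, sample_id = sid,
        role = ws$role[1], n_wells = nrow(ws), mean_od = agg$mean_od,
        cv_pct = agg$cv_pct, raw_log_conc = res$raw_log_conc,
        adjusted_log_conc = res$adjusted_log_conc,
        raw_conc = res$raw_conc, adjusted_conc = res$adjusted_conc,
        S = res$S, flags = paste(res$flags, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(plate_id = character(), batch = character(),
               sample_id = character(), role = character(),
               n_wells = integer(), mean_od = numeric(),
               cv_pct = numeric(), raw_log_conc = numeric(),
               adjusted_log_conc = numeric(), raw_conc = numeric(),
               adjusted_conc = numeric(), S = numeric(),
               flags = character(), stringsAsFactors = FALSE)
  structure(out, class = c("quant_results", "data.frame"))
}
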