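# Longitudinal quality control: inter-assay CV, shift-factor summaries,
# outlier curve flagging and the combined QC report.

#' Inter-assay coefficient of variation, integer percent
#'
#' `100 * sd / mean`, rounded half-up to the nearest whole percent — the
#' convention used for reporting control variability.
#'
#' @param mean Mean of the monitored quantity (must be positive).
#' @param sd Standard deviation (non-negative).
#' @return Integer percent.
#' @examples
#' cv_percent(0.759, 0.095)  # 13
#' cv_percent(0.672, 0.062)  # 9
#' @export
cv_percent <- function(mean, sd) {
  if (!is.finite(mean) || mean <= 0)
    es_stop("mean must be positive", "elisashift_value_error")
  if (!is.finite(sd) || sd < 0)
    es_stop("sd must be non-negative", "elisashift_value_error")
  as.integer(round_half_up(100 * sd / mean))
}

#' Fold ratio of a shift factor against its group mean
#'
#' @param s A single shift factor.
#' @param others Shift factors of the comparison group (nonzero mean).
#' @return `s / mean(others)` rounded half-up to one decimal.
#' @examples
#' fold_vs_group_mean(0.7032, 0.0338)  # 20.8
#' @export
fold_vs_group_mean <- function(s, others) {
  m <- mean(others)
  if (m == 0)
    es_stop("group mean is zero; fold ratio undefined",
            "elisashift_value_error", abs_diff = abs(s - m))
  round_half_up(s / m, 1)
}

#' Flag outlying standard curves within a lot
#'
#' Leave-one-out rule: curve `i` is flagged when
#' `|S_i - mean(S_-i)| > k * sd(S_-i)`. The published workflow identifies
#' such curves by inspection; this is the reproducible equivalent.
#'
#' @param shifts Data frame with columns `S` and an identifier column
#'   (`plate_id` or `batch`), or a named numeric vector of shift factors.
#' @param k Flagging threshold in leave-one-out standard deviations
#'   (default 3).
#' @return The flagged subset (same type as the input; empty when nothing
#'   is flagged). At least 3 curves are required.
#' @export
flag_outlier_curves <- function(shifts, k = 3) {
  S <- if (is.data.frame(shifts)) shifts$S else as.numeric(shifts)
  n <- length(S)
  if (n < 3L)
    es_stop("outlier flagging requires at least 3 curves",
            "elisashift_precondition_error")
  flagged <- vapply(seq_len(n), function(i) {
    m <- mean(S[-i]); s <- stats::sd(S[-i])
    if (s == 0) S[i] != m else abs(S[i] - m) > k * s
  }, logical(1))
  if (is.data.frame(shifts)) shifts[flagged, , drop = FALSE]
  else shifts[flagged]
}

#' Build a longitudinal QC report
#'
#' Combines per-batch shift-factor summaries (per-plate `S` within each
#' batch: mean, min, max, N, CV of S), flagged outlier curves, and
#' per-control summaries of OD and of raw versus adjusted concentration —
#' the before/after comparison that shows whether the correction brought
#' inter-assay variability back within limits.
#'
#' @param model A `"shift_model"`.
#' @param plates The plates to monitor (standard wells drive the per-plate
#'   `S` values; control wells drive the control summaries).
#' @param results Optional precomputed [quantify()] output for `plates`;
#'   computed when absent.
#' @param k Outlier threshold passed to [flag_outlier_curves()].
#' @return A `"qc_report"` list with data frames `batches`, `controls`,
#'   `flagged`, and `plate_shifts`.
#' @export
qc_report <- function(model, plates, results = NULL, k = 3) {
  stopifnot(inherits(model, "shift_model"))
  plates <- as_plate_list(plates)
  ps <- plate_shifts(plates, model$reference)

  batches <- do.call(rbind, lapply(unique(ps$batch), function(b) {
    S <- ps$S[ps$batch == b]
    m <- mean(S)
    data.frame(batch = b, mean_S = round(m, 4), min_S = round(min(S), 4),
               max_S = round(max(S), 4), n_curves = length(S),
               cv_S_pct = if (length(S) > 1 && m != 0)
                 round_half_up(100 * stats::sd(S) / abs(m), 1)
               else NA_real_,
               stringsAsFactors = FALSE)
  }))

  flagged <- do.call(rbind, lapply(unique(ps$batch), function(b) {
    sub <- ps[ps$batch == b, , drop = FALSE]
    if (nrow(sub) < 3L) return(NULL)
    out <- flag_outlier_curves(sub, k = k)
    if (nrow(out) == 0) return(NULL)
    out$reason <- sprintf("S outlier (> %g leave-one-out sd of batch %s)",
                          k, b)
    out
  }))
  if (is.null(flagged))
    flagged <- data.frame(plate_id = character(), batch = character(),
                          S = numeric(), se_S = numeric(),
                          n_points = integer(), reason = character(),
                          stringsAsFactors = FALSE)

  if (is.null(results)) results <- quantify(model, plates)
  ctl <- results[results$role == "control", , drop = FALSE]
  controls <- if (nrow(ctl) == 0)
    data.frame(control_id = character(), n = integer(), mean_od = numeric(),
               sd_od = numeric(), cv_od_pct = integer(),
               mean_raw_conc = numeric(), cv_raw_pct = integer(),
               mean_adj_conc = numeric(), cv_adj_pct = integer(),
               stringsAsFactors = FALSE)
  else do.call(rbind, lapply(unique(ctl$sample_id), function(id) {
    sub <- ctl[ctl$sample_id == id, , drop = FALSE]
    cv_or_na <- function(v) {
      v <- v[is.finite(v)]
      if (length(v) > 1 && mean(v) > 0)
        cv_percent(mean(v), stats::sd(v)) else NA_integer_
    }
    data.frame(control_id = id, n = nrow(sub),
               mean_od = mean(sub$mean_od),
               sd_od = if (nrow(sub) > 1) stats::sd(sub$mean_od) else 0,
               cv_od_pct = cv_or_na(sub$mean_od),
               mean_raw_conc = mean(sub$raw_conc, na.rm = TRUE),
               cv_raw_pct = cv_or_na(sub$raw_conc),
               mean_adj_conc = mean(sub$adjusted_conc, na.rm = TRUE),
               cv_adj_pct = cv_or_na(sub$adjusted_conc),
               stringsAsFactors = FALSE)
  }))

  structure(list(batches = batches, controls = controls, flagged = flagged,
                 plate_shifts = ps),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n=========\nPer-batch shift factors:\n")
  print(x$batches, row.names = FALSE)
  cat("\nControls (raw vs shift-adjusted):\n")
  print(x$controls, row.names = FALSE, digits = 4)
  if (nrow(x$flagged) > 0) {
    cat("\nFlagged curves:\n")
    print(x$flagged, row.names = FALSE, digits = 4)
  } else cat("\nNo flagged curves.\n")
  invisible(x)
}

#' Write a QC report to CSV
#'
#' One file with a `record` discriminator column: `batch_S` rows mirror the
#' per-lot shift summary (batch, mean_S, min_S, max_S, n) and `control`
#' rows carry the control OD/concentration summaries; `flagged` rows list
#' outlier curves.
#'
#' @param report A `"qc_report"`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  pad <- function(df, record) {
    if (nrow(df) == 0) return(NULL)
    df <- cbind(record = record, df, stringsAsFactors = FALSE)
    df
  }
  blocks <- list(pad(report$batches, "batch_S"),
                 pad(report$controls, "control"),
                 pad(report$flagged, "flagged"))
  blocks <- blocks[!vapply(blocks, is.null, TRUE)]
  all_cols <- unique(unlist(lapply(blocks, names)))
  rows <- lapply(blocks, function(b) {
    for (col in setdiff(all_cols, names(b))) b[[col]] <- NA
    b[all_cols]
  })
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(record = character())
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, na = "")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) es_stopf("elisashift_io_error", "cannot write to %s", path)
  invisible(path)
}
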