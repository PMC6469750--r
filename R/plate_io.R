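# Long-format plate CSV dialect, plate/batch assembly, and results output.
#
# Interchange format: UTF-8 CSV, "." decimal separator, header row
#   plate_id,batch,run_date,operator,well,role,sample_id,conc,od
# One row per well. `conc` is given for standards only (pg/mL); blank
# wells are carried through I/O but excluded from every fit.

PLATE_COLUMNS <- c("plate_id", "batch", "run_date", "operator",
                   "well", "role", "sample_id", "conc", "od")
WELL_ROLES <- c("standard", "control", "unknown", "blank")
WELL_RE <- "^[A-H](1[0-2]|[1-9])$"

new_plate <- function(plate_id, batch, run_date, operator, wells) {
  structure(list(plate_id = plate_id, batch = batch,
                 run_date = as.Date(run_date), operator = operator,
                 wells = wells),
            class = "elisa_plate")
}

#' @export
print.elisa_plate <- function(x, ...) {
  cat(sprintf("ELISA plate %s (batch %s, %s, operator %s): %d wells\n",
              x$plate_id, x$batch, format(x$run_date), x$operator,
              nrow(x$wells)))
  print(table(x$wells$role))
  invisible(x)
}

#' @export
print.elisa_plates <- function(x, ...) {
  cat(sprintf("Collection of %d ELISA plate(s), %d batch(es)\n",
              length(x), length(unique(vapply(x, `[[`, "", "batch")))))
  invisible(x)
}

as_plate_list <- function(plates) {
  if (inherits(plates, "elisa_plate")) plates <- list(plates)
  if (!is.list(plates) || !all(vapply(plates, inherits, TRUE, "elisa_plate")))
    es_stop("expected an elisa_plate or a list of them",
            "elisashift_value_error")
  structure(plates, class = "elisa_plates")
}

validate_wells <- function(wells, plate_id) {
  bad_role <- !wells$role %in% WELL_ROLES
  if (any(bad_role))
    es_stopf("elisashift_format_error",
             "plate %s: invalid well role '%s'", plate_id,
             wells$role[bad_role][1])
  bad_well <- !grepl(WELL_RE, wells$well)
  if (any(bad_well))
    es_stopf("elisashift_format_error",
             "plate %s: invalid well position '%s'", plate_id,
             wells$well[bad_well][1])
  std <- wells$role == "standard"
  if (any(std & (is.na(wells$conc) | wells$conc <= 0)))
    es_stopf("elisashift_format_error",
             "plate %s: standard wells must carry a positive concentration",
             plate_id)
  if (any(!is.na(wells$conc) & wells$conc < 0))
    es_stopf("elisashift_format_error",
             "plate %s: negative concentration", plate_id)
  invisible(wells)
}

#' Read ELISA plates from a long-format CSV file
#'
#' @param path Path to a CSV file in the package's interchange dialect (see
#'   Details).
#' @details Required columns: `plate_id, batch, run_date, operator, well,
#'   role, sample_id, conc, od`. `role` is one of `standard`, `control`,
#'   `unknown`, `blank`; `conc` (pg/mL) is required positive for standards
#'   and empty otherwise; well positions follow 96-well naming (`A1`–`H12`).
#'   One plate is assembled per distinct `plate_id`, wells in file order.
#' @return An `"elisa_plates"` list with one `"elisa_plate"` per plate.
#' @seealso [write_plates()], [group_by_batch()]
#' @export
read_plates <- function(path) {
  if (!file.exists(path))
    es_stopf("elisashift_io_error", "input file not found: %s", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  missing_cols <- setdiff(PLATE_COLUMNS, names(raw))
  if (length(missing_cols) > 0)
    es_stopf("elisashift_format_error",
             "missing required column(s): %s",
             paste(missing_cols, collapse = ", "))
  if (nrow(raw) == 0) return(structure(list(), class = "elisa_plates"))

  dup <- duplicated(raw[c("plate_id", "well")])
  if (any(dup))
    es_stopf("elisashift_duplicate_error",
             "duplicate well %s on plate %s",
             raw$well[dup][1], raw$plate_id[dup][1])

  parse_num <- function(col, required) {
    txt <- trimws(raw[[col]])
    out <- suppressWarnings(as.numeric(txt))
    bad <- if (required) !is.finite(out) else (txt != "" & is.na(out))
    if (any(bad))
      es_stopf("elisashift_value_error",
               "unparsable %s '%s' at data row %d", col, txt[bad][1],
               which(bad)[1])
    out
  }
  od <- parse_num("od", required = TRUE)
  conc <- parse_num("conc", required = FALSE)

  plates <- lapply(unique(raw$plate_id), function(pid) {
    rows <- raw$plate_id == pid
    meta <- raw[rows, , drop = FALSE][1, ]
    wells <- data.frame(well = raw$well[rows], role = raw$role[rows],
                        sample_id = raw$sample_id[rows],
                        conc = conc[rows], od = od[rows],
                        stringsAsFactors = FALSE)
    validate_wells(wells, pid)
    new_plate(pid, meta$batch, meta$run_date, meta$operator, wells)
  })
  structure(plates, class = "elisa_plates")
}

#' Write ELISA plates to the long-format CSV dialect
#'
#' Inverse of [read_plates()]: the round trip is lossless for every field.
#'
#' @param plates An `"elisa_plates"` list (or single plate).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_plates <- function(plates, path) {
  plates <- as_plate_list(plates)
  rows <- lapply(plates, function(p) {
    data.frame(plate_id = p$plate_id, batch = p$batch,
               run_date = format(p$run_date, "%Y-%m-%d"),
               operator = p$operator, well = p$wells$well,
               role = p$wells$role, sample_id = p$wells$sample_id,
               conc = ifelse(is.na(p$wells$conc), "",
                             fmt_num(p$wells$conc)),
               od = fmt_num(p$wells$od), stringsAsFactors = FALSE)
  })
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    as.data.frame(stats::setNames(rep(list(character(0)), 9), PLATE_COLUMNS))
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) es_stopf("elisashift_io_error", "cannot write to %s", path)
  invisible(path)
}

#' Group plates by batch label
#'
#' @param plates An `"elisa_plates"` list.
#' @return A named list: one element per batch label (in order of first
#'   appearance), each an `"elisa_plates"` list. Every plate appears in
#'   exactly one group.
#' @export
group_by_batch <- function(plates) {
  plates <- as_plate_list(plates)
  labels <- vapply(plates, `[[`, "", "batch")
  out <- lapply(unique(labels), function(b)
    structure(plates[labels == b], class = "elisa_plates"))
  names(out) <- unique(labels)
  out
}

#' Write quantification results to CSV
#'
#' Columns: `plate_id, batch, sample_id, n_wells, mean_od, cv_pct,
#' raw_conc, adjusted_conc, S, flags`; floats carry at least 6 significant
#' digits and flags are semicolon-joined tokens.
#'
#' @param results A `"quant_results"` data frame from [quantify()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  cols <- c("plate_id", "batch", "sample_id", "n_wells", "mean_od",
            "cv_pct", "raw_conc", "adjusted_conc", "S", "flags")
  results <- as.data.frame(results)
  missing_cols <- setdiff(cols, names(results))
  if (length(missing_cols) > 0)
    es_stopf("elisashift_value_error", "results lack column(s): %s",
             paste(missing_cols, collapse = ", "))
  num <- function(v) ifelse(is.na(v), "", sprintf("%.9g", v))
  out <- data.frame(plate_id = results$plate_id, batch = results$batch,
                    sample_id = results$sample_id,
                    n_wells = results$n_wells,
                    mean_od = num(results$mean_od),
                    cv_pct = num(results$cv_pct),
                    raw_conc = num(results$raw_conc),
                    adjusted_conc = num(results$adjusted_conc),
                    S = num(results$S), flags = results$flags,
                    stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) es_stopf("elisashift_io_error", "cannot write to %s", path)
  invisible(path)
}

# All standard wells of a plate collection as one data frame with
# natural-log concentrations. Blanks and non-standard roles are excluded.
standard_wells <- function(plates) {
  plates <- as_plate_list(plates)
  rows <- lapply(plates, function(p) {
    w <- p$wells[p$wells$role == "standard" & !is.na(p$wells$conc) &
                 p$wells$conc > 0, , drop = FALSE]
    if (nrow(w) == 0) return(NULL)
    data.frame(plate_id = p$plate_id, batch = p$batch, well = w$well,
               x = log(w$conc), od = w$od, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0)
    return(data.frame(plate_id = character(), batch = character(),
                      well = character(), x = numeric(), od = numeric()))
  do.call(rbind, rows)
}
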