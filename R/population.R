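cohort_conditions <- c("noncap_low", "noncap_high", "cap_low", "cap_high")

#' Aggregate per-cell rotation calls into a cohort report
#'
#' Counts CCW, CW and non-rotating calls per experimental condition
#' (non-capacitating / capacitating medium at low / high viscosity) and
#' reports percentages. Low-confidence non-rotating calls are counted as
#' non-rotating but tallied separately for auditability.
#'
#' @param records data frame with columns \code{cell_id}, \code{condition}
#'   (one of \code{noncap_low}, \code{noncap_high}, \code{cap_low},
#'   \code{cap_high}) and \code{direction} ("ccw", "cw", "non-rotating");
#'   an optional logical \code{low_confidence} column is tallied.
#' @return Object of class \code{"cohort_report"}: a data frame with one
#'   row per condition plus a grand-total row; percentage columns are exact
#'   internally and rounded only by the print method.
#' @export
aggregate_calls <- function(records) {
  if (!nrow(records)) stop("no records to aggregate", call. = FALSE)
  req <- c("cell_id", "condition", "direction")
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop("records missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- !records$condition %in% cohort_conditions
  if (any(bad))
    stop("unknown condition label for cell_id(s): ",
         paste(records$cell_id[bad], collapse = ", "), call. = FALSE)
  if (is.null(records$low_confidence)) records$low_confidence <- FALSE
  one <- function(sub, label) {
    n <- nrow(sub)
    n_ccw <- sum(sub$direction == "ccw")
    n_cw <- sum(sub$direction == "cw")
    n_non <- sum(sub$direction == "non-rotating")
    data.frame(condition = label, n_total = n, n_ccw = n_ccw, n_cw = n_cw,
               n_nonrotating = n_non,
               n_low_confidence = sum(sub$low_confidence),
               pct_ccw = if (n) 100 * n_ccw / n else NA_real_,
               pct_cw = if (n) 100 * n_cw / n else NA_real_,
               pct_nonrotating = if (n) 100 * n_non / n else NA_real_)
  }
  rows <- do.call(rbind, lapply(cohort_conditions, function(cond)
    one(records[records$condition == cond, , drop = FALSE], cond)))
  rows <- rows[rows$n_total > 0, , drop = FALSE]
  out <- rbind(rows, one(records, "total"))
  class(out) <- c("cohort_report", "data.frame")
  out
}

#' @export
print.cohort_report <- function(x, ...) {
  y <- as.data.frame(x)
  for (cl in grep("^pct_", names(y))) y[[cl]] <- round(y[[cl]])
  cat("Cohort rotation-direction report\n")
  print(y, row.names = FALSE)
  invisible(x)
}

#' Summed observation time of a cohort
#'
#' @param n_cells number of cells analysed.
#' @param per_cell_duration record length per cell (seconds).
#' @return Total observation time in minutes, rounded to the nearest
#'   integer.
#' @export
summed_observation_time <- function(n_cells, per_cell_duration) {
  stopifnot_scalar(n_cells, "n_cells")
  stopifnot_scalar(per_cell_duration, "per_cell_duration")
  round(n_cells * per_cell_duration / 60)
}
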