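# Behavioural IQ table: loading, validation, summary statistics.

IQ_SCORE_COLS <- c("viq_t1", "piq_t1", "viq_t2", "piq_t2")

#' Read a behavioural IQ table
#'
#' Reads a CSV with one row per subject and columns
#' `subject_id, viq_t1, piq_t1, viq_t2, piq_t2` (verbal and performance IQ,
#' age-standardised scale with population mean 100 and SD 15, at two
#' testing occasions). Change scores `d_viq` and `d_piq` are always
#' recomputed as Time 2 minus Time 1; if the file also carries change
#' columns they are checked against the recomputed values and any mismatch
#' is rejected.
#'
#' @param file path to a CSV file (or connection).
#' @return a tibble with columns `subject_id`, the four scores, and the
#'   recomputed `d_viq`, `d_piq`.
#' @seealso [iq_reference_table()] for the packaged 33-subject cohort.
#' @export
read_iq_table <- function(file) {
  raw <- readr::read_csv(file, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0) abort("IQ table is empty")
  need <- c("subject_id", IQ_SCORE_COLS)
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0)
    abort(paste0("IQ table is missing required column(s): ",
                 paste(miss, collapse = ", ")))
  for (col in intersect(c(need, "d_viq", "d_piq"), names(raw))) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) | is.na(raw[[col]]))
    if (length(bad) > 0)
      abort(paste0("non-numeric or missing value in column '", col,
                   "', row ", bad[1]))
    raw[[col]] <- v
  }
  tab <- tibble::tibble(
    subject_id = as.integer(raw$subject_id),
    viq_t1 = raw$viq_t1, piq_t1 = raw$piq_t1,
    viq_t2 = raw$viq_t2, piq_t2 = raw$piq_t2
  )
  if (anyDuplicated(tab$subject_id))
    abort(paste0("duplicate subject_id: ",
                 tab$subject_id[duplicated(tab$subject_id)][1]))
  for (col in IQ_SCORE_COLS) {
    bad <- which(!is.finite(tab[[col]]) | tab[[col]] <= 0)
    if (length(bad) > 0)
      abort(paste0("score must be finite and positive: column '", col,
                   "', row ", bad[1]))
  }
  tab$d_viq <- tab$viq_t2 - tab$viq_t1
  tab$d_piq <- tab$piq_t2 - tab$piq_t1
  for (dcol in c("d_viq", "d_piq")) {
    if (dcol %in% names(raw)) {
      bad <- which(raw[[dcol]] != tab[[dcol]])
      if (length(bad) > 0)
        abort(paste0("printed change column '", dcol, "' disagrees with ",
                     "t2 - t1 at row ", bad[1]))
    }
  }
  tab
}

#' Write a behavioural IQ table to CSV
#'
#' @param table an IQ table as returned by [read_iq_table()].
#' @param file output path.
#' @return the input, invisibly.
#' @export
write_iq_table <- function(table, file) {
  validate_iq_table(table)
  readr::write_csv(table, file, progress = FALSE)
  invisible(table)
}

#' The packaged 33-subject behavioural cohort
#'
#' Verbal and performance IQ for 33 teenagers tested twice about 3.5 years
#' apart, the fully printed behavioural dataset that anchors the analysis.
#'
#' @return a validated IQ tibble with 33 rows.
#' @export
iq_reference_table <- function() {
  read_iq_table(system.file("extdata", "iq_table1.csv", package = "longicv",
                            mustWork = TRUE))
}

#' Validate the structural invariants of an IQ table
#'
#' Checks required columns, unique subject ids, finite positive scores and
#' change columns equal to the difference of the two time points.
#'
#' @param table a data frame.
#' @return the table, invisibly; errors describe the first violation.
#' @export
validate_iq_table <- function(table) {
  need <- c("subject_id", IQ_SCORE_COLS, "d_viq", "d_piq")
  miss <- setdiff(need, names(table))
  if (length(miss) > 0)
    abort(paste0("IQ table missing column(s): ", paste(miss, collapse = ", ")))
  if (nrow(table) == 0) abort("IQ table is empty")
  if (anyDuplicated(table$subject_id)) abort("duplicate subject_id")
  if (!all(vapply(table[IQ_SCORE_COLS],
                  function(v) all(is.finite(v) & v > 0), logical(1))))
    abort("scores must be finite and positive")
  if (any(table$d_viq != table$viq_t2 - table$viq_t1) ||
      any(table$d_piq != table$piq_t2 - table$piq_t1))
    abort("change columns inconsistent with t2 - t1")
  invisible(table)
}

#' Summarise a behavioural IQ table
#'
#' Per measure (VIQ, PIQ): means and sample SDs at each time point,
#' mean/SD/range of the change score, the test-retest Pearson correlation,
#' Shapiro-Wilk normality p-values for each time point, and the fraction of
#' subjects whose score shifted by at least `shift_threshold` points
#' (one population SD by default).
#'
#' @param table an IQ table.
#' @param shift_threshold IQ points; a subject counts as "shifted" when
#'   `|t2 - t1| >= shift_threshold`. Default 15.
#' @return a tibble with one row per measure.
#' @export
summarise_iq <- function(table, shift_threshold = 15) {
  validate_iq_table(table)
  if (nrow(table) < 3)
    abort("at least 3 subjects are required for correlation and normality tests")
  one <- function(measure) {
    t1 <- table[[paste0(measure, "_t1")]]
    t2 <- table[[paste0(measure, "_t2")]]
    d <- t2 - t1
    r <- if (sd(t1) == 0 || sd(t2) == 0) {
      warn(paste0("test-retest correlation undefined for ", measure,
                  ": zero-variance column"))
      NA_real_
    } else cor(t1, t2)
    tibble::tibble(
      measure = measure,
      n = length(d),
      mean_t1 = mean(t1), mean_t2 = mean(t2),
      sd_t1 = sd(t1), sd_t2 = sd(t2),
      mean_change = mean(d), sd_change = sd(d),
      min_change = min(d), max_change = max(d),
      test_retest_r = r,
      shapiro_p_t1 = if (sd(t1) == 0) NA_real_ else shapiro.test(t1)$p.value,
      shapiro_p_t2 = if (sd(t2) == 0) NA_real_ else shapiro.test(t2)$p.value,
      shift_fraction = mean(abs(d) >= shift_threshold)
    )
  }
  dplyr::bind_rows(one("viq"), one("piq"))
}
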