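# Plate-assay arithmetic: LDH cytotoxicity, resazurin (PrestoBlue)
# background correction and day-1 normalization.

#' Blank-corrected LDH signal
#'
#' The LDH readout is the 490 nm absorbance minus the 680 nm instrument
#' reference. Negative results are allowed (they occur with noisy readings
#' near blank) and flagged with a warning rather than floored, so downstream
#' conservation identities stay exact.
#'
#' @param a490,a680 Absorbances (AU), vectorized.
#' @return `a490 - a680` (AU).
#' @export
ldh_signal <- function(a490, a680) {
  stopifnot(is.finite(a490), is.finite(a680), length(a490) == length(a680))
  s <- a490 - a680
  if (any(s < 0))
    warning(sum(s < 0), " negative blank-corrected LDH signal(s) retained")
  s
}

#' Cumulative cell-death and survival series from daily LDH release
#'
#' Implements the cytotoxicity arithmetic of the LDH release assay: the total
#' releasable LDH is the terminal-lysis signal plus the sum of the daily
#' supernatant signals; the cell death fraction on day i is that day's signal
#' over the total; and the surviving fraction on day i is one minus the
#' cumulative death up to day i. The returned `cell_death` and `surviving`
#' columns are exact (unclipped), so the conservation identity
#' `sum(cell_death) + surviving[n] = 1` holds to machine precision;
#' `surviving_clipped` additionally applies the `[0, 1]` clip used
#' for reporting when noisy readings go negative.
#'
#' @param daily_ldh Blank-corrected daily LDH signals, day 1 first (AU).
#' @param ldh_lysis Blank-corrected terminal lysis signal (AU).
#' @return Data frame of class `"survival_series"` with columns `day`,
#'   `cell_death`, `surviving`, `surviving_clipped`; the total LDH is
#'   attached as `attr(, "ldh_total")`.
#' @examples
#' survival_series(c(25, 25), 50)  # deaths 0.25, 0.25; surviving 0.75, 0.50
#' @export
survival_series <- function(daily_ldh, ldh_lysis) {
  stopifnot(length(daily_ldh) >= 1, is.finite(daily_ldh),
            is.finite(ldh_lysis))
  total <- ldh_lysis + sum(daily_ldh)
  if (total <= 0)
    stop("total LDH must be positive (got ", format(total), ")",
         call. = FALSE)
  death <- daily_ldh / total
  surviving <- 1 - cumsum(death)
  out <- data.frame(day = seq_along(daily_ldh),
                    cell_death = death,
                    surviving = surviving,
                    surviving_clipped = pmin(pmax(surviving, 0), 1))
  attr(out, "ldh_total") <- total
  class(out) <- c("survival_series", "data.frame")
  out
}

#' Daily LDH signals and terminal lysis signal from a plate object
#'
#' Collapses an `"assay_plate"` (see [generate_assay_series()], or a long
#' readings table read from CSV) to the blank-corrected per-day signal and
#' the lysis signal, ready for [survival_series()].
#'
#' @param plate An `"assay_plate"` object or a list with `readings` and
#'   `lysis` data frames (columns `sample`, `day`, `wavelength`,
#'   `absorbance`).
#' @param sample Sample id to extract; default the first present.
#' @return List with `daily` (named by day) and `lysis` (scalars, AU).
#' @export
ldh_from_plate <- function(plate, sample = NULL) {
  r <- plate$readings
  if (is.null(sample)) sample <- r$sample[1]
  r <- r[r$sample == sample, ]
  days <- sort(unique(r$day))
  if (!all(diff(days) == 1L))
    stop("days must form a contiguous sequence, got: ",
         paste(days, collapse = ", "), call. = FALSE)
  get <- function(df, day, wl) {
    v <- df$absorbance[df$day %in% day & df$wavelength == wl]
    if (length(v) != length(day)) stop("missing wavelength ", wl,
                                       " reading(s)", call. = FALSE)
    v
  }
  daily <- suppressWarnings(
    ldh_signal(get(r, days, 490L), get(r, days, 680L)))
  names(daily) <- days
  lys <- plate$lysis[plate$lysis$sample == sample, ]
  lysis <- lys$absorbance[lys$wavelength == 490L] -
    lys$absorbance[lys$wavelength == 680L]
  list(daily = daily, lysis = lysis)
}

#' Background-corrected resazurin (PrestoBlue) absorbance
#'
#' The metabolic signal is the 571 nm minus 601 nm absorbance of the sample,
#' minus the same difference for medium-only wells:
#' `background = medium(571) - medium(601)`;
#' `corrected = sample(571) - sample(601) - background`. Negative backgrounds
#' are handled algebraically.
#'
#' @param a_sample_571,a_sample_601 Sample absorbances (AU), vectorized.
#' @param a_medium_571,a_medium_601 Medium-only absorbances (AU).
#' @return Corrected absorbance (AU).
#' @examples
#' presto_corrected(0.5, 0.2, 0.1, 0.05)  # 0.25
#' @export
presto_corrected <- function(a_sample_571, a_sample_601,
                             a_medium_571, a_medium_601) {
  stopifnot(is.finite(a_sample_571), is.finite(a_sample_601),
            is.finite(a_medium_571), is.finite(a_medium_601))
  background <- a_medium_571 - a_medium_601
  a_sample_571 - a_sample_601 - background
}

#' Normalize a per-day series to its day-1 value
#'
#' Slice sizes vary, so assay readouts are reported relative to the first
#' day in culture: `value(day i) / value(day 1)`; day 1 maps to 1.
#'
#' @param values Per-day values.
#' @param days Day indices (1-based); default `seq_along(values)`. Day 1
#'   must be present.
#' @return Vector of relative values; all `NA` with a warning when the day-1
#'   value is zero.
#' @export
normalize_to_day1 <- function(values, days = seq_along(values)) {
  stopifnot(length(values) == length(days))
  if (!1 %in% days) stop("day 1 missing from the series", call. = FALSE)
  ref <- values[which(days == 1)[1]]
  if (!is.finite(ref) || ref == 0) {
    warning("day-1 value is zero or non-finite: normalization undefined")
    return(rep(NA_real_, length(values)))
  }
  values / ref
}
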