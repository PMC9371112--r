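#' Channel-frequency-class filter specification
#'
#' Describes a crash-test channel frequency class (CFC) low-pass filter at a
#' given sampling rate. The class value follows the SAE J211 convention:
#' CFC 1000 has its (two-pass) -3 dB point near 1650 Hz.
#'
#' @param cfc_class Positive filter class (e.g. 180, 600, 1000).
#' @param sample_rate Sampling rate in Hz. Must exceed ten times the nominal
#'   -3 dB frequency (1.65 x class) so the warped design stays meaningful.
#' @return A list of class `cfc_spec`.
#' @export
cfc_spec <- function(cfc_class, sample_rate) {
  stopifnot(is.numeric(cfc_class), cfc_class > 0,
            is.numeric(sample_rate), sample_rate > 0)
  if (sample_rate <= 10 * 1.65 * cfc_class) {
    rlang::abort(sprintf(
      "sample_rate %.0f Hz too low for CFC %.0f (need > %.0f Hz)",
      sample_rate, cfc_class, 10 * 1.65 * cfc_class
    ))
  }
  structure(list(cfc_class = cfc_class, sample_rate = sample_rate),
            class = "cfc_spec")
}

# J211 warped 2-pole Butterworth coefficients for one pass:
# y[i] = a0*x[i] + a1*x[i-1] + a2*x[i-2] + b1*y[i-1] + b2*y[i-2]
# with wd = 2*pi*class*2.0775 and wa = tan(wd*T/2) (bilinear pre-warp).
j211_coefficients <- function(cfc_class, sample_rate) {
  T <- 1 / sample_rate
  wd <- 2 * pi * cfc_class * 2.0775
  wa <- tan(wd * T / 2)
  den <- 1 + sqrt(2) * wa + wa^2
  a0 <- wa^2 / den
  list(
    num = c(a0, 2 * a0, a0),
    rec = c(2 * (1 - wa^2) / den, (-1 + sqrt(2) * wa - wa^2) / den)
  )
}

# One forward pass of the J211 biquad; constant prehistory for the
# two-sample numerator lag (the mirror padding around this makes the
# choice immaterial).
j211_pass <- function(x, co) {
  n <- length(x)
  xm1 <- c(x[1L], x[-n])
  xm2 <- c(x[1L], x[1L], x[-c(n - 1L, n)])
  num <- co$num[1L] * x + co$num[2L] * xm1 + co$num[3L] * xm2
  as.numeric(stats::filter(num, co$rec, method = "recursive"))
}

#' Phaseless CFC low-pass filter
#'
#' Applies the SAE J211 channel-frequency-class two-pole Butterworth filter
#' (warped coefficients, design frequency 2.0775 x class) forward and then
#' backward, giving a zero-phase four-pole-effective response with unit DC
#' gain. Edges are handled by odd-mirror padding which is trimmed afterwards,
#' so the output has the same length as the input.
#'
#' @param signal Numeric vector, at least 10 samples, finite.
#' @param spec A [cfc_spec()].
#' @return Filtered signal, same length as the input.
#' @examples
#' sp <- cfc_spec(1000, 20000)
#' all.equal(cfc_filter(rep(9.81, 100), sp), rep(9.81, 100), tolerance = 1e-6)
#' @export
cfc_filter <- function(signal, spec) {
  stopifnot(inherits(spec, "cfc_spec"))
  n <- length(signal)
  if (n < 10L) rlang::abort("signal must have at least 10 samples")
  if (!all(is.finite(signal))) rlang::abort("signal must be finite")
  co <- j211_coefficients(spec$cfc_class, spec$sample_rate)
  # mirror padding, 3 x settling length (settling ~ fs / class samples)
  np <- min(n - 1L, ceiling(3 * spec$sample_rate / spec$cfc_class))
  left <- 2 * signal[1L] - signal[(np + 1L):2L]
  right <- 2 * signal[n] - signal[(n - 1L):(n - np)]
  x <- c(left, signal, right)
  y <- j211_pass(x, co)
  y <- rev(j211_pass(rev(y), co))
  y[(np + 1L):(np + n)]
}

#' Filter an impact record with CFC classes
#'
#' Filters all 12 helmet channels at `helmet_class` and all 6 head channels
#' (3 linear + 3 rotational) at `head_class`, recording the classes used in
#' the record metadata.
#'
#' @param record An `impact_record`.
#' @param helmet_class CFC class for the helmet shell channels. The
#'   convention for shell accelerations is not standardized across test
#'   houses, so this is an explicit argument; CFC 1000 is the usual choice
#'   for accelerations.
#' @param head_class CFC class for the head ground-truth channels (CFC 1000
#'   per ISO 6487 practice for head accelerations).
#' @return The filtered `impact_record`.
#' @export
filter_record <- function(record, helmet_class = 1000, head_class = 1000) {
  stopifnot(inherits(record, "impact_record"))
  fs <- 1 / record$dt
  sp_helmet <- cfc_spec(helmet_class, fs)
  sp_head <- cfc_spec(head_class, fs)
  record$helmet <- t(apply(record$helmet, 1L, cfc_filter, spec = sp_helmet))
  record$head_lin <- t(apply(record$head_lin, 1L, cfc_filter, spec = sp_head))
  record$head_rot <- t(apply(record$head_rot, 1L, cfc_filter, spec = sp_head))
  record$meta$helmet_cfc <- helmet_class
  record$meta$head_cfc <- head_class
  record
}

#' Filter every record of a dataset
#'
#' @param dataset An `impact_dataset`.
#' @inheritParams filter_record
#' @return The dataset with all records filtered.
#' @export
filter_dataset <- function(dataset, helmet_class = 1000, head_class = 1000) {
  stopifnot(inherits(dataset, "impact_dataset"))
  dataset$records <- purrr::map(
    dataset$records, filter_record,
    helmet_class = helmet_class, head_class = head_class
  )
  dataset$manifest$helmet_cfc <- helmet_class
  dataset$manifest$head_cfc <- head_class
  dataset
}

#' Decimate a record to a lower sampling rate
#'
#' Keeps every `factor`-th sample of all channels. Intended for use after
#' CFC filtering, which removes the spectral content that decimation would
#' alias; shorter sequences make recurrent-network training far cheaper.
#'
#' @param record An `impact_record`.
#' @param factor Positive integer decimation factor.
#' @return The decimated record (`dt` multiplied by `factor`).
#' @export
decimate_record <- function(record, factor) {
  stopifnot(inherits(record, "impact_record"),
            factor == as.integer(factor), factor >= 1)
  idx <- seq(1L, length(record$time), by = as.integer(factor))
  record$time <- record$time[idx]
  record$helmet <- record$helmet[, idx, drop = FALSE]
  record$head_lin <- record$head_lin[, idx, drop = FALSE]
  record$head_rot <- record$head_rot[, idx, drop = FALSE]
  record$dt <- record$dt * factor
  record$meta$decimation <- c(record$meta$decimation, factor)
  record
}

#' @rdname decimate_record
#' @param dataset An `impact_dataset`.
#' @export
decimate_dataset <- function(dataset, factor) {
  stopifnot(inherits(dataset, "impact_dataset"))
  dataset$records <- purrr::map(dataset$records, decimate_record, factor = factor)
  dataset
}
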