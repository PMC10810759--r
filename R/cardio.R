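#' @name cardio
#' @title Heart-rate, HRV and physiological-noise modelling
#'
#' @description
#' Interbeat-interval metrics (heart rate, RMSSD, pNN) computed from R-peak
#' times restricted to analysis windows, and a RETROICOR-style Fourier
#' design-matrix builder for physiological-noise modelling (PNM).
NULL

#' R-R interval series
#'
#' @param r_peak_times_ms strictly increasing R-peak times in ms.
#' @return object of class `rr_series` with `peaks_ms` and `intervals_ms`.
#' @export
rr_series <- function(r_peak_times_ms) {
  p <- as.numeric(r_peak_times_ms)
  if (any(diff(p) <= 0)) stop("R-peak times must be strictly increasing",
                              call. = FALSE)
  structure(list(peaks_ms = p, intervals_ms = diff(p)), class = "rr_series")
}

#' @export
#' @method print rr_series
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> %d peaks, %d intervals\n",
              length(x$peaks_ms), length(x$intervals_ms)))
  invisible(x)
}

#' Restrict R-R intervals to an analysis window
#'
#' Keeps only intervals whose two defining R peaks both fall inside the
#' half-open window (e.g. a trial's modulation phase).
#'
#' @param peaks numeric R-peak times in ms (or an [rr_series()]).
#' @param window numeric `c(start, end)` in ms.
#' @return an [rr_series()] of the retained peaks (possibly empty).
#' @export
rr_in_window <- function(peaks, window) {
  if (inherits(peaks, "rr_series")) peaks <- peaks$peaks_ms
  stopifnot(length(window) == 2, window[2] > window[1])
  inside <- peaks[peaks >= window[1] & peaks < window[2]]
  structure(list(peaks_ms = inside, intervals_ms = diff(inside)),
            class = "rr_series")
}

#' Mean heart rate from R-R intervals
#'
#' Heart rate is computed per interval as 60 divided by the interval in
#' seconds, then averaged.
#'
#' @param rr an [rr_series()].
#' @return mean heart rate in bpm, or `NA` (with a warning) for an empty
#'   series.
#' @export
heart_rate <- function(rr) {
  stopifnot(inherits(rr, "rr_series"))
  if (length(rr$intervals_ms) < 1) {
    warning("no complete R-R interval in window; heart rate undefined")
    return(NA_real_)
  }
  mean(60000 / rr$intervals_ms)
}

#' Root mean square of successive R-R differences (RMSSD)
#'
#' @param rr an [rr_series()] with at least 2 intervals.
#' @return RMSSD in ms, or `NA` (with a warning) when undefined.
#' @export
rmssd <- function(rr) {
  stopifnot(inherits(rr, "rr_series"))
  d <- diff(rr$intervals_ms)
  if (length(d) < 1) {
    warning("fewer than 2 R-R intervals; RMSSD undefined")
    return(NA_real_)
  }
  sqrt(mean(d^2))
}

#' Percentage of successive interbeat differences above a threshold (pNN)
#'
#' With the default 35 ms threshold this is pNN35: the percentage of
#' successive normal interbeat-interval differences greater than 35 ms
#' (strict `>`).
#'
#' @param rr an [rr_series()] with at least 2 intervals.
#' @param threshold_ms default 35.
#' @return percentage in `[0, 100]`, or `NA` (with a warning) when undefined.
#' @export
pnn <- function(rr, threshold_ms = 35) {
  stopifnot(inherits(rr, "rr_series"))
  d <- diff(rr$intervals_ms)
  if (length(d) < 1) {
    warning("fewer than 2 R-R intervals; pNN undefined")
    return(NA_real_)
  }
  100 * mean(abs(d) > threshold_ms)
}

#' RETROICOR-style physiological-noise design matrix
#'
#' Builds the Fourier nuisance-regressor set: sine/cosine pairs for each
#' harmonic of the cardiac phase and of the respiratory phase, plus — for
#' each interaction order — sine/cosine pairs of both the sum and the
#' difference phase combination (`k*cardiac ± respiratory` for the
#' cardiac-by-respiratory set and `k*respiratory ± cardiac` for the
#' respiratory-by-cardiac set, i.e. 4 columns per interaction order), and one
#' heart-rate plus one respiration-volume column. With the default orders
#' `(4, 4, 2, 2)` the matrix has
#' `2*4 + 2*4 + 4*2 + 4*2 + 2 = 34` columns.
#'
#' @param cardiac_phase,resp_phase phase vectors in radians, one value per
#'   volume.
#' @param hr_trace,rv_trace heart-rate and respiration-volume nuisance
#'   traces, same length.
#' @param orders integer vector
#'   `(cardiac, respiratory, interaction_cr, interaction_rc)`.
#' @return numeric matrix with labelled columns, class `pnm_design`.
#' @export
pnm_design <- function(cardiac_phase, resp_phase, hr_trace, rv_trace,
                       orders = c(4, 4, 2, 2)) {
  stopifnot(length(orders) == 4)
  if (any(orders < 0) || any(orders != floor(orders))) {
    stop("harmonic orders must be non-negative integers", call. = FALSE)
  }
  n <- length(cardiac_phase)
  if (length(resp_phase) != n || length(hr_trace) != n || length(rv_trace) != n) {
    stop("phase and nuisance traces must have equal length", call. = FALSE)
  }
  cols <- list()
  harm <- function(phase, k, lab) {
    cols[[paste0(lab, "_sin", k)]] <<- sin(k * phase)
    cols[[paste0(lab, "_cos", k)]] <<- cos(k * phase)
  }
  for (k in seq_len(orders[1])) harm(cardiac_phase, k, "card")
  for (k in seq_len(orders[2])) harm(resp_phase, k, "resp")
  for (k in seq_len(orders[3])) {
    harm(k * cardiac_phase + resp_phase, 1, paste0("cxr", k, "p"))
    harm(k * cardiac_phase - resp_phase, 1, paste0("cxr", k, "m"))
  }
  for (k in seq_len(orders[4])) {
    harm(k * resp_phase + cardiac_phase, 1, paste0("rxc", k, "p"))
    harm(k * resp_phase - cardiac_phase, 1, paste0("rxc", k, "m"))
  }
  cols[["hr"]] <- hr_trace
  cols[["rv"]] <- rv_trace
  m <- do.call(cbind, cols)
  class(m) <- c("pnm_design", class(m))
  attr(m, "orders") <- orders
  m
}

#' Number of columns a PNM design will have
#'
#' Closed form `2c + 2r + 4*icr + 4*irc + 2` for orders
#' `(c, r, icr, irc)`.
#'
#' @param orders integer vector of length 4.
#' @return integer column count.
#' @export
pnm_n_columns <- function(orders) {
  stopifnot(length(orders) == 4, all(orders >= 0))
  as.integer(2 * orders[1] + 2 * orders[2] + 4 * orders[3] + 4 * orders[4] + 2)
}

#' Write a PNM design matrix as whitespace-delimited text
#'
#' @param design a [pnm_design()] matrix.
#' @param path output file; a header row holds the column labels.
#' @export
write_pnm_design <- function(design, path) {
  write.table(design, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
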