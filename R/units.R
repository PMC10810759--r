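#' Convert eye-tracker arbitrary units to pupil diameter in mm
#'
#' Scanner recordings report pupil diameter in device arbitrary units; the
#' calibrated conversion is `diameter (mm) = diameter (a.u.) / 1372`.
#'
#' @param au numeric vector of arbitrary-unit readings.
#' @param divisor calibration divisor (a.u. per mm), default 1372.
#' @return pupil diameter in mm.
#' @seealso [mm_to_au()]
#' @export
au_to_mm <- function(au, divisor = 1372) {
  stopifnot(is.numeric(divisor), length(divisor) == 1L, divisor > 0)
  au / divisor
}

#' @rdname au_to_mm
#' @param mm numeric vector of pupil diameters in mm.
#' @export
mm_to_au <- function(mm, divisor = 1372) {
  stopifnot(is.numeric(divisor), length(divisor) == 1L, divisor > 0)
  mm * divisor
}
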