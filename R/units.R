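#' Unit helpers for capacitance and conductance
#'
#' All internal computation is in SI units (farad, siemens, rad/s); results
#' are conventionally reported in femtofarad (fF) and picosiemens (pS), the
#' scales of single-vesicle capacitance steps and fusion-pore conductances.
#' These helpers centralise the conversions.
#'
#' @param x numeric vector.
#' @return numeric vector in the indicated unit.
#' @examples
#' fF(0.5)        # 5e-16 farad
#' as_pS(5e-12)   # 5 pS
#' @name units
NULL

#' @rdname units
#' @export
fF <- function(x) x * 1e-15

#' @rdname units
#' @export
pS <- function(x) x * 1e-12

#' @rdname units
#' @export
as_fF <- function(x) x / 1e-15

#' @rdname units
#' @export
as_pS <- function(x) x / 1e-12
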