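# qRT/PCR standard-curve calibration: log-linear Ct ~ log10(quantity).

#' Standard curve object
#'
#' Log-linear calibration between threshold cycle (Ct) and absolute quantity:
#' `Ct = intercept + slope * log10(quantity)`. The amplification efficiency
#' follows from the slope as `10^(-1/slope) - 1`; a perfect two-fold-per-cycle
#' reaction has slope `-1/log10(2) = -3.3219` and efficiency 1.
#'
#' @param slope Ct per log10 quantity (< 0).
#' @param intercept Ct at 1 unit of quantity.
#' @param quantity_unit Label for the quantity axis (default "fg").
#' @return An object of class `standard_curve` with fields `slope`,
#'   `intercept`, `efficiency`, `quantity_unit`.
#' @export
standard_curve <- function(slope, intercept, quantity_unit = "fg") {
  if (!is.finite(slope) || slope >= 0) {
    stop("standard-curve slope must be negative (Ct falls as quantity rises)",
         call. = FALSE)
  }
  structure(list(slope = slope, intercept = intercept,
                 efficiency = 10^(-1 / slope) - 1,
                 quantity_unit = quantity_unit),
            class = "standard_curve")
}

#' Fit a qRT/PCR standard curve
#'
#' Ordinary least squares of Ct on log10(known quantity) over a dilution
#' series. Requires at least three points spanning at least two decades of
#' quantity, all quantities positive.
#'
#' @param quantity_fg Known input quantities (fg), all > 0.
#' @param ct Measured threshold cycles, same length.
#' @return A [standard_curve()].
#' @examples
#' q <- 10^(0:4)
#' fit_standard_curve(q, 30 - log10(q) / log10(2))
#' @export
fit_standard_curve <- function(quantity_fg, ct) {
  stopifnot(length(quantity_fg) == length(ct))
  if (length(quantity_fg) < 3L) {
    stop("need at least 3 standard points", call. = FALSE)
  }
  if (any(!is.finite(quantity_fg)) || any(quantity_fg <= 0)) {
    stop("all standard quantities must be positive", call. = FALSE)
  }
  lq <- log10(quantity_fg)
  if (diff(range(lq)) < 2) {
    stop("standards must span at least 2 log10 units of quantity",
         call. = FALSE)
  }
  fit <- stats::lm(ct ~ lq)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0) {
    stop("degenerate standard curve: fitted slope is not negative",
         call. = FALSE)
  }
  standard_curve(slope, unname(stats::coef(fit)[1]))
}

#' Convert a Ct value to absolute quantity
#'
#' Inverse of the calibration: `quantity = 10^((ct - intercept)/slope)`.
#' Round-trips [quantity_to_ct()] exactly on noise-free input.
#'
#' @param ct Threshold cycle(s).
#' @param curve A [standard_curve()].
#' @return Quantity in the curve's unit (fg by default).
#' @export
ct_to_quantity <- function(ct, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  10^((ct - curve$intercept) / curve$slope)
}

#' Forward map: quantity to expected Ct
#'
#' @param quantity_fg Quantity (> 0).
#' @param curve A [standard_curve()].
#' @return Expected Ct.
#' @export
quantity_to_ct <- function(quantity_fg, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  if (any(quantity_fg <= 0, na.rm = TRUE)) {
    stop("quantity must be positive to map to a Ct", call. = FALSE)
  }
  curve$intercept + curve$slope * log10(quantity_fg)
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("qRT/PCR standard curve: Ct = %.4f %+.4f * log10(%s); efficiency %.3f\n",
              x$intercept, x$slope, x$quantity_unit, x$efficiency))
  invisible(x)
}
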