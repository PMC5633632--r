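#' Centred polynomial basis for non-linear exposure terms
#'
#' A power basis in `z = (x - center) / scale`, by default centred at the
#' sample mean and scaled by the sample SD. Centring decorrelates the linear,
#' quadratic and cubic columns enough for stable estimation while keeping the
#' coefficients interpretable on a known scale (the raw-scale polynomial is
#' recovered by expanding in `z`). Supports degrees 1–3, matching the
#' quadratic/cubic checks for non-linear workload-injury relationships.
#'
#' The centring constants are recorded on the basis so that model predictions
#' on new data (e.g. hazard-ratio curves over an exposure grid) reuse the
#' training centring, exactly as `stats::poly()` does.
#'
#' @param x numeric vector.
#' @param degree polynomial degree, 1, 2 or 3.
#' @param center,scale centring constants; default mean and SD of `x`.
#' @return a numeric matrix with one column per degree and attributes
#'   `degree`, `center`, `scale`.
#' @export
poly_c <- function(x, degree = 1, center = mean(x), scale = sd(x)) {
  degree <- as.integer(degree)
  if (degree < 1L || degree > 3L) {
    stop_validation("poly_c: degree must be 1, 2 or 3 (linear, quadratic or cubic)")
  }
  if (!is.finite(scale) || scale <= 0) scale <- 1
  z <- (x - center) / scale
  out <- vapply(seq_len(degree), function(d) z^d, numeric(length(x)))
  out <- matrix(out, ncol = degree,
                dimnames = list(NULL, as.character(seq_len(degree))))
  structure(out, degree = degree, center = center, scale = scale,
            class = c("poly_c", "matrix"))
}

#' @export
makepredictcall.poly_c <- function(var, call) {
  if (as.character(call)[1L] == "poly_c" ||
      identical(call[[1L]], quote(matchrisk::poly_c))) {
    call$center <- attr(var, "center")
    call$scale <- attr(var, "scale")
  }
  call
}
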