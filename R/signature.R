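# The reference-signature library and the diffusion-kurtosis signal model
# used to construct and interpret signatures.
#
# A "signature" is a pair of direction-averaged, normalized signals at the
# two key shells (Lb, Hb). The library holds two of them: B, a generic
# gray-matter-like tissue, and A, the same tissue with moderately increased
# diffusion hindrance. The signature index locates an observed signal pair
# between the two.

#' Diffusion-kurtosis parameters
#'
#' @param d diffusivity, mm^2/s (positive).
#' @param k excess kurtosis, dimensionless (> -3).
#' @return object of class `kurtosis_params`.
#' @export
kurtosis_params <- function(d, k) {
  assert_scalar_number(d, "d", positive = TRUE)
  assert_scalar_number(k, "k")
  if (k <= -3)
    stop_validation("'k' must be > -3 for a physically plausible signal decay")
  structure(list(d = d, k = k), class = "kurtosis_params")
}

#' Normalized diffusion-kurtosis signal
#'
#' The standard kurtosis signal representation
#' \deqn{S(b)/S_0 = \exp(-bD + (bD)^2 K / 6).}
#'
#' @param params a [kurtosis_params()].
#' @param b b-value(s), s/mm^2 (non-negative; vectorised).
#' @return normalized signal(s), `1` at `b = 0`.
#' @export
kurtosis_signal <- function(params, b) {
  if (!inherits(params, "kurtosis_params"))
    stop_validation("'params' must be kurtosis_params")
  if (any(b < 0)) stop_validation("'b' must be non-negative")
  bd <- b * params$d
  exp(-bd + bd^2 * params$k / 6)
}

# TRUE when the kurtosis signal is strictly decreasing on [0, b_max]:
# the exponent derivative -D + 2 b D^2 K / 6 must stay negative.
params_decreasing <- function(params, b_max) {
  params$k < 3 / (b_max * params$d)
}

#' Closed-form two-point kurtosis fit
#'
#' Inverts the kurtosis signal model from two normalized signals at the two
#' key shells. With log-attenuations \eqn{L_i = -\ln S_i} and
#' \eqn{r = Hb/Lb}, the unique solution is
#' \eqn{D = (L_2 - r^2 L_1) / (Lb \cdot r (1 - r))} and
#' \eqn{K = 6 (Lb \cdot D - L_1) / (Lb \cdot D)^2}.
#'
#' @param s_lb,s_hb normalized signals at `lb` and `hb`, with
#'   `0 < s_hb < s_lb <= 1`.
#' @param lb,hb the two key b-values, s/mm^2 (`hb > lb`).
#' @return a [kurtosis_params()] reproducing both inputs exactly.
#' @export
fit_two_point <- function(s_lb, s_hb, lb = 250, hb = 1750) {
  assert_scalar_number(s_lb, "s_lb", positive = TRUE)
  assert_scalar_number(s_hb, "s_hb", positive = TRUE)
  assert_scalar_number(lb, "lb", positive = TRUE)
  assert_scalar_number(hb, "hb", positive = TRUE)
  if (hb <= lb) stop_validation("'hb' must exceed 'lb'")
  if (s_lb > 1) stop_validation("'s_lb' must be <= 1 (normalized signal)")
  if (s_hb >= s_lb)
    stop_dwim("s_hb >= s_lb: no hindered (decaying) solution exists",
              "dwimarkers_fit_error")
  l1 <- -log(s_lb); l2 <- -log(s_hb)
  r <- hb / lb
  d <- (l2 - r^2 * l1) / (lb * r * (1 - r))
  if (!is.finite(d) || d <= 0)
    stop_dwim("two-point fit yields non-positive diffusivity", "dwimarkers_fit_error")
  k <- 6 * (lb * d - l1) / (lb * d)^2
  kurtosis_params(d, k)
}

#' Reference signature library
#'
#' Holds the two reference signal pairs \eqn{S_A} (increased hindrance) and
#' \eqn{S_B} (generic tissue) at the key shells, the intermediate signal
#' \eqn{S_N}, and the derived per-shell relative-distance spans
#' \eqn{\Delta_X = dS_X(Hb) - dS_X(Lb)} with
#' \eqn{dS_X(b) = (S_X(b) - S_N(b)) / S_N(b)} used by the signature index.
#' The default values are the study library for the mouse brain at
#' Lb = 250, Hb = 1750 s/mm^2; with the per-shell mean rule for
#' \eqn{S_N}, \eqn{\Delta_A = -\Delta_B > 0}.
#'
#' @param s_a_lb,s_a_hb signature A signals at (Lb, Hb).
#' @param s_b_lb,s_b_hb signature B signals at (Lb, Hb).
#' @param lb,hb key b-values, s/mm^2.
#' @param s_n_rule rule for the intermediate signal: `"mean"` (per-shell
#'   arithmetic mean of A and B) or a numeric length-2 vector
#'   `c(s_n_lb, s_n_hb)`.
#' @return object of class `signature_library`.
#' @export
signature_library <- function(s_a_lb = 0.858, s_a_hb = 0.370,
                              s_b_lb = 0.855, s_b_hb = 0.317,
                              lb = 250, hb = 1750,
                              s_n_rule = "mean") {
  for (nm in c("s_a_lb", "s_a_hb", "s_b_lb", "s_b_hb")) {
    v <- get(nm)
    assert_scalar_number(v, nm, positive = TRUE)
    if (v > 1) stop_validation(sprintf("'%s' must lie in (0, 1]", nm))
  }
  if (lb >= hb) stop_validation("'lb' must be smaller than 'hb'")
  if (identical(s_n_rule, "mean")) {
    s_n_lb <- (s_a_lb + s_b_lb) / 2
    s_n_hb <- (s_a_hb + s_b_hb) / 2
    rule_name <- "mean"
  } else if (is.numeric(s_n_rule) && length(s_n_rule) == 2L && all(s_n_rule > 0)) {
    s_n_lb <- s_n_rule[1]; s_n_hb <- s_n_rule[2]
    rule_name <- "fixed"
  } else {
    stop_validation("'s_n_rule' must be \"mean\" or a positive numeric length-2 vector")
  }
  ds <- function(s_l, s_h) (s_h - s_n_hb) / s_n_hb - (s_l - s_n_lb) / s_n_lb
  delta_a <- ds(s_a_lb, s_a_hb)
  delta_b <- ds(s_b_lb, s_b_hb)
  if (delta_a == 0 || delta_b == 0)
    stop_validation("degenerate library: delta_a and delta_b must be non-zero")
  structure(list(
    s_a_lb = s_a_lb, s_a_hb = s_a_hb,
    s_b_lb = s_b_lb, s_b_hb = s_b_hb,
    s_n_lb = s_n_lb, s_n_hb = s_n_hb,
    lb = lb, hb = hb,
    s_n_rule = rule_name,
    delta_a = delta_a, delta_b = delta_b
  ), class = "signature_library")
}

#' The default (study) signature library
#'
#' S_A = (0.858, 0.370), S_B = (0.855, 0.317) at b = (250, 1750) s/mm^2,
#' with the per-shell mean S_N rule.
#'
#' @return a `signature_library`.
#' @export
default_signature_library <- function() signature_library()

#' @export
print.signature_library <- function(x, ...) {
  cat(sprintf(
    "signature_library (S_N rule: %s)\n  S_A(%g, %g) = (%.4g, %.4g)\n  S_B(%g, %g) = (%.4g, %.4g)\n  delta_A = %.5g, delta_B = %.5g\n",
    x$s_n_rule, x$lb, x$hb, x$s_a_lb, x$s_a_hb, x$lb, x$hb, x$s_b_lb, x$s_b_hb,
    x$delta_a, x$delta_b))
  invisible(x)
}

#' Serialise / read a signature library as JSON
#'
#' @param library a `signature_library`.
#' @param path file path.
#' @export
write_library <- function(library, path) {
  jsonlite::write_json(
    library[c("s_a_lb", "s_a_hb", "s_b_lb", "s_b_hb", "lb", "hb", "s_n_rule",
              "s_n_lb", "s_n_hb")],
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rule <- if (identical(x$s_n_rule, "mean")) "mean" else c(x$s_n_lb, x$s_n_hb)
  signature_library(x$s_a_lb, x$s_a_hb, x$s_b_lb, x$s_b_hb,
                    lb = x$lb, hb = x$hb, s_n_rule = rule)
}

#' Derive a signature by shifting kurtosis parameters
#'
#' Evaluates the kurtosis model at `(d + dd, k + dk)` on the two key shells;
#' this is how a "moderate increase in diffusion hindrance" signature is
#' synthesised from a base tissue.
#'
#' @param base a [kurtosis_params()] describing the base tissue.
#' @param dd,dk shifts applied to diffusivity (mm^2/s) and kurtosis.
#' @param lb,hb key b-values, s/mm^2.
#' @return named numeric vector `c(s_lb = , s_hb = )`.
#' @export
make_signature <- function(base, dd = 0, dk = 0, lb = 250, hb = 1750) {
  shifted <- kurtosis_params(base$d + dd, base$k + dk)
  if (!params_decreasing(shifted, hb))
    stop_validation("shifted parameters give a non-decreasing signal over the b-range")
  c(s_lb = kurtosis_signal(shifted, lb), s_hb = kurtosis_signal(shifted, hb))
}
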