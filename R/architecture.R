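# Muscle architecture index: a dimensionless summary of pennation angle and
# optimal fiber length, 1 for parallel-fibered muscles, regressed from
# public anatomical measurement tables for pennate muscles.

.ai_coef <- c(intercept =  0.1546,
              x         = -5.7662e-5,   # pennation angle, degrees
              xy        =  6.6753e-4,   # interaction
              x2        = -2.0563e-4,
              y         = -1.3233e-3,   # optimal fiber length, cm
              y2        =  7.6327e-4)

#' Muscle architecture index from pennation angle and fiber length
#'
#' Evaluates the quadratic regression of the muscle architecture index
#' `Ia` on pennation angle `x` (degrees) and optimal fiber length `y` (cm):
#'
#' `Ia = 0.1546 - 5.7662e-5 x + 6.6753e-4 x y - 2.0563e-4 x^2
#'       - 1.3233e-3 y + 7.6327e-4 y^2`
#'
#' Muscles with a pennation angle below 5 degrees are treated as parallel
#' muscles and get an index of exactly 1 (this creates a deliberate,
#' documented jump at 5 degrees). The regression was fitted on muscles with
#' pennation between 5 and 25 degrees; larger angles are still evaluated
#' but flagged with a warning. The raw polynomial can leave the admissible
#' interval (0, 1] for extreme inputs; the result is then clamped into it
#' with a warning, because the force model requires `Ia <= 1` and `Ia > 0`.
#'
#' The fiber length is interpreted in centimetres, the unit of the
#' anatomical source tables the regression derives from; convert
#' millimetre model lengths before calling (see `fiber_length_cm` in
#' [muscle_path()]).
#'
#' @param pennation_deg Pennation angle in degrees (>= 0, finite).
#' @param optimal_length_cm Optimal fiber length in centimetres (> 0).
#' @return Architecture index in (0, 1].
#' @examples
#' architecture_index(4, 10)    # parallel rule: exactly 1
#' architecture_index(10, 10)   # 0.2633074
#' @export
architecture_index <- function(pennation_deg, optimal_length_cm) {
  if (!is.finite(pennation_deg) || !is.finite(optimal_length_cm))
    stop("pennation_deg and optimal_length_cm must be finite")
  if (pennation_deg < 0) stop("pennation_deg must be >= 0")
  if (optimal_length_cm <= 0) stop("optimal_length_cm must be positive")
  if (pennation_deg < 5) return(1.0)
  if (pennation_deg > 25)
    warning("pennation angle ", pennation_deg,
            " deg is outside the regression's 5-25 degree source range; ",
            "extrapolating")
  x <- pennation_deg; y <- optimal_length_cm
  z <- .ai_coef[["intercept"]] + .ai_coef[["x"]] * x +
    .ai_coef[["xy"]] * x * y + .ai_coef[["x2"]] * x^2 +
    .ai_coef[["y"]] * y + .ai_coef[["y2"]] * y^2
  if (z > 1) {
    warning("architecture index ", signif(z, 4), " exceeds 1; clamped to 1")
    z <- 1
  } else if (z <= 0) {
    warning("architecture index ", signif(z, 4),
            " is non-positive; clamped to 1e-6")
    z <- 1e-6
  }
  z
}

#' Diagnostics of the architecture-index regression
#'
#' @return A `regression_fit` with the polynomial coefficients and the
#'   reported fit quality (r-squared 0.98) on the anatomical source data.
#' @export
architecture_index_fit <- function() {
  structure(list(coefficients = .ai_coef, r_squared = 0.98,
                 input = "pennation (deg), optimal fiber length (cm)",
                 unit = "dimensionless"),
            class = "regression_fit")
}
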