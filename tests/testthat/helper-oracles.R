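# Shared helpers and independent oracles for the test suite.

# Transition matrix of the pelvis transcribed from the printed reference,
# row-vector convention.
printed_pelvic_matrix <- function() {
  matrix(c(0.9133, -0.4072, 0, 0,
           0.4072,  0.9133, 0, 0,
           0,       0,      1, 0,
          -0.0646, -0.0526, 0, 1),
         nrow = 4, byrow = TRUE)
}

# Independent term-by-term evaluation of the architecture-index polynomial
# (no parallel-muscle rule, no clamping).
ai_polynomial_oracle <- function(x, y) {
  0.1546 - 5.7662e-5 * x + 6.6753e-4 * x * y - 2.0563e-4 * x^2 -
    1.3233e-3 * y + 7.6327e-4 * y^2
}

# Random proper rotation matrix (QR of a Gaussian matrix, det forced to +1).
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Smooth periodic test waveform on the 101-point cycle grid.
cycle_waveform <- function(phase_shift = 0) {
  g <- seq(0, 1, length.out = 101)
  0.5 + 0.4 * sin(2 * pi * (g - phase_shift)) +
    0.15 * cos(4 * pi * (g - phase_shift))
}
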