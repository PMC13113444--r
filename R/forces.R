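# Simplified Hill-type force-length model: normalized active and passive
# force from L/L0 and the architecture index, plus cycle-offset
# compensation of active-force waveforms.

#' Normalized active muscle force
#'
#' Force-length relation of the simplified Hill-type model, driven only by
#' the ratio of instantaneous to optimal muscle length and the architecture
#' index `Ia`. For a parallel-fibered muscle (`Ia = 1`):
#'
#' `f_l = exp(-2.727 * (ln(L/L0))^2)`
#'
#' For pennate muscles (`Ia < 1`) the implemented branch is
#'
#' `f_l = exp(-(((L/L0)^0.9631 - 1) / (0.3531 * (1 - Ia)))^2)`
#'
#' Both branches are unimodal in `L` with maximum 1 at `L = L0`. The
#' pennate branch narrows as `Ia` approaches 1; the printed source form of
#' this branch is typographically ambiguous, so it is isolated here as a
#' single documented expression that preserves the constants 0.9631 and
#' 0.3531 and can be swapped without touching callers (all callers rely
#' only on the unimodal, max-1-at-L0 contract).
#'
#' @param L Instantaneous muscle length (> 0); vectorized.
#' @param L0 Optimal muscle length (> 0).
#' @param Ia Architecture index in (0, 1].
#' @return Normalized active force in (0, 1].
#' @examples
#' active_force(1.1, 1, 1)   # exp(-2.727 * log(1.1)^2)
#' @export
active_force <- function(L, L0, Ia) {
  .check_force_args(L, L0, Ia)
  r <- L / L0
  if (Ia == 1) {
    exp(-2.727 * log(r)^2)
  } else {
    exp(-((r^0.9631 - 1) / (0.3531 * (1 - Ia)))^2)
  }
}

#' Normalized passive muscle force
#'
#' Exponential stretch response of the passive element:
#'
#' `f_p = 0.0195 * exp((2.933 + 4.911 * Ia) * (L/L0 - 1))`
#'
#' Passive force depends only on instantaneous length: it is small below
#' the optimal length and becomes prominent, growing strictly and
#' exponentially, once the muscle is stretched beyond `L0`. The full
#' stiffness coefficient `2.933 + 4.911 * Ia` multiplies the relative
#' stretch inside the exponential; the alternative reading with part of
#' the coefficient outside the exponential would go negative for `L < L0`,
#' contradicting the non-negativity of a passive elastic force, and is
#' therefore not used.
#'
#' @inheritParams active_force
#' @return Normalized passive force (> 0); vectorized over `L`.
#' @examples
#' passive_force(1, 1, 1)     # 0.0195 at the optimal length
#' @export
passive_force <- function(L, L0, Ia) {
  .check_force_args(L, L0, Ia)
  0.0195 * exp((2.933 + 4.911 * Ia) * (L / L0 - 1))
}

.check_force_args <- function(L, L0, Ia) {
  if (any(!is.finite(L)) || any(L <= 0)) stop("L must be positive and finite")
  if (!is.finite(L0) || L0 <= 0) stop("L0 must be positive and finite")
  if (!is.finite(Ia) || Ia <= 0 || Ia > 1) stop("Ia must lie in (0, 1]")
}

#' Create a force profile over the gait cycle
#'
#' @param muscle Muscle name.
#' @param active Normalized active force, length 101 (0-100% cycle).
#' @param passive Normalized passive force, length 101.
#' @param applied_offset_pct Cycle-offset compensation already applied to
#'   the active series, in % of cycle.
#' @return A `force_profile` object with elements `muscle`, `grid`
#'   (0:100), `active`, `passive`, `applied_offset_pct`.
#' @export
force_profile <- function(muscle, active, passive, applied_offset_pct = 0) {
  if (length(active) != 101L || length(passive) != 101L)
    stop("active and passive series must have 101 samples (0-100% cycle)")
  if (any(!is.finite(active)) || any(!is.finite(passive)))
    stop("force series must be finite")
  if (any(passive < 0)) stop("passive force must be >= 0")
  structure(list(muscle = muscle, grid = 0:100,
                 active = as.numeric(active),
                 passive = as.numeric(passive),
                 applied_offset_pct = applied_offset_pct),
            class = "force_profile")
}

#' @export
print.force_profile <- function(x, ...) {
  cat(sprintf("Force profile '%s' (101-point gait-cycle grid)\n", x$muscle))
  cat(sprintf("  active: peak %.3f at %d%%   passive: peak %.4f\n",
              max(x$active), x$grid[which.max(x$active)], max(x$passive)))
  cat(sprintf("  applied cycle offset: %.2f%%\n", x$applied_offset_pct))
  invisible(x)
}

# Circular shift of a 101-point cycle series by k grid steps forward.
# The series is periodic with period 100 samples; sample 101 (100%)
# duplicates the cycle start and is rewritten accordingly.
.circshift_cycle <- function(series, k) {
  s <- series[1:100]
  k <- ((k %% 100) + 100) %% 100
  out <- s[((seq_len(100) - 1 - k) %% 100) + 1]
  c(out, out[1])
}

#' Apply cycle-offset compensation to a force profile
#'
#' Shifts the active series forward along the gait cycle by `offset_pct`
#' percent of the period (rounded to the nearest sample of the 101-point
#' grid), wrapping circularly. The passive series is left untouched:
#' passive force depends only on the instantaneous muscle length, so no
#' temporal compensation applies to it.
#'
#' @param profile A [force_profile()].
#' @param offset_pct Offset in percent of cycle, in `[0, 100)`.
#' @return The compensated `force_profile`, with `applied_offset_pct`
#'   incremented by the applied amount.
#' @export
apply_cycle_offset <- function(profile, offset_pct) {
  if (!is.finite(offset_pct) || offset_pct < 0 || offset_pct >= 100)
    stop("offset_pct must lie in [0, 100)")
  k <- round(offset_pct)
  profile$active <- .circshift_cycle(profile$active, k)
  profile$applied_offset_pct <- profile$applied_offset_pct + offset_pct
  profile
}

#' Estimate the cycle offset between two waveforms
#'
#' Finds the circular lag (in % of cycle) that maximizes the circular
#' cross-correlation between the candidate series, shifted forward, and
#' the reference series — the amount of temporal compensation needed to
#' align a length-driven active-force estimate with a reference waveform.
#' Ties are broken toward the smallest lag.
#'
#' @param candidate,reference Numeric series on the same 101-point cycle
#'   grid (the closing 100% sample is ignored as a duplicate of 0%).
#' @return Offset in percent of cycle, in `[0, 100)`.
#' @export
estimate_cycle_offset <- function(candidate, reference) {
  if (length(candidate) != length(reference))
    stop("series must share the cycle grid")
  n <- length(candidate)
  if (n == 101L) { candidate <- candidate[1:100]; reference <- reference[1:100] }
  m <- length(candidate)
  if (stats::sd(candidate) == 0 || stats::sd(reference) == 0)
    stop("cycle offset is undefined for a constant series")
  cc <- vapply(0:(m - 1), function(k) {
    shifted <- candidate[((seq_len(m) - 1 - k) %% m) + 1]
    stats::cor(shifted, reference)
  }, numeric(1))
  lag <- which.max(cc) - 1L           # which.max takes the first maximum
  lag * 100 / m
}

#' Normalize a waveform to unit maximum
#'
#' @param series Numeric series with a positive maximum.
#' @return `series / max(series)`.
#' @export
normalize_profile <- function(series) {
  m <- max(series)
  if (!is.finite(m) || m <= 0)
    stop("series must have a positive finite maximum to normalize")
  series / m
}

#' Packaged cycle-offset reference table
#'
#' Loads the packaged per-muscle cycle offsets (percent of gait cycle)
#' empirically determined for nine lower-limb muscles under five walking
#' conditions: self-selected free walking of elderly stroke patients
#' (`esp_free`) and four treadmill speeds of healthy elderly subjects
#' (`esnd_rfast`, `esnd_free`, `esnd_slow`, `esnd_xslow`).
#'
#' @return Data.frame with a `muscle` column and one numeric column per
#'   condition.
#' @export
cycle_offset_table <- function() {
  path <- system.file("extdata", "cycle_offsets.csv",
                      package = "gaitmuscle", mustWork = TRUE)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Mean cycle offset of a walking condition
#'
#' @param table A cycle-offset table as from [cycle_offset_table()].
#' @param condition Column name of the condition (e.g. `"esnd_xslow"`).
#' @return Arithmetic mean of the nine per-muscle offsets, percent.
#' @export
mean_cycle_offset <- function(table = cycle_offset_table(), condition) {
  if (!condition %in% names(table))
    stop("unknown condition: ", condition)
  v <- table[[condition]]
  if (any(is.na(v)))
    stop("missing offset for muscle(s): ",
         paste(table$muscle[is.na(v)], collapse = ", "))
  mean(v)
}

#' Look up the cycle offset for one muscle and condition
#'
#' @inheritParams mean_cycle_offset
#' @param muscle Muscle name as in the table.
#' @return Offset in percent of cycle.
#' @export
lookup_cycle_offset <- function(muscle, condition,
                                table = cycle_offset_table()) {
  if (!condition %in% names(table)) stop("unknown condition: ", condition)
  i <- match(muscle, table$muscle)
  if (is.na(i)) stop("muscle not in offset table: ", muscle)
  table[[condition]][i]
}
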