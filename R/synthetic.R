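# Deterministic synthetic slow-gait trials: truncated-Fourier sagittal
# joint angles driving forward kinematics over the packaged generic
# skeleton, yielding segment poses, landmark trajectories and foot-strike
# events. Stands in for optical motion capture so the whole pipeline can
# run and be tested without hardware.

.speed_conditions <- data.frame(
  label     = c("X-slow", "slow", "free", "R-fast"),
  speed_mps = c(0.61, 0.80, 1.17, 1.64),
  sd_mps    = c(0.09, 0.12, 0.14, 0.18),
  stride_m  = c(0.90, 1.00, 1.25, 1.45),
  stringsAsFactors = FALSE
)

#' Walking-speed conditions of the synthetic generator
#'
#' The four speed conditions emulated by [generate_gait_trial()]: extremely
#' slow, slow, self-selected free and relatively fast walking, with their
#' nominal speeds, the between-subject spread of each condition, and the
#' default stride length used to derive the cycle duration
#' (`duration = stride / speed`).
#'
#' @return Data.frame with columns `label`, `speed_mps`, `sd_mps`,
#'   `stride_m`.
#' @export
speed_conditions <- function() .speed_conditions

#' Parameters of the synthetic gait model
#'
#' @param stride_m Stride length in metres; `NULL` uses the speed
#'   condition's default.
#' @param cycle_duration_s Gait-cycle duration in seconds; `NULL` derives
#'   it as `stride / speed`.
#' @param asymmetry_factor Multiplier on the left side's joint-angle
#'   harmonic amplitudes (1 = symmetric gait).
#' @param amplitude_scale Global multiplier on all joint-angle harmonic
#'   amplitudes.
#' @param noise_mm Standard deviation of Gaussian marker jitter, mm.
#' @param rate_hz Sampling rate.
#' @param n_cycles Number of gait cycles generated.
#' @param seed Integer seed; all randomness (marker jitter) flows through
#'   it, so equal inputs give bitwise-identical trials.
#' @return A `gait_model_params` list.
#' @export
gait_model_params <- function(stride_m = NULL, cycle_duration_s = NULL,
                              asymmetry_factor = 1, amplitude_scale = 1,
                              noise_mm = 0, rate_hz = 100, n_cycles = 3,
                              seed = 20260326) {
  if (!is.null(cycle_duration_s) && cycle_duration_s <= 0)
    stop("cycle_duration_s must be positive")
  if (asymmetry_factor <= 0) stop("asymmetry_factor must be positive")
  if (noise_mm < 0) stop("noise_mm must be >= 0")
  if (n_cycles < 2) stop("need at least 2 cycles for cycle averaging")
  structure(list(stride_m = stride_m, cycle_duration_s = cycle_duration_s,
                 asymmetry_factor = asymmetry_factor,
                 amplitude_scale = amplitude_scale,
                 noise_mm = noise_mm, rate_hz = rate_hz,
                 n_cycles = n_cycles, seed = seed),
            class = "gait_model_params")
}

# Evaluate a 3-harmonic Fourier series (degrees) at cycle phase in [0, 1).
.fourier_angle <- function(coef, phase, amp = 1) {
  th <- 2 * pi * phase
  out <- rep(coef$a0, length(phase))
  for (k in 1:3)
    out <- out + amp * (coef$a[k] * cos(k * th) + coef$b[k] * sin(k * th))
  out
}

.rotz_deg <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

# Piecewise-linear phase warp mapping a side-specific stance fraction onto
# the nominal 62% stance phase; identity when sf == 0.62.
.warp_phase <- function(phase, sf, nominal = 0.62) {
  ifelse(phase < sf,
         phase * nominal / sf,
         nominal + (phase - sf) * (1 - nominal) / (1 - sf))
}

#' Generate a deterministic synthetic gait trial
#'
#' Sagittal hip, knee and ankle angles follow the 3-harmonic Fourier
#' patterns stored in the packaged body model; segment poses are obtained
#' by forward kinematics over the model skeleton, landmark trajectories by
#' mapping the model's landmark coordinates through the poses (plus
#' optional seeded Gaussian jitter), and foot strikes fall at cycle
#' boundaries (right foot) and half-cycle boundaries (left foot). The mean
#' forward speed equals the condition's nominal speed (`stride /
#' duration`), inside the condition's published band. Joint-angle patterns
#' are shared across speed conditions; only the cycle duration changes.
#'
#' @param speed_label One of `"X-slow"`, `"slow"`, `"free"`, `"R-fast"`.
#' @param params A [gait_model_params()].
#' @param model Body model, as from [generic_body_model()].
#' @param side_amp Internal: named list of per-side amplitude multipliers
#'   and stance fractions (used by [generate_hemiplegic_trial()]).
#' @return A `gait_trial`: list with `time`, `rate_hz`, `poses` (named
#'   list of 4x4xT row-convention pose arrays per segment), `landmarks`
#'   (named list of Tx3 matrices), `events_right`, `events_left` (s),
#'   `speed_label`, `speed_mps`, `cycle_duration_s`, `params`.
#' @export
generate_gait_trial <- function(speed_label = "slow",
                                params = gait_model_params(),
                                model = generic_body_model(),
                                side_amp = NULL) {
  cond <- .speed_conditions[.speed_conditions$label == speed_label, ]
  if (nrow(cond) != 1L)
    stop("unknown speed label: ", speed_label, " (expected one of ",
         paste(.speed_conditions$label, collapse = ", "), ")")
  stride <- if (is.null(params$stride_m)) cond$stride_m else params$stride_m
  Tcyc <- if (is.null(params$cycle_duration_s)) stride / cond$speed_mps
          else params$cycle_duration_s
  v <- stride / Tcyc * 1000                      # mm/s forward
  if (is.null(side_amp))
    side_amp <- list(right = list(amp = 1, stance = 0.62),
                     left  = list(amp = params$asymmetry_factor,
                                  stance = 0.62))
  n <- round(params$n_cycles * Tcyc * params$rate_hz)
  time <- seq(0, params$n_cycles * Tcyc, length.out = n + 1L)

  seg <- model$segments
  Lf <- seg$femur$length_mm; Lt <- seg$tibia$length_mm
  hip_local <- model$hip_center_pelvis_mm       # right hip; mirror z for left
  hip_y <- 70 - hip_local[2]                    # pelvis origin above hip
  pelvis_h <- Lf + Lt + model$ankle_height_mm + hip_y

  nT <- length(time)
  mk4 <- function() array(0, dim = c(4, 4, nT))
  poses <- list(pelvis = mk4(), femur_r = mk4(), femur_l = mk4(),
                tibia_r = mk4(), tibia_l = mk4(),
                foot_r = mk4(), foot_l = mk4())

  phase_r <- (time / Tcyc) %% 1
  pelvis_org <- cbind(v * time,
                      pelvis_h + 12 * sin(4 * pi * phase_r),
                      8 * sin(2 * pi * phase_r))
  gf <- model$gait_fourier_deg
  amp0 <- params$amplitude_scale

  for (k in seq_len(nT)) {
    Mp <- rbind(cbind(diag(3), 0), c(pelvis_org[k, ], 1))
    poses$pelvis[, , k] <- Mp
    for (s in c("r", "l")) {
      sa <- if (s == "r") side_amp$right else side_amp$left
      ph <- if (s == "r") phase_r[k] else (phase_r[k] + 0.5) %% 1
      ph <- .warp_phase(ph, sa$stance)
      amp <- amp0 * sa$amp
      hip   <- .fourier_angle(gf$hip,   ph, amp)
      knee  <- .fourier_angle(gf$knee,  ph, amp)
      ankle <- .fourier_angle(gf$ankle, ph, amp)
      hipc <- hip_local * c(1, 1, if (s == "r") 1 else -1)
      hip_lab <- pelvis_org[k, ] + hipc
      Rfe <- .rotz_deg(hip)
      knee_lab <- hip_lab + drop(Rfe %*% c(0, -Lf, 0))
      Rti <- .rotz_deg(hip - knee)
      ank_lab <- knee_lab + drop(Rti %*% c(0, -Lt, 0))
      Rfo <- .rotz_deg(hip - knee + ankle)
      poses[[paste0("femur_", s)]][, , k] <- rbind(cbind(t(Rfe), 0),
                                                   c(hip_lab, 1))
      poses[[paste0("tibia_", s)]][, , k] <- rbind(cbind(t(Rti), 0),
                                                   c(knee_lab, 1))
      poses[[paste0("foot_", s)]][, , k]  <- rbind(cbind(t(Rfo), 0),
                                                   c(ank_lab, 1))
    }
  }

  landmarks <- .trial_landmarks(model, poses, nT)
  if (params$noise_mm > 0) {
    set.seed(params$seed)
    landmarks <- lapply(landmarks, function(m)
      m + matrix(stats::rnorm(length(m), 0, params$noise_mm), nrow(m)))
  }

  structure(list(
    time = time, rate_hz = params$rate_hz, poses = poses,
    landmarks = landmarks,
    events_right = seq(0, by = Tcyc, length.out = params$n_cycles + 1L),
    events_left  = Tcyc / 2 + seq(0, by = Tcyc,
                                  length.out = params$n_cycles),
    speed_label = speed_label, speed_mps = v / 1000,
    cycle_duration_s = Tcyc, params = params
  ), class = "gait_trial")
}

# Landmark trajectories: pelvic frame-defining points plus joint centers,
# heel and toe of each side, mapped through the segment poses.
.trial_landmarks <- function(model, poses, nT) {
  lm <- model$landmarks_pelvis_mm
  pick <- function(seg, p) {
    arr <- poses[[seg]]
    t(vapply(seq_len(nT),
             function(k) drop(c(p, 1) %*% arr[, , k])[1:3], numeric(3)))
  }
  out <- list(
    RASI  = pick("pelvis", lm$P1a),
    PUBIS = pick("pelvis", lm$P2a),
    LASI  = pick("pelvis", lm$P4a)
  )
  Lf <- model$segments$femur$length_mm
  Lt <- model$segments$tibia$length_mm
  for (s in c("r", "l")) {
    S <- toupper(s)
    out[[paste0("HIP", S)]]  <- pick(paste0("femur_", s), c(0, 0, 0))
    out[[paste0("KNEE", S)]] <- pick(paste0("femur_", s), c(0, -Lf, 0))
    out[[paste0("ANK", S)]]  <- pick(paste0("tibia_", s), c(0, -Lt, 0))
    out[[paste0("HEEL", S)]] <- pick(paste0("foot_", s),
                                     model$heel_foot_mm)
    out[[paste0("TOE", S)]]  <- pick(paste0("foot_", s),
                                     model$toe_foot_mm)
  }
  out
}

#' @export
print.gait_trial <- function(x, ...) {
  cat(sprintf("Synthetic gait trial: %s (%.2f m/s), %d cycles of %.3f s\n",
              x$speed_label, x$speed_mps,
              length(x$events_right) - 1L, x$cycle_duration_s))
  cat(sprintf("  %d samples at %g Hz, %d landmarks, %d segment poses\n",
              length(x$time), x$rate_hz, length(x$landmarks),
              length(x$poses)))
  invisible(x)
}

#' Generate a synthetic hemiplegic gait trial
#'
#' Emulates post-stroke compensatory gait: the affected side's joint-angle
#' harmonic amplitudes are scaled down by `weakness_factor`, and the
#' unaffected side's stance phase is lengthened (the affected side's
#' shortened) in proportion to the weakness, reproducing the asymmetric
#' loading pattern of hemiplegic walking. A `weakness_factor` of 1 yields
#' the symmetric trial unchanged.
#'
#' @param params A [gait_model_params()].
#' @param affected_side `"left"` or `"right"`.
#' @param weakness_factor Amplitude multiplier of the affected side, in
#'   (0, 1].
#' @param speed_label Speed condition; defaults to `"free"` (stroke
#'   subjects walk at a self-selected free speed).
#' @inheritParams generate_gait_trial
#' @return A `gait_trial` with an `affected_side` element.
#' @export
generate_hemiplegic_trial <- function(params = gait_model_params(),
                                      affected_side = c("right", "left"),
                                      weakness_factor = 0.7,
                                      speed_label = "free",
                                      model = generic_body_model()) {
  affected_side <- match.arg(affected_side)
  if (!is.finite(weakness_factor) ||
      weakness_factor <= 0 || weakness_factor > 1)
    stop("weakness_factor must lie in (0, 1]")
  d <- 1 - weakness_factor
  weak   <- list(amp = weakness_factor, stance = 0.62 - 0.05 * d)
  strong <- list(amp = 1,               stance = 0.62 + 0.08 * d)
  side_amp <- if (affected_side == "right")
    list(right = weak, left = strong) else list(right = strong, left = weak)
  trial <- generate_gait_trial(speed_label, params, model,
                               side_amp = side_amp)
  trial$affected_side <- affected_side
  trial$weakness_factor <- weakness_factor
  trial
}
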