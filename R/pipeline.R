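# End-to-end estimation: gait trial + body model (+ subject anthropometry)
# -> normalized active and passive force profiles for the nine muscles.

.label_to_condition <- c("X-slow" = "esnd_xslow", "slow" = "esnd_slow",
                         "free" = "esnd_free", "R-fast" = "esnd_rfast")

#' Estimate muscle force profiles from a gait trial
#'
#' Runs the full non-invasive estimation pipeline for every muscle of the
#' body model:
#'
#' 1. optionally scale the generic model to the subject's anthropometry
#'    (per-segment ratios of subject to generic segment lengths);
#' 2. compute the muscle-tendon length at every sample from the trial's
#'    segment poses (straight-line origin-insertion distance);
#' 3. resample the length series onto the 101-point gait-cycle grid and
#'    normalize by the muscle's optimal length L0;
#' 4. evaluate the simplified Hill-type active and passive force-length
#'    relations with the muscle's architecture index;
#' 5. normalize the active waveform to unit peak and, when a walking
#'    condition is given (or derivable from the trial's speed label),
#'    apply the muscle's cycle-offset compensation from the packaged
#'    offset table. Passive force is never shifted: it depends only on
#'    instantaneous length.
#'
#' @param trial A `gait_trial` (see [generate_gait_trial()]).
#' @param model A `body_model`; defaults to the packaged generic model.
#' @param subject Optional [anthro_profile()]; its `segment_lengths_mm`
#'   are matched against the model's segments to build scale factors.
#' @param side Which leg to evaluate (`"right"` or `"left"`).
#' @param condition Walking condition for cycle-offset compensation: a
#'   column of [cycle_offset_table()], `NULL` to derive it from the
#'   trial's speed label, or `NA` to skip compensation.
#' @param normalize Normalize each active waveform to unit peak
#'   (default `TRUE`).
#' @return Named list of [force_profile()]s (class `force_profile_set`),
#'   with the normalized length series attached to each profile as
#'   attribute `lnorm`.
#' @examples
#' \dontrun{
#' trial <- generate_gait_trial("X-slow")
#' profiles <- estimate_muscle_forces(trial)
#' profiles$Iliacus
#' }
#' @export
estimate_muscle_forces <- function(trial, model = generic_body_model(),
                                   subject = NULL,
                                   side = c("right", "left"),
                                   condition = NULL, normalize = TRUE) {
  side <- match.arg(side)
  if (!is.null(subject)) {
    if (length(subject$segment_lengths_mm)) {
      sf <- compute_scale_factors(subject$segment_lengths_mm,
                                  model_segment_lengths(model))
      model <- scale_body_model(model, sf)
    }
  }
  if (is.null(condition))
    condition <- unname(.label_to_condition[trial$speed_label])
  offsets <- if (!is.null(condition) && !is.na(condition))
    cycle_offset_table() else NULL

  out <- lapply(model$muscles, function(m) {
    lnorm <- length_timeseries(m, trial, side = side)
    act <- active_force(lnorm, 1, m$architecture_index)
    pas <- passive_force(lnorm, 1, m$architecture_index)
    if (normalize) act <- normalize_profile(act)
    p <- force_profile(m$name, act, pas)
    if (!is.null(offsets) && m$name %in% offsets$muscle)
      p <- apply_cycle_offset(p, lookup_cycle_offset(m$name, condition,
                                                     offsets))
    attr(p, "lnorm") <- lnorm
    p
  })
  structure(out, class = "force_profile_set",
            side = side, condition = condition,
            speed_label = trial$speed_label)
}

#' @export
print.force_profile_set <- function(x, ...) {
  cat(sprintf("Force profiles (%d muscles, %s side%s)\n", length(x),
              attr(x, "side"),
              if (!is.null(attr(x, "condition")) && !is.na(attr(x, "condition")))
                paste0(", condition ", attr(x, "condition")) else ""))
  for (p in x)
    cat(sprintf("  %-10s active peak at %3d%% (offset %5.2f%%), passive peak %.4f\n",
                p$muscle, p$grid[which.max(p$active)],
                p$applied_offset_pct, max(p$passive)))
  invisible(x)
}
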