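# The packaged generic body model: a synthetic lower-limb skeleton with
# frame-defining landmarks, nine representative muscles and gait
# joint-angle patterns. Versioned data file with md5 integrity check.

#' Load the packaged generic body model
#'
#' Reads the versioned generic lower-limb model packaged with gaitmuscle:
#' pelvis/femur/tibia/foot segment dimensions, pelvic frame-defining
#' landmarks, 3-harmonic sagittal joint-angle patterns, and nine
#' representative lower-limb muscles (Glut_Max1, TFL, Iliacus, Pectineus,
#' Vas_Int, Med_Gas, Tib_Ant, Tib_Post, Soleus) with straight-line
#' origin/insertion coordinates, pennation angles (some below the
#' 5-degree parallel-muscle threshold, some in the 5-25 degree pennate
#' range), anatomical fiber lengths and generic optimal operating lengths.
#' The geometry is synthetic — designed for plausibility and pipeline
#' testing, not transcribed from any cadaver dataset. The file's md5 sum
#' is verified against the packaged sidecar to catch corruption.
#'
#' @param path Optional path to an alternative model JSON file (skips the
#'   checksum verification unless a `<path>.md5` sidecar exists).
#' @return A `body_model` list: `name`, `version`, `units`, `segments`,
#'   `landmarks_pelvis_mm`, `hip_center_pelvis_mm`, `ankle_height_mm`,
#'   `heel_foot_mm`, `toe_foot_mm`, `gait_fourier_deg`, and `muscles`
#'   (named list of [muscle_path()] objects).
#' @export
generic_body_model <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "generic_body_model.json",
                        package = "gaitmuscle", mustWork = TRUE)
    md5_path <- system.file("extdata", "generic_body_model.md5",
                            package = "gaitmuscle", mustWork = TRUE)
  } else {
    md5_path <- paste0(path, ".md5")
    if (!file.exists(md5_path)) md5_path <- NULL
  }
  if (!is.null(md5_path)) {
    want <- strsplit(trimws(readLines(md5_path, warn = FALSE)[1]), "\\s+")[[1]][1]
    have <- unname(tools::md5sum(path))
    if (!identical(want, have))
      stop("body model file failed its checksum (expected ", want,
           ", got ", have, "); the data file is corrupted")
  }
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  muscles <- lapply(seq_len(nrow(raw$muscles)), function(i) {
    m <- raw$muscles[i, ]
    muscle_path(name = m$name,
                origin = unlist(m$origin), origin_segment = m$origin_segment,
                insertion = unlist(m$insertion),
                insertion_segment = m$insertion_segment,
                pennation_deg = m$pennation_deg, L0 = m$L0_mm,
                fiber_length_cm = m$fiber_length_cm)
  })
  names(muscles) <- raw$muscles$name
  gf <- lapply(raw$gait_fourier_deg, function(j)
    list(a0 = j$a0, a = unlist(j$a), b = unlist(j$b)))
  structure(list(
    name = raw$name, version = raw$version, units = raw$units,
    segments = raw$segments,
    landmarks_pelvis_mm = lapply(raw$landmarks_pelvis_mm, unlist),
    hip_center_pelvis_mm = unlist(raw$hip_center_pelvis_mm),
    ankle_height_mm = raw$ankle_height_mm,
    heel_foot_mm = unlist(raw$heel_foot_mm),
    toe_foot_mm = unlist(raw$toe_foot_mm),
    gait_fourier_deg = gf,
    muscles = muscles
  ), class = "body_model")
}

#' @export
print.body_model <- function(x, ...) {
  cat(sprintf("Body model '%s' v%s (%s)\n", x$name, x$version, x$units))
  cat("  segments:",
      paste(sprintf("%s (%.0f mm)", names(x$segments),
                    vapply(x$segments, function(s) s$length_mm, numeric(1))),
            collapse = ", "), "\n")
  cat("  muscles:", paste(names(x$muscles), collapse = ", "), "\n")
  invisible(x)
}

#' Generic segment lengths of a body model
#'
#' Convenience accessor returning the named vector of segment lengths used
#' as the denominator of [compute_scale_factors()].
#'
#' @param model A `body_model`.
#' @return Named numeric vector of segment lengths (mm).
#' @export
model_segment_lengths <- function(model = generic_body_model()) {
  vapply(model$segments, function(s) s$length_mm, numeric(1))
}

#' Scale a body model to a subject
#'
#' Applies per-segment geometric scale factors to every muscle's
#' attachment coordinates (each in its owning segment's kinematic frame)
#' and optimal operating length, and to the segment dimensions and
#' landmarks. Scaling is isotropic within each segment; a muscle's L0 is
#' scaled by its origin segment's factor.
#'
#' @param model A `body_model`.
#' @param scale_set Named factors from [compute_scale_factors()]; segments
#'   without a factor keep the generic geometry.
#' @return The scaled `body_model`.
#' @export
scale_body_model <- function(model, scale_set) {
  f <- function(seg) if (seg %in% names(scale_set)) scale_set[[seg]] else 1
  for (seg in names(model$segments))
    model$segments[[seg]]$length_mm <- model$segments[[seg]]$length_mm * f(seg)
  model$landmarks_pelvis_mm <- lapply(model$landmarks_pelvis_mm,
                                      function(p) p * f("pelvis"))
  model$hip_center_pelvis_mm <- model$hip_center_pelvis_mm * f("pelvis")
  model$heel_foot_mm <- model$heel_foot_mm * f("foot")
  model$toe_foot_mm <- model$toe_foot_mm * f("foot")
  model$ankle_height_mm <- model$ankle_height_mm * f("foot")
  model$muscles <- lapply(model$muscles, function(m) {
    m$origin <- m$origin * f(m$origin_segment)
    m$insertion <- m$insertion * f(m$insertion_segment)
    m$L0 <- scale_optimal_fiber_length(m$L0, f(m$origin_segment))
    m
  })
  model
}
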