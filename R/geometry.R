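# Segment frames and homogeneous transforms.
#
# All transforms use the row-vector convention: a point (x, y, z, 1) is a
# 1x4 row vector and maps through the 4x4 matrix on the right,
#   (x', y', z', 1) = (x, y, z, 1) %*% M.
# The upper-left 3x3 block is therefore the transpose of the usual
# column-vector rotation, and the translation sits in the bottom row.

.normalize3 <- function(v, what = "vector") {
  n <- sqrt(sum(v^2))
  if (!is.finite(n) || n < 1e-9)
    stop("degenerate geometry: zero-length ", what)
  v / n
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Construct a homogeneous frame transform
#'
#' Builds a rigid 4x4 homogeneous transform in the row-vector convention
#' (`point_row %*% matrix`). Supply either a rotation/translation pair in
#' the familiar column-vector sense (`rotation`'s columns are the source
#' frame's axes expressed in target coordinates) or a ready-made 4x4
#' row-convention matrix via `row_matrix`.
#'
#' @param rotation 3x3 rotation matrix, column-vector convention.
#' @param translation Length-3 numeric: source origin in target coordinates.
#' @param from,to Frame tags (free-form labels).
#' @param row_matrix Optional full 4x4 matrix in the row convention;
#'   overrides `rotation`/`translation`.
#' @param tol Orthonormality tolerance for validation (default `1e-6`;
#'   use a looser value for matrices transcribed from printed sources).
#' @return A `frame_transform` object (a 4x4 matrix with attributes).
#' @export
frame_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            from = "source", to = "target",
                            row_matrix = NULL, tol = 1e-6) {
  if (is.null(row_matrix)) {
    stopifnot(is.matrix(rotation), all(dim(rotation) == c(3L, 3L)),
              length(translation) == 3L)
    M <- rbind(cbind(t(rotation), 0), c(translation, 1))
  } else {
    stopifnot(is.matrix(row_matrix), all(dim(row_matrix) == c(4L, 4L)))
    M <- row_matrix
  }
  if (!all(is.finite(M))) stop("non-finite entries in transform")
  if (max(abs(M[1:3, 4] - 0)) > tol || abs(M[4, 4] - 1) > tol)
    stop("last column must be (0, 0, 0, 1)")
  R <- M[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > tol)
    stop("rotation block is not orthonormal within tol = ", tol)
  if (abs(det(R) - 1) > max(tol, 1e-6) * 10)
    stop("rotation block must have determinant +1 (no reflection)")
  dimnames(M) <- NULL
  structure(M, class = "frame_transform", from = from, to = to, tol = tol)
}

#' @export
print.frame_transform <- function(x, ...) {
  cat(sprintf("Frame transform: %s -> %s (row-vector convention)\n",
              attr(x, "from"), attr(x, "to")))
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

#' Extract rotation (column convention) and translation
#'
#' @param transform A `frame_transform`.
#' @return List with `rotation` (3x3, column convention) and `translation`.
#' @export
transform_parts <- function(transform) {
  M <- unclass(transform)
  list(rotation = t(M[1:3, 1:3]), translation = M[4, 1:3])
}

#' Invert a frame transform
#' @param transform A `frame_transform`.
#' @return The inverse `frame_transform` (target -> source).
#' @export
invert_transform <- function(transform) {
  p <- transform_parts(transform)
  tol <- attr(transform, "tol"); if (is.null(tol)) tol <- 1e-6
  frame_transform(t(p$rotation), -drop(p$translation %*% p$rotation),
                  from = attr(transform, "to"), to = attr(transform, "from"),
                  tol = tol)
}

#' Compose two frame transforms (first A, then B)
#' @param a,b `frame_transform` objects applied in that order.
#' @return The composite `frame_transform`.
#' @export
compose_transforms <- function(a, b) {
  tols <- c(attr(a, "tol"), attr(b, "tol"), 1e-6)
  frame_transform(row_matrix = unclass(a) %*% unclass(b),
                  from = attr(a, "from"), to = attr(b, "to"),
                  tol = max(tols))
}

#' Map points through a frame transform
#'
#' Applies the homogeneous row-vector product: each point is augmented to
#' `(x, y, z, 1)` and multiplied on the right by the transform matrix.
#'
#' @param point Length-3 numeric vector, or an n x 3 matrix of points.
#' @param transform A `frame_transform` (or plain 4x4 row-convention
#'   matrix).
#' @return Transformed point(s), same shape as the input.
#' @export
transform_point <- function(point, transform) {
  M <- unclass(transform)
  if (is.matrix(point)) {
    stopifnot(ncol(point) == 3L)
    if (!all(is.finite(point))) stop("non-finite point coordinates")
    out <- cbind(point, 1) %*% M
    return(out[, 1:3, drop = FALSE])
  }
  stopifnot(length(point) == 3L)
  if (!all(is.finite(point))) stop("non-finite point coordinates")
  drop(c(point, 1) %*% M)[1:3]
}

#' Build the pelvic anatomical and kinematic frames from landmarks
#'
#' The anatomical pelvic frame has its origin at the midpoint of the
#' superior margin of the pubic symphysis (`P2a`), its y axis along the
#' vector from that point to the midpoint of the inter-ASIS line (`P3a`,
#' pointing superiorly), its x axis perpendicular to the frontal plane
#' pointing anteriorly, and its z axis completing the right-handed triad
#' along the left-to-right ASIS direction. The kinematic frame has its
#' origin at `P3a`, z axis from the left ASIS (`P4a`) toward the right ASIS
#' (`P1a`), x axis anterior and y axis superior.
#'
#' @param landmarks Named list/environment with 3-D points `P1a` (right
#'   ASIS), `P2a` (pubic symphysis superior-margin midpoint) and `P4a`
#'   (left ASIS), in lab coordinates. `P3a` is derived as the midpoint of
#'   `P1a` and `P4a` (and cross-checked if supplied).
#' @return List with `anatomical` and `kinematic`, each a `frame_transform`
#'   mapping that frame's coordinates into the lab frame.
#' @export
build_pelvic_frames <- function(landmarks) {
  need <- c("P1a", "P2a", "P4a")
  if (!all(need %in% names(landmarks)))
    stop("landmarks must contain ", paste(need, collapse = ", "))
  P1 <- as.numeric(landmarks$P1a)
  P2 <- as.numeric(landmarks$P2a)
  P4 <- as.numeric(landmarks$P4a)
  P3 <- (P1 + P4) / 2
  if (!is.null(landmarks$P3a) &&
      max(abs(as.numeric(landmarks$P3a) - P3)) > 1e-3 * max(1, max(abs(P3))))
    warning("supplied P3a is not the midpoint of P1a and P4a; using midpoint")
  y_a <- .normalize3(P3 - P2, "pubis-to-ASIS-midpoint axis")
  z_dir <- P1 - P4                       # left ASIS -> right ASIS
  x_a <- .normalize3(.cross3(y_a, z_dir), "anterior axis (landmarks collinear?)")
  z_a <- .cross3(x_a, y_a)
  anatomical <- frame_transform(cbind(x_a, y_a, z_a), P2,
                                from = "pelvis_anatomical", to = "lab")
  z_k <- .normalize3(z_dir, "inter-ASIS axis")
  x_k <- .normalize3(.cross3(P3 - P2, z_k), "anterior axis (landmarks collinear?)")
  y_k <- .cross3(z_k, x_k)
  kinematic <- frame_transform(cbind(x_k, y_k, z_k), P3,
                               from = "pelvis_kinematic", to = "lab")
  list(anatomical = anatomical, kinematic = kinematic)
}

#' Least-squares rigid transition matrix between two point sets
#'
#' Solves the closed-form orthogonal Procrustes problem (rotation +
#' translation, no scaling) mapping anatomical-frame points onto their
#' kinematic-frame counterparts under the row-vector convention, minimizing
#' the summed squared residuals. This is how a segment's transition matrix
#' (pelvis, femur, tibia, foot) is estimated from paired calibration points.
#'
#' @param points_anatomical,points_kinematic n x 3 matrices of paired
#'   points, n >= 3, not collinear.
#' @param from,to Frame tags for the result.
#' @return A `frame_transform` with attribute `residual_rms` (root mean
#'   squared residual over points).
#' @export
estimate_transition_matrix <- function(points_anatomical, points_kinematic,
                                       from = "anatomical", to = "kinematic") {
  A <- as.matrix(points_anatomical)
  B <- as.matrix(points_kinematic)
  if (!all(dim(A) == dim(B)) || ncol(A) != 3L)
    stop("point sets must be matching n x 3 matrices")
  n <- nrow(A)
  if (n < 3L) stop("need at least 3 paired points")
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  sv <- svd(Ac)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stop("points are collinear; the transition matrix is not determined")
  H <- crossprod(Ac, Bc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)     # column convention: b = R a + t
  tr <- cb - drop(R %*% ca)
  out <- frame_transform(R, tr, from = from, to = to)
  res <- cbind(A, 1) %*% unclass(out)
  attr(out, "residual_rms") <- sqrt(mean(rowSums((res[, 1:3] - B)^2)))
  out
}

#' Define a muscle path
#'
#' A muscle is modelled as a straight line from its origin to its insertion,
#' each attachment fixed in the kinematic frame of its owning segment. The
#' path carries the muscle's architecture parameters: pennation angle,
#' optimal (muscle-tendon operating) length used to normalize instantaneous
#' length, the anatomical optimal fiber length feeding the architecture
#' index regression, and the resulting architecture index.
#'
#' @param name Muscle name.
#' @param origin,insertion Length-3 attachment coordinates (mm) in the
#'   owning segment's kinematic frame.
#' @param origin_segment,insertion_segment Owning segment names.
#' @param pennation_deg Pennation angle, degrees (>= 0).
#' @param L0 Optimal operating length (mm, > 0) for length normalization.
#' @param fiber_length_cm Anatomical optimal fiber length in centimetres
#'   used to evaluate the architecture-index regression; defaults to
#'   `L0 / 10` (i.e. `L0` read as cm) when not supplied.
#' @param architecture_index Optional pre-computed index in (0, 1];
#'   computed from `pennation_deg` and `fiber_length_cm` when `NULL`.
#' @return A `muscle_path` object.
#' @export
muscle_path <- function(name, origin, origin_segment,
                        insertion, insertion_segment,
                        pennation_deg, L0,
                        fiber_length_cm = L0 / 10,
                        architecture_index = NULL) {
  stopifnot(length(origin) == 3L, length(insertion) == 3L)
  if (!is.finite(pennation_deg) || pennation_deg < 0)
    stop("pennation_deg must be >= 0")
  if (!is.finite(L0) || L0 <= 0) stop("L0 must be positive")
  if (is.null(architecture_index))
    architecture_index <- architecture_index(pennation_deg, fiber_length_cm)
  if (!is.finite(architecture_index) ||
      architecture_index <= 0 || architecture_index > 1)
    stop("architecture_index must lie in (0, 1]")
  structure(list(name = name,
                 origin = as.numeric(origin),
                 origin_segment = origin_segment,
                 insertion = as.numeric(insertion),
                 insertion_segment = insertion_segment,
                 pennation_deg = pennation_deg,
                 L0 = L0,
                 fiber_length_cm = fiber_length_cm,
                 architecture_index = architecture_index),
            class = "muscle_path")
}

#' @export
print.muscle_path <- function(x, ...) {
  cat(sprintf("Muscle path '%s': %s -> %s\n", x$name,
              x$origin_segment, x$insertion_segment))
  cat(sprintf("  pennation %.1f deg, L0 %.1f mm, architecture index %.3f\n",
              x$pennation_deg, x$L0, x$architecture_index))
  invisible(x)
}

#' Instantaneous muscle-tendon length
#'
#' Maps the origin and insertion into the lab frame through their segments'
#' poses and returns the straight-line (Euclidean) distance between them.
#'
#' @param path A [muscle_path()].
#' @param poses Named list of `frame_transform`s (segment kinematic frame ->
#'   lab), one per segment; must contain both attachment segments.
#' @return Muscle-tendon length (same unit as the attachment coordinates).
#' @export
muscle_tendon_length <- function(path, poses) {
  for (seg in c(path$origin_segment, path$insertion_segment))
    if (is.null(poses[[seg]]))
      stop("no pose available for segment: ", seg)
  o <- transform_point(path$origin, poses[[path$origin_segment]])
  i <- transform_point(path$insertion, poses[[path$insertion_segment]])
  sqrt(sum((o - i)^2))
}

# Poses of every segment at time index k of a trial, as a named list of
# plain 4x4 row-convention matrices (cheap; validation skipped on purpose).
.poses_at <- function(trial, k) {
  lapply(trial$poses, function(arr) arr[, , k])
}

#' Normalized muscle-length time series over the gait cycle
#'
#' Computes the muscle-tendon length at every sample of a gait trial,
#' resamples it onto the 101-point gait-cycle grid (0-100%, foot strike to
#' foot strike, multiple cycles averaged), and divides by the optimal
#' length.
#'
#' @param path A [muscle_path()].
#' @param trial A `gait_trial` (see [generate_gait_trial()]).
#' @param L0 Optimal length used for normalization; defaults to `path$L0`.
#' @param side Which leg's events and segment poses to use (`"right"` or
#'   `"left"`); side-suffixed segment names (`femur_r`, ...) are resolved
#'   from the path's generic segment names.
#' @return Numeric vector of length 101: L/L0 at 0, 1, ..., 100% cycle.
#' @export
length_timeseries <- function(path, trial, L0 = path$L0,
                              side = c("right", "left")) {
  side <- match.arg(side)
  if (!is.finite(L0) || L0 <= 0) stop("L0 must be positive")
  sided <- .sided_path(path, side, names(trial$poses))
  nT <- length(trial$time)
  len <- vapply(seq_len(nT), function(k)
    muscle_tendon_length(sided, .poses_at(trial, k)), numeric(1))
  events <- if (side == "right") trial$events_right else trial$events_left
  resample_to_cycle(trial$time, len, events) / L0
}

# Resolve generic segment names (pelvis/femur/tibia/foot) to the trial's
# side-specific pose names. Attachment coordinates are authored for the
# right side; the left side mirrors them across the sagittal plane
# (z -> -z, z pointing right in every segment frame).
.sided_path <- function(path, side, available) {
  suf <- if (side == "right") "_r" else "_l"
  fix <- function(seg) {
    if (seg %in% available) return(seg)
    cand <- paste0(seg, suf)
    if (cand %in% available) return(cand)
    seg
  }
  path$origin_segment <- fix(path$origin_segment)
  path$insertion_segment <- fix(path$insertion_segment)
  if (side == "left") {
    path$origin[3] <- -path$origin[3]
    path$insertion[3] <- -path$insertion[3]
  }
  path
}
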