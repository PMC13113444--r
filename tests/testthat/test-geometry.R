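test_that("frame transforms follow the row-vector convention", {
  id <- frame_transform()
  expect_equal(transform_point(c(1, 2, 3), id), c(1, 2, 3))
  # rotation + translation built from the column convention
  expect_error(frame_transform(diag(c(1, 1, -1)), c(0, 0, 0)),
               "determinant")   # reflection, det -1
  th <- 0.3
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  tr <- frame_transform(Rz, c(1, 2, 3))
  p <- c(0.5, -0.2, 0.7)
  expect_equal(transform_point(p, tr), drop(Rz %*% p) + c(1, 2, 3),
               tolerance = 1e-12)
  # matrix input maps row-wise
  P <- rbind(c(0, 0, 0), p)
  expect_equal(transform_point(P, tr)[1, ], c(1, 2, 3))
})

test_that("inversion and composition behave like rigid transforms", {
  set.seed(42)
  for (i in 1:5) {
    A <- frame_transform(random_rotation(), stats::rnorm(3))
    B <- frame_transform(random_rotation(), stats::rnorm(3))
    p <- stats::rnorm(3)
    # round trip through the inverse
    expect_equal(transform_point(transform_point(p, A), invert_transform(A)),
                 p, tolerance = 1e-9)
    # composition equals sequential application
    expect_equal(transform_point(p, compose_transforms(A, B)),
                 transform_point(transform_point(p, A), B),
                 tolerance = 1e-12)
  }
})

test_that("pelvic frames are built from the ASIS and pubic landmarks", {
  # symmetric pelvis: ASIS at +/-120 on the lateral axis, pubis below/ahead
  lm <- list(P1a = c(0, 0, 120), P2a = c(0, -80, 0), P4a = c(0, 0, -120))
  fr <- build_pelvic_frames(lm)
  pk <- transform_parts(fr$kinematic)
  expect_equal(pk$rotation, diag(3), tolerance = 1e-12)
  expect_equal(pk$translation, c(0, 0, 0))
  pa <- transform_parts(fr$anatomical)
  expect_equal(pa$rotation, diag(3), tolerance = 1e-12)  # y up, z right
  expect_equal(pa$translation, c(0, -80, 0))             # origin at pubis
  # orthonormality of both rotation blocks
  for (f in fr) {
    R <- transform_parts(f)$rotation
    expect_equal(crossprod(R), diag(3), tolerance = 1e-9)
    expect_equal(det(R), 1, tolerance = 1e-9)
  }
})

test_that("pelvic frame construction matches explicit cross products", {
  lm <- list(P1a = c(10, 5, 130), P2a = c(35, -75, 4), P4a = c(-6, 9, -110))
  fr <- build_pelvic_frames(lm)
  P3 <- (lm$P1a + lm$P4a) / 2
  y <- (P3 - lm$P2a); y <- y / sqrt(sum(y^2))
  zd <- lm$P1a - lm$P4a
  x <- c(y[2] * zd[3] - y[3] * zd[2], y[3] * zd[1] - y[1] * zd[3],
         y[1] * zd[2] - y[2] * zd[1])
  x <- x / sqrt(sum(x^2))
  z <- c(x[2] * y[3] - x[3] * y[2], x[3] * y[1] - x[1] * y[3],
         x[1] * y[2] - x[2] * y[1])
  pa <- transform_parts(fr$anatomical)
  expect_equal(pa$rotation, cbind(x, y, z), tolerance = 1e-12,
               ignore_attr = TRUE)
  # anterior axis points forward, superior axis upward
  expect_gt(pa$rotation[1, 1], 0)
  expect_gt(pa$rotation[2, 2], 0)
  expect_error(build_pelvic_frames(list(P1a = c(0, 0, 1), P2a = c(0, 0, 0),
                                        P4a = c(0, 0, -1))), "degenerate")
})

test_that("the printed pelvic transition matrix is consistent", {
  Tp <- printed_pelvic_matrix()
  R <- Tp[1:3, 1:3]
  # orthonormal with unit determinant within transcription tolerance
  expect_lt(max(abs(crossprod(R) - diag(3))), 2e-3)
  expect_lt(abs(det(R) - 1), 2e-3)
  expect_equal(0.9133^2 + 0.4072^2, 1, tolerance = 1e-3)
  # the anatomical origin maps to the printed translation row
  ft <- frame_transform(row_matrix = Tp, tol = 1e-3)
  expect_equal(transform_point(c(0, 0, 0), ft), c(-0.0646, -0.0526, 0))
  # round trip through the inverse, limited by the transcription precision
  # of the printed rotation block (orthonormal only to ~1e-4)
  p <- c(0.2, -0.1, 0.05)
  expect_equal(transform_point(transform_point(p, ft), invert_transform(ft)),
               p, tolerance = 1e-3)
})

test_that("rigid Procrustes fit recovers planted transforms exactly", {
  # identical point sets give the identity with zero residual
  P <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0.3, 0.2, 0.9))
  fit <- estimate_transition_matrix(P, P)
  expect_equal(unclass(fit), diag(4), tolerance = 1e-12, ignore_attr = TRUE)
  expect_lt(attr(fit, "residual_rms"), 1e-12)
  set.seed(7)
  for (n in c(3, 4, 10, 40)) {
    A <- matrix(stats::rnorm(3 * n, sd = 50), n, 3)
    R <- random_rotation(); tr <- stats::rnorm(3, sd = 100)
    B <- sweep(A %*% t(R), 2, tr, `+`)
    fit <- estimate_transition_matrix(A, B)
    M <- rbind(cbind(t(R), 0), c(tr, 1))
    expect_lt(max(abs(unclass(fit) - M)), 1e-9)
    expect_lt(attr(fit, "residual_rms"), 1e-9)
  }
  expect_error(estimate_transition_matrix(P[1:2, ], P[1:2, ]), "3")
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(estimate_transition_matrix(line, line), "collinear")
})

test_that("Procrustes fit agrees with an independent implementation", {
  set.seed(11)
  A <- matrix(stats::rnorm(30, sd = 10), 10, 3)
  B <- sweep(A %*% t(random_rotation()), 2, c(5, -2, 1), `+`) +
    matrix(stats::rnorm(30, sd = 0.1), 10, 3)   # small noise
  fit <- estimate_transition_matrix(A, B)
  ours <- transform_point(A, fit)
  ref <- vegan::procrustes(B, A, scale = FALSE, symmetric = FALSE)
  # translation conventions differ; compare the centered configurations
  expect_equal(sweep(ours, 2, colMeans(ours)),
               sweep(unclass(ref$Yrot), 2, colMeans(ref$Yrot)),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("muscle-tendon length is a straight-line distance under poses", {
  id <- frame_transform()
  path <- muscle_path("toy", c(0, 0, 0), "A", c(3, 4, 0), "B",
                      pennation_deg = 0, L0 = 5)
  poses <- list(A = id, B = id)
  expect_equal(muscle_tendon_length(path, poses), 5)
  expect_error(muscle_tendon_length(path, list(A = id)), "B")
  # homogeneity: scaling attachments and translations scales the length
  s <- 2.5
  path2 <- path; path2$origin <- s * path$origin
  path2$insertion <- s * path$insertion
  expect_equal(muscle_tendon_length(path2, poses), s * 5)
  # invariance under a common rigid transform of all poses
  set.seed(3)
  G <- frame_transform(random_rotation(), stats::rnorm(3, sd = 10))
  A1 <- frame_transform(random_rotation(), stats::rnorm(3))
  B1 <- frame_transform(random_rotation(), stats::rnorm(3))
  l1 <- muscle_tendon_length(path, list(A = A1, B = B1))
  l2 <- muscle_tendon_length(path, list(A = compose_transforms(A1, G),
                                        B = compose_transforms(B1, G)))
  expect_equal(l1, l2, tolerance = 1e-9)
})

test_that("length time series lives on the 101-point grid", {
  trial <- generate_gait_trial("slow")
  m <- generic_body_model()$muscles$Iliacus
  ln <- length_timeseries(m, trial)
  expect_length(ln, 101)
  expect_true(all(ln > 0))
  expect_error(length_timeseries(m, trial, L0 = 0), "positive")
  # a hip-flexion sweep produces a continuous length curve
  expect_lt(max(abs(diff(ln))), 0.05)
})
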