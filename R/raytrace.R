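# Paraxial ABCD ray tracing of the folded, polarization-split
# remote-focusing detection path.
#
# Conventions: a ray is the column vector [n*alpha, y]^T (reduced angle =
# refractive index times paraxial angle, transverse height in mm), and an
# element acts by left multiplication.  Fold mirrors (PBS, remote mirror)
# are unfolded for the matrix algebra -- a fold rotates the working optical
# axis but leaves (n*alpha, y) unchanged -- so every trace runs along a
# single unrolled axial coordinate; fold elements only book-keep the axis
# rotation for plotting.

#' Create a paraxial ray
#'
#' @param reduced_angle Refractive-index-weighted angle `n * alpha` (radians).
#' @param height Transverse position y (mm).
#' @return An object of class `paraxial_ray`.
#' @export
paraxial_ray <- function(reduced_angle, height) {
  if (!is.finite(reduced_angle) || !is.finite(height))
    stop("ray coordinates must be finite")
  structure(list(reduced_angle = reduced_angle, height = height),
            class = "paraxial_ray")
}

new_abcd <- function(kind, matrix, ...) {
  structure(c(list(kind = kind, matrix = matrix), list(...)),
            class = "abcd_element")
}

#' Translation (free propagation) ABCD element
#'
#' Matrix `[[1, 0], [d/n, 1]]` acting on `[n alpha, y]^T`: propagation over a
#' gap `d` in a medium of index `n`.
#'
#' @param d Gap length (mm); may be negative for virtual back-propagation.
#' @param n Refractive index of the medium (> 0).
#' @return An `abcd_element`.
#' @export
make_translation <- function(d, n = 1) {
  if (!is.finite(n) || n <= 0) stop("refractive index must be positive")
  if (!is.finite(d)) stop("gap length must be finite")
  new_abcd("translation", rbind(c(1, 0), c(d / n, 1)), d = d, n = n)
}

#' Thin-lens ABCD element
#'
#' Matrix `[[1, -n/f], [0, 1]]`: a thin lens of focal length `f` in a medium
#' of index `n` (the reduced-angle convention keeps the power as `n/f`).
#'
#' @param f Focal length (mm), nonzero.
#' @param n Refractive index of the surrounding medium.
#' @return An `abcd_element`.
#' @export
make_thin_lens <- function(f, n = 1) {
  if (!is.finite(f) || f == 0) stop("focal length must be nonzero")
  if (!is.finite(n) || n <= 0) stop("refractive index must be positive")
  new_abcd("thin_lens", rbind(c(1, -n / f), c(0, 1)), f = f, n = n)
}

#' Fold (axis rotation) element
#'
#' A fold mirror or beam-splitter reflection rotates the working optical
#' axis; in the unfolded paraxial algebra it is the identity on
#' `[n alpha, y]^T` and only records the rotation for geometry/plotting.
#'
#' @param angle_deg Rotation of the optical axis (degrees).
#' @return An `abcd_element` of kind `"fold"`.
#' @export
make_fold <- function(angle_deg) {
  if (!is.finite(angle_deg)) stop("fold angle must be finite")
  new_abcd("fold", diag(2), fold_angle = angle_deg)
}

#' Propagate a ray through a sequence of ABCD elements
#'
#' Applies the elements in order by left multiplication
#' (`v' = M_k ... M_1 v`).  An empty element list returns the ray unchanged.
#'
#' @param ray A [paraxial_ray].
#' @param elements List of `abcd_element`s, in propagation order.
#' @return The propagated [paraxial_ray].
#' @export
propagate_ray <- function(ray, elements) {
  stopifnot(inherits(ray, "paraxial_ray"))
  v <- c(ray$reduced_angle, ray$height)
  for (el in elements) v <- el$matrix %*% v
  paraxial_ray(v[1], v[2])
}

#' Composed system matrix of an element sequence
#'
#' @param elements List of `abcd_element`s in propagation order.
#' @return The 2x2 composed matrix `M_k ... M_1`.
#' @export
system_matrix <- function(elements) {
  m <- diag(2)
  for (el in elements) m <- el$matrix %*% m
  m
}

#' Image plane of a composed system
#'
#' For a system matrix `S` taken from an object plane, the image forms after
#' a further translation `t` in the exit medium where the height becomes
#' independent of the launch angle: `S[2,1] + (t/n) S[1,1] = 0`.  The
#' lateral magnification there is `1/S[1,1]` (unimodularity).
#'
#' @param sysmat 2x2 system matrix from the object plane.
#' @param n_out Refractive index of the exit medium.
#' @return List with `distance` (mm, possibly negative for a virtual image,
#'   `Inf` if afocal) and `magnification`.
#' @export
image_plane <- function(sysmat, n_out = 1) {
  a <- sysmat[1, 1]
  c_ <- sysmat[2, 1]
  if (abs(a) < 1e-14)
    return(list(distance = Inf, magnification = NA_real_))
  list(distance = -n_out * c_ / a, magnification = 1 / a)
}

#' Effective focal length of an immersion objective
#'
#' `f_obj = f_tube * n / M_obj`: the focal length implied by the designed
#' tube-lens focal length, the objective magnification, and the immersion
#' index.
#'
#' @param f_tube Designed tube-lens focal length (mm, > 0).
#' @param m_obj Objective magnification (> 0).
#' @param n Immersion refractive index (> 0).
#' @return Effective focal length (mm).
#' @examples
#' effective_focal_length(200, 40, 1.33) # water-immersion 40x -> 6.65 mm
#' @export
effective_focal_length <- function(f_tube, m_obj, n = 1) {
  if (any(!is.finite(c(f_tube, m_obj, n))) || f_tube <= 0 || m_obj <= 0 || n <= 0)
    stop("all inputs to effective_focal_length must be positive")
  f_tube * n / m_obj
}

#' Detection-path model of the remote-focusing microscope
#'
#' Assembles the folded detection train: water-immersion detection objective
#' (Obj1), tube lens L4, relay lens L5, polarizing beam splitter (fold),
#' remote air objective Obj2, remote mirror (the axial-scan element, modeled
#' as a variable doubled gap between two copies of Obj2), return fold at the
#' PBS, and camera lens L6.  Gaps not supplied default to their 4f-nominal
#' values (sum of adjacent focal lengths).
#'
#' @param f_tube_design Designed tube-lens focal length of Obj1 (mm).
#' @param m_obj Magnification of Obj1.
#' @param n_water Immersion index of Obj1 (applies up to and including the
#'   objective; air afterwards).
#' @param f_l4,f_l5,f_l6 Focal lengths of the tube, relay and camera lenses (mm).
#' @param f_obj2 Effective focal length of the remote objective (mm).
#' @param theta Launch angle between the S and P chief rays at Obj2 (degrees).
#' @param s1 Object distance in front of Obj1 (mm); default its focal length.
#' @param d1 Obj1-to-L4 gap (mm); default 4f-nominal.
#' @param gap_l4_l5,gap_l5_obj2,gap_obj2_l6 Remaining gaps (mm); default
#'   4f-nominal.
#' @param gap_pbs_obj2 PBS-to-Obj2 distance (mm), only used to place the fold
#'   inside `gap_l5_obj2`; default half that gap.
#' @param na_obj1,na_obj2 Numerical apertures (pupil sampling, apertures).
#' @param pupil_matched If `TRUE`, override `f_l5` with the perfect-imaging
#'   (pupil-matched) value `m_obj * f_obj2 / n_water`, which makes the
#'   remote-space lateral magnification exactly `n_water / n_air`.
#' @return An object of class `detection_path_model`.
#' @export
detection_model <- function(f_tube_design = 200, m_obj = 40, n_water = 1.33,
                            f_l4 = 200, f_l5 = 300, f_obj2 = 10, f_l6 = 300,
                            theta = 8,
                            s1 = NULL, d1 = NULL,
                            gap_l4_l5 = NULL, gap_l5_obj2 = NULL,
                            gap_obj2_l6 = NULL, gap_pbs_obj2 = NULL,
                            na_obj1 = 0.8, na_obj2 = 0.75,
                            pupil_matched = FALSE) {
  f_obj <- effective_focal_length(f_tube_design, m_obj, n_water)
  if (pupil_matched) f_l5 <- m_obj * f_obj2 / n_water
  estimated <- character(0)
  if (is.null(s1)) s1 <- f_obj
  if (is.null(d1)) { d1 <- f_obj + f_l4; estimated <- c(estimated, "d1") }
  if (is.null(gap_l4_l5)) { gap_l4_l5 <- f_l4 + f_l5; estimated <- c(estimated, "gap_l4_l5") }
  if (is.null(gap_l5_obj2)) { gap_l5_obj2 <- f_l5 + f_obj2; estimated <- c(estimated, "gap_l5_obj2") }
  if (is.null(gap_obj2_l6)) { gap_obj2_l6 <- f_obj2 + f_l6; estimated <- c(estimated, "gap_obj2_l6") }
  if (is.null(gap_pbs_obj2)) gap_pbs_obj2 <- gap_l5_obj2 / 2
  gaps <- c(s1 = s1, d1 = d1, gap_l4_l5 = gap_l4_l5,
            gap_l5_obj2 = gap_l5_obj2, gap_obj2_l6 = gap_obj2_l6)
  if (any(!is.finite(gaps)) || any(gaps[-1] < 0))
    stop("inconsistent gap configuration")
  if (gap_pbs_obj2 > gap_l5_obj2)
    stop("inconsistent gap configuration: PBS beyond Obj2")
  structure(list(
    f_tube_design = f_tube_design, m_obj = m_obj, n_water = n_water,
    f_obj = f_obj, f_l4 = f_l4, f_l5 = f_l5, f_obj2 = f_obj2, f_l6 = f_l6,
    theta = theta, s1 = s1, d1 = d1,
    gap_l4_l5 = gap_l4_l5, gap_l5_obj2 = gap_l5_obj2,
    gap_obj2_l6 = gap_obj2_l6, gap_pbs_obj2 = gap_pbs_obj2,
    na_obj1 = na_obj1, na_obj2 = na_obj2,
    delta_l = delta_l(f_obj2, theta),
    estimated = estimated
  ), class = "detection_path_model")
}

#' Build a detection-path model from a configuration list or YAML file
#'
#' @param config Named list (or path to a YAML file) whose entries are
#'   arguments of [detection_model()].
#' @return A `detection_path_model`.
#' @export
build_detection_model <- function(config = list()) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    config <- yaml::read_yaml(config)
  }
  known <- names(formals(detection_model))
  bad <- setdiff(names(config), known)
  if (length(bad))
    stop("unknown configuration entries: ", paste(bad, collapse = ", "))
  do.call(detection_model, config)
}

#' As-built preset of the detection path
#'
#' The shipped geometry: tube lens ~100 mm from Obj1, remote objective
#' ~500 mm from the PBS (both breaking the 4f condition to keep the S/P
#' launch angle small), object plane at the measured S1 = 6.695 mm (45 um
#' beyond the designed focal plane), launch angle 8 degrees.  Gaps that were
#' only ever ruler-measured are marked `estimated` in the returned model.
#'
#' @param ... Overrides passed on to [detection_model()].
#' @return A `detection_path_model`.
#' @export
detection_model_preset <- function(...) {
  args <- list(s1 = 6.695, d1 = 100, gap_l5_obj2 = 510, gap_pbs_obj2 = 500,
               theta = 8)
  user <- list(...)
  args[names(user)] <- user
  m <- do.call(detection_model, args)
  m$estimated <- union(m$estimated, c("d1", "gap_l5_obj2", "gap_pbs_obj2"))
  m
}

#' S/P image separation at the remote mirror
#'
#' `delta_L = f_obj2 * theta` (theta in radians): the lateral distance
#' between the two polarization images formed at the remote mirror.
#'
#' @param f_obj2 Remote-objective focal length (mm).
#' @param theta_deg Launch angle (degrees).
#' @return Separation (mm).
#' @export
delta_l <- function(f_obj2, theta_deg) {
  if (f_obj2 <= 0) stop("f_obj2 must be positive")
  f_obj2 * theta_deg * pi / 180
}

# Element list of the full unfolded path for a given mirror gap (mm,
# distance from Obj2 to the remote mirror; the doubled segment models the
# forward and backward passes).  `through` selects how far to build.
model_elements <- function(model, mirror_gap,
                           through = c("camera", "second_obj2", "first_obj2")) {
  through <- match.arg(through)
  els <- list(
    make_translation(model$s1, model$n_water),
    make_thin_lens(model$f_obj, model$n_water),
    make_translation(model$d1, 1),
    make_thin_lens(model$f_l4),
    make_translation(model$gap_l4_l5),
    make_thin_lens(model$f_l5),
    make_translation(model$gap_l5_obj2 - model$gap_pbs_obj2),
    make_fold(45),
    make_translation(model$gap_pbs_obj2),
    make_thin_lens(model$f_obj2)
  )
  if (through == "first_obj2") return(els)
  els <- c(els, list(
    make_translation(2 * mirror_gap),   # to the mirror and back (unfolded)
    make_thin_lens(model$f_obj2)
  ))
  if (through == "second_obj2") return(els)
  c(els, list(
    make_translation(model$gap_pbs_obj2),
    make_fold(-45),
    make_translation(model$gap_obj2_l6 - model$gap_pbs_obj2),
    make_thin_lens(model$f_l6)
  ))
}

# In-focus mirror gap: the image distance after the first pass through Obj2.
infocus_mirror_gap <- function(model) {
  ip <- image_plane(system_matrix(model_elements(model, 0, "first_obj2")))
  if (!is.finite(ip$distance))
    stop("remote image is at infinity; cannot place the mirror")
  ip$distance
}

#' Trace the field through the full detection path
#'
#' Traces 3 field points (FOV edges and axis) x 3 pupil rays (pupil edges
#' and center) through the unfolded path, with the remote mirror at the
#' in-focus position unless given.  Reports the remote-space image (at the
#' mirror) and the final image after the camera lens, with lateral
#' magnifications from the composed matrices; per-ray polylines are sampled
#' at every element boundary along the unrolled axis.
#'
#' @param model A `detection_path_model`.
#' @param field_half_width Field half-width at the object (um).
#' @param mirror_gap Obj2-to-mirror distance (mm); default in-focus.
#' @return List of class `raytrace_result`: `rays` (data frame of polylines),
#'   `remote_image`, `camera_image` (each distance mm + magnification),
#'   `s3` (second-Obj2-to-image distance, mm), `converged`.
#' @export
trace_field <- function(model, field_half_width = 50, mirror_gap = NULL) {
  stopifnot(inherits(model, "detection_path_model"))
  if (is.null(mirror_gap)) mirror_gap <- infocus_mirror_gap(model)

  m_first <- system_matrix(model_elements(model, mirror_gap, "first_obj2"))
  remote <- image_plane(m_first)
  m_second <- system_matrix(model_elements(model, mirror_gap, "second_obj2"))
  s3 <- image_plane(m_second)$distance
  els <- model_elements(model, mirror_gap, "camera")
  m_full <- system_matrix(els)
  camera <- image_plane(m_full)

  h <- field_half_width / 1000          # um -> mm
  alpha_max <- model$na_obj1 / model$n_water
  fields <- c(-h, 0, h)
  pupil <- c(-1, 0, 1)
  rays <- list()
  for (i in seq_along(fields)) {
    for (j in seq_along(pupil)) {
      ray <- paraxial_ray(model$n_water * alpha_max * pupil[j], fields[i])
      # sample the polyline: position along the unrolled axis at element
      # boundaries, with fold rotations book-kept
      z <- 0; axis_angle <- 0
      v <- c(ray$reduced_angle, ray$height)
      pts <- data.frame(z = z, height = v[2], axis_angle = axis_angle)
      for (el in els) {
        if (el$kind == "translation") z <- z + el$d
        if (el$kind == "fold") axis_angle <- axis_angle + el$fold_angle
        v <- el$matrix %*% v
        pts <- rbind(pts, data.frame(z = z, height = v[2],
                                     axis_angle = axis_angle))
      }
      pts$field_point <- c("edge_neg", "axis", "edge_pos")[i]
      pts$pupil_ray <- c("edge_neg", "center", "edge_pos")[j]
      rays[[length(rays) + 1L]] <- pts
    }
  }
  rays <- do.call(rbind, rays)

  # convergence: rays from one field point must cross at the reported image
  converged <- TRUE
  if (is.finite(camera$distance)) {
    tail_m <- make_translation(camera$distance)$matrix %*% m_full
    hts <- vapply(pupil, function(p) {
      v <- tail_m %*% c(model$n_water * alpha_max * p, h)
      v[2]
    }, numeric(1))
    converged <- diff(range(hts)) < 1e-9
  } else converged <- FALSE

  structure(list(rays = rays, remote_image = remote, camera_image = camera,
                 s3 = s3, mirror_gap = mirror_gap, converged = converged),
            class = "raytrace_result")
}

# Solve the mirror gap that keeps the final image at a fixed distance
# `t_ref` after the camera lens (the LFA surrogate: the camera never moves).
# A and C of the full matrix are affine in the gap, so the solution is
# closed-form.
solve_mirror_gap <- function(model, s1, t_ref) {
  m <- model
  m$s1 <- s1
  f_at <- function(z) system_matrix(model_elements(m, z, "camera"))
  m0 <- f_at(0); m1 <- f_at(1)
  a0 <- m0[1, 1]; a1 <- m1[1, 1] - a0
  c0 <- m0[2, 1]; c1 <- m1[2, 1] - c0
  den <- c1 + t_ref * a1
  if (abs(den) < 1e-14) stop("degenerate refocus geometry")
  z <- -(c0 + t_ref * a0) / den
  list(mirror_gap = z, sysmat = f_at(z))
}

#' Lateral magnification versus axial scan position
#'
#' For each object offset the remote mirror is repositioned so the final
#' image stays on the fixed camera plane (the software surrogate of the
#' linear focus actuator, which holds S3 constant), and the lateral
#' magnification is reported referred to remote image space (camera
#' magnification divided by the fixed Obj2-to-L6 relay factor `f_l6/f_obj2`),
#' the scale on which perfect pupil-matched imaging gives
#' `n_water / n_air`.
#'
#' @param model A `detection_path_model`.
#' @param object_offsets Object-plane offsets along the scan axis (um).
#' @param max_offset Largest allowed |offset| (um); outside -> error.
#' @return Data frame with `offset_um`, `mirror_gap_mm`, `magnification`.
#' @export
magnification_vs_scan <- function(model, object_offsets, max_offset = 50) {
  stopifnot(inherits(model, "detection_path_model"))
  if (any(abs(object_offsets) > max_offset))
    stop("object offset outside the modeled range (|offset| > ",
         max_offset, " um)")
  # reference: in-focus configuration at offset 0
  gap0 <- infocus_mirror_gap(model)
  m_full0 <- system_matrix(model_elements(model, gap0, "camera"))
  t_ref <- image_plane(m_full0)$distance
  if (!is.finite(t_ref)) stop("reference configuration is afocal at the camera")
  relay <- model$f_l6 / model$f_obj2
  out <- lapply(object_offsets, function(off) {
    sol <- solve_mirror_gap(model, model$s1 + off / 1000, t_ref)
    mag <- abs(image_plane(sol$sysmat)$magnification) / relay
    data.frame(offset_um = off, mirror_gap_mm = sol$mirror_gap,
               magnification = mag)
  })
  do.call(rbind, out)
}

# Area of intersection of two discs (radii r1, r2, center distance d).
circle_overlap_area <- function(r1, r2, d) {
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(pi * min(r1, r2)^2)
  a1 <- r1^2 * acos((d^2 + r1^2 - r2^2) / (2 * d * r1))
  a2 <- r2^2 * acos((d^2 + r2^2 - r1^2) / (2 * d * r2))
  tri <- 0.5 * sqrt(pmax(0, (-d + r1 + r2) * (d + r1 - r2) *
                           (d - r1 + r2) * (d + r1 + r2)))
  a1 + a2 - tri
}

#' Geometric collection efficiency of the remote objective
#'
#' Fraction of the ray bundle that re-enters the remote objective's aperture
#' after reflecting from the (defocused) remote mirror, for an image point
#' formed off-axis (the S/P images sit at `+-delta_L/2`).  The converging
#' bundle fills the aperture disc; unfolding the flat mirror displaced by
#' `defocus` from the focal plane maps that disc onto a scaled, shifted disc
#' at the aperture plane, and the efficiency is the fractional disc overlap
#' (closed form).
#'
#' @param model A `detection_path_model`.
#' @param defocus Mirror displacement from the remote focal plane (um;
#'   positive = away from the objective).
#' @param field_offset Lateral offset of the image point (um), e.g.
#'   `delta_L/2`.
#' @param aperture_radius Clipping aperture radius (mm); default
#'   `f_obj2 * na_obj2`.
#' @return Fraction in `[0, 1]`.
#' @export
collection_efficiency <- function(model, defocus, field_offset,
                                  aperture_radius = NULL) {
  stopifnot(inherits(model, "detection_path_model"))
  if (is.null(aperture_radius))
    aperture_radius <- model$f_obj2 * model$na_obj2
  if (aperture_radius < 0) stop("aperture radius must be non-negative")
  if (aperture_radius == 0) return(0)
  f <- model$f_obj2
  d <- defocus / 1000       # um -> mm
  x <- field_offset / 1000
  s <- 1 + 2 * d / f        # scale of the returning footprint
  if (s <= 0) stop("defocus beyond the geometric model's validity (|2d| >= f)")
  r <- aperture_radius
  # accepted launch points: |(u,v) - c| <= r/s with c = 2(1+d/f)x/s along x
  centre_dist <- abs(2 * (1 + d / f) * x / s)
  circle_overlap_area(r, r / s, centre_dist) / (pi * r^2)
}

#' Choose the S/P launch angle
#'
#' Grid search over theta: the traced forward and backward beam footprints
#' at the remote pupil grow monotonically with theta (each chief ray walks
#' off-axis by the PBS-to-Obj2 lever arm), so minimizing the footprint
#' subject to a minimum S/P image separation at the mirror selects the
#' smallest feasible angle.
#'
#' @param model A `detection_path_model`.
#' @param min_separation Minimum required `delta_L` at the mirror (mm).
#' @param theta_max Largest angle searched (degrees).
#' @param step Grid step (degrees).
#' @return List with `theta` (degrees), `delta_l` (mm) and `footprint` (mm,
#'   pupil-edge excursion of the launched chief ray at Obj2).
#' @export
choose_theta <- function(model, min_separation = 0.5, theta_max = 20,
                         step = 0.1) {
  grid <- seq(step, theta_max, by = step)
  dl <- delta_l(model$f_obj2, grid)
  feasible <- dl >= min_separation
  if (!any(feasible)) stop("no feasible launch angle on the grid")
  theta <- grid[which(feasible)[1]]
  lever <- model$gap_pbs_obj2
  footprint <- model$f_obj2 * model$na_obj2 + lever * theta * pi / 180
  list(theta = theta, delta_l = delta_l(model$f_obj2, theta),
       footprint = footprint)
}

#' Calibrate the tube-lens gap d1 against measured magnifications
#'
#' Scalar least squares: finds the `d1` whose traced relative magnification
#' curve (normalized at offset 0) best matches measured relative
#' magnifications.
#'
#' @param model A `detection_path_model` (starting geometry).
#' @param measured Data frame with `offset_um` and `relative_magnification`.
#' @param interval Search interval for d1 (mm).
#' @return The fitted model (with calibrated `d1`) and the attained RSS, as
#'   a list.
#' @export
calibrate_d1 <- function(model, measured, interval = c(10, 400)) {
  stopifnot(all(c("offset_um", "relative_magnification") %in% names(measured)))
  obj <- function(d1) {
    m <- model; m$d1 <- d1
    cur <- magnification_vs_scan(m, c(0, measured$offset_um),
                                 max_offset = max(abs(measured$offset_um), 1))
    rel <- cur$magnification[-1] / cur$magnification[1]
    sum((rel - measured$relative_magnification)^2)
  }
  opt <- stats::optimize(obj, interval = interval)
  fitted <- model; fitted$d1 <- opt$minimum
  list(model = fitted, d1 = opt$minimum, rss = opt$objective)
}

#' Calibrate the object distance S1 against an absolute magnification
#'
#' @param model A `detection_path_model`.
#' @param measured_magnification Absolute remote-space magnification at the
#'   scan center.
#' @param interval Search interval for S1 (mm).
#' @return List with the fitted model and `s1`.
#' @export
calibrate_s1 <- function(model, measured_magnification,
                         interval = NULL) {
  if (is.null(interval)) interval <- model$f_obj * c(0.95, 1.05)
  obj <- function(s1) {
    m <- model; m$s1 <- s1
    cur <- magnification_vs_scan(m, 0)
    (cur$magnification - measured_magnification)^2
  }
  opt <- stats::optimize(obj, interval = interval)
  fitted <- model; fitted$s1 <- opt$minimum
  list(model = fitted, s1 = opt$minimum, rss = opt$objective)
}

#' @export
print.detection_path_model <- function(x, ...) {
  cat("Detection-path model (pmRF, polarization-split)\n")
  cat(sprintf("  f_obj %.4g mm (f_tube %.4g / M %.4g, n %.3g)\n",
              x$f_obj, x$f_tube_design, x$m_obj, x$n_water))
  cat(sprintf("  f_L4 %.4g | f_L5 %.6g | f_obj2 %.4g | f_L6 %.4g mm\n",
              x$f_l4, x$f_l5, x$f_obj2, x$f_l6))
  cat(sprintf("  S1 %.4g mm, d1 %.4g mm, L4-L5 %.4g, L5-Obj2 %.4g, Obj2-L6 %.4g mm\n",
              x$s1, x$d1, x$gap_l4_l5, x$gap_l5_obj2, x$gap_obj2_l6))
  cat(sprintf("  theta %.3g deg -> delta_L %.4g mm", x$theta, x$delta_l))
  if (length(x$estimated))
    cat("  [estimated gaps: ", paste(x$estimated, collapse = ", "), "]", sep = "")
  cat("\n")
  invisible(x)
}
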