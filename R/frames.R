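## Base-pair reference frames and the mid-frame (CEHS/3DNA-style) helical
## parameter decomposition. Angles are degrees at every interface; radians
## appear only inside the rotation algebra. The decomposition here is exactly
## invertible: compose_step() reconstructs the successor frame from the six
## parameters, and step_params(compose_step(f, p)) == p to machine precision.

#' Construct a base(-pair) reference frame
#'
#' A frame is a rigid placement: an origin (Angstrom) and a right-handed
#' orthonormal 3x3 rotation whose columns are the x, y and z unit vectors.
#' For a base pair, x points into the major groove, y along the long bp axis
#' towards the Watson-strand backbone, and z along the local helix axis.
#'
#' @param origin Numeric length-3 origin, Angstrom.
#' @param axes 3x3 rotation matrix (columns = x, y, z axes).
#' @return An object of class `base_frame`.
#' @export
base_frame <- function(origin = c(0, 0, 0), axes = diag(3)) {
  origin <- as.numeric(origin)
  axes <- unname(as.matrix(axes))
  stopifnot(length(origin) == 3L, all(dim(axes) == c(3L, 3L)))
  f <- structure(list(origin = origin, axes = axes), class = "base_frame")
  validate_frame(f)
  f
}

#' @export
print.base_frame <- function(x, ...) {
  cat("<base_frame> origin:", sprintf("%.3f", x$origin), "\n")
  print(round(x$axes, 4))
  invisible(x)
}

validate_frame <- function(f, tol = 1e-10) {
  if (!inherits(f, "base_frame"))
    stop("expected a 'base_frame' object")
  err <- max(abs(crossprod(f$axes) - diag(3)))
  if (err > tol)
    stop(sprintf("frame axes are not orthonormal (max deviation %.3g)", err))
  if (abs(det(f$axes) - 1) > tol)
    stop("frame axes are not right-handed (det != +1)")
  invisible(f)
}

## Rodrigues rotation about a unit axis, angle in radians.
rot_axis <- function(axis, theta) {
  n <- axis / sqrt(sum(axis^2))
  ct <- cos(theta); st <- sin(theta)
  K <- matrix(c(0, n[3], -n[2], -n[3], 0, n[1], n[2], -n[1], 0), 3, 3)
  diag(3) * ct + st * K + (1 - ct) * tcrossprod(n)
}

rot_z <- function(theta) {
  ct <- cos(theta); st <- sin(theta)
  matrix(c(ct, st, 0, -st, ct, 0, 0, 0, 1), 3, 3)
}

## Signed angle (radians) from a to b about unit axis n (a, b orthogonal to
## nothing in particular; only their components normal to n matter).
signed_angle <- function(a, b, n) {
  atan2(sum(crossprod_vec(a, b) * n), sum(a * b))
}

crossprod_vec <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## Core symmetric mid-frame decomposition between two frames.
## Returns translations projected on the mid-frame axes and the
## (tilt, roll, twist)-style angles (degrees) about the mid-frame x, y, z.
decompose_frames <- function(f1, f2) {
  validate_frame(f1); validate_frame(f2)
  R1 <- f1$axes; R2 <- f2$axes
  z1 <- R1[, 3]; z2 <- R2[, 3]
  cr <- crossprod_vec(z1, z2)
  crn <- sqrt(sum(cr^2))
  gamma <- atan2(crn, sum(z1 * z2))
  if (crn < 1e-12) {
    hinge <- R1[, 1]  # arbitrary: no bend component
    gamma <- 0
    R1p <- R1; R2p <- R2
  } else {
    hinge <- cr / crn
    R1p <- rot_axis(hinge, gamma / 2) %*% R1
    R2p <- rot_axis(hinge, -gamma / 2) %*% R2
  }
  zm <- R1p[, 3]
  omega <- signed_angle(R1p[, 1], R2p[, 1], zm)
  xm <- rot_axis(zm, omega / 2) %*% R1p[, 1]
  Rm <- cbind(xm, crossprod_vec(zm, xm), zm)
  om <- (f1$origin + f2$origin) / 2
  if (gamma < 1e-12) {
    roll <- 0; tilt <- 0
  } else {
    phi <- signed_angle(Rm[, 2], hinge, zm)
    roll <- gamma * cos(phi)
    tilt <- -gamma * sin(phi)   # positive tilt = positive rotation about mid x
  }
  trans <- as.numeric(crossprod(Rm, f2$origin - f1$origin))
  list(mid = base_frame(om, Rm),
       trans = trans,
       angles = rad2deg(c(tilt, roll, omega)))
}

## Inverse of decompose_frames: place the successor frame.
compose_frames <- function(f1, trans, angles_deg) {
  validate_frame(f1)
  tilt <- deg2rad(angles_deg[1]); roll <- deg2rad(angles_deg[2])
  omega <- deg2rad(angles_deg[3])
  gamma <- sqrt(roll^2 + tilt^2)
  phi <- atan2(-tilt, roll)
  hb <- c(-sin(phi), cos(phi), 0)          # hinge in mid-frame body coords
  Rm <- f1$axes %*% rot_z(omega / 2) %*% rot_axis(hb, gamma / 2)
  R2 <- Rm %*% rot_axis(hb, gamma / 2) %*% rot_z(omega / 2)
  o2 <- f1$origin + as.numeric(Rm %*% trans)
  om <- (f1$origin + o2) / 2
  list(frame = base_frame(o2, R2), mid = base_frame(om, Rm))
}

#' Six inter-base-pair step parameters between consecutive bp frames
#'
#' Decomposes the rigid transformation from bp frame `frame1` to `frame2`
#' symmetrically about their mid-frame: shift/slide/rise are the projections
#' of the origin displacement on the mid-frame x/y/z axes (Angstrom), and
#' tilt/roll/twist the rotation components about those axes (degrees).
#'
#' @param frame1,frame2 Consecutive `base_frame` objects (5' to 3').
#' @return Named numeric vector `shift, slide, rise, tilt, roll, twist`.
#' @seealso [compose_step()] for the exact inverse.
#' @export
step_params <- function(frame1, frame2) {
  d <- decompose_frames(frame1, frame2)
  stats::setNames(c(d$trans, d$angles), STEP_PAR_NAMES)
}

#' Build the successor bp frame from step parameters
#'
#' Exact inverse of [step_params()]: `step_params(frame, compose_step(frame,
#' params))` returns `params` to machine precision.
#'
#' @param frame A `base_frame`.
#' @param params Numeric 6-vector in `shift, slide, rise, tilt, roll, twist`
#'   order (Angstrom / degrees), or a named vector with those names.
#' @return The successor `base_frame`.
#' @export
compose_step <- function(frame, params) {
  params <- as_param6(params, STEP_PAR_NAMES)
  stopifnot(all(is.finite(params)))
  compose_frames(frame, params[1:3], params[4:6])$frame
}

as_param6 <- function(params, nm) {
  p <- as.numeric(params)
  if (!is.null(names(params)) && all(nm %in% names(params)))
    p <- as.numeric(params[nm])
  if (length(p) != 6L) stop("expected a 6-vector of helical parameters")
  p
}

#' Base-pair frame and intra-base-pair parameters
#'
#' Combines a Watson and a Crick base frame into the bp mid-frame and the six
#' intra-bp parameters (shear, stretch, stagger in Angstrom; buckle,
#' propeller, opening in degrees). The Crick frame must already be flipped to
#' the common convention (180 degrees about its x axis, see [flip_frame()]);
#' the decomposition runs from the flipped Crick frame to the Watson frame.
#'
#' @param frame_w Watson-strand base frame.
#' @param frame_c Crick-strand base frame, flipped to the Watson convention.
#' @return List with `frame` (the bp `base_frame`) and `params` (named
#'   6-vector of intra-bp parameters).
#' @export
bp_frame_and_params <- function(frame_w, frame_c) {
  d <- decompose_frames(frame_c, frame_w)
  list(frame = d$mid,
       params = stats::setNames(c(d$trans, d$angles), INTRA_PAR_NAMES))
}

#' Flip a Crick-strand base frame to the Watson convention
#'
#' 180 degree rotation about the frame's own x axis (negates the y and z
#' axes), the standard anti-parallel strand correction.
#'
#' @param frame A `base_frame`.
#' @return The flipped `base_frame`.
#' @export
flip_frame <- function(frame) {
  validate_frame(frame)
  base_frame(frame$origin, frame$axes %*% diag(c(1, -1, -1)))
}

#' End-to-end twist of a fragment
#'
#' Sum of the per-step helical twists over a contiguous range of bp steps --
#' the collective variable controlled by the torsional restraint. Step `i`
#' joins bp `i` and `i + 1` (1-based).
#'
#' @param frames List of consecutive bp `base_frame`s, or a numeric vector /
#'   matrix of per-step twists (degrees); for a matrix, rows are frames and
#'   columns steps.
#' @param region Integer range of step indices (default: all steps).
#' @return Total twist in degrees (vector with one value per frame for
#'   matrix input).
#' @export
end_to_end_twist <- function(frames, region = NULL) {
  if (is.list(frames) && inherits(frames[[1]], "base_frame")) {
    n_steps <- length(frames) - 1L
    if (n_steps < 1L) stop("need at least two frames (one step)")
    tw <- vapply(seq_len(n_steps), function(i)
      step_params(frames[[i]], frames[[i + 1]])[["twist"]], numeric(1))
  } else if (is.matrix(frames)) {
    tw <- frames
    n_steps <- ncol(tw)
  } else {
    tw <- as.numeric(frames)
    n_steps <- length(tw)
  }
  if (is.null(region)) region <- seq_len(n_steps)
  region <- as.integer(region)
  if (length(region) == 0L) stop("empty step region")
  if (any(region < 1L | region > n_steps))
    stop("region outside the fragment's steps")
  if (is.matrix(tw)) rowSums(tw[, region, drop = FALSE]) else sum(tw[region])
}

#' Per-step axis bending profile
#'
#' Bending at step i is the angle between the local helix axes (frame z
#' axes) of bp i and bp i + 1, in degrees.
#'
#' @param frames List of bp `base_frame`s (>= 2).
#' @return Numeric vector of bend angles in `[0, 180]`, one per step, class
#'   `bend_profile`.
#' @export
axis_bending <- function(frames) {
  stopifnot(is.list(frames), length(frames) >= 2L)
  n <- length(frames) - 1L
  ang <- vapply(seq_len(n), function(i) {
    z1 <- frames[[i]]$axes[, 3]; z2 <- frames[[i + 1]]$axes[, 3]
    rad2deg(acos(max(-1, min(1, sum(z1 * z2)))))
  }, numeric(1))
  structure(ang, class = "bend_profile")
}
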