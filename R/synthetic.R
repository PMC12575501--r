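#' Synthetic abdominal aorta centerline
#'
#' Generates the aortic centerline of a synthetic patient. The aorta runs
#' predominantly along the cranio-caudal (z) axis from caudal (z = 0) to
#' cranial (z = length), with optional low-frequency in-plane tortuosity whose
#' phases are drawn from the seeded stream. With `tortuosity_amp_mm = 0` the
#' result is a straight vertical polyline of arc length exactly `length_mm`.
#'
#' @param length_mm axial extent of the aorta (mm), > 0.
#' @param radius_mm lumen radius of the aortic tube (mm), > 0.
#' @param tortuosity_amp_mm amplitude of the sinusoidal in-plane wander (mm);
#'   0 gives a straight vessel.
#' @param n_points number of centerline points (>= 10).
#' @param seed integer seed; identical arguments give bitwise-identical output.
#' @return a `centerline` with constant `radius`.
#' @export
generate_aorta_centerline <- function(length_mm, radius_mm,
                                      tortuosity_amp_mm = 0,
                                      n_points = 201, seed = 1) {
  if (!is.numeric(length_mm) || length_mm <= 0)
    stop("invalid config: `length_mm` must be > 0")
  if (!is.numeric(radius_mm) || radius_mm <= 0)
    stop("invalid config: `radius_mm` must be > 0")
  if (tortuosity_amp_mm < 0)
    stop("invalid config: `tortuosity_amp_mm` must be >= 0")
  if (n_points < 10L) stop("invalid config: `n_points` must be >= 10")
  rs <- .rng_stream(seed, 101L)
  z <- seq(0, length_mm, length.out = n_points)
  if (tortuosity_amp_mm > 0) {
    ph <- rs(2) * 2 * pi
    # one-and-a-half waves over the vessel: gentle, aorta-like wander
    x <- tortuosity_amp_mm * sin(2 * pi * 1.5 * z / length_mm + ph[1])
    y <- tortuosity_amp_mm * sin(2 * pi * 1.0 * z / length_mm + ph[2])
  } else {
    x <- y <- rep(0, n_points)
  }
  centerline(cbind(x, y, z), radius = radius_mm)
}

#' Synthetic renal branch centerline
#'
#' Grows a renal-artery centerline off the aorta at a prescribed branching
#' angle. The branch origin lies exactly on the aortic tube surface; the
#' initial direction makes `branching_angle_deg` with the local aortic tangent
#' (90 deg = perpendicular take-off). The branch is a circular arc of constant
#' curvature bending towards the anterior (+y) direction, optionally decorated
#' with a small seeded sinusoidal out-of-plane perturbation; a zero curvature
#' profile gives a straight branch whose measured branching angle recovers the
#' generator parameter to well under a degree.
#'
#' @param aorta aortic `centerline` (its `radius` attribute supplies the tube
#'   radius at the ostium).
#' @param side `"left"` (branch towards +x) or `"right"` (towards -x).
#' @param branching_angle_deg take-off angle from the aortic tangent, in
#'   (10, 170) degrees.
#' @param length_mm branch arc length (mm), between 20 and 80.
#' @param radius_mm branch lumen radius (mm), between 2.5 and 3.5 so the diameter is
#'   within the 5-7 mm renal lumen range.
#' @param curvature_profile either a single curvature in 1/mm (0 = straight)
#'   or a list with elements `kappa` (1/mm), `wobble_amp_mm`,
#'   `wobble_period_mm` for the out-of-plane perturbation.
#' @param bend_direction direction (in the patient frame, before projection
#'   perpendicular to the take-off) towards which the arc bends. The default,
#'   anterior, curves the vessel towards the kidney parenchyma while keeping
#'   the branch plane near-horizontal, so that cranio-caudal respiratory
#'   motion of the distal end loads the vessel transversely (in bending), the
#'   regime the breathing analysis assumes.
#' @param seed integer seed.
#' @param ostium_frac where along the aorta the ostium sits (fraction of
#'   points, default 0.5 = mid-aorta).
#' @param spacing_mm sampling step along the branch (default 1 mm).
#' @return a `centerline` with an `ostium` attribute holding the aortic point
#'   index nearest the take-off.
#' @export
generate_renal_branch <- function(aorta, side = c("left", "right"),
                                  branching_angle_deg = 90,
                                  length_mm = 45, radius_mm = 3,
                                  curvature_profile = 0,
                                  bend_direction = c(0, 1, 0),
                                  seed = 1,
                                  ostium_frac = 0.5, spacing_mm = 1) {
  side <- match.arg(side)
  if (branching_angle_deg <= 10 || branching_angle_deg >= 170)
    stop("invalid config: `branching_angle_deg` must lie in (10, 170)")
  if (length_mm < 20 || length_mm > 80)
    stop("invalid config: `length_mm` must lie in [20, 80]")
  if (radius_mm < 2.5 || radius_mm > 3.5)
    stop("invalid config: `radius_mm` must lie in [2.5, 3.5] (5-7 mm lumen)")
  if (length_mm < min(sg_catalog()$length_mm))
    warning("branch shorter than every stent-graft in the catalog")
  prof <- .curvature_profile(curvature_profile)
  rs <- .rng_stream(seed, 211L)

  pts_a <- unclass(as.matrix(aorta))
  i0 <- max(2L, min(nrow(pts_a) - 1L, round(ostium_frac * nrow(pts_a))))
  t_a <- .tangent_at(pts_a, i0)
  r_a <- attr(aorta, "radius")
  if (is.null(r_a)) stop("aorta centerline must carry a tube radius")
  r_a <- r_a[i0]
  lateral <- if (side == "left") c(1, 0, 0) else c(-1, 0, 0)
  n_hat <- .unit(lateral - sum(lateral * t_a) * t_a)  # outward surface normal
  p0 <- pts_a[i0, ] + r_a * n_hat
  th <- branching_angle_deg * pi / 180
  d0 <- cos(th) * t_a + sin(th) * n_hat          # take-off direction
  b0 <- .unit(bend_direction - sum(bend_direction * d0) * d0)  # bend normal
  w0 <- .cross3(d0, b0)                          # out-of-plane direction

  s <- seq(0, length_mm, by = spacing_mm)
  if (s[length(s)] < length_mm - 1e-9) s <- c(s, length_mm)
  k <- prof$kappa
  if (abs(k) < 1e-12) {
    arc <- outer(s, d0)
  } else {
    arc <- outer(sin(k * s) / k, d0) + outer((1 - cos(k * s)) / k, b0)
  }
  pts <- sweep(arc, 2, p0, "+")
  if (prof$wobble_amp_mm > 0) {
    phase <- rs(1) * 2 * pi
    # ramp suppresses the perturbation near the ostium so the take-off
    # direction (hence the branching angle) is untouched
    ramp <- pmin(1, s / max(prof$wobble_period_mm / 2, 1e-9))^2
    w <- prof$wobble_amp_mm * ramp *
      sin(2 * pi * s / prof$wobble_period_mm + phase)
    pts <- pts + outer(w, w0)
  }
  cl <- centerline(pts, radius = radius_mm)
  attr(cl, "ostium") <- i0
  attr(cl, "side") <- side
  cl
}

.curvature_profile <- function(p) {
  if (is.numeric(p) && length(p) == 1L)
    p <- list(kappa = p)
  stopifnot(is.list(p))
  out <- list(kappa = p$kappa %||% 0,
              wobble_amp_mm = p$wobble_amp_mm %||% 0,
              wobble_period_mm = p$wobble_period_mm %||% 15)
  if (out$kappa < 0 || out$wobble_amp_mm < 0 || out$wobble_period_mm <= 0)
    stop("invalid curvature profile")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Respiratory displacement boundary condition
#'
#' Builds the breathing boundary condition applied at the distal ends of the
#' two renal branches while both aortic ends stay fixed. Displacement
#' components are given on the anatomical axes (left-right, antero-posterior,
#' cranio-caudal); respiratory organ motion is dominated by the cranio-caudal
#' component, and that dominance is enforced as an invariant. The left-right
#' component is mirrored between the two sides.
#'
#' @param cc_mm cranio-caudal displacement (mm); its magnitude must be at
#'   least that of the other two components.
#' @param ap_mm antero-posterior displacement (mm).
#' @param lr_mm left-right displacement (mm); applied as `+lr_mm` on the left
#'   branch and `-lr_mm` on the right.
#' @param per_branch_jitter fractional per-branch, per-component multiplicative
#'   jitter (e.g. 0.1 for +/-10%), drawn from the seeded stream.
#' @param seed integer seed.
#' @return an object of class `breathing_bc`: list with per-branch 3-vectors
#'   (`left`, `right`) in (lr, ap, cc) = (x, y, z) order and
#'   `fixed_aorta_ends = TRUE`.
#' @export
generate_breathing_bc <- function(cc_mm = 10, ap_mm = 2, lr_mm = 1,
                                  per_branch_jitter = 0, seed = 1) {
  if (abs(cc_mm) < max(abs(ap_mm), abs(lr_mm)))
    stop("invalid config: cranio-caudal component must dominate (|cc| >= |ap|, |lr|)")
  if (per_branch_jitter < 0 || per_branch_jitter >= 1)
    stop("invalid config: `per_branch_jitter` must lie in [0, 1)")
  rs <- .rng_stream(seed, 307L)
  mk <- function(lr_sign) {
    v <- c(lr_sign * lr_mm, ap_mm, cc_mm)
    if (per_branch_jitter > 0)
      v <- v * (1 + per_branch_jitter * (2 * rs(3) - 1))
    v
  }
  out <- list(left = mk(1), right = mk(-1), fixed_aorta_ends = TRUE)
  for (v in out[c("left", "right")])
    if (abs(v[3]) < max(abs(v[1]), abs(v[2])))
      stop("invalid config: jitter broke cranio-caudal dominance")
  class(out) <- "breathing_bc"
  out
}

#' @export
print.breathing_bc <- function(x, ...) {
  cat("<breathing displacement BC (mm, lr/ap/cc); aorta ends fixed>\n")
  cat(sprintf("  left : (%6.2f, %6.2f, %6.2f)\n", x$left[1], x$left[2], x$left[3]))
  cat(sprintf("  right: (%6.2f, %6.2f, %6.2f)\n", x$right[1], x$right[2], x$right[3]))
  invisible(x)
}

#' Synthetic patient: aorta, two renal branches and breathing BC
#'
#' Draws a reproducible synthetic patient. Geometry parameters are sampled
#' within anatomically motivated ranges: near-perpendicular branching angles
#' (78-100 deg), renal lumen radii 2.5-3.5 mm (diameters 5-7 mm), branch
#' lengths 40-52 mm and a constant-curvature anterior hook towards the kidney
#' (radius of curvature 29-40 mm). All randomness flows from one master seed
#' through fixed per-stage substreams, so the stage order can never change
#' the result.
#'
#' @param seed master integer seed for the patient.
#' @param aorta_length_mm,aorta_radius_mm,aorta_tortuosity_mm aorta geometry.
#' @param branch_length_range_mm,branch_angle_range_deg,branch_radius_range_mm
#'   sampling ranges for the two renal branches.
#' @param branch_kappa_range sampling range for the constant branch curvature
#'   (1/mm).
#' @param wobble_amp_mm out-of-plane sinusoidal perturbation amplitude (mm).
#' @param breathing list of breathing magnitudes
#'   (`cc_mm`, `ap_mm`, `lr_mm`, `per_branch_jitter`); configurable stand-ins
#'   for patient-specific CT-measured vectors.
#' @return an object of class `synthetic_patient` with elements `aorta`,
#'   `renal_left`, `renal_right`, `breathing`, `seed`.
#' @export
synthetic_patient <- function(seed = 1,
                              aorta_length_mm = 200,
                              aorta_radius_mm = 10,
                              aorta_tortuosity_mm = 2,
                              branch_length_range_mm = c(40, 52),
                              branch_angle_range_deg = c(78, 100),
                              branch_radius_range_mm = c(2.5, 3.5),
                              branch_kappa_range = c(0.025, 0.035),
                              wobble_amp_mm = 0,
                              breathing = list(cc_mm = 10, ap_mm = 2,
                                               lr_mm = 1,
                                               per_branch_jitter = 0.1)) {
  seed <- as.integer(seed)
  rs <- .rng_stream(seed, 1L)
  aorta <- generate_aorta_centerline(aorta_length_mm, aorta_radius_mm,
                                     aorta_tortuosity_mm, seed = seed)
  draw <- function(range) range[1] + rs(1) * (range[2] - range[1])
  branches <- list()
  fracs <- c(left = 0.52, right = 0.48)   # renal take-offs near mid-aorta
  for (side in c("left", "right")) {
    branches[[side]] <- generate_renal_branch(
      aorta, side,
      branching_angle_deg = draw(branch_angle_range_deg),
      length_mm = draw(branch_length_range_mm),
      radius_mm = draw(branch_radius_range_mm),
      curvature_profile = list(kappa = draw(branch_kappa_range),
                               wobble_amp_mm = wobble_amp_mm,
                               wobble_period_mm = 18),
      seed = seed + if (side == "left") 13L else 17L,
      ostium_frac = fracs[[side]])
  }
  bc <- generate_breathing_bc(breathing$cc_mm %||% 10, breathing$ap_mm %||% 2,
                              breathing$lr_mm %||% 1,
                              breathing$per_branch_jitter %||% 0,
                              seed = seed + 29L)
  structure(list(aorta = aorta, renal_left = branches$left,
                 renal_right = branches$right, breathing = bc, seed = seed),
            class = "synthetic_patient")
}

#' @export
print.synthetic_patient <- function(x, ...) {
  cat(sprintf("<synthetic patient, seed %d>\n", x$seed))
  cat("  aorta      : "); print(x$aorta)
  cat("  renal left : "); print(x$renal_left)
  cat("  renal right: "); print(x$renal_right)
  print(x$breathing)
  invisible(x)
}

#' Distance from a branch origin to the aortic axis at the ostium
#'
#' Geometric-consistency helper: for a well-formed patient the first point of
#' each renal branch lies on the aortic tube surface, i.e. its distance to the
#' local aortic axis (the tangent line at the ostium) equals the aortic
#' radius.
#'
#' @param aorta aortic `centerline` (with radius).
#' @param branch renal `centerline` carrying an `ostium` attribute.
#' @return distance (mm) from the branch origin to the aortic tangent line at
#'   the ostium.
#' @export
ostium_offset <- function(aorta, branch) {
  i0 <- attr(branch, "ostium")
  if (is.null(i0)) stop("branch has no `ostium` attribute")
  pts_a <- unclass(as.matrix(aorta))
  t_a <- .tangent_at(pts_a, i0)
  v <- unclass(as.matrix(branch))[1, ] - pts_a[i0, ]
  sqrt(sum(v * v) - sum(v * t_a)^2)
}

# ---- seeded substreams ----------------------------------------------------

# Counter-based substream: every draw site derives its own RNG from
# (seed, tag) so stage order cannot change results. Returns a closure
# yielding `n` U(0,1) draws per call, advancing an internal counter.
.rng_stream <- function(seed, tag) {
  counter <- 0L
  function(n) {
    counter <<- counter + 1L
    mix <- (as.double(seed) * 2654435761 + as.double(tag) * 40503 +
              counter * 69991) %% 2147483647
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(as.integer(mix))
    stats::runif(n)
  }
}
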