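#' Discrete pointwise curvature of a centerline
#'
#' Curvature (the inverse of the local radius of curvature, 1/mm) is estimated
#' at every interior point as the Menger curvature of the consecutive point
#' triple: the reciprocal circumradius of the three points, kappa = 4A/(abc).
#' The estimator is exact on circles, parameter-free, and matches sampling the
#' curve every 1 mm; collinear triples get curvature 0. Endpoints carry no
#' curvature estimate. The maximum over interior points is the summary used in
#' the analysis.
#'
#' @param x a `centerline` with at least 3 points, ideally resampled at 1 mm
#'   (see [resample_centerline()]).
#' @return list with `profile` (curvature at each interior point, 1/mm),
#'   `max` (its maximum) and `arc` (arc-length coordinate of each interior
#'   point, mm).
#' @export
pointwise_curvature <- function(x) {
  pts <- unclass(as.matrix(x))
  n <- nrow(pts)
  if (n < 3L) stop("curvature needs at least 3 points")
  prof <- vapply(2:(n - 1L), function(i)
    menger_curvature(pts[i - 1L, ], pts[i, ], pts[i + 1L, ]), numeric(1))
  list(profile = prof, max = max(prof), arc = .arc_coords(pts)[2:(n - 1L)])
}

#' Menger curvature of a point triple
#'
#' @param a,b,c 3-vectors (mm).
#' @return curvature 4A/(|ab| |bc| |ac|) in 1/mm; 0 for collinear points.
#' @export
menger_curvature <- function(a, b, c) {
  ab <- b - a; bc <- c - b; ac <- c - a
  cr <- .cross3(ab, ac)
  twoA <- sqrt(sum(cr * cr))
  den <- sqrt(sum(ab * ab) * sum(bc * bc) * sum(ac * ac))
  if (den < 1e-30 || twoA < 1e-14 * den) return(0)
  2 * twoA / den
}

#' Branching angle between aorta and renal branch
#'
#' The branching angle is measured between the aortic centerline and the
#' renal-artery centerline: the angle between (a) the aortic tangent at the
#' point nearest the branch origin and (b) the least-squares direction of the
#' branch (oriented ostium to distal). 90 deg corresponds to a perpendicular
#' take-off. By default the whole renal centerline enters the direction fit,
#' reading the two centerlines as lines; a finite `fit_window_mm` restricts
#' the fit to the first window of branch arc length.
#'
#' @param aorta aortic `centerline`.
#' @param branch renal `centerline`, first point at the ostium (within 1 mm
#'   of the aortic tube surface).
#' @param fit_window_mm branch arc length entering the direction fit
#'   (>= 3 mm), or `NULL` (default) for the entire branch. Branches shorter
#'   than the window shrink it with a warning.
#' @return angle in degrees, in (0, 180).
#' @export
branching_angle <- function(aorta, branch, fit_window_mm = NULL) {
  pts_a <- unclass(as.matrix(aorta))
  pts_b <- unclass(as.matrix(branch))
  d2 <- rowSums(sweep(pts_a, 2, pts_b[1, ])^2)
  i0 <- which.min(d2)
  t_a <- .tangent_at(pts_a, i0)
  L <- arc_length(branch)
  if (is.null(fit_window_mm)) {
    win <- pts_b
  } else {
    if (fit_window_mm < 3) stop("`fit_window_mm` must be >= 3 mm")
    if (fit_window_mm > L) {
      warning("branch shorter than fit window; using the whole branch")
      fit_window_mm <- L
    }
    win <- .points_in_arc(pts_b, 0, fit_window_mm)
  }
  .angle_deg(t_a, .ls_direction(win))
}

#' End-stent angle at the distal end of a deployed stent-graft
#'
#' The end-stent angle is measured between the stented and unstented portions
#' of the renal centerline: the angle between the least-squares direction of
#' the last `fit_window_mm` of stented centerline and that of the first
#' `fit_window_mm` of unstented centerline distal to the stent end. 0 deg
#' means the two portions are collinear. A guard zone of `guard_mm` (default
#' one 1-mm sampling step) on both sides of the stent end keeps the direction
#' fits out of the junction transition, where the discrete stent boundary
#' sits within half a sampling step of the nominal `s_end`. When less than
#' `guard_mm + fit_window_mm` of artery remains beyond the stent the metric
#' is unavailable and `NA` is returned.
#'
#' @param branch renal `centerline` (deformed or rest), arc length anchored at
#'   the ostium.
#' @param deployed a `deployed_sg` (see [deploy_geometric()]); its in-artery
#'   extent ends at arc length `s_end`.
#' @param fit_window_mm direction-fit window (default 5 mm).
#' @param guard_mm junction guard zone excluded from both fits (default 1 mm).
#' @return angle in degrees, or `NA_real_` when unavailable.
#' @export
end_stent_angle <- function(branch, deployed, fit_window_mm = 5,
                            guard_mm = 1) {
  s_end <- deployed$s_end
  pts <- unclass(as.matrix(branch))
  L <- arc_length(branch)
  if (L - s_end < guard_mm + fit_window_mm - 1e-9) return(NA_real_)
  stented <- .points_in_arc(pts, max(0, s_end - guard_mm - fit_window_mm),
                            s_end - guard_mm)
  distal <- .points_in_arc(pts, s_end + guard_mm,
                           s_end + guard_mm + fit_window_mm)
  if (nrow(stented) < 2L || nrow(distal) < 2L) return(NA_real_)
  .angle_deg(.ls_direction(stented), .ls_direction(distal))
}

#' Full morphometric profile of one branch configuration
#'
#' Convenience wrapper computing, for one (possibly deformed, possibly
#' stented) renal branch: the branching angle against the aorta, the
#' end-stent angle (if a deployed stent-graft is supplied and enough artery
#' remains beyond it), and the curvature profile every `spacing_mm` with its
#' maximum.
#'
#' @param aorta aortic `centerline`.
#' @param branch renal `centerline`.
#' @param deployed optional `deployed_sg`.
#' @param spacing_mm curvature sampling step (default 1 mm).
#' @param branching_window_mm passed to [branching_angle()] (default `NULL`,
#'   whole branch).
#' @param end_stent_window_mm passed to [end_stent_angle()] (default 5 mm).
#' @param label free-form configuration label carried into delta pairing.
#' @return object of class `morpho_metrics`.
#' @export
morpho_metrics <- function(aorta, branch, deployed = NULL, spacing_mm = 1,
                           branching_window_mm = NULL,
                           end_stent_window_mm = 5, label = "") {
  rs <- resample_centerline(branch, spacing_mm)
  curv <- pointwise_curvature(rs)
  out <- list(
    branching_angle = branching_angle(aorta, branch, branching_window_mm),
    end_stent_angle = if (is.null(deployed)) NA_real_ else
      end_stent_angle(rs, deployed, end_stent_window_mm),
    max_curvature = curv$max,
    curvature_profile = curv$profile,
    curvature_arc = curv$arc,
    label = label)
  class(out) <- "morpho_metrics"
  out
}

#' @export
print.morpho_metrics <- function(x, ...) {
  cat(sprintf("<morphometrics%s>\n  branching angle: %.2f deg\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              x$branching_angle))
  if (!is.na(x$end_stent_angle))
    cat(sprintf("  end-stent angle: %.2f deg\n", x$end_stent_angle))
  cat(sprintf("  max curvature  : %.4f 1/mm\n", x$max_curvature))
  invisible(x)
}

#' Inspiration-to-expiration morphometric deltas
#'
#' Absolute differences of branching angle, end-stent angle and maximum
#' curvature between the inspiration (rest) and expiration (equilibrium)
#' configurations of the same branch. Deltas are stored as absolute values.
#'
#' @param inspiration,expiration `morpho_metrics` of the same branch and
#'   stent configuration; mismatched labels raise an invalid-pairing error.
#' @return object of class `morpho_delta` with fields
#'   `d_branching_angle_deg`, `d_end_stent_angle_deg`, `d_max_curvature`.
#' @export
breathing_deltas <- function(inspiration, expiration) {
  stopifnot(inherits(inspiration, "morpho_metrics"),
            inherits(expiration, "morpho_metrics"))
  if (!identical(inspiration$label, expiration$label))
    stop("invalid pairing: inspiration and expiration labels differ (",
         inspiration$label, " vs ", expiration$label, ")")
  out <- list(
    d_branching_angle_deg = abs(expiration$branching_angle -
                                  inspiration$branching_angle),
    d_end_stent_angle_deg = abs(expiration$end_stent_angle -
                                  inspiration$end_stent_angle),
    d_max_curvature = abs(expiration$max_curvature -
                            inspiration$max_curvature),
    label = inspiration$label)
  class(out) <- "morpho_delta"
  out
}

#' @export
print.morpho_delta <- function(x, ...) {
  cat(sprintf(
    "<breathing deltas%s>\n  |d branching| = %.2f deg\n  |d end-stent| = %s\n  |d max curv | = %.4f 1/mm\n",
    if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
    x$d_branching_angle_deg,
    if (is.na(x$d_end_stent_angle_deg)) "n/a" else
      sprintf("%.2f deg", x$d_end_stent_angle_deg),
    x$d_max_curvature))
  invisible(x)
}
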