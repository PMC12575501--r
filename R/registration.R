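#' Optimal rigid alignment of paired point sets (Kabsch)
#'
#' Least-squares rigid transform (proper rotation + translation) mapping
#' `source_points` onto `target_points` with known one-to-one correspondence;
#' the SVD branch with det(R) = +1 is always selected, so an improper
#' rotation (reflection) is never returned.
#'
#' @param source_points,target_points matrices (n x 3), n >= 3, not all
#'   collinear.
#' @return object of class `rigid_transform`: list with `R` (3 x 3 rotation)
#'   and `t` (3-vector, mm); apply as `x %*% t(R) + t` or via
#'   [apply_transform()].
#' @export
kabsch_align <- function(source_points, target_points) {
  s <- as.matrix(source_points); t_ <- as.matrix(target_points)
  if (nrow(s) != nrow(t_) || nrow(s) < 3L)
    stop("point sets must be equal-sized with >= 3 points")
  cs <- colMeans(s); ct <- colMeans(t_)
  H <- crossprod(sweep(s, 2, cs), sweep(t_, 2, ct))
  sv <- svd(H)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1e-300))
    stop("rank deficiency: point set is degenerate (collinear or coincident)")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  structure(list(R = R, t = as.numeric(ct - R %*% cs)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(max(-1, min(1, (sum(diag(x$R)) - 1) / 2))) * 180 / pi
  cat(sprintf("<rigid transform: rotation %.3f deg, translation (%.3f, %.3f, %.3f) mm>\n",
              ang, x$t[1], x$t[2], x$t[3]))
  invisible(x)
}

#' @rdname kabsch_align
#' @param transform a `rigid_transform`.
#' @param points n x 3 matrix (or `centerline`).
#' @export
apply_transform <- function(transform, points) {
  pts <- unclass(as.matrix(points))
  out <- sweep(pts %*% t(transform$R), 2, transform$t, "+")
  if (inherits(points, "centerline"))
    out <- centerline(out, radius = attr(points, "radius"))
  out
}

#' Iterative closest point registration
#'
#' Rigid registration of two point sets: after an initial alignment of their
#' centroids, closest-point correspondence (each source point paired with the
#' nearest point on the target polyline) and Kabsch alignment alternate until
#' the RMS correspondence distance stops improving by more than `tol_mm` or
#' `max_iter` is reached. The recorded RMS history is
#' non-increasing. If the very first iteration brings no improvement over the
#' centroid alignment, the centroid-only transform is returned with a
#' warning.
#'
#' @param source,target point matrices (n x 3) or `centerline`s, each with at
#'   least 10 points.
#' @param max_iter iteration cap (default 500; correspondence sliding along
#'   smooth centerlines makes the final approach linear, so ample iterations
#'   are cheap insurance).
#' @param tol_mm RMS improvement tolerance (default 1e-9 mm).
#' @return list with `transform` (`rigid_transform` mapping source to
#'   target), `rms_history` (mm, one entry per iteration including the
#'   centroid stage), `iterations`.
#' @export
icp <- function(source, target, max_iter = 500, tol_mm = 1e-9) {
  s <- unclass(as.matrix(source)); t_ <- unclass(as.matrix(target))
  if (nrow(s) < 10L || nrow(t_) < 10L)
    stop("ICP needs at least 10 points in each set")
  cs <- colMeans(s); ct <- colMeans(t_)
  R <- diag(3); tt <- as.numeric(ct - cs)
  cur <- sweep(s, 2, tt, "+")
  corr <- function(x) .nearest_on_polyline(x, t_)
  nn <- corr(cur)
  history <- sqrt(mean(nn$d2))
  for (it in seq_len(max_iter)) {
    # fit on interior correspondences only: points clamped to the ends of
    # the target polyline bias the rotation and stall convergence
    use <- if (sum(nn$interior) >= 3L) nn$interior else rep(TRUE, nrow(s))
    tr <- kabsch_align(s[use, , drop = FALSE],
                       nn$proj[use, , drop = FALSE])
    cand <- apply_transform(tr, s)
    nn_cand <- corr(cand)
    rms <- sqrt(mean(nn_cand$d2))
    if (rms > history[length(history)] - tol_mm) {
      if (it == 1L && rms > history[1L] + tol_mm)
        warning("ICP made no improvement over centroid alignment; returning centroid-only transform")
      if (rms <= history[length(history)]) {
        R <- tr$R; tt <- tr$t; history <- c(history, rms)
      }
      break
    }
    R <- tr$R; tt <- tr$t
    cur <- cand
    nn <- nn_cand
    history <- c(history, rms)
  }
  list(transform = structure(list(R = R, t = tt), class = "rigid_transform"),
       rms_history = history, iterations = length(history) - 1L)
}

.nearest_neighbours <- function(a, b) {
  # for each row of a, index of nearest row of b (exact, O(n m))
  bb <- rowSums(b * b)
  d2 <- outer(rowSums(a * a), bb, "+") - 2 * tcrossprod(a, b)
  idx <- max.col(-d2, ties.method = "first")
  list(idx = idx, d2 = pmax(0, d2[cbind(seq_len(nrow(a)), idx)]))
}

# closest point of the polyline b (ordered rows) to each row of a; treating
# the target as a curve rather than a vertex set avoids the sliding stall of
# vertex-to-vertex correspondence on smooth centerlines
.nearest_on_polyline <- function(a, b) {
  n <- nrow(a)
  nb <- nrow(b)
  best_d2 <- rep(Inf, n)
  best <- matrix(0, n, 3)
  interior <- rep(TRUE, n)
  for (j in seq_len(nb - 1L)) {
    p0 <- b[j, ]; d <- b[j + 1L, ] - p0
    len2 <- sum(d * d)
    rel <- sweep(a, 2, p0)
    t_raw <- as.vector(rel %*% d) / len2
    t_par <- pmin(1, pmax(0, t_raw))
    proj <- outer(t_par, d) + matrix(p0, n, 3, byrow = TRUE)
    d2 <- rowSums((a - proj)^2)
    upd <- d2 < best_d2
    if (any(upd)) {
      best_d2[upd] <- d2[upd]
      best[upd, ] <- proj[upd, , drop = FALSE]
      interior[upd] <- !((j == 1L & t_raw[upd] < -1e-12) |
                           (j == nb - 1L & t_raw[upd] > 1 + 1e-12))
    }
  }
  list(proj = best, d2 = best_d2, interior = interior)
}

#' Corresponding-point distances between two centerlines
#'
#' Both centerlines are resampled to `n_corresponding` arc-length-proportional
#' points (index 1 at the ostium end) and distances between same-index points
#' are measured. If the two polylines are stored in opposite directions (the
#' endpoint-pairing test) the second is reversed automatically with a notice.
#'
#' @param a,b `centerline`s (or n x 3 matrices).
#' @param n_corresponding number of corresponding points (>= 10, default 100).
#' @return object of class `distance_profile`: list with `distances_mm`
#'   (length `n_corresponding`), `mean_mm`, `sd_mm`, `max_mm`.
#' @export
centerline_distance <- function(a, b, n_corresponding = 100) {
  if (n_corresponding < 10L) stop("`n_corresponding` must be >= 10")
  if (!inherits(a, "centerline")) a <- centerline(a)
  if (!inherits(b, "centerline")) b <- centerline(b)
  pa <- unclass(as.matrix(a)); pb <- unclass(as.matrix(b))
  same <- sum((pa[1, ] - pb[1, ])^2) + sum((pa[nrow(pa), ] - pb[nrow(pb), ])^2)
  flip <- sum((pa[1, ] - pb[nrow(pb), ])^2) + sum((pa[nrow(pa), ] - pb[1, ])^2)
  if (flip < same) {
    message("centerline_distance: opposite orientations detected; reversing second centerline")
    b <- centerline(pb[nrow(pb):1, , drop = FALSE], radius = rev(attr(b, "radius")))
  }
  ra <- unclass(as.matrix(resample_centerline(a, n_points = n_corresponding)))
  rb <- unclass(as.matrix(resample_centerline(b, n_points = n_corresponding)))
  d <- sqrt(rowSums((ra - rb)^2))
  structure(list(distances_mm = d, mean_mm = mean(d),
                 sd_mm = stats::sd(d), max_mm = max(d)),
            class = "distance_profile")
}

#' @export
print.distance_profile <- function(x, ...) {
  cat(sprintf("<distance profile (%d points): mean %.2f +/- %.2f mm, max %.2f mm>\n",
              length(x$distances_mm), x$mean_mm, x$sd_mm, x$max_mm))
  invisible(x)
}

#' Stent-graft placement accuracy score
#'
#' Percentage of corresponding centerline points whose simulated-vs-imaged
#' distance is strictly below the tolerance threshold. The default 3 mm
#' threshold budgets 2 mm for image acquisition errors plus 1 mm for
#' segmentation (one third of the 3 mm mean renal radius). Ties at exactly
#' the threshold count as failures ("below" is read strictly).
#'
#' @param profile a `distance_profile` (or numeric vector of distances, mm).
#' @param tolerance_mm threshold (default 3 mm), > 0.
#' @return object of class `score_report`: `accuracy_score_pct` between 0 and 100
#'   (100 iff the maximum distance is below the threshold), `n_points`,
#'   `tolerance_mm`, `profile`.
#' @export
placement_accuracy_score <- function(profile, tolerance_mm = 3) {
  if (tolerance_mm <= 0) stop("`tolerance_mm` must be > 0")
  d <- if (inherits(profile, "distance_profile")) profile$distances_mm
       else as.numeric(profile)
  if (!length(d)) stop("empty distance profile")
  score <- 100 * sum(d < tolerance_mm) / length(d)
  structure(list(accuracy_score_pct = score, n_points = length(d),
                 tolerance_mm = tolerance_mm,
                 profile = if (inherits(profile, "distance_profile")) profile
                           else NULL),
            class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf("<SG placement accuracy score: %.1f%% of %d points below %.1f mm>\n",
              x$accuracy_score_pct, x$n_points, x$tolerance_mm))
  invisible(x)
}

#' Validation thresholds for placement and protrusion
#'
#' @param tolerance_mm centerline-distance threshold (default 3 mm: 2 mm
#'   imaging + 1 mm segmentation error budget).
#' @param protrusion_band_mm acceptable protrusion range (default
#'   `c(3.4, 4.3)` mm, a marginally widened clinical 3.6-4.1 mm median range).
#' @param protrusion_reference_mm clinical reference protrusion (3.88 mm).
#' @return list of class `validation_config`.
#' @export
validation_config <- function(tolerance_mm = 3,
                              protrusion_band_mm = c(3.4, 4.3),
                              protrusion_reference_mm = 3.88) {
  if (tolerance_mm <= 0) stop("`tolerance_mm` must be > 0")
  if (protrusion_band_mm[1] >= protrusion_band_mm[2])
    stop("protrusion band lower bound must be below the upper bound")
  structure(list(tolerance_mm = tolerance_mm,
                 protrusion_band_mm = protrusion_band_mm,
                 protrusion_reference_mm = protrusion_reference_mm),
            class = "validation_config")
}

#' Protrusion-length criterion
#'
#' Checks each deployed stent-graft's protrusion into the aortic lumen against
#' the acceptable band and reports the arithmetic mean protrusion.
#'
#' @param deployed_list list of `deployed_sg` objects, or a numeric vector of
#'   protrusion lengths (mm); must be non-empty.
#' @param config a [validation_config()].
#' @return list with `protrusion_mm` (vector), `pass` (logical vector),
#'   `mean_mm`, `band_mm`, `all_pass`.
#' @export
check_protrusions <- function(deployed_list, config = validation_config()) {
  p <- if (is.numeric(deployed_list)) as.numeric(deployed_list)
       else vapply(deployed_list, function(d) d$protrusion_length_mm, numeric(1))
  if (!length(p)) stop("empty deployment list")
  band <- config$protrusion_band_mm
  pass <- p >= band[1] & p <= band[2]
  list(protrusion_mm = p, pass = pass, mean_mm = mean(p),
       band_mm = band, all_pass = all(pass))
}
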