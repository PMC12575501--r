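#' Vessel centerline
#'
#' A centerline is an ordered 3-D polyline in millimetres, the common currency
#' of every stage of the pipeline: synthetic geometry, rod mechanics,
#' morphometrics and registration all consume and produce centerlines.
#' Coordinates live in a right-handed patient frame with
#' x = left-right, y = antero-posterior, z = cranio-caudal (superior positive).
#'
#' @param points numeric matrix (n x 3) of xyz coordinates in mm, ordered along
#'   the vessel; n >= 2 and consecutive points must not coincide.
#' @param radius optional per-point lumen radius in mm (length n or scalar).
#' @return An object of class `centerline`: the point matrix with attributes
#'   `radius` (possibly `NULL`).
#' @examples
#' cl <- centerline(cbind(0, 0, 0:10))
#' arc_length(cl)
#' @export
centerline <- function(points, radius = NULL) {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 3L)
    stop("`points` must be a numeric n x 3 matrix of xyz coordinates (mm)")
  if (nrow(points) < 2L)
    stop("a centerline needs at least 2 points")
  if (anyNA(points) || any(!is.finite(points)))
    stop("centerline coordinates must be finite")
  seg <- .seg_lengths(points)
  if (any(seg <= 1e-9))
    stop("consecutive centerline points must be distinct (spacing > 1e-9 mm)")
  if (!is.null(radius)) {
    if (length(radius) == 1L) radius <- rep(as.numeric(radius), nrow(points))
    if (length(radius) != nrow(points) || any(radius <= 0))
      stop("`radius` must be positive, scalar or one value per point")
  }
  dimnames(points) <- list(NULL, c("x", "y", "z"))
  structure(points, radius = radius, class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline: %d points, arc length %.2f mm%s>\n",
              nrow(x), arc_length(x),
              if (is.null(attr(x, "radius"))) "" else
                sprintf(", radius %.2f-%.2f mm",
                        min(attr(x, "radius")), max(attr(x, "radius")))))
  invisible(x)
}

#' @export
as.data.frame.centerline <- function(x, ...) {
  d <- data.frame(x_mm = x[, 1], y_mm = x[, 2], z_mm = x[, 3])
  if (!is.null(attr(x, "radius"))) d$r_mm <- attr(x, "radius")
  d
}

#' @rdname centerline
#' @param x a `centerline`.
#' @export
arc_length <- function(x) {
  sum(.seg_lengths(unclass(as.matrix(x))))
}

#' Arc-length resampling of a centerline
#'
#' Redistributes points at equal arc-length spacing by linear interpolation
#' along the polyline. Both endpoints are preserved exactly; when the total
#' length is not an integer multiple of `spacing_mm` the final interval is
#' shorter. Metric extraction samples curvature every 1 mm, so 1 mm is the
#' default spacing used throughout.
#'
#' @param x a `centerline`.
#' @param spacing_mm target spacing in mm (default 1); must be positive and
#'   smaller than the arc length.
#' @param n_points alternatively, resample to exactly `n_points` points equally
#'   spaced in arc length (used for corresponding-point distances). Overrides
#'   `spacing_mm`.
#' @return a resampled `centerline`.
#' @export
resample_centerline <- function(x, spacing_mm = 1, n_points = NULL) {
  pts <- unclass(as.matrix(x))
  s <- c(0, cumsum(.seg_lengths(pts)))
  L <- s[length(s)]
  if (is.null(n_points)) {
    if (!is.numeric(spacing_mm) || spacing_mm <= 0)
      stop("`spacing_mm` must be positive")
    if (spacing_mm >= L)
      stop("`spacing_mm` must be smaller than the arc length (", round(L, 3), " mm)")
    targets <- seq(0, L, by = spacing_mm)
    if (targets[length(targets)] < L - 1e-9) targets <- c(targets, L)
    else targets[length(targets)] <- L
  } else {
    if (n_points < 2L) stop("`n_points` must be >= 2")
    targets <- seq(0, L, length.out = n_points)
  }
  out <- vapply(seq_len(3L),
                function(j) stats::approx(s, pts[, j], xout = targets,
                                          ties = "ordered")$y,
                numeric(length(targets)))
  out[1, ] <- pts[1, ]
  out[nrow(out), ] <- pts[nrow(pts), ]
  r <- attr(x, "radius")
  if (!is.null(r))
    r <- stats::approx(s, r, xout = targets, ties = "ordered")$y
  centerline(out, radius = r)
}

#' Read / write centerlines as CSV
#'
#' The on-disk dialect is a plain CSV with header `x_mm,y_mm,z_mm` and an
#' optional `r_mm` radius column; a JSON variant carries the same columns plus
#' free-form metadata (seed, frame) under a `meta` field.
#'
#' @param x a `centerline`.
#' @param path file path.
#' @param meta named list of metadata (JSON only).
#' @return `read_centerline_*` return a `centerline` (JSON: with a `meta`
#'   attribute); writers return `path` invisibly.
#' @export
write_centerline_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_centerline_csv
#' @export
read_centerline_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(d)))
    stop("centerline CSV must have columns x_mm,y_mm,z_mm[,r_mm]: ", path)
  centerline(as.matrix(d[need]),
             radius = if ("r_mm" %in% names(d)) d$r_mm else NULL)
}

#' @rdname write_centerline_csv
#' @export
write_centerline_json <- function(x, path, meta = list()) {
  obj <- list(points = unclass(as.matrix(x)), frame = "LR-AP-CC (mm)",
              meta = meta)
  if (!is.null(attr(x, "radius"))) obj$radius <- attr(x, "radius")
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_centerline_csv
#' @export
read_centerline_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cl <- centerline(obj$points, radius = obj$radius)
  attr(cl, "meta") <- obj$meta
  cl
}

# interpolate a polyline at the given arc-length coordinates
.resample_at <- function(pts, targets) {
  s <- c(0, cumsum(.seg_lengths(pts)))
  out <- vapply(seq_len(3L),
                function(j) stats::approx(s, pts[, j], xout = targets,
                                          ties = "ordered")$y,
                numeric(length(targets)))
  out[1, ] <- pts[1, ]
  out[length(targets), ] <- pts[nrow(pts), ]
  out
}

# ---- internal geometry helpers -------------------------------------------

.seg_lengths <- function(pts) {
  d <- diff(pts)
  sqrt(rowSums(d * d))
}

.unit <- function(v) {
  n <- sqrt(sum(v * v))
  if (n < 1e-12) stop("cannot normalise a (near-)zero vector")
  v / n
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# cumulative arc-length coordinate of each point
.arc_coords <- function(pts) c(0, cumsum(.seg_lengths(pts)))

# least-squares direction of a point set, oriented from first to last point
.ls_direction <- function(pts) {
  if (nrow(pts) < 2L) stop("need >= 2 points for a direction")
  if (nrow(pts) == 2L) return(.unit(pts[2, ] - pts[1, ]))
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))
  d <- sv$v[, 1]
  if (sum(d * (pts[nrow(pts), ] - pts[1, ])) < 0) d <- -d
  d
}

# local tangent at point index i by central differences
.tangent_at <- function(pts, i) {
  n <- nrow(pts)
  i0 <- max(1L, i - 1L); i1 <- min(n, i + 1L)
  .unit(pts[i1, ] - pts[i0, ])
}

# points of a polyline with arc-length coordinate inside [s0, s1]
.points_in_arc <- function(pts, s0, s1) {
  s <- .arc_coords(pts)
  pts[s >= s0 - 1e-9 & s <= s1 + 1e-9, , drop = FALSE]
}

.angle_deg <- function(u, v) {
  cs <- sum(.unit(u) * .unit(v))
  cs <- max(-1, min(1, cs))
  acos(cs) * 180 / pi
}
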