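#' Sweep a tube surface along a centerline
#'
#' Builds an open-ended triangulated tube of constant radius around a
#' centerline using rotation-minimising (parallel-transport) frames, for STL
#' export and visual/registration checks. Every vertex lies at distance
#' `radius_mm` from the swept axis. If the centerline bends more tightly than
#' the tube radius (curvature radius < `radius_mm`) the surface would
#' self-intersect and a warning is raised.
#'
#' @param x a `centerline`.
#' @param radius_mm tube radius (mm), > 0.
#' @param n_circumferential vertices per ring (>= 8).
#' @return an object of class `surface_mesh`: list with `vertices` (V x 3) and
#'   `faces` (F x 3, 1-based vertex indices).
#' @export
sweep_tube_mesh <- function(x, radius_mm, n_circumferential = 16) {
  if (radius_mm <= 0) stop("`radius_mm` must be > 0")
  if (n_circumferential < 8L) stop("`n_circumferential` must be >= 8")
  pts <- unclass(as.matrix(x))
  n <- nrow(pts)
  if (n >= 3L) {
    kmax <- max(pointwise_curvature(x)$profile)
    if (kmax > 0 && 1 / kmax < radius_mm)
      warning("centerline curvature radius smaller than tube radius: swept surface self-intersects")
  }
  # parallel-transport frames
  tangents <- t(apply(rbind(pts[2, ] - pts[1, ],
                            if (n > 2) pts[3:n, ] - pts[1:(n - 2), ] else NULL,
                            pts[n, ] - pts[n - 1, ]), 1, .unit))
  ref <- c(0, 0, 1)
  if (abs(sum(ref * tangents[1, ])) > 0.9) ref <- c(1, 0, 0)
  nrm <- .unit(ref - sum(ref * tangents[1, ]) * tangents[1, ])
  normals <- matrix(0, n, 3)
  normals[1, ] <- nrm
  for (i in 2:n) {
    t0 <- tangents[i - 1, ]; t1 <- tangents[i, ]
    axis <- .cross3(t0, t1)
    sa <- sqrt(sum(axis * axis)); ca <- max(-1, min(1, sum(t0 * t1)))
    if (sa < 1e-12) {
      normals[i, ] <- normals[i - 1, ]
    } else {
      axis <- axis / sa
      ang <- atan2(sa, ca)
      v <- normals[i - 1, ]
      normals[i, ] <- v * cos(ang) + .cross3(axis, v) * sin(ang) +
        axis * sum(axis * v) * (1 - cos(ang))
    }
    normals[i, ] <- .unit(normals[i, ] - sum(normals[i, ] * t1) * t1)
  }
  phi <- seq(0, 2 * pi, length.out = n_circumferential + 1L)[-(n_circumferential + 1L)]
  verts <- matrix(0, n * n_circumferential, 3)
  for (i in 1:n) {
    b <- .cross3(tangents[i, ], normals[i, ])
    ring <- pts[rep(i, n_circumferential), , drop = FALSE] +
      radius_mm * (outer(cos(phi), normals[i, ]) + outer(sin(phi), b))
    verts[(i - 1) * n_circumferential + seq_len(n_circumferential), ] <- ring
  }
  faces <- matrix(0L, 2L * (n - 1L) * n_circumferential, 3)
  f <- 0L
  for (i in 1:(n - 1)) {
    base0 <- (i - 1L) * n_circumferential
    base1 <- i * n_circumferential
    for (j in seq_len(n_circumferential)) {
      jn <- if (j == n_circumferential) 1L else j + 1L
      faces[f + 1L, ] <- c(base0 + j, base1 + j, base1 + jn)
      faces[f + 2L, ] <- c(base0 + j, base1 + jn, base0 + jn)
      f <- f + 2L
    }
  }
  structure(list(vertices = verts, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface mesh: %d vertices, %d triangles>\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Write / read triangulated surfaces as STL
#'
#' Binary little-endian STL by default (`ascii = TRUE` writes the text
#' dialect); `read_stl` auto-detects the format. Binary STL stores float32
#' coordinates, so a round trip preserves vertices to about 1e-5 mm at
#' centimetre scale.
#'
#' @param mesh a `surface_mesh`.
#' @param path file path.
#' @param ascii write ASCII STL instead of binary.
#' @return `read_stl` returns a `surface_mesh` (with one vertex per face
#'   corner, not deduplicated); `write_stl` returns `path` invisibly.
#' @export
write_stl <- function(mesh, path, ascii = FALSE) {
  v <- mesh$vertices; f <- mesh$faces
  tri <- function(i) v[f[i, ], , drop = FALSE]
  nrm <- function(p) {
    nv <- .cross3(p[2, ] - p[1, ], p[3, ] - p[1, ])
    l <- sqrt(sum(nv * nv)); if (l < 1e-20) c(0, 0, 0) else nv / l
  }
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid mesh", con)
    for (i in seq_len(nrow(f))) {
      p <- tri(i); nv <- nrm(p)
      writeLines(c(sprintf("facet normal %.9g %.9g %.9g", nv[1], nv[2], nv[3]),
                   "  outer loop",
                   sprintf("    vertex %.9g %.9g %.9g", p[, 1], p[, 2], p[, 3]),
                   "  endloop", "endfacet"), con)
    }
    writeLines("endsolid mesh", con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0L, 80L)), con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    for (i in seq_len(nrow(f))) {
      p <- tri(i)
      writeBin(c(nrm(p), t(p)), con, size = 4L, endian = "little")
      writeBin(as.integer(0L), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' @rdname write_stl
#' @export
read_stl <- function(path) {
  head <- readBin(path, "raw", n = 5L)
  is_ascii <- identical(rawToChar(head), "solid") && {
    # binary files may also start with "solid": check triangle count math
    sz <- file.info(path)$size
    con <- file(path, "rb"); on.exit(close(con))
    invisible(readBin(con, "raw", n = 80L))
    nf <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    close(con); on.exit()
    sz != 84 + 50 * nf
  }
  if (is_ascii) {
    lines <- readLines(path)
    vx <- grep("^\\s*vertex", lines, value = TRUE)
    coords <- do.call(rbind, lapply(strsplit(trimws(vx), "\\s+"),
                                    function(p) as.numeric(p[2:4])))
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    invisible(readBin(con, "raw", n = 80L))
    nf <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    coords <- matrix(0, 3L * nf, 3)
    for (i in seq_len(nf)) {
      rec <- readBin(con, "numeric", n = 12L, size = 4L, endian = "little")
      invisible(readBin(con, "integer", n = 1L, size = 2L, endian = "little"))
      coords[3L * (i - 1L) + 1:3, ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
    }
  }
  nf <- nrow(coords) / 3L
  structure(list(vertices = coords,
                 faces = matrix(seq_len(3L * nf), nf, 3, byrow = TRUE)),
            class = "surface_mesh")
}
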