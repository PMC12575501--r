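# geometric fixtures built in code

# circle sampled exactly on the curve at `spacing` mm of arc length
circle_cl <- function(radius = 10, arc = 2 * pi * 0.9, spacing = 1) {
  t <- seq(0, arc, by = spacing / radius)
  if (t[length(t)] < arc) t <- c(t, arc)
  centerline(cbind(radius * cos(t), radius * sin(t), 0))
}

# helix sampled exactly at `spacing` mm of arc length
helix_cl <- function(r = 10, c = 5, length_mm = 120, spacing = 1) {
  v <- sqrt(r^2 + c^2)
  s <- seq(0, length_mm, by = spacing)
  t <- s / v
  centerline(cbind(r * cos(t), r * sin(t), c * t))
}

rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

rigid_move <- function(pts, axis = c(1, 2, 3), angle = 0.4,
                       shift = c(5, -3, 2)) {
  R <- rotation_matrix(axis, angle)
  sweep(unclass(as.matrix(pts)) %*% t(R), 2, shift, "+")
}

straight_cl <- function(length_mm = 19, spacing = 1) {
  centerline(cbind(0, 0, seq(0, length_mm, by = spacing)))
}

# a small test patient (clean arcs, no wobble) shared across tests
test_patient <- function(seed = 3) synthetic_patient(seed = seed)

published_protrusions <- function() {
  utils::read.csv(system.file("extdata", "protrusion_lengths.csv",
                              package = "renalrod"))
}
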