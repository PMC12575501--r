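#' Stent-graft material constants
#'
#' Mechanical constants of the balloon-expandable bridging stent-graft: a
#' cobalt-chromium stent (linear-elastic regime) and an expanded-PTFE graft
#' modelled as an orthotropic lamina. Values are the characterised constants
#' for this device family; units are N and mm (moduli in MPa = N/mm^2).
#'
#' @return list of class `material_properties`:
#'   `stent_E_mpa` (268e3), `stent_nu` (0.3), `graft_E1_mpa` (1200),
#'   `graft_E2_mpa` (1.8), `graft_nu12` (0.16), `graft_G12_mpa` (1),
#'   `graft_G13_mpa` (60), `graft_G23_mpa` (35), `graft_thickness_mm` (0.2).
#' @export
material_properties <- function() {
  out <- list(stent_E_mpa = 268e3, stent_nu = 0.3,
              graft_E1_mpa = 1200, graft_E2_mpa = 1.8,
              graft_nu12 = 0.16, graft_G12_mpa = 1,
              graft_G13_mpa = 60, graft_G23_mpa = 35,
              graft_thickness_mm = 0.2)
  class(out) <- "material_properties"
  out
}

#' Stent strut cross-section
#'
#' Rectangular strut profile of the stent wire as segmented from micro-CT.
#'
#' @param width_mm strut width (default 0.115 mm).
#' @param height_mm strut height (default 0.145 mm).
#' @return list with `width_mm`, `height_mm` and the rectangle's second moment
#'   of area about its bending axis, `I_mm4` = w h^3 / 12.
#' @export
strut_cross_section <- function(width_mm = 0.115, height_mm = 0.145) {
  if (width_mm <= 0 || height_mm <= 0)
    stop("strut dimensions must be positive")
  list(width_mm = width_mm, height_mm = height_mm,
       I_mm4 = width_mm * height_mm^3 / 12)
}

#' Bridging stent-graft catalog
#'
#' The twelve bridging stent-grafts of the study: for each of two patients and
#' both renal arteries, the nominally implanted device plus a shorter and a
#' longer commercially available size.
#'
#' @return data.frame with columns `patient` (1, 2), `artery` ("RRA", "LRA"),
#'   `size_class` ("shorter", "nominal", "longer"), `length_mm`, `diameter_mm`.
#' @export
sg_catalog <- function() {
  data.frame(
    patient = rep(c(1L, 2L), each = 6L),
    artery = rep(rep(c("RRA", "LRA"), each = 3L), 2L),
    size_class = rep(c("shorter", "nominal", "longer"), 4L),
    length_mm = c(18, 23, 27, 18, 22, 28,
                  18, 22, 28, 18, 22, 28),
    diameter_mm = c(7, 7, 7, 5, 5, 5,
                    6, 6, 6, 5, 5, 5),
    stringsAsFactors = FALSE)
}

#' Look up one catalog entry
#'
#' @param patient 1 or 2.
#' @param artery "RRA" or "LRA".
#' @param size_class "shorter", "nominal" or "longer".
#' @return one-row data.frame of class `sg_spec` (columns as [sg_catalog()]).
#' @export
sg_lookup <- function(patient, artery, size_class) {
  cat_ <- sg_catalog()
  row <- cat_[cat_$patient == patient & cat_$artery == artery &
                cat_$size_class == size_class, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("no catalog entry for patient ", patient, " ", artery, " ", size_class)
  class(row) <- c("sg_spec", class(row))
  row
}

#' Effective bending rigidity of the stented artery segment
#'
#' Reduces the device constants to the single number the rod model needs: the
#' composite bending rigidity (N mm^2) of artery + stent struts + graft tube.
#' Struts are `struts_per_ring` rectangular beams tied to the graft on the
#' tube wall, so they bend about the tube axis with both their own-axis
#' inertia and the parallel-axis term: I = n (w h^3/12 + A r^2/2) (the r^2/2
#' factor is the circumferential average of r^2 sin^2). The graft is a
#' thin-walled tube of its longitudinal modulus (E1 pi r^3 t). The composite
#' is always strictly stiffer than the bare artery.
#'
#' @param material [material_properties()].
#' @param cross_section [strut_cross_section()].
#' @param spec one catalog row ([sg_lookup()]) supplying the tube diameter.
#' @param struts_per_ring number of load-carrying struts in a circumferential
#'   ring (default 6; 0 disables the stent term for degenerate composites -
#'   the strut layout is a free design parameter and only the order of
#'   magnitude of the resulting stiffness ratio matters).
#' @param artery_rigidity bending rigidity of the unstented artery wall
#'   (N mm^2), > 0.
#' @return total composite rigidity in N mm^2.
#' @export
effective_bending_rigidity <- function(material = material_properties(),
                                       cross_section = strut_cross_section(),
                                       spec,
                                       struts_per_ring = 6,
                                       artery_rigidity) {
  if (struts_per_ring < 0) stop("invalid config: `struts_per_ring` must be >= 0")
  if (artery_rigidity <= 0) stop("invalid config: `artery_rigidity` must be > 0")
  if (material$graft_thickness_mm < 0) stop("invalid config: negative graft thickness")
  r <- spec$diameter_mm / 2
  if (r <= 0) stop("invalid config: non-positive stent diameter")
  A <- cross_section$width_mm * cross_section$height_mm
  stent <- struts_per_ring * material$stent_E_mpa *
    (cross_section$I_mm4 + A * r^2 / 2)
  graft <- material$graft_E1_mpa * pi * r^3 * material$graft_thickness_mm
  artery_rigidity + stent + graft
}

#' Midspan force in the three-point bending linear regime
#'
#' Simply-supported beam with a midspan point load: F = 48 EI delta / L^3.
#' The characterisation protocol caps the deflection at 3 mm to stay below the
#' Co-Cr plastic limit, so larger deflections are outside the model's validity
#' and raise an error.
#'
#' @param rigidity bending rigidity EI (N mm^2).
#' @param span_mm support span L (mm), > 0.
#' @param deflection_mm midspan deflection (mm), <= 3.
#' @return force in N.
#' @export
three_point_bending_force <- function(rigidity, span_mm, deflection_mm) {
  if (span_mm <= 0) stop("`span_mm` must be > 0")
  if (deflection_mm > 3)
    stop("out of validity: deflections beyond 3 mm enter the plastic regime, which is not modelled")
  48 * rigidity * deflection_mm / span_mm^3
}

#' Geometric deployment of a bridging stent-graft
#'
#' Places a stent-graft on a renal branch centerline as a purely geometric
#' surrogate for balloon deployment: the device occupies the ostium-anchored
#' arc-length interval `[-protrusion, length - protrusion]`, its proximal end
#' protruding into the aortic lumen and flared to the fenestration diameter.
#' No contact mechanics is modelled.
#'
#' @param branch renal `centerline` (arc length anchored at the ostium, s = 0).
#' @param spec one catalog row ([sg_lookup()]).
#' @param protrusion_target_mm intended protrusion past the ostium (mm, >= 0);
#'   clinically acceptable placements fall in the 3.4-4.3 mm band.
#' @param fenestration_diameter_mm flared proximal diameter (mm).
#' @return object of class `deployed_sg`: list with `spec`, `s_start`
#'   (= -protrusion), `s_end`, `protrusion_length_mm`, `flare_diameter_mm`.
#' @export
deploy_geometric <- function(branch, spec, protrusion_target_mm = 3.95,
                             fenestration_diameter_mm = 8) {
  if (protrusion_target_mm < 0)
    stop("`protrusion_target_mm` must be >= 0")
  L <- arc_length(branch)
  len <- spec$length_mm
  if (len - protrusion_target_mm > L + 1e-9)
    stop("deployment infeasible: stent length ", len,
         " mm exceeds protrusion + branch length (",
         round(protrusion_target_mm + L, 2), " mm)")
  out <- list(spec = spec,
              s_start = -protrusion_target_mm,
              s_end = len - protrusion_target_mm,
              protrusion_length_mm = protrusion_target_mm,
              flare_diameter_mm = fenestration_diameter_mm)
  class(out) <- "deployed_sg"
  out
}

#' @export
print.deployed_sg <- function(x, ...) {
  cat(sprintf(
    "<deployed SG %g x %g mm (%s): arc [%.2f, %.2f] mm, protrusion %.2f mm, flare %.1f mm>\n",
    x$spec$length_mm, x$spec$diameter_mm, x$spec$size_class,
    x$s_start, x$s_end, x$protrusion_length_mm, x$flare_diameter_mm))
  invisible(x)
}

#' Bending rigidity of the bare artery wall
#'
#' Thin-walled tube estimate E pi r^3 t for the unstented renal artery. Renal
#' wall properties are not separately characterised; the default modulus is a
#' low-strain arterial value and the result is a config parameter of the rod
#' model, not a measured constant.
#'
#' @param E_mpa wall elastic modulus (default 2 MPa).
#' @param radius_mm lumen radius (default 3 mm).
#' @param thickness_mm wall thickness (default 0.5 mm).
#' @return rigidity in N mm^2.
#' @export
artery_bending_rigidity <- function(E_mpa = 2, radius_mm = 3,
                                    thickness_mm = 0.5) {
  if (E_mpa <= 0 || radius_mm <= 0 || thickness_mm <= 0)
    stop("invalid config: artery properties must be positive")
  E_mpa * pi * radius_mm^3 * thickness_mm
}

#' Axial (stretch) stiffness of the bare artery wall
#'
#' Tube-section estimate E A = E 2 pi r t. Arteries are physiologically
#' extensible; this is the stiffness with which the rod model absorbs
#' along-vessel displacement components.
#'
#' @inheritParams artery_bending_rigidity
#' @return stiffness in N (force per unit strain).
#' @export
artery_stretch_stiffness <- function(E_mpa = 2, radius_mm = 3,
                                     thickness_mm = 0.5) {
  if (E_mpa <= 0 || radius_mm <= 0 || thickness_mm <= 0)
    stop("invalid config: artery properties must be positive")
  E_mpa * 2 * pi * radius_mm * thickness_mm
}
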