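#' Admission requirements for a CT series triplet
#'
#' The defaults encode the collection rules this pipeline assumes: a thin
#' axial series of 1-1.25 mm slices at an interval of 0.7-1.25 mm that never
#' exceeds the thickness, plus 5 mm / 5 mm thick axial and coronal series.
#'
#' @param thin_thickness_range Length-2 numeric, allowed thin-slice thickness (mm).
#' @param thin_interval_range Length-2 numeric, allowed thin-slice interval (mm);
#'   the interval must additionally be <= the thickness.
#' @param thick_thickness,thick_interval Required thick-series values (mm).
#' @param orthogonality_tol Tolerance passed to [check_orthogonality()].
#' @return An object of class `series_requirements`.
#' @export
series_requirements <- function(thin_thickness_range = c(1, 1.25),
                                thin_interval_range = c(0.7, 1.25),
                                thick_thickness = 5,
                                thick_interval = 5,
                                orthogonality_tol = 1e-3) {
  stopifnot(all(thin_thickness_range > 0), all(thin_interval_range > 0),
            thick_thickness > 0, thick_interval > 0,
            thin_interval_range[1] <= thin_thickness_range[2])
  structure(list(thin_thickness_range = thin_thickness_range,
                 thin_interval_range = thin_interval_range,
                 thick_thickness = thick_thickness,
                 thick_interval = thick_interval,
                 orthogonality_tol = orthogonality_tol),
            class = "series_requirements")
}

.slice_interval <- function(vol) {
  # computed from positions (geometry), not the thickness tag
  vol$geometry$spacing[3]
}

.slice_thickness <- function(vol) {
  as.numeric(vol$tags$SliceThickness %||% vol$geometry$spacing[3])
}

#' Validate a thin-axial / thick-axial / thick-coronal triplet
#'
#' Checks every admission rule individually and returns a tidy per-rule
#' report. A triplet is accepted iff the thin axial series has thickness in
#' [1, 1.25] mm and an interval in [0.7, 1.25] mm not exceeding the thickness,
#' both thick series are 5 mm thickness at 5 mm interval, and each axial
#' series is right-orthogonal to the coronal series.
#'
#' @param thin_axial,thick_axial,thick_coronal [ct_volume()] objects.
#' @param req A [series_requirements()].
#' @return A tibble with columns `rule`, `pass`, `detail` and an attribute
#'   `accepted`; use [triplet_accepted()] for the overall verdict.
#' @export
validate_triplet <- function(thin_axial, thick_axial, thick_coronal,
                             req = series_requirements()) {
  in_range <- function(x, r, tol = 1e-6) x >= r[1] - tol & x <= r[2] + tol
  near <- function(x, v, tol = 1e-6) abs(x - v) <= tol
  th_thin <- .slice_thickness(thin_axial); iv_thin <- .slice_interval(thin_axial)
  rules <- tibble::tibble(
    rule = c("thin_thickness", "thin_interval_range", "thin_interval_le_thickness",
             "thick_axial_thickness", "thick_axial_interval",
             "thick_coronal_thickness", "thick_coronal_interval",
             "orthogonal_thin_axial_coronal", "orthogonal_thick_axial_coronal"),
    pass = c(
      in_range(th_thin, req$thin_thickness_range),
      in_range(iv_thin, req$thin_interval_range),
      iv_thin <= th_thin + 1e-6,
      near(.slice_thickness(thick_axial), req$thick_thickness),
      near(.slice_interval(thick_axial), req$thick_interval),
      near(.slice_thickness(thick_coronal), req$thick_thickness),
      near(.slice_interval(thick_coronal), req$thick_interval),
      check_orthogonality(thin_axial$geometry, thick_coronal$geometry,
                          req$orthogonality_tol),
      check_orthogonality(thick_axial$geometry, thick_coronal$geometry,
                          req$orthogonality_tol)),
    detail = c(
      sprintf("thickness %.3g mm, allowed [%g, %g]", th_thin,
              req$thin_thickness_range[1], req$thin_thickness_range[2]),
      sprintf("interval %.3g mm, allowed [%g, %g]", iv_thin,
              req$thin_interval_range[1], req$thin_interval_range[2]),
      sprintf("interval %.3g mm vs thickness %.3g mm", iv_thin, th_thin),
      sprintf("thickness %.3g mm, required %g", .slice_thickness(thick_axial),
              req$thick_thickness),
      sprintf("interval %.3g mm, required %g", .slice_interval(thick_axial),
              req$thick_interval),
      sprintf("thickness %.3g mm, required %g", .slice_thickness(thick_coronal),
              req$thick_thickness),
      sprintf("interval %.3g mm, required %g", .slice_interval(thick_coronal),
              req$thick_interval),
      "thin-axial vs coronal slice normals / patient-axis alignment",
      "thick-axial vs coronal slice normals / patient-axis alignment"))
  attr(rules, "accepted") <- all(rules$pass)
  rules
}

#' Overall verdict of [validate_triplet()]
#'
#' @param report The tibble returned by [validate_triplet()].
#' @return `TRUE` iff every rule passed.
#' @export
triplet_accepted <- function(report) isTRUE(attr(report, "accepted"))
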