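#' LED emitter array
#'
#' A planar grid of identical LED emitters. Each emitter radiates with a
#' radially symmetric angular intensity, Gaussian in the polar angle theta,
#' reaching half its on-axis intensity at `half_angle_deg` (the datasheet's
#' "light within 24 degrees" cone read as a 12 degree half-angle). The
#' Fresnel lens and diffuser are not ray-traced: their effect is absorbed
#' into this effective angular profile plus an overall `transmission`
#' factor, which can be calibrated so the peak field matches a measured
#' irradiance (see [calibrate_transmission()]).
#'
#' @param n_side Emitters per side (default 5).
#' @param extent_mm Edge-to-edge span of the emitter grid (mm, default 33,
#'   i.e. a pitch of extent/(n_side - 1)).
#' @param power_mW Optical power per emitter (mW, default 520).
#' @param half_angle_deg Half-intensity half-angle (degrees, default 12).
#' @param transmission Power fraction reaching the sample plane (default 1).
#' @return A list of class `pdt_emitter_array` with an `emitters` tibble
#'   (x_mm, y_mm, power_mW) centred on the origin.
#' @export
emitter_array <- function(n_side = 5, extent_mm = 33, power_mW = 520,
                          half_angle_deg = 12, transmission = 1) {
  if (power_mW <= 0) abort("emitter power must be positive")
  if (half_angle_deg <= 0 || half_angle_deg >= 90) {
    abort("half angle must lie in (0, 90) degrees")
  }
  coords <- if (n_side == 1) 0 else seq(-extent_mm / 2, extent_mm / 2,
                                        length.out = n_side)
  grid <- expand.grid(x_mm = coords, y_mm = coords)
  structure(
    list(
      emitters = tibble(x_mm = grid$x_mm, y_mm = grid$y_mm,
                        power_mW = power_mW),
      half_angle_deg = half_angle_deg,
      transmission = transmission
    ),
    class = "pdt_emitter_array"
  )
}

# on-axis radiant intensity (mW/sr) for a Gaussian-in-theta profile of unit
# power: 1 / integral over the hemisphere of exp(-ln2 theta^2/th^2) dOmega
gaussian_profile_norm <- function(half_angle_rad) {
  integrand <- function(theta) {
    exp(-log(2) * (theta / half_angle_rad)^2) * 2 * pi * sin(theta)
  }
  1 / stats::integrate(integrand, 0, pi / 2, rel.tol = 1e-10)$value
}

#' Simulate the irradiance field on the sample plane
#'
#' Superposes per-emitter contributions: Gaussian angular intensity,
#' inverse-square distance falloff and cosine obliquity. For a plane wide
#' enough to catch the whole beam, the plane-integrated power equals the
#' emitted power times the transmission factor (the solid-angle integral is
#' exact), which the tests verify to within 2%.
#'
#' @param array A [emitter_array()].
#' @param z_mm Height of the sample plane above the emitters (mm), > 0.
#' @param grid_mm Either a single spacing (mm) for a default square window,
#'   or a list with components `x` and `y` giving the grid coordinates.
#' @param window_mm Half-width of the default square window (mm, default 40).
#' @return A list of class `pdt_field`: matrix `irradiance_mWcm2`
#'   (rows = y, cols = x), vectors `x_mm`, `y_mm`, and `z_mm`.
#' @export
simulate_field <- function(array, z_mm = 25.4, grid_mm = 0.5,
                           window_mm = 40) {
  if (z_mm <= 0) abort("sample plane height must be positive")
  if (is.list(grid_mm)) {
    x <- grid_mm$x
    y <- grid_mm$y
  } else {
    x <- seq(-window_mm, window_mm, by = grid_mm)
    y <- seq(-window_mm, window_mm, by = grid_mm)
  }
  if (length(x) == 0 || length(y) == 0) abort("field grid is empty")
  half_rad <- array$half_angle_deg * pi / 180
  norm <- gaussian_profile_norm(half_rad)

  px <- matrix(rep(x, each = length(y)), nrow = length(y))
  py <- matrix(rep(y, times = length(x)), nrow = length(y))
  e_mWmm2 <- matrix(0, nrow = length(y), ncol = length(x))
  for (i in seq_len(nrow(array$emitters))) {
    em <- array$emitters[i, ]
    dx <- px - em$x_mm
    dy <- py - em$y_mm
    r2 <- dx^2 + dy^2 + z_mm^2
    cos_th <- z_mm / sqrt(r2)
    theta <- acos(pmin(cos_th, 1))
    intensity <- em$power_mW * norm * exp(-log(2) * (theta / half_rad)^2)
    e_mWmm2 <- e_mWmm2 + intensity * cos_th / r2
  }
  structure(
    list(
      irradiance_mWcm2 = e_mWmm2 * 100 * array$transmission,  # mm^-2 -> cm^-2
      x_mm = x, y_mm = y, z_mm = z_mm
    ),
    class = "pdt_field"
  )
}

#' Circular Gaussian beam field (laser comparator)
#'
#' Irradiance E(r) = E0 exp(-2 r^2 / w^2), the flattened laser beam profile
#' the LED array is compared against. The waist is configuration: the
#' builders' laser beam radius is not published.
#'
#' @param waist_mm 1/e^2 beam radius (mm), default 25.4.
#' @param peak_mWcm2 On-axis irradiance (mW/cm2).
#' @param grid_mm,window_mm As in [simulate_field()].
#' @param center_mm Beam centre (x, y) in mm.
#' @return A `pdt_field`.
#' @export
gaussian_laser_field <- function(waist_mm = 25.4, peak_mWcm2 = 100,
                                 grid_mm = 0.5, window_mm = 40,
                                 center_mm = c(0, 0)) {
  if (waist_mm <= 0) abort("waist must be positive")
  x <- seq(-window_mm, window_mm, by = grid_mm)
  y <- seq(-window_mm, window_mm, by = grid_mm)
  px <- matrix(rep(x, each = length(y)), nrow = length(y))
  py <- matrix(rep(y, times = length(x)), nrow = length(y))
  r2 <- (px - center_mm[1])^2 + (py - center_mm[2])^2
  structure(
    list(irradiance_mWcm2 = peak_mWcm2 * exp(-2 * r2 / waist_mm^2),
         x_mm = x, y_mm = y, z_mm = NA_real_),
    class = "pdt_field"
  )
}

#' Integrate a field over its plane
#'
#' @param field A `pdt_field`.
#' @return Total power in mW (trapezoid in both axes).
#' @export
field_power_mW <- function(field) {
  # mW/cm2 over mm grid: / 100 converts to mW/mm2
  inner <- apply(field$irradiance_mWcm2 / 100, 2,
                 function(col) pracma::trapz(field$y_mm, col))
  pracma::trapz(field$x_mm, inner)
}

#' Rescale an array's transmission so the simulated peak hits a target
#'
#' @param array A [emitter_array()].
#' @param peak_mWcm2 Target peak irradiance at full duty (mW/cm2), e.g. the
#'   measured 400 mW/cm2 system maximum.
#' @param z_mm,grid_mm Field evaluation parameters.
#' @return The array with `transmission` adjusted.
#' @export
calibrate_transmission <- function(array, peak_mWcm2, z_mm = 25.4,
                                   grid_mm = 0.5) {
  f <- simulate_field(array, z_mm = z_mm, grid_mm = grid_mm)
  array$transmission <- array$transmission * peak_mWcm2 /
    max(f$irradiance_mWcm2)
  array
}

#' Rectangular aperture mask
#'
#' The spatial light filter is an opaque sheet with rectangular openings
#' that restrict illumination to the wells of interest (3x3, 2x3 or 2x2
#' footprints). A mask is a list of open rectangles; a point is illuminated
#' when it falls inside any of them.
#'
#' @param rects A data frame with columns `x0_mm`, `x1_mm`, `y0_mm`,
#'   `y1_mm`, one row per open rectangle; `NULL` for a fully open mask.
#' @return A list of class `pdt_mask`.
#' @export
aperture_mask <- function(rects = NULL) {
  if (!is.null(rects)) {
    need <- c("x0_mm", "x1_mm", "y0_mm", "y1_mm")
    if (!all(need %in% names(rects))) {
      abort(sprintf("mask rectangles need columns %s", paste(need, collapse = ", ")))
    }
    rects <- as_tibble(rects)
  }
  structure(list(rects = rects), class = "pdt_mask")
}

#' @rdname aperture_mask
#' @export
closed_mask <- function() {
  # an empty (inverted) rectangle: no point can satisfy it
  aperture_mask(tibble(x0_mm = 0, x1_mm = -1, y0_mm = 0, y1_mm = -1))
}

point_in_mask <- function(mask, x, y) {
  if (is.null(mask$rects)) return(rep(TRUE, length(x)))
  open <- rep(FALSE, length(x))
  for (i in seq_len(nrow(mask$rects))) {
    r <- mask$rects[i, ]
    open <- open | (x >= r$x0_mm & x <= r$x1_mm & y >= r$y0_mm & y <= r$y1_mm)
  }
  open
}

#' Open-aperture mask over a group of wells
#'
#' Builds a single rectangular opening covering the given wells plus half a
#' pitch of margin on each side - the footprint the spatial filter exposes
#' for one visit.
#'
#' @param wells Character well names.
#' @param format A [plate_format()].
#' @param margin_mm Margin beyond the outer well centres (default half the
#'   pitch).
#' @return A `pdt_mask`.
#' @export
group_mask <- function(wells, format = plate_format_96(), margin_mm = NULL) {
  pos <- well_position(wells, format)
  margin_mm <- margin_mm %||% (format$well_pitch_mm / 2)
  aperture_mask(tibble(
    x0_mm = min(pos$x_mm) - margin_mm, x1_mm = max(pos$x_mm) + margin_mm,
    y0_mm = min(pos$y_mm) - margin_mm, y1_mm = max(pos$y_mm) + margin_mm
  ))
}

#' Apply an aperture mask to a field
#'
#' @param field A `pdt_field`.
#' @param mask A [aperture_mask()].
#' @return The field with irradiance zeroed outside the open region.
#' @export
mask_field <- function(field, mask) {
  px <- matrix(rep(field$x_mm, each = length(field$y_mm)),
               nrow = length(field$y_mm))
  py <- matrix(rep(field$y_mm, times = length(field$x_mm)),
               nrow = length(field$y_mm))
  open <- matrix(point_in_mask(mask, as.vector(px), as.vector(py)),
                 nrow = length(field$y_mm))
  field$irradiance_mWcm2 <- field$irradiance_mWcm2 * open
  field
}

#' Mean irradiance over each well's footprint
#'
#' Averages the field over each well's disc footprint; wells whose centres
#' fall under a closed region of the mask report 0.
#'
#' @param field A `pdt_field`.
#' @param wells Character well names.
#' @param format A [plate_format()]; well centres are taken in the field's
#'   coordinate frame (set `a1_offset_mm` accordingly).
#' @param mask Optional [aperture_mask()].
#' @return A tibble with columns `well`, `mean_mWcm2`.
#' @export
per_well_irradiance <- function(field, wells, format = plate_format_96(),
                                mask = NULL) {
  pos <- well_position(wells, format)
  radius <- format$well_diameter_mm / 2
  rng_x <- range(field$x_mm)
  rng_y <- range(field$y_mm)
  if (any(pos$x_mm - radius < rng_x[1] | pos$x_mm + radius > rng_x[2] |
            pos$y_mm - radius < rng_y[1] | pos$y_mm + radius > rng_y[2])) {
    abort("well footprint extends outside the simulated field grid")
  }
  f <- if (is.null(mask)) field else mask_field(field, mask)
  means <- purrr::map2_dbl(pos$x_mm, pos$y_mm, function(wx, wy) {
    if (!is.null(mask) && !point_in_mask(mask, wx, wy)) return(0)
    ix <- which(abs(f$x_mm - wx) <= radius)
    iy <- which(abs(f$y_mm - wy) <= radius)
    sub_x <- f$x_mm[ix]
    sub_y <- f$y_mm[iy]
    dx <- matrix(rep(sub_x - wx, each = length(sub_y)), nrow = length(sub_y))
    dy <- matrix(rep(sub_y - wy, times = length(sub_x)), nrow = length(sub_y))
    inside <- dx^2 + dy^2 <= radius^2
    vals <- f$irradiance_mWcm2[iy, ix, drop = FALSE]
    mean(vals[inside])
  })
  tibble(well = pos$well, mean_mWcm2 = means)
}

#' Centre-versus-corner uniformity metric for a 3x3 well group
#'
#' 100 * (centre - min(corners)) / centre: the relative power shortfall of
#' the least-illuminated corner well against the centre well.
#'
#' @param per_well Nine per-well mean irradiances: either a 3x3 matrix or a
#'   length-9 vector in row-major order (centre = element 5).
#' @return Percent difference (0 for a perfectly flat field).
#' @examples
#' uniformity_metric(matrix(c(90, 95, 90, 95, 100, 95, 90, 95, 90), 3))
#' @export
uniformity_metric <- function(per_well) {
  v <- as.numeric(per_well)
  if (length(v) != 9) abort("uniformity metric needs exactly 9 well means")
  center <- v[5]
  if (center <= 0) abort("centre well irradiance must be positive")
  corners <- v[c(1, 3, 7, 9)]
  100 * (center - min(corners)) / center
}

#' @export
print.pdt_field <- function(x, ...) {
  cat(sprintf(
    "<irradiance field: %d x %d grid, peak %.4g mW/cm2%s>\n",
    length(x$y_mm), length(x$x_mm), max(x$irradiance_mWcm2),
    if (is.na(x$z_mm)) "" else sprintf(" at z = %.4g mm", x$z_mm)
  ))
  invisible(x)
}

#' @export
autoplot.pdt_field <- function(object, ...) {
  df <- tidyr::expand_grid(y_mm = object$y_mm, x_mm = object$x_mm)
  df$irradiance_mWcm2 <- as.vector(t(object$irradiance_mWcm2))
  ggplot2::ggplot(df, ggplot2::aes(.data$x_mm, .data$y_mm,
                                   fill = .data$irradiance_mWcm2)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "mW/cm²") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}
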