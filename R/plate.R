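#' Multiwell plate format
#'
#' Geometry of a standard rectangular multiwell plate. Defaults follow the
#' ANSI/SLAS footprint: 9.0 mm well pitch for 96-well plates, 19.3 mm for
#' 24-well plates.
#'
#' @param n_rows,n_cols Plate dimensions (8 x 12 for 96-well).
#' @param well_pitch_mm Centre-to-centre well spacing (mm).
#' @param a1_offset_mm Length-2 numeric, (x, y) of well A1's centre in the
#'   plate coordinate frame (mm).
#' @param well_diameter_mm Well diameter (mm), used for footprint averaging.
#' @return A list of class `pdt_plate_format`.
#' @export
plate_format <- function(n_rows = 8, n_cols = 12, well_pitch_mm = 9,
                         a1_offset_mm = c(0, 0), well_diameter_mm = 6.4) {
  if (well_pitch_mm <= 0) abort("well pitch must be positive")
  if (n_rows < 1 || n_cols < 1) abort("plate must have at least one well")
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         well_pitch_mm = well_pitch_mm,
         a1_offset_mm = as.numeric(a1_offset_mm),
         well_diameter_mm = well_diameter_mm),
    class = "pdt_plate_format"
  )
}

#' @rdname plate_format
#' @export
plate_format_96 <- function() plate_format(8, 12, 9, well_diameter_mm = 6.4)

#' @rdname plate_format
#' @export
plate_format_24 <- function() plate_format(4, 6, 19.3, well_diameter_mm = 15.6)

#' Convert between well names and indices/positions
#'
#' Wells are named in the "A1" convention (row letter + 1-based column).
#' Internally the package uses 0-based (row, col) indices; names appear only
#' at parse/serialize boundaries.
#'
#' @param well Character vector of well names ("A1", "H12", ...).
#' @param format A [plate_format()].
#' @return `parse_wells()`: tibble with columns `well`, `row`, `col`
#'   (0-based). `well_name()`: character names from 0-based indices.
#'   `well_position()`: tibble with `well`, `x_mm`, `y_mm` of well centres.
#' @export
parse_wells <- function(well, format = plate_format_96()) {
  m <- regmatches(well, regexec("^([A-Za-z])([0-9]+)$", well))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    abort(sprintf("malformed well name(s): %s",
                  paste(well[bad], collapse = ", ")))
  }
  row <- match(toupper(vapply(m, `[`, "", 2L)), LETTERS) - 1L
  col <- as.integer(vapply(m, `[`, "", 3L)) - 1L
  out_of_range <- row >= format$n_rows | col >= format$n_cols | col < 0
  if (any(out_of_range)) {
    abort(sprintf("well(s) outside the %dx%d plate: %s",
                  format$n_rows, format$n_cols,
                  paste(well[out_of_range], collapse = ", ")))
  }
  tibble(well = as.character(well), row = row, col = col)
}

#' @rdname parse_wells
#' @param row,col 0-based indices.
#' @export
well_name <- function(row, col) paste0(LETTERS[row + 1L], col + 1L)

#' @rdname parse_wells
#' @export
well_position <- function(well, format = plate_format_96()) {
  idx <- parse_wells(well, format)
  tibble(
    well = idx$well,
    x_mm = format$a1_offset_mm[1] + idx$col * format$well_pitch_mm,
    y_mm = format$a1_offset_mm[2] + idx$row * format$well_pitch_mm
  )
}

control_roles <- c("DNL", "LND", "NDNL", "MO")

#' Build a plate layout
#'
#' A layout assigns wells to labelled experimental groups. Each group has a
#' role: `treatment` (photosensitizer + light, with a per-group light dose),
#' or one of the four controls - `DNL` (drug, no light), `LND` (light, no
#' drug), `NDNL` (no drug, no light; defines 100% viability) and `MO`
#' (media only; defines 0% viability).
#'
#' @param groups A data frame with columns `group`, `role` (one of
#'   "treatment", "DNL", "LND", "NDNL", "MO"), `wells` (list-column of well
#'   name vectors, or a comma-separated string) and `dose_Jcm2`.
#' @param format A [plate_format()].
#' @param replicates Declared replicate count per group (default: the modal
#'   group size), checked by [validate_layout()]; `NA` skips the check for
#'   layouts with intentionally unequal group sizes.
#' @return A tibble of class `pdt_layout` with one row per well: `group`,
#'   `role`, `well`, `dose_Jcm2`; the format and replicate count are carried
#'   as attributes.
#' @export
plate_layout <- function(groups, format = plate_format_96(),
                         replicates = NULL) {
  need <- c("group", "role", "wells", "dose_Jcm2")
  if (!all(need %in% names(groups))) {
    abort(sprintf("layout groups need columns %s", paste(need, collapse = ", ")))
  }
  if (!is.list(groups$wells)) {
    groups$wells <- strsplit(gsub(" ", "", groups$wells), ",")
  }
  long <- tidyr::unnest(as_tibble(groups), "wells") |>
    dplyr::rename(well = "wells") |>
    dplyr::select("group", "role", "well", "dose_Jcm2")
  parse_wells(long$well, format)  # validates names against the format
  bad_role <- setdiff(unique(long$role), c("treatment", control_roles))
  if (length(bad_role) > 0) {
    abort(sprintf("unknown role(s): %s", paste(bad_role, collapse = ", ")))
  }
  if (is.null(replicates)) {
    sizes <- table(long$group)
    replicates <- as.integer(names(sort(table(sizes), decreasing = TRUE))[1])
  }
  structure(
    long,
    format = format,
    replicates = as.integer(replicates),
    class = c("pdt_layout", class(long))
  )
}

#' The canonical staggered dose-response layout for a 96-well plate
#'
#' Sixteen groups of six wells each (2 rows x 3 columns per group): two
#' staggered treatment series over the standard dose ladder plus the four
#' controls. The two series are interleaved so that no two groups sharing a
#' dose sit in edge-adjacent illumination footprints - a misalignment of the
#' automated stage then produces a visibly wrong dose pattern instead of a
#' silently swapped replicate.
#'
#' @param doses_Jcm2 Dose ladder for each treatment series (default
#'   2, 4, 6, 8, 10, 12 J/cm2).
#' @return A `pdt_layout` on a 96-well plate, with the group footprint
#'   (2 x 3) recorded in the `footprint` attribute.
#' @export
canonical_layout_96 <- function(doses_Jcm2 = c(2, 4, 6, 8, 10, 12)) {
  stopifnot(length(doses_Jcm2) == 6)
  d <- doses_Jcm2
  # 4 x 4 grid of 2x3 well blocks; doses staggered between series 1 and 2
  spec <- list(
    list("PDT1_a", "treatment", d[1]), list("PDT1_b", "treatment", d[2]),
    list("PDT1_c", "treatment", d[3]), list("PDT1_d", "treatment", d[4]),
    list("PDT2_b", "treatment", d[2]), list("PDT2_a", "treatment", d[1]),
    list("PDT2_d", "treatment", d[4]), list("PDT2_c", "treatment", d[3]),
    list("PDT1_e", "treatment", d[5]), list("PDT1_f", "treatment", d[6]),
    list("DNL", "DNL", 0), list("NDNL", "NDNL", 0),
    list("PDT2_f", "treatment", d[6]), list("PDT2_e", "treatment", d[5]),
    list("LND", "LND", max(d)), list("MO", "MO", 0)
  )
  rows <- purrr::imap_dfr(spec, function(g, i) {
    block_row <- (i - 1) %/% 4
    block_col <- (i - 1) %% 4
    wr <- block_row * 2 + 0:1
    wc <- block_col * 3 + 0:2
    grid <- expand.grid(row = wr, col = wc)
    tibble(group = g[[1]], role = g[[2]],
           wells = list(well_name(grid$row, grid$col)), dose_Jcm2 = g[[3]])
  })
  out <- plate_layout(rows, plate_format_96(), replicates = 6L)
  attr(out, "footprint") <- c(2L, 3L)
  out
}

#' Validate a plate layout
#'
#' @param layout A [plate_layout()].
#' @param staggered Also check the staggered-alignment rule: no two groups
#'   with the same (nonzero) dose may occupy edge-adjacent illumination
#'   footprints (default FALSE).
#' @return Character vector of violations; empty when the layout is valid.
#' @export
validate_layout <- function(layout, staggered = FALSE) {
  violations <- character()
  dup <- unique(layout$well[duplicated(layout$well)])
  for (w in dup) {
    violations <- c(violations, sprintf("well assigned twice: %s", w))
  }
  for (role in control_roles) {
    if (!role %in% layout$role) {
      violations <- c(violations, sprintf("missing control: %s", role))
    }
  }
  reps <- attr(layout, "replicates")
  if (!is.null(reps) && !is.na(reps)) {
    sizes <- dplyr::count(as_tibble(layout), .data$group)
    off <- sizes[sizes$n != reps, ]
    for (i in seq_len(nrow(off))) {
      violations <- c(violations, sprintf(
        "group %s has %d wells, expected %d replicates",
        off$group[i], off$n[i], reps
      ))
    }
  }
  if (staggered) {
    violations <- c(violations, check_stagger(layout))
  }
  violations
}

# staggered-alignment rule: groups sharing a nonzero dose must not sit in
# edge-adjacent footprints (footprint = bounding block of the group's wells)
check_stagger <- function(layout) {
  fmt <- attr(layout, "format") %||% plate_format_96()
  idx <- parse_wells(layout$well, fmt)
  g <- dplyr::group_by(
    tibble(group = layout$group, dose = layout$dose_Jcm2,
           row = idx$row, col = idx$col),
    .data$group, .data$dose
  ) |>
    dplyr::summarise(r0 = min(.data$row), r1 = max(.data$row),
                     c0 = min(.data$col), c1 = max(.data$col),
                     .groups = "drop") |>
    dplyr::filter(.data$dose > 0)
  out <- character()
  if (nrow(g) < 2) return(out)
  for (i in seq_len(nrow(g) - 1)) {
    for (j in seq(i + 1, nrow(g))) {
      if (g$dose[i] != g$dose[j]) next
      row_gap <- max(g$r0[i], g$r0[j]) - min(g$r1[i], g$r1[j])
      col_gap <- max(g$c0[i], g$c0[j]) - min(g$c1[i], g$c1[j])
      # edge-adjacent: touching in one axis, overlapping in the other
      if ((row_gap == 1 && col_gap <= 0) || (col_gap == 1 && row_gap <= 0)) {
        out <- c(out, sprintf(
          "staggering violated: groups %s and %s share dose %g in adjacent footprints",
          g$group[i], g$group[j], g$dose[i]
        ))
      }
    }
  }
  out
}

#' Layout JSON serialization
#'
#' The interchange format is
#' `{"format": {...}, "groups": [{"label", "role", "wells", "dose_Jcm2"}]}`.
#'
#' @param path File path.
#' @return `read_layout_json()` returns a `pdt_layout`;
#'   `write_layout_json()` returns `path` invisibly.
#' @export
read_layout_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fmt <- plate_format(
    n_rows = obj$format$n_rows, n_cols = obj$format$n_cols,
    well_pitch_mm = obj$format$well_pitch_mm,
    a1_offset_mm = obj$format$a1_offset_mm %||% c(0, 0),
    well_diameter_mm = obj$format$well_diameter_mm %||% 6.4
  )
  groups <- as_tibble(obj$groups)
  names(groups)[names(groups) == "label"] <- "group"
  if (!is.list(groups$wells)) groups$wells <- as.list(groups$wells)
  plate_layout(groups, fmt, replicates = obj$replicates)
}

#' @rdname read_layout_json
#' @param layout A `pdt_layout`.
#' @export
write_layout_json <- function(layout, path) {
  fmt <- attr(layout, "format")
  groups <- dplyr::group_by(as_tibble(layout), .data$group, .data$role,
                            .data$dose_Jcm2) |>
    dplyr::summarise(wells = list(.data$well), .groups = "drop") |>
    dplyr::rename(label = "group")
  jsonlite::write_json(
    list(
      format = fmt[c("n_rows", "n_cols", "well_pitch_mm", "a1_offset_mm",
                     "well_diameter_mm")],
      replicates = attr(layout, "replicates"),
      groups = groups
    ),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Stepper-motor motion configuration
#'
#' Two independent linear screw axes move the plate. The per-step travel is
#' configurable; the default 25 um/step follows the builders' stated motion
#' precision (note a 5 mm screw pitch at 400 steps/rotation works out to
#' 12.5 um, so check your own hardware).
#'
#' @param step_size_um Linear travel per motor step (um), default 25.
#' @return A list of class `pdt_motion_config`.
#' @export
motion_config <- function(step_size_um = 25) {
  if (step_size_um <= 0) abort("step size must be positive")
  structure(list(step_size_um = step_size_um), class = "pdt_motion_config")
}

#' Convert a plate displacement to motor steps
#'
#' @param from_mm,to_mm Length-2 numeric (x, y) positions in mm.
#' @param cfg A [motion_config()].
#' @return A tibble with one row per axis: `axis`, `steps` (non-negative
#'   count), `direction` (-1, 0, 1) and `residual_mm` (signed placement
#'   error after rounding to whole steps; always within half a step).
#' @export
motion_steps <- function(from_mm, to_mm, cfg = motion_config()) {
  delta <- as.numeric(to_mm) - as.numeric(from_mm)
  if (any(!is.finite(delta))) abort("coordinates must be finite")
  step_mm <- cfg$step_size_um / 1000
  steps <- round(abs(delta) / step_mm)
  tibble(
    axis = c("x", "y"),
    steps = as.integer(steps),
    direction = as.integer(sign(delta)),
    residual_mm = abs(delta) - steps * step_mm
  )
}
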