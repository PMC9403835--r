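#' Histological shrinkage factor
#'
#' Ratio between the fresh brain volume and the brain volume after
#' histological treatment (embedding shrinks the tissue); multiplying
#' histological volumes by this factor restores fresh-tissue scale.
#'
#' @param fresh_volume,processed_volume volumes in the same unit, both > 0.
#' @return tibble: `fresh_volume`, `processed_volume`, `factor`.
#' @export
#' @examples
#' shrinkage_factor(1349, 700)
shrinkage_factor <- function(fresh_volume, processed_volume) {
  if (any(fresh_volume <= 0) || any(processed_volume <= 0)) {
    abort("volumes must be > 0.")
  }
  tibble(fresh_volume = fresh_volume, processed_volume = processed_volume,
         factor = fresh_volume / processed_volume)
}

#' Cavalieri volume estimate from serial-section areas
#'
#' Volume = shrinkage factor x section spacing x sum of cross-sectional
#' areas, the Cavalieri estimator over equidistant sections (default
#' spacing 1.2 mm, i.e. at least every 60th 20-um section measured).
#'
#' @param measurements data frame with one row per measured section;
#'   must contain `cross_section_area_mm2`, and is typically grouped
#'   beforehand by brain, hemisphere and area. Alternatively a numeric
#'   vector of areas.
#' @param section_spacing_mm distance between measured sections (scalar;
#'   mixed spacings require explicit per-gap handling upstream and are
#'   rejected here).
#' @param factor shrinkage correction factor.
#' @return volume in mm^3 (numeric scalar), or — if `measurements` is a
#'   grouped data frame — a tibble with one `volume_mm3` per group.
#' @export
cavalieri_volume <- function(measurements, section_spacing_mm = 1.2,
                             factor = 1) {
  if (length(section_spacing_mm) != 1L) {
    abort("mixed section spacings are not supported; give one spacing per series.")
  }
  stop_if_not_number(section_spacing_mm, "section_spacing_mm", positive = TRUE)
  if (is.numeric(measurements)) {
    if (!length(measurements)) abort("need at least one measurement.")
    return(factor * section_spacing_mm * sum(measurements))
  }
  if (!"cross_section_area_mm2" %in% names(measurements)) {
    abort("`measurements` must have a `cross_section_area_mm2` column.")
  }
  dplyr::summarise(
    measurements,
    volume_mm3 = factor * section_spacing_mm * sum(.data$cross_section_area_mm2),
    .groups = "drop"
  )
}

#' Normalize an area volume to whole-brain volume
#'
#' @param volume area volume.
#' @param whole_brain_volume whole-brain volume in the same unit, > 0.
#' @return the volume fraction.
#' @export
normalize_volume <- function(volume, whole_brain_volume) {
  if (any(whole_brain_volume <= 0)) abort("`whole_brain_volume` must be > 0.")
  volume / whole_brain_volume
}

#' Group aggregates of a per-brain volume table
#'
#' Computes the descriptive surface of a per-brain x hemisphere x area
#' volume table: per-cell means and sample SDs by sex, bilateral (left +
#' right) per-brain area volumes with group aggregates, per-brain
#' hemisphere totals and whole (bilateral) totals, each summarized by sex
#' and over all brains. Sample SDs use n - 1. Values are returned at full
#' precision; round with [round_half_away()] when comparing against
#' printed integer tables.
#'
#' @param records data frame with columns `brain`, `sex`, `hemisphere`
#'   (`"left"`/`"right"`), `area`, `volume_mm3`. Every brain must have a
#'   complete set of hemisphere x area cells.
#' @return an object of class `volume_summary`: list of tibbles `cells`
#'   (sex, hemisphere, area, n, mean, sd), `areas_bilateral` (area, n,
#'   mean, sd over per-brain left+right sums), `hemisphere_totals` (sex
#'   incl. `"all"`, hemisphere, n, mean, sd over per-brain totals) and
#'   `brain_totals` (sex incl. `"all"`, n, mean, sd over per-brain
#'   bilateral totals).
#' @export
aggregate_table <- function(records) {
  needed <- c("brain", "sex", "hemisphere", "area", "volume_mm3")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  records <- as_tibble(records)
  # completeness: every brain must have every hemisphere x area cell once
  grid <- tidyr::expand_grid(brain = unique(records$brain),
                             hemisphere = unique(records$hemisphere),
                             area = unique(records$area))
  have <- dplyr::count(records, .data$brain, .data$hemisphere, .data$area)
  miss <- dplyr::anti_join(grid, have, by = c("brain", "hemisphere", "area"))
  if (nrow(miss)) {
    abort(paste0("incomplete table; missing cell(s): ",
                 paste(utils::head(paste(miss$brain, miss$hemisphere, miss$area,
                                         sep = "/"), 5), collapse = ", ")))
  }

  cells <- records |>
    dplyr::group_by(.data$sex, .data$hemisphere, .data$area) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$volume_mm3),
                     sd = sd(.data$volume_mm3), .groups = "drop")

  bilateral <- records |>
    dplyr::group_by(.data$brain, .data$sex, .data$area) |>
    dplyr::summarise(volume_mm3 = sum(.data$volume_mm3), .groups = "drop")
  areas_bilateral <- bilateral |>
    dplyr::group_by(.data$area) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$volume_mm3),
                     sd = sd(.data$volume_mm3), .groups = "drop")

  hemi <- records |>
    dplyr::group_by(.data$brain, .data$sex, .data$hemisphere) |>
    dplyr::summarise(volume_mm3 = sum(.data$volume_mm3), .groups = "drop")
  hemisphere_totals <- dplyr::bind_rows(
    hemi |>
      dplyr::group_by(sex = as.character(.data$sex), .data$hemisphere) |>
      dplyr::summarise(n = dplyr::n(), mean = mean(.data$volume_mm3),
                       sd = sd(.data$volume_mm3), .groups = "drop"),
    hemi |>
      dplyr::group_by(.data$hemisphere) |>
      dplyr::summarise(sex = "all", n = dplyr::n(), mean = mean(.data$volume_mm3),
                       sd = sd(.data$volume_mm3), .groups = "drop")
  )

  totals <- hemi |>
    dplyr::group_by(.data$brain, .data$sex) |>
    dplyr::summarise(volume_mm3 = sum(.data$volume_mm3), .groups = "drop")
  brain_totals <- dplyr::bind_rows(
    totals |>
      dplyr::group_by(sex = as.character(.data$sex)) |>
      dplyr::summarise(n = dplyr::n(), mean = mean(.data$volume_mm3),
                       sd = sd(.data$volume_mm3), .groups = "drop"),
    totals |>
      dplyr::summarise(sex = "all", n = dplyr::n(), mean = mean(.data$volume_mm3),
                       sd = sd(.data$volume_mm3))
  )

  structure(list(cells = cells, areas_bilateral = areas_bilateral,
                 hemisphere_totals = hemisphere_totals,
                 brain_totals = brain_totals),
            class = "volume_summary")
}

#' @export
print.volume_summary <- function(x, ...) {
  cat("<volume_summary>\n## cells (sex x hemisphere x area)\n")
  print(x$cells, n = Inf)
  cat("## bilateral area volumes\n")
  print(x$areas_bilateral)
  cat("## hemisphere totals\n")
  print(x$hemisphere_totals)
  cat("## bilateral totals\n")
  print(x$brain_totals)
  invisible(x)
}

#' @export
tidy.volume_summary <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$cells, statistic = "cell", .before = 1),
    dplyr::mutate(x$areas_bilateral, statistic = "area_bilateral", .before = 1),
    dplyr::mutate(x$hemisphere_totals, statistic = "hemisphere_total", .before = 1),
    dplyr::mutate(x$brain_totals, statistic = "brain_total", .before = 1)
  )
}
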