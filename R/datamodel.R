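#' Construct a single stage measurement record
#'
#' The unit record of the analysis: one embryo at one developmental stage,
#' with its 3D morphometric quantities. All lengths are in um, areas in
#' um^2, volumes in um^3, times in hours post fertilization (hpf).
#'
#' @param embryo_id opaque label.
#' @param stage_hpf stage, hours post fertilization.
#' @param tissue_volume tissue volume, um^3.
#' @param apical_area apical tissue surface area, um^2.
#' @param total_surface_area total tissue surface area, um^2 (must exceed
#'   `apical_area`; basal area is the difference).
#' @param thickness_samples numeric vector of thickness measurements, um
#'   (nominally 5 positions; at least 1).
#' @param n_cells total cell count.
#' @param n_mitotic mitotic cell count.
#' @param mitotic_diameters numeric vector of mitotic cell diameters, um
#'   (may be empty; only 15-20 cells/retina are measured).
#' @param nuclear_zone_height height of the nuclear zone, um.
#' @param nuclear_long_axis mean nuclear long axis, um.
#' @return A list of class `stage_measurement`.
#' @export
stage_measurement <- function(embryo_id, stage_hpf, tissue_volume,
                              apical_area, total_surface_area,
                              thickness_samples, n_cells, n_mitotic,
                              mitotic_diameters = numeric(0),
                              nuclear_zone_height, nuclear_long_axis) {
  m <- structure(list(
    embryo_id = as.character(embryo_id), stage_hpf = as.numeric(stage_hpf),
    tissue_volume = as.numeric(tissue_volume),
    apical_area = as.numeric(apical_area),
    total_surface_area = as.numeric(total_surface_area),
    thickness_samples = as.numeric(thickness_samples),
    n_cells = as.numeric(n_cells), n_mitotic = as.numeric(n_mitotic),
    mitotic_diameters = as.numeric(mitotic_diameters),
    nuclear_zone_height = as.numeric(nuclear_zone_height),
    nuclear_long_axis = as.numeric(nuclear_long_axis)),
    class = "stage_measurement")
  validate_stage_measurement(m)
  m
}

validate_stage_measurement <- function(m, where = "") {
  fail <- function(msg) stop("invalid stage measurement", where, ": ", msg,
                             call. = FALSE)
  pos <- c(tissue_volume = m$tissue_volume, apical_area = m$apical_area,
           total_surface_area = m$total_surface_area,
           nuclear_zone_height = m$nuclear_zone_height,
           nuclear_long_axis = m$nuclear_long_axis)
  if (any(!is.finite(pos)) || any(pos <= 0))
    fail(paste("non-positive or non-finite:",
               paste(names(pos)[!is.finite(pos) | pos <= 0], collapse = ", ")))
  if (!length(m$thickness_samples)) fail("thickness_samples empty")
  if (any(m$thickness_samples <= 0)) fail("non-positive thickness sample")
  if (m$apical_area >= m$total_surface_area)
    fail("apical_area must be smaller than total_surface_area")
  if (m$n_mitotic < 0 || m$n_mitotic > m$n_cells)
    fail("n_mitotic must lie in [0, n_cells]")
  if (length(m$mitotic_diameters) && any(m$mitotic_diameters <= 0))
    fail("non-positive mitotic diameter")
  invisible(TRUE)
}

#' Assemble stage measurements into a stage table
#'
#' @param rows list of [stage_measurement()] records.
#' @return An object of class `stage_table` with elements `rows` and
#'   `stages` (sorted unique stage values, after rounding stages to 0.1 h).
#' @export
stage_table <- function(rows) {
  stopifnot(is.list(rows), length(rows) >= 1,
            all(vapply(rows, inherits, logical(1), "stage_measurement")))
  stages <- sort(unique(round(vapply(rows, `[[`, numeric(1), "stage_hpf"), 1)))
  structure(list(rows = rows, stages = stages), class = "stage_table")
}

#' @export
print.stage_table <- function(x, ...) {
  cat("<stage_table>", length(x$rows), "measurements over",
      length(x$stages), "stages:", paste(x$stages, collapse = ", "), "hpf\n")
  invisible(x)
}

#' Number of measurements in a stage table
#' @param x a `stage_table`.
#' @export
length.stage_table <- function(x) length(x$rows)

#' Flatten a stage table to a data.frame
#'
#' Wide per-embryo rows in the on-disk dialect: thickness samples become
#' `thickness_um_1..k` columns; mitotic diameters are not included (they
#' live in the long-format companion table, see [write_stage_table()]).
#'
#' @param x a `stage_table`.
#' @param ... unused.
#' @return data.frame with one row per measurement.
#' @export
as.data.frame.stage_table <- function(x, ...) {
  k <- max(vapply(x$rows, function(m) length(m$thickness_samples), integer(1)))
  do.call(rbind, lapply(x$rows, function(m) {
    th <- c(m$thickness_samples, rep(NA_real_, k - length(m$thickness_samples)))
    d <- data.frame(embryo_id = m$embryo_id, stage_hpf = m$stage_hpf,
                    tissue_volume_um3 = m$tissue_volume,
                    apical_area_um2 = m$apical_area,
                    total_surface_area_um2 = m$total_surface_area)
    for (i in seq_len(k)) d[[paste0("thickness_um_", i)]] <- th[i]
    d$n_cells <- m$n_cells; d$n_mitotic <- m$n_mitotic
    d$nuclear_zone_height_um <- m$nuclear_zone_height
    d$nuclear_long_axis_um <- m$nuclear_long_axis
    d
  }))
}

#' Read a stage table from its CSV dialect
#'
#' Expects the columns
#' `embryo_id,stage_hpf,tissue_volume_um3,apical_area_um2,total_surface_area_um2,thickness_um_1..k,n_cells,n_mitotic,nuclear_zone_height_um,nuclear_long_axis_um`
#' and, optionally, a long-format companion file `<stem>_mitotic_diameters.csv`
#' with columns `embryo_id,stage_hpf,diameter_um`. Units are fixed to
#' um/um^2/um^3 and hours. Malformed rows are rejected with row-indexed
#' messages.
#'
#' @param path CSV file path.
#' @param diameters_path optional explicit path of the diameters companion;
#'   by default `<stem>_mitotic_diameters.csv` is read when present.
#' @return A validated [stage_table()].
#' @export
read_stage_table <- function(path, diameters_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("embryo_id", "stage_hpf", "tissue_volume_um3", "apical_area_um2",
            "total_surface_area_um2", "n_cells", "n_mitotic",
            "nuclear_zone_height_um", "nuclear_long_axis_um")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("stage table schema error: missing column(s) ",
         paste(missing, collapse = ", "))
  th_cols <- grep("^thickness_um_[0-9]+$", names(df), value = TRUE)
  if (!length(th_cols))
    stop("stage table schema error: missing column(s) thickness_um_1")
  if (!nrow(df)) stop("stage table schema error: file has no data rows")

  if (is.null(diameters_path)) {
    cand <- sub("\\.csv$", "_mitotic_diameters.csv", path)
    if (file.exists(cand)) diameters_path <- cand
  }
  dia <- NULL
  if (!is.null(diameters_path)) {
    dia <- utils::read.csv(diameters_path, stringsAsFactors = FALSE)
    dneed <- c("embryo_id", "stage_hpf", "diameter_um")
    if (!all(dneed %in% names(dia)))
      stop("diameter table schema error: expected columns ",
           paste(dneed, collapse = ", "))
  }

  rows <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    th <- as.numeric(r[th_cols]); th <- th[!is.na(th)]
    dd <- numeric(0)
    if (!is.null(dia)) {
      sel <- dia$embryo_id == r$embryo_id &
        round(dia$stage_hpf, 1) == round(r$stage_hpf, 1)
      dd <- dia$diameter_um[sel]
    }
    m <- structure(list(
      embryo_id = as.character(r$embryo_id), stage_hpf = r$stage_hpf,
      tissue_volume = r$tissue_volume_um3, apical_area = r$apical_area_um2,
      total_surface_area = r$total_surface_area_um2, thickness_samples = th,
      n_cells = r$n_cells, n_mitotic = r$n_mitotic, mitotic_diameters = dd,
      nuclear_zone_height = r$nuclear_zone_height_um,
      nuclear_long_axis = r$nuclear_long_axis_um),
      class = "stage_measurement")
    validate_stage_measurement(m, where = paste0(" (row ", i, ")"))
    m
  })
  stage_table(rows)
}

#' Write a stage table to its CSV dialect
#'
#' Writes the wide per-embryo table, and a long-format companion
#' `<stem>_mitotic_diameters.csv` when any row carries mitotic diameters.
#' Floating values are written with full precision (15 significant digits)
#' so that [read_stage_table()] round-trips values.
#'
#' @param table a [stage_table()].
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_stage_table <- function(table, path) {
  stopifnot(inherits(table, "stage_table"))
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 15, format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  dia <- do.call(rbind, lapply(table$rows, function(m) {
    if (!length(m$mitotic_diameters)) return(NULL)
    data.frame(embryo_id = m$embryo_id, stage_hpf = m$stage_hpf,
               diameter_um = formatC(m$mitotic_diameters, digits = 15,
                                     format = "g"))
  }))
  if (!is.null(dia))
    utils::write.csv(dia, sub("\\.csv$", "_mitotic_diameters.csv", path),
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a pipeline configuration
#'
#' YAML file with top-level keys `seed`, `stages`, `n_embryos`, `scenario`,
#' `thickness_correction`, `cmz_correction_factor`, `heatmap_bins`,
#' `transition_hpf`, `ramp_hours`, and an optional `calibration` block of
#' per-stage overrides (list keyed by stage, values replacing
#' [default_calibration()] columns). Absent optional keys receive defaults;
#' unknown keys are a hard error so typos never pass silently.
#'
#' @param path YAML file path, or `NULL` for the packaged reference
#'   configuration.
#' @return A list of class `pipeline_config`.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "reference_config.yaml",
                        package = "psegrowth", mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  defaults <- list(seed = 1L, stages = c(20, 24, 30, 36, 42, 48),
                   n_embryos = 10L, scenario = "control",
                   thickness_correction = TRUE, cmz_correction_factor = 0.95,
                   heatmap_bins = 8L, transition_hpf = 35.5, ramp_hours = 6,
                   calibration = NULL)
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, raw)
  if (is.null(raw$seed))
    message("no seed in configuration; using default seed ", cfg$seed)
  stopifnot(is.numeric(cfg$seed), length(cfg$seed) == 1,
            is.numeric(cfg$stages), length(cfg$stages) >= 1)
  cfg$seed <- as.integer(cfg$seed)
  cfg$stages <- sort(as.numeric(cfg$stages))

  calib <- default_calibration(cfg$stages)
  if (!is.null(cfg$calibration)) {
    for (key in names(cfg$calibration)) {
      i <- match_stage(calib$stage_hpf, as.numeric(key))
      if (!length(i))
        stop("calibration block for stage ", key, " not in configured stages")
      blk <- cfg$calibration[[key]]
      bad <- setdiff(names(blk), names(calib))
      if (length(bad))
        stop("unknown calibration key(s): ", paste(bad, collapse = ", "))
      for (col in names(blk)) calib[i, col] <- blk[[col]]
    }
  }
  cfg$calibration <- calib
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config> seed", x$seed, "| stages",
      paste(x$stages, collapse = ", "), "hpf |", x$n_embryos, "embryos/stage\n")
  invisible(x)
}
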