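#' Construct a cardiac-resolved phase-contrast series
#'
#' Bundles the per-cardiac-phase magnitude and velocity rasters with the
#' acquisition metadata the pipeline needs: the velocity-encoding value
#' (venc), the in-plane pixel size and the phase-encoding axis along which
#' ghost replicas propagate.
#'
#' @param magnitude numeric array `[row, col, cardiac_phase]`, arbitrary
#'   intensity units.
#' @param velocity numeric array of the same shape, cm/s, signed; negative
#'   values are downward (caudal) through-plane flow.
#' @param venc velocity encoding in cm/s (> 0); the velocity mapped to a
#'   phase of pi.
#' @param pixel_size length-2 numeric, mm per pixel along (row, col).
#' @param pe_axis `"rows"` or `"cols"`: the image axis along which
#'   phase-encode ghosts propagate. Never inferred from image content.
#' @return An object of class `pc_series`.
#' @export
pc_series <- function(magnitude, velocity, venc,
                      pixel_size = c(0.2, 0.2),
                      pe_axis = c("rows", "cols")) {
  pe_axis <- match.arg(pe_axis)
  if (!is.array(magnitude) || length(dim(magnitude)) != 3L)
    stop("magnitude must be a 3-D array [row, col, cardiac_phase]")
  if (!identical(dim(magnitude), dim(velocity)))
    stop("magnitude and velocity shapes differ")
  if (dim(magnitude)[3] < 2L)
    stop("need at least 2 cardiac phases")
  if (!is.numeric(venc) || length(venc) != 1L || venc <= 0)
    stop("venc must be a single positive number (cm/s)")
  structure(
    list(magnitude = magnitude, velocity = velocity,
         venc = venc, n_phases = dim(magnitude)[3],
         pixel_size = as.numeric(pixel_size), pe_axis = pe_axis),
    class = "pc_series")
}

#' @export
print.pc_series <- function(x, ...) {
  d <- dim(x$magnitude)
  cat(sprintf("<pc_series> %d x %d pixels, %d cardiac phases, venc %.3g cm/s, pe_axis %s\n",
              d[1], d[2], d[3], x$venc, x$pe_axis))
  invisible(x)
}

#' Convert a phase raster (radians) to velocity (cm/s)
#'
#' Linear, odd map: `v = phase / pi * venc`, so a phase of pi corresponds
#' to the encoding velocity.
#'
#' @param phase numeric array, radians in `[-pi, pi)`.
#' @param venc velocity encoding, cm/s.
#' @return velocity in cm/s, same shape.
#' @export
phase_to_velocity <- function(phase, venc) {
  stopifnot(is.numeric(venc), venc > 0)
  phase / pi * venc
}

#' Read a phase-contrast series from NIfTI files
#'
#' @param magnitude_path path to the 3-D magnitude NIfTI.
#' @param velocity_path path to the 3-D velocity (cm/s) or phase (radians)
#'   NIfTI; which one it is must be declared via `velocity_units`.
#' @param venc velocity encoding in cm/s.
#' @param pe_axis `"rows"` or `"cols"`.
#' @param pixel_size mm per pixel (row, col).
#' @param velocity_units `"cm/s"` (passed through) or `"radians"`
#'   (converted via [phase_to_velocity()]).
#' @return a [pc_series()].
#' @export
read_pc_series <- function(magnitude_path, velocity_path, venc,
                           pe_axis = c("rows", "cols"),
                           pixel_size = c(0.2, 0.2),
                           velocity_units = c("cm/s", "radians")) {
  velocity_units <- match.arg(velocity_units)
  pe_axis <- match.arg(pe_axis)
  if (!file.exists(magnitude_path)) stop("magnitude file not found: ", magnitude_path)
  if (!file.exists(velocity_path)) stop("velocity file not found: ", velocity_path)
  mag <- as_plain_array(RNifti::readNifti(magnitude_path))
  vel <- as_plain_array(RNifti::readNifti(velocity_path))
  if (!identical(dim(mag), dim(vel)))
    stop("magnitude and velocity rasters have different shapes")
  if (velocity_units == "radians") vel <- phase_to_velocity(vel, venc)
  pc_series(mag, vel, venc = venc, pixel_size = pixel_size, pe_axis = pe_axis)
}

as_plain_array <- function(x) {
  a <- array(as.numeric(x), dim = dim(x))
  a
}

#' Write a phase-contrast series to a pair of NIfTI files
#'
#' @param series a [pc_series()].
#' @param magnitude_path,velocity_path output paths (`.nii` / `.nii.gz`).
#' @return invisibly, the two paths.
#' @export
write_pc_series <- function(series, magnitude_path, velocity_path) {
  stopifnot(inherits(series, "pc_series"))
  RNifti::writeNifti(series$magnitude, magnitude_path)
  RNifti::writeNifti(series$velocity, velocity_path)
  invisible(c(magnitude_path, velocity_path))
}

#' Read / write a binary mask raster
#'
#' Masks are plain 0/1 integer matrices `[row, col]`.
#'
#' @param path NIfTI file path.
#' @return `read_mask`: a 0/1 integer matrix.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("mask file not found: ", path)
  m <- RNifti::readNifti(path)
  m <- array(as.numeric(m), dim = dim(m))
  if (length(dim(m)) == 3L && dim(m)[3] == 1L) m <- m[, , 1]
  if (length(dim(m)) != 2L) stop("mask must be 2-D")
  if (!all(m %in% c(0, 1))) stop("mask values must be strictly 0/1")
  matrix(as.integer(m), nrow(m), ncol(m))
}

#' @param mask 0/1 matrix.
#' @rdname read_mask
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.matrix(mask), all(mask %in% c(0L, 1L)))
  RNifti::writeNifti(matrix(as.integer(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

# ---- perforator tables ------------------------------------------------

#' Write / read a perforator table as CSV
#'
#' One row per detected perforator: id, location (1-based row/col),
#' cluster id and size, mean velocity with its 95% CI, inclusion status
#' and exclusion reason, followed by one `v<t>` column per cardiac phase
#' holding the velocity-time curve. The reader inverts the writer
#' losslessly (full double precision).
#'
#' @param records a perforator data.frame as returned by
#'   [detect_perforators()].
#' @param path CSV output path.
#' @return invisibly, `path`.
#' @export
write_perforator_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  df <- records
  num <- vapply(df, is.numeric, logical(1))
  # full precision so that write -> read is bit-faithful
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_perforator_table
#' @export
read_perforator_table <- function(path) {
  if (!file.exists(path)) stop("perforator table not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  int_cols <- intersect(c("id", "row", "col", "cluster_id", "cluster_size"),
                        names(df))
  for (cc in int_cols) df[[cc]] <- as.integer(df[[cc]])
  if ("included" %in% names(df)) df$included <- as.logical(df$included)
  df
}

#' Number of cardiac phases represented in a perforator table
#' @param records perforator data.frame.
#' @return integer count of `v<t>` curve columns.
#' @export
curve_columns <- function(records) {
  grep("^v[0-9]+$", names(records), value = TRUE)
}

#' Extract the velocity-time curves from a perforator table
#' @param records perforator data.frame.
#' @return numeric matrix, one row per perforator, one column per phase.
#' @export
perforator_curves <- function(records) {
  cols <- curve_columns(records)
  as.matrix(records[, cols, drop = FALSE])
}

# ---- configuration ----------------------------------------------------

#' Default analysis configuration
#'
#' All tunable parameters of the detection and censoring pipeline, with
#' the published defaults: 70-px detrending median window, top 0.3%
#' intensity threshold for large-vessel identification, minimum cluster
#' of 3 voxels ("more than two"), the 80-voxel size rule assigning
#' (dilate 2 px, extend 200 px) to large clusters and (1 px, 110 px) to
#' smaller ones, an 80-px central-WM margin and alpha = 0.05. The
#' background-phase median window (31 px) and 8-connectivity are this
#' package's documented choices.
#'
#' @return a named list of class `perfcensor_config`.
#' @export
default_config <- function() {
  structure(list(
    detrend_window      = 70L,
    vessel_top_fraction = 0.003,
    vessel_min_cluster  = 3L,
    big_cluster_threshold = 80L,
    big_dilate   = 2L,
    big_extend   = 200L,
    small_dilate = 1L,
    small_extend = 110L,
    wm_margin    = 80L,
    alpha        = 0.05,
    phase_bg_window = 31L,
    connectivity = 8L,
    extend_mode  = "per_side",
    seed         = 1L
  ), class = "perfcensor_config")
}

#' Load an analysis configuration from YAML
#'
#' Missing keys fall back to [default_config()]; out-of-range values
#' raise an error naming the offending key.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return validated `perfcensor_config` list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (!is.null(user)) {
      unknown <- setdiff(names(user), names(cfg))
      if (length(unknown))
        stop("unknown config key(s): ", paste(unknown, collapse = ", "))
      cfg <- structure(modifyList(unclass(cfg), user),
                       class = "perfcensor_config")
    }
  }
  validate_config(cfg)
}

#' @rdname load_config
#' @param config a config list to validate.
#' @export
validate_config <- function(config) {
  pos_int <- c("detrend_window", "vessel_min_cluster", "big_cluster_threshold",
               "big_dilate", "big_extend", "small_dilate", "small_extend",
               "phase_bg_window")
  for (key in pos_int) {
    v <- config[[key]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || v < 1 || v != round(v))
      stop("config key '", key, "' must be a positive integer")
    config[[key]] <- as.integer(v)
  }
  if (!is.numeric(config$wm_margin) || config$wm_margin < 0)
    stop("config key 'wm_margin' must be a nonnegative number")
  f <- config$vessel_top_fraction
  if (!is.numeric(f) || f <= 0 || f >= 1)
    stop("config key 'vessel_top_fraction' must lie strictly in (0, 1)")
  a <- config$alpha
  if (!is.numeric(a) || a <= 0 || a >= 1)
    stop("config key 'alpha' must lie strictly in (0, 1)")
  if (!config$connectivity %in% c(4L, 8L))
    stop("config key 'connectivity' must be 4 or 8")
  if (!config$extend_mode %in% c("per_side", "total"))
    stop("config key 'extend_mode' must be 'per_side' or 'total'")
  config
}

#' Write a configuration to YAML
#' @param config `perfcensor_config`.
#' @param path output path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
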