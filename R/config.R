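## Run configuration and scene files (YAML in, YAML out), JSON reports,
## and frame export. All lengths in files carry explicit unit suffixes
## (nm, um, mm) and are normalized to nm internally.

CONFIG_KEYS <- c(
  "scene", "optics", "camera", "scan", "autofocus", "seed", "output_dir"
)
SCAN_KEYS <- c(
  "nx", "ny", "nz", "dz", "overlap_fraction", "order", "autofocus_policy"
)
AUTOFOCUS_KEYS <- c("method", "range", "points", "speed_nm_per_s")

#' Load a run configuration
#'
#' Reads a YAML configuration describing a scene, optics preset, camera
#' settings, scan parameters and seed; fills documented defaults,
#' normalizes all lengths to nm, and validates ranges against the stage
#' travel. Unknown keys are an error (they usually mean a typo), as are
#' unit-less lengths.
#'
#' @param path YAML file path.
#' @return an object of class `vs_config`.
#' @seealso [save_config()], [load_scene()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), CONFIG_KEYS)
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  cfg <- list(
    scene = raw$scene %||% list(type = "blood_smear"),
    optics = raw$optics %||% list(preset = "0.65NA-dry"),
    camera = raw$camera %||% list(),
    scan = raw$scan %||% list(),
    autofocus = raw$autofocus %||% list(),
    seed = as.integer(raw$seed %||% 1L),
    output_dir = raw$output_dir %||% "."
  )
  if (!is.null(cfg$scan$dz)) {
    cfg$scan$dz_nm <- parse_length_nm(cfg$scan$dz, "scan dz")
    cfg$scan$dz <- NULL
  }
  unknown_scan <- setdiff(names(cfg$scan), c(SCAN_KEYS, "dz_nm"))
  if (length(unknown_scan) > 0L) {
    stop("unknown scan key(s): ", paste(unknown_scan, collapse = ", "),
      call. = FALSE
    )
  }
  if (!is.null(cfg$autofocus$range)) {
    cfg$autofocus$range_nm <- parse_length_nm(
      cfg$autofocus$range, "autofocus range"
    )
    cfg$autofocus$range <- NULL
  }
  unknown_af <- setdiff(names(cfg$autofocus), c(AUTOFOCUS_KEYS, "range_nm"))
  if (length(unknown_af) > 0L) {
    stop("unknown autofocus key(s): ", paste(unknown_af, collapse = ", "),
      call. = FALSE
    )
  }
  travel_z <- 4e6
  rng <- cfg$autofocus$range_nm %||% 20000
  if (rng > travel_z) {
    stop(sprintf(
      "autofocus range (%g nm) exceeds the %g mm z travel",
      rng, travel_z / 1e6
    ), call. = FALSE)
  }
  nz <- cfg$scan$nz %||% 1
  dz <- cfg$scan$dz_nm %||% 0
  if ((nz - 1) * dz > travel_z) {
    stop(sprintf(
      "z-stack span (%g nm) exceeds the %g mm z travel",
      (nz - 1) * dz, travel_z / 1e6
    ), call. = FALSE)
  }
  structure(cfg, class = "vs_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a run configuration
#'
#' Writes the normalized configuration back to YAML; lengths are emitted
#' with explicit `nm` suffixes so `load_config(save_config(cfg))` is the
#' identity.
#'
#' @param config a `vs_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "vs_config"))
  out <- unclass(config)
  if (!is.null(out$scan$dz_nm)) {
    out$scan$dz <- format_length_nm(out$scan$dz_nm)
    out$scan$dz_nm <- NULL
  }
  if (!is.null(out$autofocus$range_nm)) {
    out$autofocus$range <- format_length_nm(out$autofocus$range_nm)
    out$autofocus$range_nm <- NULL
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Build simulator components from a scene description
#'
#' A scene is the YAML counterpart of [specimen_field()] plus optics and
#' camera settings: `specimen` (`type`: `blood_smear`, `knife_edge`,
#' `grid` or `flat`, plus that constructor's parameters), `optics`
#' (`preset` plus overrides) and `camera` overrides.
#'
#' @param path YAML scene file.
#' @param seed seed for any randomized specimen layout.
#' @return list with `specimen`, `optics`, `camera`.
#' @export
load_scene <- function(path, seed = 1L) {
  if (!file.exists(path)) stop("scene file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), c("specimen", "optics", "camera"))
  if (length(unknown) > 0L) {
    stop("unknown scene key(s): ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  sp <- raw$specimen %||% list(type = "blood_smear")
  type <- sp$type %||% "blood_smear"
  args <- sp[setdiff(names(sp), "type")]
  specimen <- switch(type,
    blood_smear = do.call(specimen_blood_smear, c(args, list(seed = seed))),
    knife_edge = do.call(specimen_knife_edge, args),
    grid = do.call(specimen_grid, args),
    flat = do.call(specimen_flat, args),
    stop("unknown specimen type: ", type, call. = FALSE)
  )
  op <- raw$optics %||% list()
  optics <- if (!is.null(op$preset)) {
    do.call(optics_preset, c(list(name = op$preset),
      op[setdiff(names(op), "preset")]
    ))
  } else {
    do.call(optics_config, op)
  }
  camera <- do.call(camera_config, raw$camera %||% list())
  list(specimen = specimen, optics = optics, camera = camera)
}

#' Write a JSON analysis report
#'
#' Serializes a result object (focus result, PSF estimate, distortion fit,
#' shading table, pixel calibration, mosaic, or a plain list) together
#' with the package version, seed and configuration hash. Reports with the
#' same inputs and seed are byte-identical; wall-clock timestamps are
#' deliberately excluded.
#'
#' @param result object to report.
#' @param path output JSON path.
#' @param seed seed the run used (recorded, not applied).
#' @param config optional `vs_config` whose hash is recorded.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, seed = NA_integer_, config = NULL) {
  body <- as_report(result)
  cfg_hash <- if (is.null(config)) {
    NA_character_
  } else {
    tmp <- tempfile(fileext = ".json")
    on.exit(unlink(tmp), add = TRUE)
    writeLines(
      jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA), tmp
    )
    unname(tools::md5sum(tmp))
  }
  report <- c(
    list(
      generator = "virtuscope",
      version = as.character(packageVersion("virtuscope")),
      seed = seed,
      config_hash = cfg_hash
    ),
    body
  )
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report, path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Convert a result object to its report form
#'
#' @param x a virtuscope result object.
#' @return a named list ready for JSON serialization.
#' @export
as_report <- function(x) UseMethod("as_report")

#' @export
as_report.default <- function(x) {
  if (is.list(x)) {
    return(list(kind = "generic", result = x))
  }
  list(kind = "value", result = x)
}

#' @export
as_report.vs_focus <- function(x) {
  list(
    kind = "focus", method = x$method, best_z_nm = x$best_z_nm,
    at_boundary = x$at_boundary, samples = x$samples
  )
}

#' @export
as_report.vs_psf <- function(x) {
  list(
    kind = "psf", fwhm_nm = x$fwhm_nm,
    profile = list(positions_nm = x$positions_nm, values = x$values)
  )
}

#' @export
as_report.vs_distortion <- function(x) {
  list(
    kind = "distortion", k = x$k,
    max_fractional_displacement_pct = x$max_fractional_displacement_pct,
    n_points = x$n_points
  )
}

#' @export
as_report.vs_shading <- function(x) {
  list(
    kind = "shading", grid_dims = as.list(x$grid_dims),
    gains = lapply(seq_len(dim(x$gains)[3L]), function(ch) {
      unname(apply(x$gains[, , ch, drop = FALSE], 1L, as.numeric,
        simplify = FALSE
      ))
    })
  )
}

#' @export
as_report.vs_pixcal <- function(x) {
  list(
    kind = "pixel_calibration", nm_per_px = x$nm_per_px,
    fov_um = as.list(x$fov_um), period_px = x$period_px
  )
}

#' @export
as_report.vs_mosaic <- function(x) {
  list(
    kind = "mosaic",
    size_px = c(nrow(x$image), ncol(x$image)),
    crop_margin_fraction = x$crop_margin_fraction,
    tile_positions = x$recovered_offsets_px,
    flagged_pairs = x$flagged_pairs
  )
}

#' Write a frame (or any raster) to PNG or TIFF
#'
#' @param frame a `vs_frame` or numeric raster in counts (0-255).
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_frame <- function(frame, path) {
  pixels <- if (inherits(frame, "vs_frame")) frame$pixels else frame
  img <- pixels / 255
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("the 'png' package is required to write PNG", call. = FALSE)
    }
    png::writePNG(img, path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("the 'tiff' package is required to write TIFF", call. = FALSE)
    }
    tiff::writeTIFF(img, path)
  } else {
    stop("unsupported image extension: .", ext, call. = FALSE)
  }
  invisible(path)
}

#' Read a raster image as counts
#'
#' Reads PNG or TIFF into the package's raster convention (matrix or
#' `[h, w, 3]` array of counts 0-255).
#' @param path image path.
#' @return numeric matrix or array.
#' @export
read_frame <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else {
    stop("unsupported image extension: .", ext, call. = FALSE)
  }
  if (length(dim(img)) == 3L && dim(img)[3L] == 4L) img <- img[, , 1:3]
  img * 255
}
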