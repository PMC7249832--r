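## Tile-set persistence: numbered TIFF tiles plus a JSON manifest carrying
## the plan geometry, per-tile positions and per-site focus results, so a
## scan can be stitched (or re-analysed) in a later session or by the
## command-line tools.

#' Write a tile set to a directory
#'
#' Tiles are written as numbered TIFF files next to a `manifest.json`
#' holding the plan geometry, the pixel pitch, per-tile commanded
#' positions and focus metadata.
#'
#' @param tiles a `vs_tileset` from [execute_scan()].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_tileset <- function(tiles, dir) {
  stopifnot(inherits(tiles, "vs_tileset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- vector("list", length(tiles$tiles))
  for (idx in seq_along(tiles$tiles)) {
    t <- tiles$tiles[[idx]]
    file <- sprintf("tile_%04d.tif", idx)
    write_frame(t$frame, file.path(dir, file))
    entries[[idx]] <- list(
      file = file,
      site_index = t$site_index,
      i = unname(t$grid_index[["i"]]), j = unname(t$grid_index[["j"]]),
      x_nm = unname(t$site_xy_nm[["x"]]), y_nm = unname(t$site_xy_nm[["y"]]),
      z_offset_nm = t$z_offset_nm,
      focus_z_nm = t$focus_z_nm,
      timestamp_s = t$frame$timestamp_s
    )
  }
  plan <- tiles$plan
  manifest <- list(
    generator = "virtuscope",
    version = as.character(packageVersion("virtuscope")),
    pixel_pitch_nm = tiles$pixel_pitch_nm,
    plan = list(
      kind = plan$kind, nx = plan$nx, ny = plan$ny, nz = plan$nz,
      dz_nm = plan$dz_nm, overlap_fraction = plan$overlap_fraction,
      fov_um = plan$fov_um, order = plan$order
    ),
    tiles = entries
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Read a tile set from a directory
#'
#' Counterpart of [write_tileset()]; reconstructs a `vs_tileset`
#' sufficient for stitching and re-analysis.
#'
#' @param dir directory containing `manifest.json` and the tile images.
#' @return a `vs_tileset`.
#' @export
read_tileset <- function(dir) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path)) {
    stop("no manifest.json under ", dir, call. = FALSE)
  }
  man <- jsonlite::read_json(path)
  plan <- list(
    kind = man$plan$kind, nx = man$plan$nx, ny = man$plan$ny,
    nz = man$plan$nz, dz_nm = man$plan$dz_nm,
    overlap_fraction = man$plan$overlap_fraction,
    fov_um = unlist(man$plan$fov_um), order = man$plan$order,
    sites = list()
  )
  class(plan) <- "vs_scanplan"
  tiles <- lapply(man$tiles, function(e) {
    pixels <- read_frame(file.path(dir, e$file))
    frame <- structure(
      list(
        pixels = pixels,
        true_position_nm = NULL,
        commanded_position_nm = c(x = e$x_nm, y = e$y_nm, z = e$focus_z_nm +
          e$z_offset_nm),
        timestamp_s = e$timestamp_s,
        compressed_size_bytes = NA_integer_,
        meta = list(pixel_pitch_nm = man$pixel_pitch_nm)
      ),
      class = "vs_frame"
    )
    list(
      frame = frame,
      site_index = e$site_index,
      grid_index = c(i = e$i, j = e$j),
      site_xy_nm = c(x = e$x_nm, y = e$y_nm),
      z_offset_nm = e$z_offset_nm,
      focus_z_nm = e$focus_z_nm,
      focus = NULL
    )
  })
  structure(
    list(
      tiles = tiles, manifest = NULL, plan = plan,
      pixel_pitch_nm = man$pixel_pitch_nm
    ),
    class = "vs_tileset"
  )
}
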