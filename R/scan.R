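#' Plan a tile (grid) scan
#'
#' Lays out `nx * ny` lateral capture sites spaced by
#' `fov * (1 - overlap_fraction)` on each axis, each carrying `nz` z-stack
#' offsets spaced `dz_nm` and centred on 0 (so the stack is symmetric about
#' the focus found at the site). Sites are ordered in snake (boustrophedon)
#' order by default, which minimizes stage travel; `"raster"` returns to
#' the row start each time.
#'
#' @param nx,ny grid size (columns, rows).
#' @param nz z-stack size per site.
#' @param dz_nm z-stack spacing, nm.
#' @param overlap_fraction fraction of the field of view shared by
#'   adjacent tiles (0 to <1).
#' @param fov_um field of view `c(width, height)` in microns (a scalar is
#'   recycled).
#' @param order `"snake"` or `"raster"`.
#' @param centre_nm lateral centre of the scan, nm.
#' @param autofocus_policy autofocus run at each site before the stack:
#'   `"none"`, `"laplacian"` or `"jpeg"`.
#' @param travel_nm per-axis stage travel used to validate the plan.
#' @return an object of class `vs_scanplan`; `n_captures()` gives the
#'   total capture count `nx * ny * nz`.
#' @export
#' @examples
#' plan <- plan_grid_scan(10, 10, nz = 5, dz_nm = 500, fov_um = c(82, 61.6))
#' n_captures(plan) # 500
plan_grid_scan <- function(nx, ny, nz = 1L, dz_nm = 0,
                           overlap_fraction = 0.2,
                           fov_um = c(82, 61.6),
                           order = c("snake", "raster"),
                           centre_nm = c(x = 0, y = 0),
                           autofocus_policy = c("none", "laplacian", "jpeg"),
                           travel_nm = c(x = 12e6, y = 12e6, z = 4e6)) {
  order <- match.arg(order)
  autofocus_policy <- match.arg(autofocus_policy)
  stopifnot(
    nx >= 1L, ny >= 1L, nz >= 1L,
    overlap_fraction >= 0, overlap_fraction < 1,
    nz == 1L || dz_nm > 0
  )
  if (length(fov_um) == 1L) fov_um <- c(fov_um, fov_um)
  spacing_nm <- fov_um * 1e3 * (1 - overlap_fraction)
  z_offsets <- if (nz == 1L) 0 else (seq_len(nz) - (nz + 1) / 2) * dz_nm

  sites <- list()
  for (j in 0:(ny - 1L)) {
    is <- 0:(nx - 1L)
    if (order == "snake" && j %% 2L == 1L) is <- rev(is)
    for (i in is) {
      x <- centre_nm[["x"]] + (i - (nx - 1) / 2) * spacing_nm[[1L]]
      y <- centre_nm[["y"]] + (j - (ny - 1) / 2) * spacing_nm[[2L]]
      sites[[length(sites) + 1L]] <- list(
        grid_index = c(i = i, j = j),
        target_xy_nm = c(x = x, y = y),
        autofocus_policy = autofocus_policy,
        z_offsets_nm = z_offsets,
        capture_time_s = NA_real_
      )
    }
  }

  travel_nm <- per_axis(travel_nm, c(x = 12e6, y = 12e6, z = 4e6))
  bad <- which(vapply(sites, function(s) {
    abs(s$target_xy_nm[["x"]]) > travel_nm[["x"]] / 2 ||
      abs(s$target_xy_nm[["y"]]) > travel_nm[["y"]] / 2
  }, logical(1L)))
  if (length(bad) > 0L) {
    labels <- vapply(sites[bad], function(s) {
      sprintf("(%d,%d)", s$grid_index[["i"]], s$grid_index[["j"]])
    }, character(1L))
    stop(
      "scan plan exceeds stage travel at ", length(bad), " site(s): ",
      paste(head(labels, 10L), collapse = " "),
      if (length(bad) > 10L) " ..." else "",
      call. = FALSE
    )
  }

  structure(
    list(
      sites = sites, nx = nx, ny = ny, nz = as.integer(nz), dz_nm = dz_nm,
      overlap_fraction = overlap_fraction, fov_um = fov_um,
      spacing_nm = spacing_nm, order = order, kind = "grid"
    ),
    class = "vs_scanplan"
  )
}

#' Plan a time-lapse acquisition
#'
#' A single-site plan with `n_frames` timed captures at fixed intervals.
#' With `autofocus_before_capture = TRUE` each capture is preceded by a
#' sharpness-sweep autofocus, which compensates slow focus drift of the
#' mechanism over long acquisitions.
#'
#' @param n_frames number of captures (>= 1).
#' @param interval_s time between captures, seconds.
#' @param autofocus_before_capture refocus before every capture.
#' @return an object of class `vs_scanplan` with `kind = "timelapse"`.
#' @export
plan_timelapse <- function(n_frames, interval_s,
                           autofocus_before_capture = FALSE) {
  stopifnot(n_frames >= 1L, interval_s > 0)
  policy <- if (isTRUE(autofocus_before_capture)) "laplacian" else "none"
  sites <- lapply(seq_len(n_frames), function(i) {
    list(
      grid_index = c(i = 0L, j = i - 1L),
      target_xy_nm = NULL, # stay in place
      autofocus_policy = policy,
      z_offsets_nm = 0,
      capture_time_s = (i - 1) * interval_s
    )
  })
  structure(
    list(
      sites = sites, nx = 1L, ny = as.integer(n_frames), nz = 1L, dz_nm = 0,
      overlap_fraction = 0, fov_um = c(NA_real_, NA_real_),
      spacing_nm = c(0, 0), order = "raster", kind = "timelapse",
      interval_s = interval_s
    ),
    class = "vs_scanplan"
  )
}

#' Total captures of a scan plan
#' @param plan a `vs_scanplan`.
#' @return integer capture count.
#' @export
n_captures <- function(plan) {
  stopifnot(inherits(plan, "vs_scanplan"))
  sum(vapply(plan$sites, function(s) length(s$z_offsets_nm), integer(1L)))
}

#' Total commanded lateral travel of a plan
#'
#' Sum of |dx| + |dy| between consecutive sites; snake ordering minimizes
#' it relative to raster on any grid with at least two rows.
#' @param plan a `vs_scanplan`.
#' @return travel in nm.
#' @export
plan_travel_nm <- function(plan) {
  stopifnot(inherits(plan, "vs_scanplan"))
  xy <- t(vapply(
    plan$sites,
    function(s) if (is.null(s$target_xy_nm)) c(0, 0) else s$target_xy_nm,
    numeric(2L)
  ))
  if (nrow(xy) < 2L) {
    return(0)
  }
  sum(abs(diff(xy[, 1L]))) + sum(abs(diff(xy[, 2L])))
}

#' @export
print.vs_scanplan <- function(x, ...) {
  if (x$kind == "grid") {
    cat(sprintf(
      "<vs_scanplan> %dx%d grid, %d-image z-stack (dz=%g nm), %s order, %d captures\n",
      x$nx, x$ny, x$nz, x$dz_nm, x$order, n_captures(x)
    ))
  } else {
    cat(sprintf(
      "<vs_scanplan> time-lapse, %d frames every %g s (autofocus: %s)\n",
      length(x$sites), x$interval_s, x$sites[[1L]]$autofocus_policy
    ))
  }
  invisible(x)
}
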