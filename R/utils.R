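## Internal helpers shared across modules.

AXES <- c("x", "y", "z")

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded rendering does not disturb
#' the caller's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

## Derive a per-frame child seed from a base seed; stays below 2^31.
child_seed <- function(base_seed, index) {
  as.integer((as.double(base_seed) * 48271 + as.double(index) * 7919) %%
    2147483647)
}

## Coerce a partial named per-axis vector (e.g. c(z = 500)) into a full
## c(x=,y=,z=) vector, filling missing axes from `default`.
per_axis <- function(v, default = c(x = 0, y = 0, z = 0)) {
  out <- default
  if (is.null(v)) {
    return(out)
  }
  if (is.null(names(v)) || any(!nzchar(names(v)))) {
    if (length(v) == 3L) {
      names(v) <- AXES
    } else if (length(v) == 1L) {
      v <- c(x = v[[1L]], y = v[[1L]], z = v[[1L]])
    } else {
      stop("per-axis values must be named (x, y, z) or length 3", call. = FALSE)
    }
  }
  bad <- setdiff(names(v), AXES)
  if (length(bad) > 0L) {
    stop("unknown axis name(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  out[names(v)] <- v
  out
}

## Rec.601 luminance for an RGB array [h, w, 3]; grayscale passes through.
as_gray <- function(pixels) {
  if (is.matrix(pixels)) {
    return(pixels)
  }
  if (length(dim(pixels)) == 3L && dim(pixels)[3L] == 3L) {
    return(
      0.299 * pixels[, , 1L] + 0.587 * pixels[, , 2L] + 0.114 * pixels[, , 3L]
    )
  }
  stop("expected a grayscale matrix or an [h, w, 3] RGB array", call. = FALSE)
}

## Parse a length given as "500nm", "10 um", "0.5 mm", "1.2e3 nm" to nm.
## Bare numbers are rejected so configuration files are unit-explicit.
parse_length_nm <- function(x, what = "length") {
  if (is.numeric(x)) {
    stop(
      "unit-less ", what, " (", x, "): lengths must carry a unit ",
      "suffix (nm, um, mm)",
      call. = FALSE
    )
  }
  x <- trimws(as.character(x))
  m <- regexec("^([-+]?[0-9]*\\.?[0-9]+(?:[eE][-+]?[0-9]+)?)\\s*(nm|um|µm|mm)$", x)
  parts <- regmatches(x, m)[[1L]]
  if (length(parts) != 3L) {
    stop(
      "cannot parse ", what, " '", x,
      "': expected e.g. '500nm', '10 um', '0.5 mm'",
      call. = FALSE
    )
  }
  value <- as.numeric(parts[2L])
  mult <- switch(parts[3L], nm = 1, um = 1e3, "µm" = 1e3, mm = 1e6)
  value * mult
}

format_length_nm <- function(nm) paste0(format(nm, scientific = FALSE), "nm")

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

## Block-mean binning by an integer factor (trailing remainder dropped),
## as camera preview pipelines do before focus metrics.
bin_image <- function(m, factor) {
  factor <- as.integer(factor)
  if (factor <= 1L) {
    return(m)
  }
  h <- (nrow(m) %/% factor) * factor
  w <- (ncol(m) %/% factor) * factor
  m <- m[seq_len(h), seq_len(w)]
  # average factor x factor blocks
  m <- rowsum(m, rep(seq_len(h %/% factor), each = factor)) / factor
  t(rowsum(t(m), rep(seq_len(w %/% factor), each = factor)) / factor)
}

## Moving average with a centred odd window; ends use shrinking windows.
moving_average <- function(x, window) {
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1", call. = FALSE)
  if (window %% 2L == 0L) window <- window + 1L
  half <- window %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1L))
}
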