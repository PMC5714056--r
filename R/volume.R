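#' Voxel volume container
#'
#' A `ct_volume` wraps a 3-D numeric (or integer) array together with its
#' voxel spacing and origin. Voxel indices are 1-based in R; the world
#' coordinate of the center of voxel `(i, j, k)` is
#' `origin + (c(i, j, k) - 0.5) * spacing` (millimetres), i.e. the
#' conventional voxel-center model with right-handed axes and axial slices
#' along z.
#'
#' @param data numeric 3-D array (`nx` x `ny` x `nz`).
#' @param spacing numeric length-3, voxel spacing in mm.
#' @param origin numeric length-3, world position of the corner of voxel
#'   `(1, 1, 1)` in mm.
#' @param kind one of `"HU"`, `"density"`, `"dose"`, `"label"`, `"mask"`,
#'   `"raw"`; purely descriptive.
#' @param meta named list of free-form provenance metadata.
#' @return an object of class `ct_volume`.
#' @export
ct_volume <- function(data, spacing, origin = NULL, kind = "raw", meta = list()) {
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L)
  stopifnot(length(dim(data)) == 3L, length(spacing) == 3L, all(spacing > 0))
  if (is.null(origin)) origin <- -dim(data) * spacing / 2
  stopifnot(length(origin) == 3L)
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), kind = kind, meta = meta),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ct_volume [%s]> %d x %d x %d voxels, spacing %s mm\n",
              x$kind, d[1], d[2], d[3],
              paste(format(x$spacing, digits = 4), collapse = " x ")))
  rng <- range(x$data)
  cat(sprintf("  value range [%.4g, %.4g]\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$data)

# world coordinates (mm) of voxel centers along one axis
axis_centers <- function(vol, axis) {
  n <- dim(vol$data)[axis]
  vol$origin[axis] + (seq_len(n) - 0.5) * vol$spacing[axis]
}

same_grid <- function(a, b, tol = 1e-9) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

stop_grid_mismatch <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop(sprintf("grid mismatch between %s: dims %s vs %s, spacing %s vs %s",
                 what,
                 paste(dim(a$data), collapse = "x"),
                 paste(dim(b$data), collapse = "x"),
                 paste(format(a$spacing), collapse = "x"),
                 paste(format(b$spacing), collapse = "x")))
  invisible(TRUE)
}

#' Structure mask
#'
#' Boolean voxel grid on the same lattice as a reference volume. Used for
#' PTVs, metal regions and the phantom body.
#'
#' @param mask logical 3-D array.
#' @param reference `ct_volume` supplying spacing/origin.
#' @param name structure name (for example `"PTV1"`, `"metal"`, `"body"`).
#' @return a `ct_volume` of kind `"mask"` with `meta$name` set.
#' @export
structure_mask <- function(mask, reference, name = "structure") {
  if (length(dim(mask)) == 2L) dim(mask) <- c(dim(mask), 1L)
  stopifnot(identical(dim(mask), dim(reference$data)), is.logical(mask))
  ct_volume(mask, reference$spacing, reference$origin, kind = "mask",
            meta = list(name = name))
}
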