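#' Polychromatic CT acquisition simulator
#'
#' Parallel-beam axial acquisition: exact ray-voxel forward projection of a
#' labeled phantom at each spectrum energy, Poisson photon noise on the
#' detected counts, log normalization with a photon-starvation validity
#' mask, and ramp-filtered back projection to Hounsfield units. Beam
#' hardening arises from the polychromatic spectrum; photon starvation from
#' near-zero counts behind dense metal.
#'
#' @name ct_sim
NULL

#' Parallel-beam scan geometry
#'
#' @param n_views number of views over 180 degrees (>= 2).
#' @param n_bins number of detector bins (>= 2).
#' @param bin_mm detector bin width in mm.
#' @param mode only `"parallel"` is implemented.
#' @return object of class `scan_geometry` with precomputed view angles
#'   (radians) and detector bin center offsets (cm).
#' @export
scan_geometry <- function(n_views = 360, n_bins, bin_mm, mode = "parallel") {
  mode <- match.arg(mode, "parallel")
  stopifnot(n_views >= 2, n_bins >= 2, bin_mm > 0)
  structure(list(mode = mode, n_views = as.integer(n_views),
                 n_bins = as.integer(n_bins), bin_mm = bin_mm,
                 angles = (seq_len(n_views) - 1) * pi / n_views,
                 dets = (seq_len(n_bins) - (n_bins + 1) / 2) * bin_mm / 10),
            class = "scan_geometry")
}

# geometry matched to a volume grid: detector bins at voxel pitch spanning
# twice the image width
default_geometry <- function(vol, n_views = 360) {
  n <- dim(vol$data)[1]
  scan_geometry(n_views = n_views, n_bins = 2L * n, bin_mm = vol$spacing[1])
}

new_sinogram <- function(values, domain, geometry, valid = NULL, N0 = NA,
                         seed = NA, meta = list()) {
  structure(list(values = values, domain = domain, geometry = geometry,
                 valid = valid, N0 = N0, seed = seed, meta = meta),
            class = "ct_sinogram")
}

#' @export
print.ct_sinogram <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<ct_sinogram [%s]> %d bins x %d views x %s\n", x$domain,
              d[1], d[2], paste(d[-(1:2)], collapse = " x ")))
  invisible(x)
}

# per-material intersection lengths (cm): array [nbins, nviews, nslices, nmat]
project_material_paths <- function(labels, geometry) {
  n <- dim(labels$data)
  nmat <- length(labels$meta$materials)
  sp <- labels$spacing / 10  # cm
  g0 <- labels$origin / 10
  out <- array(0, c(geometry$n_bins, geometry$n_views, n[3], nmat))
  for (k in seq_len(n[3])) {
    out[, , k, ] <- cpp_project_paths(
      labels$data[, , k], nmat, sp[1], sp[2], g0[1], g0[2],
      geometry$angles, geometry$dets)
  }
  out
}

#' Forward project a labeled volume at given energies
#'
#' Line integrals of the linear attenuation map at each energy, via exact
#' ray-voxel intersection-length traversal. Rays that miss the grid yield
#' zero.
#'
#' @param labels label `ct_volume` from [build_phantom()].
#' @param geometry a `scan_geometry`.
#' @param table an `attenuation_table`.
#' @param energies photon energies in keV.
#' @param materials material database (named list of `ct_material`).
#' @return `ct_sinogram` in the line-integral domain; `values` has
#'   dimension `[n_bins, n_views, n_slices, n_energies]` and the energies
#'   are stored in `meta$energies`.
#' @export
forward_project <- function(labels, geometry, table, energies,
                            materials = load_materials()) {
  paths <- project_material_paths(labels, geometry)
  d <- dim(paths)
  matnames <- labels$meta$materials
  mu <- vapply(matnames, function(nm) {
    linear_attenuation(materials[[nm]], energies, table)
  }, numeric(length(energies)))           # [nE, nmat]
  mu <- matrix(mu, nrow = length(energies))
  p <- array(matrix(paths, ncol = d[4]) %*% t(mu),
             c(d[1], d[2], d[3], length(energies)))
  new_sinogram(p, "line-integral", geometry,
               meta = list(energies = energies, paths = paths,
                           grid = list(dim = dim(labels$data),
                                       spacing = labels$spacing,
                                       origin = labels$origin)))
}

#' Simulate detected photon counts
#'
#' Expected counts per bin `lambda = N0 * sum_E w(E) exp(-p(E))`; observed
#' counts are Poisson draws. Deterministic given `seed`.
#'
#' @param line_integrals per-energy `ct_sinogram` from [forward_project()];
#'   its energies must match the spectrum bins.
#' @param spec an `xray_spectrum`.
#' @param N0 incident photons per detector bin (> 0).
#' @param seed integer RNG seed.
#' @return counts-domain `ct_sinogram` (`values` `[n_bins, n_views, n_slices]`).
#' @export
simulate_counts <- function(line_integrals, spec, N0, seed = 0L) {
  stopifnot(N0 > 0, line_integrals$domain == "line-integral")
  en <- line_integrals$meta$energies
  if (!isTRUE(all.equal(en, spec$energy)))
    stop("line-integral energies do not match the spectrum bins")
  p <- line_integrals$values
  d <- dim(p)
  lambda <- array(N0 * (exp(-matrix(p, ncol = length(en))) %*% spec$weights),
                  d[1:3])
  set.seed(as.integer(seed))
  counts <- array(stats::rpois(length(lambda), lambda), dim(lambda))
  new_sinogram(counts, "counts", line_integrals$geometry, N0 = N0,
               seed = seed, meta = line_integrals$meta)
}

#' Log-normalize counts to line integrals
#'
#' `p = log(N0 / max(counts, floor))`. Bins with counts below
#' `starvation_threshold` are flagged invalid: they are the missing
#' projections caused by photon starvation behind dense metal.
#'
#' @param counts counts-domain `ct_sinogram` (with `N0` set).
#' @param starvation_threshold counts below this are invalid (default 5).
#' @param floor count floor preventing `log(0)` (default 0.5).
#' @return line-integral `ct_sinogram` with a logical `valid` mask.
#' @export
log_normalize <- function(counts, starvation_threshold = 5, floor = 0.5) {
  stopifnot(counts$domain == "counts")
  p <- log(counts$N0 / pmax(counts$values, floor))
  valid <- counts$values >= starvation_threshold
  new_sinogram(p, "line-integral", counts$geometry, valid = valid,
               N0 = counts$N0, seed = counts$seed, meta = counts$meta)
}

# frequency-domain ramp filtering of projections [nbins, nviews]
ramp_filter <- function(p, ds, apodization = c("ramp", "hann")) {
  apodization <- match.arg(apodization)
  nb <- nrow(p)
  npad <- 2^ceiling(log2(2 * nb))
  P <- rbind(p, matrix(0, npad - nb, ncol(p)))
  freq <- c(seq(0, npad / 2), seq(-npad / 2 + 1, -1)) / (npad * ds)
  H <- abs(freq)
  if (apodization == "hann") {
    numax <- 1 / (2 * ds)
    H <- H * 0.5 * (1 + cos(pi * freq / numax))
  }
  Q <- Re(stats::mvfft(stats::mvfft(P) * H, inverse = TRUE)) / npad
  Q[seq_len(nb), , drop = FALSE]
}

#' Filtered back projection reconstruction
#'
#' Ramp-filtered backprojection of line-integral projections to a linear
#' attenuation map at the reference energy, then conversion to clamped HU.
#' Invalid bins are used as-is: the uncorrected reconstruction deliberately
#' keeps corrupted data, which is what produces metal streaks.
#'
#' @param projections line-integral `ct_sinogram`.
#' @param geometry `scan_geometry` (defaults to the sinogram's own).
#' @param mu_water_ref water attenuation at the reference energy (1/cm).
#' @param n reconstructed in-plane matrix size.
#' @param spacing_mm reconstructed voxel spacing.
#' @param slice_mm slice thickness.
#' @param filter `"ramp"` (default) or `"hann"` apodization.
#' @return HU `ct_volume`.
#' @export
reconstruct_fbp <- function(projections, geometry = projections$geometry,
                            mu_water_ref, n = geometry$n_bins %/% 2,
                            spacing_mm = geometry$bin_mm, slice_mm = 2.5,
                            filter = "ramp") {
  stopifnot(projections$domain == "line-integral")
  if (geometry$n_views < 2) stop("need at least 2 views to reconstruct")
  d <- dim(projections$values)
  ns <- if (length(d) >= 3) d[3] else 1L
  ds <- geometry$bin_mm / 10
  sp <- c(spacing_mm, spacing_mm, slice_mm)
  origin <- -c(n, n, ns) * sp / 2
  img <- array(0, c(n, n, ns))
  for (k in seq_len(ns)) {
    pk <- if (length(d) >= 3) projections$values[, , k] else projections$values
    q <- ramp_filter(pk, ds, filter)
    img[, , k] <- cpp_backproject(q, geometry$angles, geometry$dets,
                                  n, n, sp[1] / 10, sp[2] / 10,
                                  origin[1] / 10, origin[2] / 10)
  }
  hu <- hu_from_mu(img, mu_water_ref)
  ct_volume(hu, sp, origin, kind = "HU",
            meta = list(mu_water_ref = mu_water_ref, filter = filter))
}

#' End-to-end synthetic acquisition
#'
#' Composition of [forward_project()], [simulate_counts()],
#' [log_normalize()] and [reconstruct_fbp()], per slice, with per-slice
#' seeds derived as `seed + slice - 1`. Deterministic given `seed`.
#'
#' @param labels label `ct_volume`.
#' @param spec `xray_spectrum`.
#' @param geometry `scan_geometry` (default derived from the volume grid).
#' @param N0 incident photons per bin (default 1e7).
#' @param seed integer master seed.
#' @param table attenuation table.
#' @param materials material database.
#' @param reference_energy reconstruction reference energy (keV); default
#'   the spectrum's effective energy through 16 cm of water.
#' @param starvation_threshold,floor see [log_normalize()].
#' @param filter reconstruction filter.
#' @return list with `counts` (`ct_sinogram`), `projections`
#'   (log-normalized line integrals with validity mask), `image`
#'   (uncorrected HU `ct_volume`) and `reference_energy`.
#' @export
acquire <- function(labels, spec, geometry = default_geometry(labels),
                    N0 = 1e7, seed = 0L, table = load_attenuation_table(),
                    materials = load_materials(),
                    reference_energy = NULL,
                    starvation_threshold = 5, floor = 0.5,
                    filter = "ramp") {
  if (is.null(reference_energy))
    reference_energy <- effective_energy(spec, table)
  mu_w <- loglog_interp(table$energy, table$mu_rho[, "water"],
                        reference_energy)
  li <- forward_project(labels, geometry, table, spec$energy, materials)
  ns <- dim(labels$data)[3]
  counts_vals <- array(0, c(geometry$n_bins, geometry$n_views, ns))
  for (k in seq_len(ns)) {
    sl <- new_sinogram(li$values[, , k, , drop = FALSE], "line-integral",
                       geometry, meta = li$meta)
    dim(sl$values) <- c(geometry$n_bins, geometry$n_views, 1L,
                        length(spec$energy))
    counts_vals[, , k] <- simulate_counts(sl, spec, N0,
                                          seed = seed + k - 1L)$values
  }
  counts <- new_sinogram(counts_vals, "counts", geometry, N0 = N0,
                         seed = seed, meta = li$meta)
  proj <- log_normalize(counts, starvation_threshold, floor)
  img <- reconstruct_fbp(proj, geometry, mu_w,
                         n = dim(labels$data)[1],
                         spacing_mm = labels$spacing[1],
                         slice_mm = labels$spacing[3], filter = filter)
  img$origin <- labels$origin
  img$meta$seed <- seed
  img$meta$reference_energy <- reference_energy
  list(counts = counts, projections = proj, image = img,
       reference_energy = reference_energy, mu_water_ref = mu_w)
}
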