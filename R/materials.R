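#' Physical materials, attenuation tables and CT number conversions
#'
#' The package ships a small material database (tissue surrogates resembling
#' a multi-insert calibration phantom, plus titanium and the Bi/Pb/Sn/Cd
#' Cerrobend alloy) and per-material mass attenuation / mass
#' energy-absorption tables on a log energy grid covering 20-2000 keV.
#' Attenuation is interpolated log-log between grid points.
#'
#' @name materials
NULL

# Z and A for the elements used by the shipped material compositions.
.ELEMENTS <- data.frame(
  symbol = c("H", "C", "N", "O", "Mg", "Si", "P", "Cl", "Ar", "Ca",
             "Ti", "Cd", "Sn", "Pb", "Bi"),
  Z = c(1, 6, 7, 8, 12, 14, 15, 17, 18, 20, 22, 48, 50, 82, 83),
  A = c(1.008, 12.011, 14.007, 15.999, 24.305, 28.085, 30.974, 35.45,
        39.948, 40.078, 47.867, 112.414, 118.710, 207.2, 208.980),
  stringsAsFactors = FALSE)

HU_MIN <- -1024
HU_MAX <- 3071

#' Define a material
#'
#' @param name material name.
#' @param mass_density mass density in g/cm^3 (> 0).
#' @param composition named numeric vector of elemental mass fractions
#'   (names are element symbols); must sum to 1 within 1e-6.
#' @return an object of class `ct_material` with the relative electron
#'   density (electrons per volume relative to water) precomputed.
#' @export
material <- function(name, mass_density, composition) {
  stopifnot(is.numeric(mass_density), mass_density > 0)
  w <- as.numeric(composition)
  el <- names(composition)
  if (abs(sum(w) - 1) > 1e-6)
    stop(sprintf("mass fractions of '%s' sum to %.8f, not 1", name, sum(w)))
  unknown <- setdiff(el, .ELEMENTS$symbol)
  if (length(unknown))
    stop(sprintf("unknown element symbol(s) %s; known elements: %s",
                 paste(unknown, collapse = ", "),
                 paste(.ELEMENTS$symbol, collapse = ", ")))
  m <- structure(list(name = name, mass_density = mass_density,
                      composition = composition), class = "ct_material")
  m$relative_electron_density <- .electron_density_raw(m) / .WATER_NE
  m
}

# electrons per cm^3 / N_A: rho * sum(w_i Z_i / A_i)
.electron_density_raw <- function(m) {
  idx <- match(names(m$composition), .ELEMENTS$symbol)
  m$mass_density * sum(as.numeric(m$composition) *
                         .ELEMENTS$Z[idx] / .ELEMENTS$A[idx])
}
.WATER_NE <- 1.0 * (0.1119 * 1 / 1.008 + 0.8881 * 8 / 15.999)

#' @export
print.ct_material <- function(x, ...) {
  cat(sprintf("<ct_material> %s: rho = %.4g g/cm3, rho_e = %.4g\n",
              x$name, x$mass_density, x$relative_electron_density))
  invisible(x)
}

#' Relative electron density of a material
#'
#' Electrons per unit volume relative to water:
#' `rho * sum(w_i Z_i / A_i)` normalized by the same quantity for water.
#'
#' @param material a `ct_material`.
#' @return dimensionless relative electron density.
#' @export
electron_density <- function(material) {
  stopifnot(inherits(material, "ct_material"))
  .electron_density_raw(material) / .WATER_NE
}

#' Load the material database from a structured text file
#'
#' The file format is documented in the shipped
#' `extdata/materials.txt`: blocks of `material:`, `density:` and
#' `composition:` key-value lines.
#'
#' @param path file path; default is the packaged database.
#' @return named list of `ct_material` objects.
#' @export
load_materials <- function(path = system.file("extdata", "materials.txt",
                                              package = "ctmar")) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  mats <- list()
  cur <- list()
  flush <- function(cur, mats) {
    if (!length(cur)) return(mats)
    if (is.null(cur$name) || is.null(cur$density) || is.null(cur$comp))
      stop("incomplete material block in ", path)
    mats[[cur$name]] <- material(cur$name, cur$density, cur$comp)
    mats
  }
  for (ln in lines) {
    kv <- strsplit(ln, ":", fixed = TRUE)[[1]]
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = ":"))
    if (key == "material") {
      mats <- flush(cur, mats)
      cur <- list(name = val)
    } else if (key == "density") {
      cur$density <- as.numeric(val)
    } else if (key == "composition") {
      pairs <- strsplit(strsplit(val, "\\s+")[[1]], "=", fixed = TRUE)
      comp <- vapply(pairs, function(p) as.numeric(p[2]), numeric(1))
      names(comp) <- vapply(pairs, `[`, character(1), 1)
      cur$comp <- comp
    } else stop("unknown key '", key, "' in ", path)
  }
  flush(cur, mats)
}

#' Load the attenuation table
#'
#' Per-material mass attenuation and mass energy-absorption coefficients
#' (cm^2/g) on a strictly increasing energy grid (keV).
#'
#' @param path TSV file; default is the packaged table.
#' @return object of class `attenuation_table` with fields `energy`
#'   (keV), `mu_rho` and `muen_rho` (matrices, energy x material), and
#'   `materials` (column names).
#' @export
load_attenuation_table <- function(path = system.file(
    "extdata", "attenuation.tsv", package = "ctmar")) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  energy <- sort(unique(df$energy_kev))
  mats <- unique(df$material)
  mu <- muen <- matrix(NA_real_, length(energy), length(mats),
                       dimnames = list(NULL, mats))
  for (m in mats) {
    sub <- df[df$material == m, ]
    sub <- sub[order(sub$energy_kev), ]
    if (!isTRUE(all.equal(sub$energy_kev, energy)))
      stop("material '", m, "' does not cover the full energy grid")
    mu[, m] <- sub$mu_rho
    muen[, m] <- sub$muen_rho
  }
  if (any(mu <= 0) || any(muen <= 0)) stop("non-positive table entries")
  structure(list(energy = energy, mu_rho = mu, muen_rho = muen,
                 materials = mats), class = "attenuation_table")
}

# log-log interpolation of a tabulated coefficient at arbitrary energies
loglog_interp <- function(energy_grid, values, energy) {
  if (any(energy < energy_grid[1] | energy > energy_grid[length(energy_grid)]))
    stop(sprintf("energy out of table range [%g, %g] keV",
                 energy_grid[1], energy_grid[length(energy_grid)]))
  exp(stats::approx(log(energy_grid), log(values), xout = log(energy),
                    rule = 1)$y)
}

#' Linear attenuation coefficient of a material
#'
#' `mu = (mu/rho)(E) * rho`, with log-log interpolation of the mass
#' attenuation coefficient between table grid points.
#'
#' @param material a `ct_material` whose name appears in the table.
#' @param energy photon energy in keV (scalar or vector), inside the table
#'   range.
#' @param table an `attenuation_table`.
#' @param quantity `"mu"` (attenuation, default) or `"muen"`
#'   (energy absorption).
#' @return linear coefficient(s) in 1/cm.
#' @export
linear_attenuation <- function(material, energy, table, quantity = c("mu", "muen")) {
  quantity <- match.arg(quantity)
  stopifnot(inherits(material, "ct_material"),
            inherits(table, "attenuation_table"))
  if (!material$name %in% table$materials)
    stop("material '", material$name, "' not in attenuation table")
  col <- if (quantity == "mu") table$mu_rho[, material$name]
         else table$muen_rho[, material$name]
  loglog_interp(table$energy, col, energy) * material$mass_density
}

#' Convert attenuation to Hounsfield units
#'
#' `HU = 1000 (mu - mu_water) / mu_water`, clamped to the scanner range
#' `[-1024, 3071]`.
#'
#' @param mu numeric array/vector of linear attenuation values (1/cm).
#' @param mu_water water attenuation at the same energy (> 0).
#' @return HU values, same shape as `mu`.
#' @export
hu_from_mu <- function(mu, mu_water) {
  stopifnot(is.numeric(mu_water), mu_water > 0)
  if (any(!is.finite(mu))) stop("non-finite attenuation values")
  hu <- 1000 * (mu - mu_water) / mu_water
  pmin(pmax(hu, HU_MIN), HU_MAX)
}

#' Inverse HU conversion
#'
#' Maps HU back to linear attenuation; exact inverse of [hu_from_mu()] for
#' HU strictly inside the clamp range.
#'
#' @param hu HU values.
#' @param mu_water water attenuation (1/cm).
#' @return attenuation values (1/cm).
#' @export
mu_from_hu <- function(hu, mu_water) {
  stopifnot(mu_water > 0)
  mu_water * (1 + hu / 1000)
}

#' Load the packaged 140 kVp spectrum
#'
#' @param path TSV with columns `energy_kev`, `weight`; default packaged.
#' @param kvp tube potential (kV); bin energies must not exceed it.
#' @return object of class `xray_spectrum` with normalized weights.
#' @export
load_spectrum <- function(path = system.file("extdata", "spectrum_140kvp.tsv",
                                             package = "ctmar"), kvp = 140) {
  df <- utils::read.delim(path, comment.char = "#")
  xray_spectrum(df$energy_kev, df$weight, kvp)
}

#' Construct an x-ray spectrum
#'
#' @param energy bin-center energies, keV, strictly increasing.
#' @param weights nonnegative relative fluence weights (renormalized).
#' @param kvp tube potential in kV; `max(energy) <= kvp` is enforced.
#' @return an `xray_spectrum` (fields `kvp`, `energy`, `weights`).
#' @export
xray_spectrum <- function(energy, weights, kvp = max(energy)) {
  stopifnot(all(diff(energy) > 0), all(weights >= 0), sum(weights) > 0,
            max(energy) <= kvp)
  structure(list(kvp = kvp, energy = as.numeric(energy),
                 weights = as.numeric(weights) / sum(weights)),
            class = "xray_spectrum")
}

#' Effective (water-equivalent) energy of a spectrum
#'
#' The monochromatic energy whose water attenuation matches the effective
#' attenuation of the spectrum after traversing `depth_cm` of water:
#' `mu_eff = -log(sum w exp(-mu_w(E) d)) / d`. Used as the reconstruction
#' reference energy so water reconstructs near 0 HU.
#'
#' @param spec an `xray_spectrum`.
#' @param table an `attenuation_table`.
#' @param depth_cm water depth, default 16 cm.
#' @return energy in keV.
#' @export
effective_energy <- function(spec, table, depth_cm = 16) {
  muw <- loglog_interp(table$energy, table$mu_rho[, "water"], spec$energy)
  mu_eff <- -log(sum(spec$weights * exp(-muw * depth_cm))) / depth_cm
  # invert the water mu(E) curve (monotone decreasing on the table grid)
  f <- function(e) loglog_interp(table$energy, table$mu_rho[, "water"], e) - mu_eff
  stats::uniroot(f, lower = 30, upper = 200, tol = 1e-6)$root
}
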