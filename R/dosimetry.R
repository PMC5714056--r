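#' Desk-scale photon dosimetry
#'
#' HU-to-electron-density calibration, a kerma-approximation primary photon
#' engine (with a Monte Carlo cross-check mode), metal-avoiding beam-angle
#' selection and five-beam fluence optimization. The beam model is
#' monoenergetic (2 MeV default, a 6 MV-like surrogate); the medium is
#' treated as water of scaled electron density, so dose follows
#' `fluence x exp(-mu_eff * radiological path)` along each beamlet.
#'
#' @name dosimetry
NULL

#' Piecewise-linear HU to relative electron density calibration
#'
#' @param points data.frame with columns `hu` and `density`
#'   (relative electron density); at least 2 rows, strictly increasing HU,
#'   non-decreasing density.
#' @return object of class `calibration_curve`. Evaluation clamps outside
#'   the control range.
#' @export
calibrate_hu_density <- function(points) {
  stopifnot(nrow(points) >= 2, all(c("hu", "density") %in% names(points)))
  points <- points[order(points$hu), ]
  if (any(diff(points$hu) <= 0)) stop("duplicate HU control points")
  if (any(diff(points$density) < 0))
    stop("calibration densities must be monotone non-decreasing in HU")
  if (any(points$density < 0)) stop("negative density control point")
  structure(list(hu = points$hu, density = points$density),
            class = "calibration_curve")
}

# evaluate a calibration curve (clamped linear interpolation)
curve_density <- function(curve, hu) {
  stats::approx(curve$hu, curve$density, xout = hu, rule = 2)$y
}

#' Default calibration curve from the material database
#'
#' Control points are the (HU at the reference energy, relative electron
#' density) pairs of the tissue materials, anchored near (-1000, 0) by air
#' and at (0, 1) by water. When the scanned configuration contains a known
#' metal, a control point at its (clamped) HU maps the saturated scanner
#' value to the metal's electron density — the desk-scale analogue of a
#' clinical density override for a known implant.
#'
#' @param materials material database.
#' @param table attenuation table.
#' @param reference_energy reconstruction reference energy (keV).
#' @param metal optional metal material name for the top control point.
#' @return a `calibration_curve`.
#' @export
default_calibration <- function(materials, table, reference_energy,
                                metal = NULL) {
  mu_w <- loglog_interp(table$energy, table$mu_rho[, "water"],
                        reference_energy)
  tissues <- c("air", "lung", "adipose", "breast", "water", "solid_water",
               "brain", "liver", "inner_bone", "cortical_bone")
  tissues <- intersect(tissues, names(materials))
  pts <- do.call(rbind, lapply(tissues, function(nm) {
    m <- materials[[nm]]
    data.frame(hu = hu_from_mu(linear_attenuation(m, reference_energy, table),
                               mu_w),
               density = m$relative_electron_density)
  }))
  if (!is.null(metal)) {
    m <- materials[[metal]]
    pts <- rbind(pts, data.frame(
      hu = hu_from_mu(linear_attenuation(m, reference_energy, table), mu_w),
      density = m$relative_electron_density))
  }
  pts <- pts[!duplicated(round(pts$hu, 6)), ]
  calibrate_hu_density(pts)
}

#' Convert an HU volume to relative electron density
#'
#' @param image HU `ct_volume`.
#' @param curve a `calibration_curve`.
#' @return density `ct_volume` on the same grid.
#' @export
hu_to_density <- function(image, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  out <- image
  out$data <- array(curve_density(curve, image$data), dim(image$data))
  out$kind <- "density"
  out
}

#' Treatment plan specification
#'
#' @param angles beam propagation directions in degrees (exactly 5).
#' @param prescription_gy prescribed target dose, default 10 Gy.
#' @param target PTV `ct_volume` mask.
#' @param beamlet_mm beamlet width, default 5 mm.
#' @param energy_mev beam energy, default 2 MeV.
#' @param isocenter_cm optional (x, y) isocenter; default target centroid.
#' @return object of class `plan_spec`.
#' @export
plan_spec <- function(angles, prescription_gy = 10, target,
                      beamlet_mm = 5, energy_mev = 2, isocenter_cm = NULL) {
  stopifnot(length(angles) == 5, prescription_gy > 0, beamlet_mm > 0)
  if (is.null(isocenter_cm)) {
    idx <- which(target$data, arr.ind = TRUE)
    isocenter_cm <- c(
      mean(target$origin[1] + (idx[, 1] - 0.5) * target$spacing[1]),
      mean(target$origin[2] + (idx[, 2] - 0.5) * target$spacing[2])) / 10
  }
  structure(list(angles = as.numeric(angles),
                 prescription_gy = prescription_gy, target = target,
                 beamlet_mm = beamlet_mm, energy_mev = energy_mev,
                 isocenter_cm = isocenter_cm),
            class = "plan_spec")
}

#' Construct a fluence map
#'
#' @param angles beam angles (degrees), one per beam.
#' @param offsets_cm list of beamlet center offsets (cm, along the beam's
#'   transverse axis, relative to the isocenter), one vector per beam.
#' @param weights list of nonnegative beamlet weights (Gy at zero depth),
#'   one vector per beam.
#' @return object of class `fluence_map`.
#' @export
fluence_map <- function(angles, offsets_cm, weights) {
  stopifnot(length(angles) == length(offsets_cm),
            length(angles) == length(weights))
  for (b in seq_along(weights)) {
    stopifnot(length(offsets_cm[[b]]) == length(weights[[b]]))
    if (any(weights[[b]] < 0)) stop("fluence weights must be nonnegative")
  }
  structure(list(angles = angles, offsets_cm = offsets_cm,
                 weights = weights), class = "fluence_map")
}

# total number of beamlets
n_beamlets <- function(fl) sum(lengths(fl$weights))

# transverse coordinate of each voxel center for a beam direction (cm)
beam_s_coord <- function(vol, angle_deg, iso_cm) {
  n <- dim(vol$data)[1:2]
  a <- angle_deg * pi / 180
  xc <- (vol$origin[1] + (seq_len(n[1]) - 0.5) * vol$spacing[1]) / 10
  yc <- (vol$origin[2] + (seq_len(n[2]) - 0.5) * vol$spacing[2]) / 10
  X <- matrix(xc, n[1], n[2]); Y <- matrix(yc, n[1], n[2], byrow = TRUE)
  (X - iso_cm[1]) * (-sin(a)) + (Y - iso_cm[2]) * cos(a)
}

# exp(-mu_eff * radiological path) for one beam on one density slice
beam_attenuation <- function(dens2d, spacing_mm, origin_mm, angle_deg, mu_eff) {
  sp <- spacing_mm / 10; g0 <- origin_mm / 10
  rp <- cpp_radpath(dens2d, sp[1], sp[2], g0[1], g0[2], angle_deg * pi / 180)
  exp(-mu_eff * rp)
}

mu_eff_water <- function(table, energy_mev) {
  loglog_interp(table$energy, table$mu_rho[, "water"], energy_mev * 1000)
}

#' Compute dose
#'
#' Primary mode: for each beamlet, dose = weight x
#' `exp(-mu_eff * radiological path)` deposited along the beamlet strip
#' (collision kerma to water; radiological path via exact voxel traversal
#' of the relative electron density). Monte Carlo mode: photon histories
#' sampled from the fluence, transported with Klein-Nishina Compton
#' scattering and photoelectric absorption, energy deposited under the
#' kerma approximation. Deterministic given `seed`.
#'
#' @param density relative electron density `ct_volume`.
#' @param plan a `plan_spec`.
#' @param fluence a `fluence_map`.
#' @param mode `"primary"` or `"mc"`.
#' @param seed integer seed (mc mode).
#' @param histories photon histories per slice (mc mode).
#' @param table attenuation table.
#' @return dose `ct_volume` (Gy); mc mode attaches `meta$rel_unc`
#'   (per-voxel relative uncertainty) and `meta$energy_balance`.
#' @export
compute_dose <- function(density, plan, fluence, mode = c("primary", "mc"),
                         seed = 0L, histories = 2e5,
                         table = load_attenuation_table()) {
  mode <- match.arg(mode)
  stopifnot(inherits(density, "ct_volume"))
  if (any(density$data < 0)) stop("negative density voxels")
  d <- dim(density$data)
  out <- density
  out$kind <- "dose"
  out$data <- array(0, d)
  out$meta <- list(engine = mode)
  if (n_beamlets(fluence) == 0 || all(unlist(fluence$weights) == 0))
    return(out)
  mu <- mu_eff_water(table, plan$energy_mev)
  iso <- plan$isocenter_cm
  w_cm <- plan$beamlet_mm / 10
  if (mode == "primary") {
    for (b in seq_along(fluence$angles)) {
      S <- beam_s_coord(density, fluence$angles[b], iso)
      off <- fluence$offsets_cm[[b]]
      wts <- fluence$weights[[b]]
      lo <- off[1] - w_cm / 2
      idx <- floor((S - lo) / w_cm) + 1
      wlut <- numeric(length(S))
      ok <- idx >= 1 & idx <= length(wts)
      wlut[ok] <- wts[idx[ok]]
      dim(wlut) <- dim(S)
      for (k in seq_len(d[3])) {
        att <- beam_attenuation(density$data[, , k], density$spacing[1:2],
                                density$origin[1:2], fluence$angles[b], mu)
        out$data[, , k] <- out$data[, , k] + wlut * att
      }
    }
  } else {
    eg <- exp(seq(log(20), log(plan$energy_mev * 1000 * 1.02),
                  length.out = 60))
    eg_cl <- pmin(pmax(eg, 20), 2000)
    mu_w_grid <- loglog_interp(table$energy, table$mu_rho[, "water"], eg_cl)
    # approximate photoelectric fraction for water (E^-3.1 power law)
    tau <- 0.55 * (20 / eg)^3.1
    pe_frac <- pmin(tau / mu_w_grid, 1)
    E0 <- plan$energy_mev * 1000
    muen_E0 <- loglog_interp(table$energy, table$muen_rho[, "water"], E0)
    kJ <- 1.602176634e-13   # Gy per (keV per g)
    sp_cm <- density$spacing / 10
    vox_cm3 <- prod(sp_cm)
    blt_angle <- blt_s <- blt_nphot <- numeric(0)
    for (b in seq_along(fluence$angles)) {
      a <- fluence$angles[b] * pi / 180
      v <- c(-sin(a), cos(a))
      s_abs <- fluence$offsets_cm[[b]] + sum(iso * v)
      area <- w_cm * sp_cm[3]
      psi <- fluence$weights[[b]] / (muen_E0 * kJ)   # keV / cm^2
      blt_angle <- c(blt_angle, rep(a, length(s_abs)))
      blt_s <- c(blt_s, s_abs)
      blt_nphot <- c(blt_nphot, psi * area / E0)
    }
    emitted <- deposited <- 0
    for (k in seq_len(d[3])) {
      set.seed(as.integer(seed) + k - 1L)
      res <- cpp_mc_dose(density$data[, , k], sp_cm[1], sp_cm[2],
                         density$origin[1] / 10, density$origin[2] / 10,
                         blt_angle, blt_s, blt_nphot, w_cm, E0,
                         eg, mu_w_grid, pe_frac,
                         as.integer(histories), 10L)
      mass <- density$data[, , k] * vox_cm3   # g (water-equivalent)
      dk <- res$edep * kJ / pmax(mass, 1e-12)
      dk[mass <= 1e-12] <- 0
      out$data[, , k] <- dk
      out$meta$rel_unc <- res$rel_unc
      emitted <- emitted + res$emitted
      deposited <- deposited + res$deposited
    }
    out$meta$energy_balance <- c(emitted_kev = emitted,
                                 deposited_kev = deposited)
  }
  out
}

#' Select metal-avoiding beam angles
#'
#' Scores each candidate direction by casting the beam through the metal
#' mask: a direction is blocked when any target voxel sees metal upstream
#' of it. Returns the 5 feasible angles with the largest angular spread
#' (greedy nearest-to-ideal search, lexicographically smallest set among
#' ties). If fewer than 5 directions are feasible — the PTV itself contains
#' metal — the 5 most-spread candidates are returned with feasibility flag
#' `"unavoidable"`.
#'
#' @param candidates candidate directions in degrees (>= 5 required).
#' @param metal metal mask `ct_volume` (or all-FALSE for no metal).
#' @param target PTV mask `ct_volume`.
#' @return list with `angles` (sorted, degrees) and `feasibility`
#'   (`"ok"` or `"unavoidable"`).
#' @export
select_beam_angles <- function(candidates = 0:359, metal, target) {
  if (!length(candidates)) stop("empty candidate angle list")
  stopifnot(length(candidates) >= 5)
  k_mid <- ceiling(dim(target$data)[3] / 2)
  tmask <- target$data[, , k_mid]
  mmask <- metal$data[, , k_mid] * 1.0
  dim(mmask) <- dim(tmask)
  sp <- target$spacing / 10; g0 <- target$origin / 10
  blocked <- vapply(candidates, function(a) {
    if (!any(mmask > 0)) return(FALSE)
    rp <- cpp_radpath(mmask, sp[1], sp[2], g0[1], g0[2], a * pi / 180)
    any(rp[tmask] > 0.05)
  }, logical(1))
  feasible <- candidates[!blocked]
  pool <- if (length(feasible) >= 5) feasible else candidates
  flag <- if (length(feasible) >= 5) "ok" else "unavoidable"
  lex_less <- function(a, b) {
    if (is.null(b)) return(TRUE)
    d <- which(a != b)
    length(d) > 0 && a[d[1]] < b[d[1]]
  }
  best <- NULL; best_gap <- -1
  for (seed_a in pool) {
    ideal <- (seed_a + (0:4) * 72) %% 360
    pick <- vapply(ideal, function(x) {
      gaps <- abs(((pool - x + 180) %% 360) - 180)
      pool[which.min(gaps)]
    }, numeric(1))
    pick <- sort(unique(pick))
    if (length(pick) < 5) next
    g <- min(diff(c(pick, pick[1] + 360)))
    if (g > best_gap + 1e-9 ||
        (abs(g - best_gap) <= 1e-9 && lex_less(pick, best))) {
      best <- pick; best_gap <- g
    }
  }
  if (is.null(best)) best <- sort(pool)[1:5]
  list(angles = best, feasibility = flag)
}

# projected-gradient nonnegative quadratic solver:
# min 0.5 w'Hw - c'w  s.t.  w >= 0, with objective trace
pg_nnls <- function(H, c, iters = 500) {
  L <- max(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
  w <- rep(0, length(c))
  objs <- numeric(iters)
  for (i in seq_len(iters)) {
    g <- H %*% w - c
    w <- pmax(0, w - as.numeric(g) / L)
    objs[i] <- 0.5 * sum(w * (H %*% w)) - sum(c * w)
  }
  list(w = as.numeric(w), objective = objs)
}

#' Optimize beamlet fluence weights
#'
#' Assembles the beamlet dose-influence matrix with the primary engine on
#' the supplied (typically uncorrected) density volume and solves
#' `min ||D w - prescription||^2 on the PTV + gamma ||D w||^2 outside`,
#' subject to `w >= 0`, by projected gradient with a fixed iteration
#' budget.
#'
#' @param density relative electron density `ct_volume` used for planning.
#' @param plan a `plan_spec`.
#' @param gamma out-of-target penalty weight, default 0.1.
#' @param iters projected-gradient iterations, default 500.
#' @param body optional body mask `ct_volume` restricting the out-of-target
#'   term (default: all voxels outside the PTV).
#' @param table attenuation table.
#' @return a `fluence_map` with `meta` attributes `objective` (trace) and
#'   `influence_nonzero`.
#' @export
optimize_fluence <- function(density, plan, gamma = 0.1, iters = 500,
                             body = NULL, table = load_attenuation_table()) {
  target <- plan$target
  if (!any(target$data)) stop("empty optimization target")
  d <- dim(density$data)
  iso <- plan$isocenter_cm
  w_cm <- plan$beamlet_mm / 10
  # beamlet ladder covering the target extent plus margin
  idx <- which(target$data[, , 1], arr.ind = TRUE)
  xs <- (target$origin[1] + (idx[, 1] - 0.5) * target$spacing[1]) / 10
  ys <- (target$origin[2] + (idx[, 2] - 0.5) * target$spacing[2]) / 10
  rt <- max(sqrt((xs - iso[1])^2 + (ys - iso[2])^2))
  half <- rt + 0.5
  nblt <- max(1L, ceiling(2 * half / w_cm))
  offsets <- (seq_len(nblt) - (nblt + 1) / 2) * w_cm
  mu <- mu_eff_water(table, plan$energy_mev)

  ptv_idx <- which(target$data)
  out_idx <- if (is.null(body)) which(!target$data)
             else which(body$data & !target$data)
  ncol_D <- 5L * nblt
  D_ptv <- matrix(0, length(ptv_idx), ncol_D)
  D_out <- matrix(0, length(out_idx), ncol_D)
  col <- 0L
  for (b in seq_along(plan$angles)) {
    S <- beam_s_coord(density, plan$angles[b], iso)
    att3 <- array(0, d)
    for (k in seq_len(d[3]))
      att3[, , k] <- beam_attenuation(density$data[, , k],
                                      density$spacing[1:2],
                                      density$origin[1:2], plan$angles[b], mu)
    jidx <- floor((S - (offsets[1] - w_cm / 2)) / w_cm) + 1
    for (j in seq_len(nblt)) {
      strip <- jidx == j
      col <- col + 1L
      contrib <- array(0, d)
      for (k in seq_len(d[3]))
        contrib[, , k] <- att3[, , k] * strip
      D_ptv[, col] <- contrib[ptv_idx]
      D_out[, col] <- contrib[out_idx]
    }
  }
  if (all(D_ptv == 0)) stop("beams miss the target: all-zero influence matrix")
  # both terms normalized per voxel so gamma weighs mean-squared dose
  # outside the target against mean-squared prescription error inside it
  H <- crossprod(D_ptv) / length(ptv_idx) +
    gamma * crossprod(D_out) / max(1, length(out_idx))
  cvec <- crossprod(D_ptv, rep(plan$prescription_gy, length(ptv_idx))) /
    length(ptv_idx)
  sol <- pg_nnls(2 * H, 2 * as.numeric(cvec), iters)
  fl <- fluence_map(plan$angles,
                    rep(list(offsets), 5),
                    split(sol$w, rep(seq_len(5), each = nblt)))
  attr(fl, "objective") <- sol$objective + plan$prescription_gy^2
  attr(fl, "influence_nonzero") <- sum(D_ptv != 0)
  fl
}

#' Recompute a fixed plan on several volumes
#'
#' Applies [compute_dose()] with the same fluence map to each density
#' volume; the fluence is never re-optimized per volume.
#'
#' @param fluence a `fluence_map`.
#' @param plan a `plan_spec`.
#' @param volumes named list of density `ct_volume`s on identical grids.
#' @param mode,seed,histories,table passed to [compute_dose()].
#' @return named list of dose `ct_volume`s.
#' @export
recompute_plans <- function(fluence, plan, volumes, mode = "primary",
                            seed = 0L, histories = 2e5,
                            table = load_attenuation_table()) {
  ref <- volumes[[1]]
  for (v in volumes) stop_grid_mismatch(ref, v, "plan volumes")
  lapply(volumes, compute_dose, plan = plan, fluence = fluence, mode = mode,
         seed = seed, histories = histories, table = table)
}
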