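# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fx_materials <- function() {
  if (is.null(.fx$mats)) .fx$mats <- load_materials()
  .fx$mats
}

fx_table <- function() {
  if (is.null(.fx$tab)) .fx$tab <- load_attenuation_table()
  .fx$tab
}

fx_spectrum <- function() {
  if (is.null(.fx$spec)) .fx$spec <- load_spectrum()
  .fx$spec
}

fx_eref <- function() {
  if (is.null(.fx$eref)) .fx$eref <- effective_energy(fx_spectrum(), fx_table())
  .fx$eref
}

fx_mu_water <- function(energy) {
  tab <- fx_table()
  ctmar:::loglog_interp(tab$energy, tab$mu_rho[, "water"], energy)
}

# noiseless polychromatic line integrals from a per-energy sinogram
noiseless_poly <- function(li, spec) {
  d <- dim(li$values)
  array(-log(exp(-matrix(li$values, ncol = d[4])) %*% spec$weights), d[1:3])
}

# uniform water cylinder on a fine grid (single slice)
water_cylinder <- function(n = 192, spacing_mm = 1.5, diameter_cm = 20) {
  phantom_spec(body_diameter_cm = diameter_cm, body_material = "water",
               n = n, spacing_mm = spacing_mm, n_slices = 1)
}

# the full desk-scale study (both configurations), run once and cached;
# this is the shared artifact behind the end-to-end and acceptance tests
fx_study <- function() {
  if (is.null(.fx$study)) {
    cfg <- run_config(configurations = c(1, 2), n = 128, spacing_mm = 3,
                      n_views = 180, seed = 1, log_level = "quiet")
    .fx$study <- run_study(cfg)
  }
  .fx$study
}

# full enumeration of the exact Mann-Whitney two-sided p-value (the U null
# distribution is symmetric, so the symmetric tail equals the doubled tail)
enumerate_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  rk <- rank(pooled)
  U_obs <- sum(rk[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(length(pooled), n)
  Us <- apply(combs, 2, function(idx) sum(rk[idx]) - n * (n + 1) / 2)
  mu <- n * length(b) / 2
  mean(abs(Us - mu) >= abs(U_obs - mu) - 1e-9)
}

# small metal-free acquisition, cached
fx_acq3_small <- function() {
  if (is.null(.fx$acq3)) {
    lab <- build_phantom(standard_phantom(3, n = 96, spacing_mm = 4,
                                          n_slices = 1))
    .fx$acq3 <- acquire(lab, fx_spectrum(),
                        ctmar:::default_geometry(lab, 120),
                        seed = 42, table = fx_table(),
                        materials = fx_materials(),
                        reference_energy = fx_eref())
    .fx$acq3_labels <- lab
  }
  list(acq = .fx$acq3, labels = .fx$acq3_labels)
}
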