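#' Study orchestration
#'
#' `run_study()` executes the complete experiment for the requested phantom
#' configurations: build phantom, simulate the acquisition, apply MAR,
#' build the software-substituted ground truth, convert to electron
#' density, select metal-avoiding beams, optimize each PTV's five-beam
#' fluence on the uncorrected volume, recompute dose with fixed fluence on
#' all three volumes, and assemble the evaluation report. Every stochastic
#' stage is seeded deterministically from the master seed.
#'
#' @name study
NULL

#' Study run configuration
#'
#' @param configurations phantom configurations to run: subset of
#'   `c(1, 2)` (1 = titanium, 2 = Cerrobend).
#' @param n in-plane matrix size.
#' @param spacing_mm in-plane voxel spacing (mm).
#' @param n_slices,slice_mm axial grid.
#' @param n_views projection views over 180 degrees.
#' @param N0 incident photons per detector bin.
#' @param mar a [mar_config()].
#' @param prescription_gy target prescription (Gy).
#' @param beamlet_mm beamlet width (mm).
#' @param energy_mev beam energy (MeV).
#' @param gamma out-of-target optimization penalty.
#' @param opt_iters fluence optimization iterations.
#' @param engine `"primary"` or `"mc"` dose engine.
#' @param histories mc histories per slice.
#' @param seed master seed (integer).
#' @param ptvs PTV presets to plan.
#' @param dvh_bin_gy DVH bin width.
#' @param out_dir optional output directory for report + volume artifacts.
#' @param log_level `"quiet"`, `"info"` or `"debug"`.
#' @return object of class `run_config`.
#' @export
run_config <- function(configurations = c(1, 2), n = 256, spacing_mm = 1.5,
                       n_slices = 3, slice_mm = 2.5, n_views = 360,
                       N0 = 1e7, mar = mar_config(), prescription_gy = 10,
                       beamlet_mm = 5, energy_mev = 2, gamma = 0.1,
                       opt_iters = 500, engine = "primary",
                       histories = 2e5, seed = 0L,
                       ptvs = c("PTV1", "PTV2", "PTV3"),
                       dvh_bin_gy = 0.05, out_dir = NULL,
                       log_level = "info") {
  stopifnot(all(configurations %in% c(1, 2)), n >= 32,
            engine %in% c("primary", "mc"),
            all(ptvs %in% c("PTV1", "PTV2", "PTV3")))
  structure(list(configurations = configurations, n = as.integer(n),
                 spacing_mm = spacing_mm, n_slices = as.integer(n_slices),
                 slice_mm = slice_mm, n_views = as.integer(n_views),
                 N0 = N0, mar = mar, prescription_gy = prescription_gy,
                 beamlet_mm = beamlet_mm, energy_mev = energy_mev,
                 gamma = gamma, opt_iters = as.integer(opt_iters),
                 engine = engine, histories = histories,
                 seed = as.integer(seed), ptvs = ptvs,
                 dvh_bin_gy = dvh_bin_gy, out_dir = out_dir,
                 log_level = log_level),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys match the arguments of [run_config()]; `mar:` is a
#' nested mapping passed to [mar_config()]. Unknown keys raise an error
#' naming the offender.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  # YAML 1.1 implicitly types a bare `n:` key as a boolean; accept it as
  # the matrix-size argument (or quote the key as "n" in the file)
  names(y)[names(y) %in% c("FALSE", "no")] <- "n"
  known <- names(formals(run_config))
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         " (known: ", paste(known, collapse = ", "), ")")
  if (!is.null(y$mar)) {
    bad_m <- setdiff(names(y$mar), names(formals(mar_config)))
    if (length(bad_m))
      stop("unknown mar config key(s): ", paste(bad_m, collapse = ", "))
    y$mar <- do.call(mar_config, y$mar)
  }
  do.call(run_config, y)
}

#' Deterministic configuration hash
#'
#' MD5 of the canonical serialization of a configuration (or any plain R
#' object); changes whenever any parameter changes.
#'
#' @param config object to hash.
#' @return 32-character hex string.
#' @export
config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  # strip non-semantic fields
  x <- unclass_deep(config)
  x$out_dir <- NULL
  x$log_level <- NULL
  con <- file(tf, "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(tools::md5sum(tf))
}

study_log <- function(level, cfg_level, ...) {
  levels <- c(quiet = 0, info = 1, debug = 2)
  if (levels[[cfg_level]] >= levels[[level]])
    message(sprintf("[ctmar] %s", paste0(...)))
}

# derived per-stage seeds, kept well below 2^31
derive_seed <- function(master, stage_offset) {
  (abs(master) %% 1000000L) * 1000L + stage_offset
}

#' Run the full study
#'
#' @param config a [run_config()].
#' @return list of class `study_run` with elements `report`
#'   (a `study_report`), `datasets`, `plans`, `reference_energy` and
#'   `hash`. If `config$out_dir` is set, the report (JSON + CSV), all HU
#'   and dose volumes (NRRD) and a manifest with MD5 hashes are written
#'   there.
#' @export
run_study <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  hash <- config_hash(config)
  lvl <- config$log_level
  study_log("info", lvl, "config hash ", hash, ", seed ", config$seed)
  mats <- load_materials()
  table <- load_attenuation_table()
  spec140 <- load_spectrum()
  e_ref <- effective_energy(spec140, table)
  study_log("info", lvl, sprintf("reference energy %.1f keV", e_ref))
  metal_of <- c(`1` = "titanium", `2` = "cerrobend")

  # configuration-3 (metal-free) acquisition shared by all ground truths
  lab3 <- build_phantom(standard_phantom(3, n = config$n,
                                         spacing_mm = config$spacing_mm,
                                         n_slices = config$n_slices,
                                         slice_mm = config$slice_mm))
  geometry <- default_geometry(lab3, n_views = config$n_views)
  acq3 <- acquire(lab3, spec140, geometry, N0 = config$N0,
                  seed = derive_seed(config$seed, 300L), table = table,
                  materials = mats, reference_energy = e_ref)
  study_log("info", lvl, "configuration 3 (solid water) acquired")

  datasets <- list(); plans <- list()
  for (cfg in config$configurations) {
    key <- c("lowZ", "highZ")[cfg]
    metal_name <- metal_of[[as.character(cfg)]]
    lab <- build_phantom(standard_phantom(cfg, n = config$n,
                                          spacing_mm = config$spacing_mm,
                                          n_slices = config$n_slices,
                                          slice_mm = config$slice_mm))
    acq <- acquire(lab, spec140, geometry, N0 = config$N0,
                   seed = derive_seed(config$seed, cfg * 100L),
                   table = table, materials = mats,
                   reference_energy = e_ref)
    study_log("info", lvl, key, " acquired")
    corrected <- mar_pipeline(acq$counts, acq$image, config$mar, geometry,
                              spec140, table, mats, e_ref,
                              assignment = metal_name)
    if (lvl == "debug") {
      for (k in seq_along(corrected$meta$objective)) {
        tr <- corrected$meta$objective[[k]]
        if (length(tr))
          study_log("debug", lvl, sprintf(
            "%s slice %d completion objective: %s", key, k,
            paste(sprintf("%.4g", tr), collapse = " ")))
      }
    }
    gt <- make_ground_truth(acq3$image, lab,
                            stats::setNames(list(mats[[metal_name]],
                                                 mats[[metal_name]]),
                                            c("A", "B")),
                            table, e_ref)
    body <- body_mask_from_spec(lab$meta$spec, acq$image)
    metal_mask <- structure_mask(label_mask(lab, metal_name), acq$image,
                                 name = "metal")
    curve <- default_calibration(mats, table, e_ref, metal = metal_name)
    dens <- lapply(list(uncorrected = acq$image, corrected = corrected,
                        gt = gt), hu_to_density, curve = curve)
    datasets[[key]] <- list(uncorrected = acq$image, corrected = corrected,
                            gt = gt, body = body, metal = metal_mask,
                            labels = lab)
    plans[[key]] <- list()
    for (pi in seq_along(config$ptvs)) {
      ptv_name <- config$ptvs[pi]
      ptv <- preset_ptv(ptv_name, acq$image)
      sel <- select_beam_angles(0:359, metal_mask, ptv)
      plan <- plan_spec(sel$angles, config$prescription_gy, ptv,
                        beamlet_mm = config$beamlet_mm,
                        energy_mev = config$energy_mev)
      fl <- optimize_fluence(dens$uncorrected, plan, gamma = config$gamma,
                             iters = config$opt_iters, body = body,
                             table = table)
      doses <- recompute_plans(fl, plan, dens, mode = config$engine,
                               seed = derive_seed(config$seed,
                                                  cfg * 100L + 10L + pi),
                               histories = config$histories, table = table)
      plans[[key]][[ptv_name]] <- list(ptv = ptv, plan = plan, fluence = fl,
                                       doses = doses,
                                       feasibility = sel$feasibility)
      study_log("info", lvl, key, " ", ptv_name, " planned (",
                sel$feasibility, "), angles ",
                paste(sel$angles, collapse = "/"))
    }
  }
  report <- evaluate_study(datasets, plans,
                           config = list(seed = config$seed,
                                         config_hash = hash),
                           bin_gy = config$dvh_bin_gy)
  run <- structure(list(report = report, datasets = datasets, plans = plans,
                        reference_energy = e_ref, hash = hash),
                   class = "study_run")
  if (!is.null(config$out_dir)) write_study_artifacts(run, config)
  study_log("info", lvl, sprintf("study complete in %.1f s",
                                 as.numeric(Sys.time() - t0, units = "secs")))
  run
}

# write report, volumes and a hashed manifest
write_study_artifacts <- function(run, config) {
  dir <- config$out_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- write_report(run$report, dir)
  stages <- c("report", "report")
  for (key in names(run$datasets)) {
    ds <- run$datasets[[key]]
    for (nm in c("uncorrected", "corrected", "gt")) {
      vol <- ds[[nm]]
      vol$meta <- list(stage = nm, config_hash = run$hash,
                       seed = config$seed)
      f <- file.path(dir, paste0(key, "_", nm, ".nrrd"))
      write_nrrd(vol, f)
      files <- c(files, f); stages <- c(stages, "image")
    }
    for (ptv in names(run$plans[[key]])) {
      for (nm in names(run$plans[[key]][[ptv]]$doses)) {
        vol <- run$plans[[key]][[ptv]]$doses[[nm]]
        vol$meta <- list(stage = paste0("dose_", nm), ptv = ptv,
                         config_hash = run$hash, seed = config$seed)
        f <- file.path(dir, paste0(key, "_", ptv, "_dose_", nm, ".nrrd"))
        write_nrrd(vol, f)
        files <- c(files, f); stages <- c(stages, "dose")
      }
    }
  }
  manifest <- data.frame(file = basename(files), stage = stages,
                         md5 = unname(tools::md5sum(files)))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
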