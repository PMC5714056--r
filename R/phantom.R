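#' Digital insert phantom
#'
#' A cylindrical solid-water body with replaceable cylindrical insert slots,
#' modelled after a 16-slot tissue-characterization phantom. Slots A and B
#' hold the experimental inserts: 1 cm titanium (configuration 1), 3 cm
#' Cerrobend (configuration 2) or 3 cm solid water (configuration 3, the
#' basis of the software-substituted ground truth). A ring of
#' tissue-surrogate inserts occupies further slots.
#'
#' @name phantom
NULL

#' Phantom specification
#'
#' @param body_diameter_cm body cylinder diameter (cm).
#' @param body_material body material name.
#' @param slots data.frame with columns `name`, `x_cm`, `y_cm`,
#'   `diameter_cm`, `material`.
#' @param n in-plane matrix size (square), voxels.
#' @param spacing_mm in-plane voxel spacing (mm).
#' @param n_slices number of axial slices.
#' @param slice_mm slice thickness (mm), default 2.5.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(body_diameter_cm = 33, body_material = "solid_water",
                         slots = NULL, n = 256, spacing_mm = 1.5,
                         n_slices = 3, slice_mm = 2.5) {
  if (is.null(slots))
    slots <- data.frame(name = character(), x_cm = numeric(),
                        y_cm = numeric(), diameter_cm = numeric(),
                        material = character(), stringsAsFactors = FALSE)
  stopifnot(spacing_mm > 0, slice_mm > 0, n >= 8, n_slices >= 1)
  r_body <- body_diameter_cm / 2
  if (nrow(slots)) {
    d_cen <- sqrt(slots$x_cm^2 + slots$y_cm^2)
    out <- d_cen + slots$diameter_cm / 2 > r_body + 1e-9
    if (any(out))
      stop("slot(s) ", paste(slots$name[out], collapse = ", "),
           " extend outside the phantom body")
    if (nrow(slots) > 1) {
      for (i in seq_len(nrow(slots) - 1)) for (j in (i + 1):nrow(slots)) {
        d <- sqrt((slots$x_cm[i] - slots$x_cm[j])^2 +
                    (slots$y_cm[i] - slots$y_cm[j])^2)
        if (d < (slots$diameter_cm[i] + slots$diameter_cm[j]) / 2 - 1e-9)
          stop(sprintf("slots %s and %s overlap", slots$name[i], slots$name[j]))
      }
    }
  }
  structure(list(body_diameter_cm = body_diameter_cm,
                 body_material = body_material, slots = slots,
                 n = as.integer(n), spacing_mm = spacing_mm,
                 n_slices = as.integer(n_slices), slice_mm = slice_mm),
            class = "phantom_spec")
}

# default ring of tissue-surrogate inserts occupying non-experimental slots
default_ring_slots <- function() {
  ang <- c(15, 75, 135, 195, 255, 315) * pi / 180
  r <- 11
  data.frame(name = paste0("ring", seq_along(ang)),
             x_cm = r * cos(ang), y_cm = r * sin(ang),
             diameter_cm = 2.8,
             material = c("lung", "adipose", "breast", "liver",
                          "inner_bone", "cortical_bone"),
             stringsAsFactors = FALSE)
}

#' Standard phantom configurations
#'
#' Configuration 1: 1 cm titanium in slots A and B (low-Z metal).
#' Configuration 2: 3 cm Cerrobend in slots A and B (high-Z metal).
#' Configuration 3: 3 cm solid water in slots A and B (metal-free; used to
#' build the ground truth by software substitution).
#'
#' Slot A is at (-7, 0) cm and slot B at (7, 0) cm; both lie on the central
#' axial plane, so the worst streaks develop along the line joining them.
#'
#' @param configuration 1, 2 or 3.
#' @param n,spacing_mm,n_slices,slice_mm grid parameters, see [phantom_spec()].
#' @param ring include the tissue-surrogate insert ring (default TRUE).
#' @return a `phantom_spec`.
#' @export
standard_phantom <- function(configuration, n = 256, spacing_mm = 1.5,
                             n_slices = 3, slice_mm = 2.5, ring = TRUE) {
  stopifnot(configuration %in% 1:3)
  ins <- switch(configuration,
                `1` = list(d = 1, mat = "titanium"),
                `2` = list(d = 3, mat = "cerrobend"),
                `3` = list(d = 3, mat = "solid_water"))
  ab <- data.frame(name = c("A", "B"), x_cm = c(-7, 7), y_cm = c(0, 0),
                   diameter_cm = ins$d, material = ins$mat,
                   stringsAsFactors = FALSE)
  slots <- if (ring) rbind(ab, default_ring_slots()) else ab
  phantom_spec(slots = slots, n = n, spacing_mm = spacing_mm,
               n_slices = n_slices, slice_mm = slice_mm)
}

#' Voxelize a phantom specification
#'
#' A voxel takes a slot's label iff its center lies inside the slot disk;
#' voxels inside the body but outside every slot take the body material;
#' voxels outside the body are air. Deterministic.
#'
#' @param spec a `phantom_spec`.
#' @return a `ct_volume` of kind `"label"` whose data are 1-based indices
#'   into `attr(, "materials") = meta$materials` (a character vector;
#'   index 1 is always `"air"`).
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$n
  sp <- c(spec$spacing_mm, spec$spacing_mm, spec$slice_mm)
  ext <- c(n, n, spec$n_slices) * sp
  origin <- -ext / 2
  mats <- unique(c("air", spec$body_material, spec$slots$material))
  xc <- (origin[1] + (seq_len(n) - 0.5) * sp[1]) / 10  # cm
  yc <- (origin[2] + (seq_len(n) - 0.5) * sp[2]) / 10
  X <- matrix(xc, n, n)
  Y <- matrix(yc, n, n, byrow = TRUE)
  lab <- matrix(1L, n, n)
  body <- X^2 + Y^2 <= (spec$body_diameter_cm / 2)^2
  lab[body] <- match(spec$body_material, mats)
  if (nrow(spec$slots)) for (s in seq_len(nrow(spec$slots))) {
    inside <- (X - spec$slots$x_cm[s])^2 + (Y - spec$slots$y_cm[s])^2 <=
      (spec$slots$diameter_cm[s] / 2)^2
    lab[inside] <- match(spec$slots$material[s], mats)
  }
  arr <- array(lab, dim = c(n, n, spec$n_slices))
  ct_volume(arr, sp, origin, kind = "label",
            meta = list(materials = mats, spec = spec))
}

# boolean mask of voxels labeled with a given material
label_mask <- function(labels, material_name) {
  idx <- match(material_name, labels$meta$materials)
  if (is.na(idx)) array(FALSE, dim(labels$data)) else labels$data == idx
}

# mask of a named slot's voxel set (center-in-disk, matching build_phantom)
slot_mask <- function(labels, slot_name) {
  spec <- labels$meta$spec
  s <- match(slot_name, spec$slots$name)
  if (is.na(s)) stop("slot '", slot_name, "' not defined in phantom spec")
  n <- spec$n
  xc <- (labels$origin[1] + (seq_len(n) - 0.5) * labels$spacing[1]) / 10
  yc <- (labels$origin[2] + (seq_len(n) - 0.5) * labels$spacing[2]) / 10
  X <- matrix(xc, n, n); Y <- matrix(yc, n, n, byrow = TRUE)
  inside <- (X - spec$slots$x_cm[s])^2 + (Y - spec$slots$y_cm[s])^2 <=
    (spec$slots$diameter_cm[s] / 2)^2
  array(inside, dim(labels$data))
}

#' Construct the artifact-free ground truth
#'
#' Takes the reconstructed metal-free (solid water in slots A/B)
#' configuration-3 image and overwrites the voxels of the named slots with
#' the HU value of the substituted material at the reconstruction reference
#' energy (clamped to the scanner range). All other voxels are untouched.
#'
#' @param solid_water_volume reconstructed configuration-3 `ct_volume` (HU).
#' @param labels `ct_volume` labels of the metal-bearing configuration
#'   (defines the slot voxel sets to substitute).
#' @param substitutions named list mapping slot name to a `ct_material`,
#'   e.g. `list(A = mat$titanium, B = mat$titanium)`.
#' @param table an `attenuation_table`.
#' @param reference_energy reconstruction reference energy (keV).
#' @return ground-truth `ct_volume` (HU).
#' @export
make_ground_truth <- function(solid_water_volume, labels, substitutions,
                              table, reference_energy) {
  stopifnot(inherits(solid_water_volume, "ct_volume"))
  gt <- solid_water_volume
  mu_w <- loglog_interp(table$energy, table$mu_rho[, "water"],
                        reference_energy)
  for (slot in names(substitutions)) {
    m <- substitutions[[slot]]
    mask <- slot_mask(labels, slot)
    hu <- hu_from_mu(linear_attenuation(m, reference_energy, table), mu_w)
    gt$data[mask] <- hu
  }
  gt$meta$stage <- "ground_truth"
  gt
}

#' Cylindrical planning target volume mask
#'
#' @param center_cm length-2 (x, y) center in cm.
#' @param diameter_cm cylinder diameter, default 4 cm.
#' @param reference `ct_volume` defining the grid.
#' @param name structure name.
#' @return a mask `ct_volume` (all slices).
#' @export
define_ptv <- function(center_cm, diameter_cm = 4, reference,
                       name = "PTV") {
  n <- dim(reference$data)[1:2]
  xc <- (reference$origin[1] + (seq_len(n[1]) - 0.5) * reference$spacing[1]) / 10
  yc <- (reference$origin[2] + (seq_len(n[2]) - 0.5) * reference$spacing[2]) / 10
  X <- matrix(xc, n[1], n[2]); Y <- matrix(yc, n[1], n[2], byrow = TRUE)
  inside <- (X - center_cm[1])^2 + (Y - center_cm[2])^2 <= (diameter_cm / 2)^2
  if (!any(inside)) stop("empty PTV mask: cylinder misses the grid")
  arr <- array(inside, dim(reference$data))
  structure_mask(arr, reference, name = name)
}

#' Preset PTV locations
#'
#' PTV1 sits midway between the two insert slots, centered on the worst
#' streak band; PTV2 sits off-axis near the streak band; PTV3 sits on
#' slot A and therefore overlaps the metal insert. All are 4 cm diameter;
#' the centers are commensurate with the default voxel lattices so the
#' three cylinders rasterize to identical voxel counts.
#'
#' @param which `"PTV1"`, `"PTV2"` or `"PTV3"`.
#' @param reference `ct_volume` defining the grid.
#' @return a mask `ct_volume`.
#' @export
preset_ptv <- function(which = c("PTV1", "PTV2", "PTV3"), reference) {
  which <- match.arg(which)
  center <- switch(which,
                   PTV1 = c(0, 0),
                   PTV2 = c(0, 4.5),
                   PTV3 = c(-6.9, 0))
  define_ptv(center, 4, reference, name = which)
}

# body mask (voxels inside the body cylinder) from a phantom spec
body_mask_from_spec <- function(spec, reference) {
  n <- dim(reference$data)[1:2]
  xc <- (reference$origin[1] + (seq_len(n[1]) - 0.5) * reference$spacing[1]) / 10
  yc <- (reference$origin[2] + (seq_len(n[2]) - 0.5) * reference$spacing[2]) / 10
  X <- matrix(xc, n[1], n[2]); Y <- matrix(yc, n[1], n[2], byrow = TRUE)
  inside <- X^2 + Y^2 <= (spec$body_diameter_cm / 2)^2
  structure_mask(array(inside, dim(reference$data)), reference, name = "body")
}
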