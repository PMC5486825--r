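# Phantom configuration: acquisition geometry, tissue diffusion parameters,
# delineation behaviour and noise model for the synthetic DWI cohort.

#' Default tissue parameter table
#'
#' One row per tissue compartment of the pelvic phantom. `s0` is the
#' noise-free signal at b = 0 in arbitrary units; `adc_mean` / `adc_sd` give
#' the within-case voxelwise ADC distribution (truncated normal, mm^2/s);
#' `adc_case_sd` is the between-case SD of the tissue's mean ADC, so that
#' subjects differ the way patients do (tumor mean ADC spread across cases
#' of about 0.25e-3 mm^2/s).
#'
#' Tumor diffusion is centred at 1.44e-3 mm^2/s. The urinary bladder is the
#' high-ADC contaminant (3.0e-3), normal rectal wall sits at 1.8e-3 and
#' pelvic muscle at 1.6e-3, the air-filled lumen is near zero with a signal
#' at the noise floor, and mesorectal fat is fat-suppressed (low s0) with
#' intermediate-low apparent ADC (partial suppression and partial-volume
#' mixing with mesorectal vessels and connective tissue).
#'
#' @return data.frame with columns `tissue`, `label`, `s0`, `adc_mean`,
#'   `adc_sd`, `adc_case_sd`.
#' @export
default_tissue_params <- function() {
  data.frame(
    tissue      = c("background", "tumor", "rectal_wall", "lumen",
                    "mesorectal_fat", "bladder", "muscle"),
    label       = 0:6,
    s0          = c(3, 1000, 800, 10, 150, 1200, 600),
    adc_mean    = c(2e-5, 1.44e-3, 1.8e-3, 2e-5, 1.1e-3, 3.0e-3, 1.6e-3),
    adc_sd      = c(1e-5, 3.8e-4, 2.0e-4, 1e-5, 3.0e-4, 1.5e-4, 1.5e-4),
    adc_case_sd = c(0, 2.5e-4, 1.0e-4, 0, 5e-5, 1.5e-4, 1.0e-4),
    stringsAsFactors = FALSE
  )
}

#' Configuration of the synthetic DWI phantom
#'
#' Defaults emulate the acquisition of the study protocol this package
#' models: six b-values (0, 25, 50, 100, 500, 1000 s/mm^2), 1.82 x 2.26 mm
#' in-plane voxels and 5.0 mm slices with a 0.5 mm gap (5.5 mm
#' centre-to-centre), and a rectal tumor drawn as a random ellipsoid whose
#' volume is of the order of 3 cm^3.
#'
#' @param grid_shape integer triple, voxels along (x, y, z).
#' @param voxel_spacing numeric triple, mm per axis; the z entry is the
#'   slice centre-to-centre distance (thickness + gap).
#' @param b_values strictly increasing b-values in s/mm^2, first must be 0.
#' @param tissue_params data.frame as [default_tissue_params()].
#' @param tumor_semiaxes list with elements `x`, `y`, `z`: (min, max) ranges
#'   in mm for the tumor ellipsoid semi-axes.
#' @param margin_mm non-precise delineation margin added around the tumor
#'   cross-section on every slice, in mm. The default is calibrated so the
#'   cohort-mean non-precise VOI volume is about three times the precise
#'   volume.
#' @param noise_sigma Rician noise scale in signal units. The default keeps
#'   the fitted tumor-mean ADC bias below 2% of truth.
#' @param reader_jitter reader-variability magnitude: the probability that a
#'   precise-delineation boundary voxel is flipped, and (scaled by 2 mm) the
#'   SD of the per-slice margin/centre perturbation of the non-precise
#'   ellipse. 0 gives identical masks for all readers.
#' @param seed master seed for cohort generation.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(48L, 40L, 20L),
                           voxel_spacing = c(1.82, 2.26, 5.5),
                           b_values = c(0, 25, 50, 100, 500, 1000),
                           tissue_params = default_tissue_params(),
                           tumor_semiaxes = list(x = c(7, 13),
                                                 y = c(7, 13),
                                                 z = c(6, 12)),
                           margin_mm = 6.5,
                           noise_sigma = 10,
                           reader_jitter = 0.2,
                           seed = 1L) {
  cfg <- list(grid_shape = as.integer(grid_shape),
              voxel_spacing = as.numeric(voxel_spacing),
              b_values = as.numeric(b_values),
              tissue_params = tissue_params,
              tumor_semiaxes = tumor_semiaxes,
              margin_mm = margin_mm,
              noise_sigma = noise_sigma,
              reader_jitter = reader_jitter,
              seed = as.integer(seed))
  class(cfg) <- "phantom_config"
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  if (length(cfg$grid_shape) != 3L || any(cfg$grid_shape < 8L))
    input_error("grid_shape must be three voxel counts, each >= 8")
  if (length(cfg$voxel_spacing) != 3L || any(cfg$voxel_spacing <= 0))
    input_error("voxel_spacing entries must all be > 0")
  b <- cfg$b_values
  if (length(b) < 2L || any(diff(b) <= 0))
    input_error("b_values must be strictly increasing with length >= 2")
  if (b[1] != 0)
    input_error("first b-value must be 0")
  tp <- cfg$tissue_params
  need <- c("tissue", "label", "s0", "adc_mean", "adc_sd", "adc_case_sd")
  if (!all(need %in% names(tp)))
    input_error("tissue_params must have columns ",
                paste(need, collapse = ", "))
  if (any(tp$adc_mean < 0))
    input_error("tissue ADC means must be >= 0")
  if (cfg$noise_sigma < 0) input_error("noise_sigma must be >= 0")
  if (cfg$margin_mm < 0) input_error("margin_mm must be >= 0")
  if (cfg$reader_jitter < 0) input_error("reader_jitter must be >= 0")
  for (ax in c("x", "y", "z")) {
    r <- cfg$tumor_semiaxes[[ax]]
    if (is.null(r) || length(r) != 2L || r[1] <= 0 || r[2] < r[1])
      input_error("tumor_semiaxes$", ax, " must be a valid (min, max) range")
  }
  # the largest tumor, plus the rectal wall shell and placement jitter, must
  # stay clear of the volume edge
  fov <- cfg$grid_shape * cfg$voxel_spacing
  clearance <- c(4, 4, 2.75) + 3 + 2 * cfg$voxel_spacing  # jitter + wall + 2 voxels
  for (i in 1:3) {
    ax <- c("x", "y", "z")[i]
    if (cfg$tumor_semiaxes[[ax]][2] + clearance[i] > fov[i] / 2)
      input_error("tumor does not fit in grid: semi-axis ", ax,
                  " up to ", cfg$tumor_semiaxes[[ax]][2],
                  " mm exceeds the available half-extent of ",
                  signif(fov[i] / 2 - clearance[i], 4), " mm")
  }
  invisible(cfg)
}
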