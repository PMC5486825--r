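# Synthetic DWI phantom: pelvic tissue geometry, mono-exponential signal
# generation with Rician noise, and simulated reader delineations.

tissue_label <- function(cfg, tissue) {
  tp <- cfg$tissue_params
  tp$label[match(tissue, tp$tissue)]
}

# voxel-centre coordinate arrays (mm) for a grid
grid_coords <- function(shape, spacing) {
  list(x = (seq_len(shape[1]) - 0.5) * spacing[1],
       y = (seq_len(shape[2]) - 0.5) * spacing[2],
       z = (seq_len(shape[3]) - 0.5) * spacing[3])
}

# logical 3-D array: voxel centres inside an axis-aligned ellipsoid
ellipsoid_mask <- function(co, centre, semi) {
  dx2 <- ((co$x - centre[1]) / semi[1])^2
  dy2 <- ((co$y - centre[2]) / semi[2])^2
  dz2 <- ((co$z - centre[3]) / semi[3])^2
  r <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  r <= 1
}

#' Build one synthetic DWI phantom case
#'
#' Places a random ellipsoidal tumor in the rectal wall, surrounds it with
#' lumen (air), rectal wall, mesorectal fat, an adjacent high-ADC bladder and
#' pelvic muscle, draws per-voxel ground-truth ADC values from truncated
#' normals, and synthesises the DWI series through the mono-exponential
#' decay model S(b) = S0 * exp(-b * ADC) with Rician magnitude noise.
#' Two simulated readers per delineation method are attached.
#'
#' @param config a [phantom_config()].
#' @param case_seed integer seed controlling every random element of the case.
#' @param case_id identifier stored with the case.
#' @return object of class `phantom_case`: a list with elements `dwi`
#'   (class `dwi_series`: `signal` 4-D array, `b_values`, `voxel_spacing`),
#'   `label_map` (3-D integer array), `tissue_params`, `truth_adc` (class
#'   `adc_map`), `tumor` (centre/semi-axes in mm), `precise_masks` and
#'   `nonprecise_masks` (lists of `voi_mask`), and `case_id`.
#' @export
build_phantom_case <- function(config, case_seed, case_id = "case") {
  validate_phantom_config(config)
  cfg <- config
  shape <- cfg$grid_shape
  sp <- cfg$voxel_spacing
  fov <- shape * sp
  co <- grid_coords(shape, sp)

  geom <- with_seed(case_seed, {
    semi <- c(stats::runif(1, cfg$tumor_semiaxes$x[1], cfg$tumor_semiaxes$x[2]),
              stats::runif(1, cfg$tumor_semiaxes$y[1], cfg$tumor_semiaxes$y[2]),
              stats::runif(1, cfg$tumor_semiaxes$z[1], cfg$tumor_semiaxes$z[2]))
    centre <- fov / 2 + c(stats::runif(1, -4, 4), stats::runif(1, -4, 4),
                          stats::runif(1, -2.75, 2.75))
    tp <- cfg$tissue_params
    case_means <- pmax(tp$adc_mean + stats::rnorm(nrow(tp)) * tp$adc_case_sd,
                       1e-5)
    list(semi = semi, centre = centre, case_means = case_means)
  })
  semi <- geom$semi; centre <- geom$centre

  # --- tissue label map, assigned in precedence order ---------------------
  # muscle fills the pelvis (pelvic organs and musculature, ~1.6e-3); the
  # rectum = tumor + air lumen + 3 mm wall, wrapped in a thin ring of
  # fat-suppressed mesorectal fat; the urine-filled bladder sits against
  # the anterior wall so a margin delineation picks up high-ADC voxels
  lab <- array(tissue_label(cfg, "muscle"), dim = shape)
  tumor <- ellipsoid_mask(co, centre, semi)
  lumen_semi <- c(min(semi[1], 6), 3, max(semi[3] * 0.7, 3))
  lumen_centre <- centre + c(0, semi[2] * 0.8 + 2.5, 0)
  lumen <- ellipsoid_mask(co, lumen_centre, lumen_semi)
  wall <- (ellipsoid_mask(co, centre, semi + 3) |
             ellipsoid_mask(co, lumen_centre, lumen_semi + 3))
  bladder <- ellipsoid_mask(co, centre + c(0, -(semi[2] + 3 + 16), 0),
                            c(24, 16, 22))
  fat <- ellipsoid_mask(co, centre, semi + 5.5)
  lab[fat] <- tissue_label(cfg, "mesorectal_fat")
  lab[bladder] <- tissue_label(cfg, "bladder")
  lab[wall] <- tissue_label(cfg, "rectal_wall")
  lab[lumen] <- tissue_label(cfg, "lumen")
  lab[tumor] <- tissue_label(cfg, "tumor")
  # thin air frame at the in-plane volume edge, where nothing else sits
  frame <- array(FALSE, dim = shape)
  frame[c(1:2, shape[1] - 1:0), , ] <- TRUE
  frame[, c(1:2, shape[2] - 1:0), ] <- TRUE
  bg <- frame & lab == tissue_label(cfg, "muscle")
  lab[bg] <- tissue_label(cfg, "background")

  # --- ground-truth ADC and signal ---------------------------------------
  tp <- cfg$tissue_params
  idx <- match(lab, tp$label)
  nb <- length(cfg$b_values)
  sim <- with_seed(derive_seed(case_seed, 1L), {
    adc <- pmax(geom$case_means[idx] + stats::rnorm(length(idx)) * tp$adc_sd[idx],
                1e-5)
    s0 <- tp$s0[idx]
    signal <- array(0, dim = c(shape, nb))
    for (j in seq_len(nb)) {
      s <- s0 * exp(-cfg$b_values[j] * adc)
      if (cfg$noise_sigma > 0) {
        n1 <- stats::rnorm(length(s)) * cfg$noise_sigma
        n2 <- stats::rnorm(length(s)) * cfg$noise_sigma
        s <- sqrt((s + n1)^2 + n2^2)
      }
      signal[, , , j] <- s
    }
    list(adc = array(adc, dim = shape), signal = signal)
  })

  case <- list(
    dwi = structure(list(signal = sim$signal, b_values = cfg$b_values,
                         voxel_spacing = sp), class = "dwi_series"),
    label_map = lab,
    tissue_params = tp,
    truth_adc = structure(list(adc = sim$adc, voxel_spacing = sp,
                               fit_valid = array(TRUE, dim = shape)),
                          class = "adc_map"),
    tumor = list(centre = centre, semi = semi),
    config = cfg,
    case_id = case_id
  )
  class(case) <- "phantom_case"

  case$precise_masks <- list(
    R1 = draw_precise_mask(case, cfg$reader_jitter, derive_seed(case_seed, 2L),
                           reader_id = "R1"),
    R2 = draw_precise_mask(case, cfg$reader_jitter, derive_seed(case_seed, 3L),
                           reader_id = "R2"))
  case$nonprecise_masks <- list(
    R3 = draw_nonprecise_mask(case, cfg$margin_mm, derive_seed(case_seed, 4L),
                              reader_id = "R3"),
    R4 = draw_nonprecise_mask(case, cfg$margin_mm, derive_seed(case_seed, 5L),
                              reader_id = "R4"))
  case
}

new_voi_mask <- function(mask, method, reader_id, spacing) {
  structure(list(mask = mask, method = method, reader_id = reader_id,
                 voxel_spacing = spacing), class = "voi_mask")
}

# in-plane (slice-wise) 4-neighbour boundary layers of a 3-D mask
slice_boundaries <- function(m) {
  d <- dim(m)
  shift <- function(a, dx, dy) {
    out <- array(FALSE, dim = d)
    xs <- seq_len(d[1]); ys <- seq_len(d[2])
    xs_src <- xs - dx; ys_src <- ys - dy
    okx <- xs_src >= 1 & xs_src <= d[1]
    oky <- ys_src >= 1 & ys_src <= d[2]
    out[xs[okx], ys[oky], ] <- a[xs_src[okx], ys_src[oky], ]
    out
  }
  nb <- shift(m, 1, 0) | shift(m, -1, 0) | shift(m, 0, 1) | shift(m, 0, -1)
  inner <- m & !(shift(m, 1, 0) & shift(m, -1, 0) &
                   shift(m, 0, 1) & shift(m, 0, -1))
  outer_b <- !m & nb
  list(inner = inner, outer = outer_b)
}

#' Simulate a precise (tumor-tracing) delineation for one reader
#'
#' The reader closely traces the tumor on every slice; inter-reader
#' variability is modelled as a seeded random flip of in-plane boundary
#' voxels: each voxel of the inner boundary layer is dropped, and each voxel
#' of the outer layer added, independently with probability `reader_jitter`.
#' `reader_jitter = 0` returns exactly the tumor label set, and the eroded
#' tumor core is always retained.
#'
#' @param case a `phantom_case`.
#' @param reader_jitter flip probability in [0, 1].
#' @param reader_seed integer seed for this reader.
#' @param reader_id label stored in the mask.
#' @return a `voi_mask` with `method = "precise"`.
#' @export
draw_precise_mask <- function(case, reader_jitter, reader_seed,
                              reader_id = "R1") {
  tumor <- case$label_map == tissue_label(case$config, "tumor")
  if (!any(tumor)) input_error("case has no tumor voxels")
  m <- tumor
  if (reader_jitter > 0) {
    b <- slice_boundaries(tumor)
    m <- with_seed(reader_seed, {
      drop_idx <- which(b$inner)
      add_idx <- which(b$outer)
      m[drop_idx[stats::runif(length(drop_idx)) < reader_jitter]] <- FALSE
      m[add_idx[stats::runif(length(add_idx)) < reader_jitter]] <- TRUE
      m
    })
  }
  new_voi_mask(m, "precise", reader_id, case$dwi$voxel_spacing)
}

#' Simulate a non-precise (circular/oval with margin) delineation
#'
#' On every slice containing tumor, the reader draws the filled bounding
#' ellipse of the tumor cross-section expanded by `margin_mm`, so the VOI
#' includes surrounding rectal wall, fat, lumen and - when the margin
#' reaches it - bladder. Reader variability perturbs the per-slice margin
#' and ellipse centre (SD = 2 mm x the configured `reader_jitter`). A
#' warning is issued if the ellipse is clipped at the volume edge.
#'
#' @inheritParams draw_precise_mask
#' @param margin_mm margin around the tumor cross-section, mm (>= 0).
#' @return a `voi_mask` with `method = "nonprecise"`.
#' @export
draw_nonprecise_mask <- function(case, margin_mm, reader_seed,
                                 reader_id = "R3") {
  if (margin_mm < 0) input_error("margin_mm must be >= 0")
  cfg <- case$config
  shape <- dim(case$label_map)
  sp <- case$dwi$voxel_spacing
  co <- grid_coords(shape, sp)
  centre <- case$tumor$centre; semi <- case$tumor$semi
  tumor <- case$label_map == tissue_label(cfg, "tumor")
  slices <- which(apply(tumor, 3, any))
  jit_sd <- 2 * cfg$reader_jitter
  m <- array(FALSE, dim = shape)
  clipped <- FALSE
  with_seed(reader_seed, {
    for (k in slices) {
      rz <- 1 - ((co$z[k] - centre[3]) / semi[3])^2
      if (rz <= 0) next
      az <- semi[1] * sqrt(rz) + margin_mm + max(stats::rnorm(1, 0, jit_sd), -margin_mm / 2)
      bz <- semi[2] * sqrt(rz) + margin_mm + max(stats::rnorm(1, 0, jit_sd), -margin_mm / 2)
      cx <- centre[1] + stats::rnorm(1, 0, jit_sd)
      cy <- centre[2] + stats::rnorm(1, 0, jit_sd)
      if (cx - az < 0 || cx + az > shape[1] * sp[1] ||
          cy - bz < 0 || cy + bz > shape[2] * sp[2]) clipped <- TRUE
      ell <- outer(((co$x - cx) / az)^2, ((co$y - cy) / bz)^2, `+`) <= 1
      m[, , k] <- m[, , k] | ell
    }
  })
  if (clipped)
    warning("non-precise VOI clipped at the volume edge for reader ",
            reader_id, call. = FALSE)
  new_voi_mask(m, "nonprecise", reader_id, sp)
}

#' Generate a synthetic cohort with prognostic labels
#'
#' Cases are generated with independent seeds derived from `config$seed`.
#' Binary outcome labels mimic a primary-staging rectal cancer cohort: cN
#' stage and mesorectal fascia (cMRF) involvement depend on tumor volume
#' through a logistic model with slope `outcome_effect` on the standardised
#' volume (the only true imaging signal), while differentiation grade,
#' response and distant metastasis are independent Bernoulli draws.
#'
#' @param config a [phantom_config()].
#' @param n_cases number of cases (>= 2).
#' @param outcome_effect logistic slope of cN/cMRF on standardised tumor
#'   volume; 0 makes all labels independent of imaging.
#' @return list with `cases` (list of `phantom_case`) and `labels`
#'   (data.frame: case_id, cN, cMRF, differentiation, response, metastasis).
#' @export
generate_cohort <- function(config, n_cases = 37L, outcome_effect = 2.5) {
  if (n_cases < 2) input_error("n_cases must be >= 2 (group statistics undefined)")
  cases <- lapply(seq_len(n_cases), function(i) {
    build_phantom_case(config, derive_seed(config$seed, i * 101L),
                       case_id = sprintf("case_%02d", i))
  })
  labels <- cohort_labels(cases, outcome_effect,
                          derive_seed(config$seed, 999983L))
  list(cases = cases, labels = labels)
}

# expected tumor volume and SD (mm^3) under the configured semi-axis ranges,
# used to standardise volume in the label model without peeking at the cohort
tumor_volume_moments <- function(cfg) {
  mid <- function(r) mean(r)
  sdu <- function(r) diff(r) / sqrt(12)
  a <- cfg$tumor_semiaxes$x; b <- cfg$tumor_semiaxes$y; c3 <- cfg$tumor_semiaxes$z
  mu <- 4 / 3 * pi * mid(a) * mid(b) * mid(c3)
  cv <- sqrt((sdu(a) / mid(a))^2 + (sdu(b) / mid(b))^2 + (sdu(c3) / mid(c3))^2)
  list(mean = mu, sd = mu * cv)
}

cohort_labels <- function(cases, outcome_effect, seed) {
  cfg <- cases[[1]]$config
  vm <- tumor_volume_moments(cfg)
  vol <- vapply(cases, function(cs) {
    sum(cs$label_map == tissue_label(cfg, "tumor")) *
      prod(cs$dwi$voxel_spacing)
  }, numeric(1))
  z <- (vol - vm$mean) / vm$sd
  with_seed(seed, {
    data.frame(
      case_id = vapply(cases, `[[`, character(1), "case_id"),
      cN = as.integer(stats::runif(length(z)) <
                        stats::plogis(0.85 + outcome_effect * z)),
      cMRF = as.integer(stats::runif(length(z)) <
                          stats::plogis(-0.49 + outcome_effect * z)),
      differentiation = stats::rbinom(length(z), 1, 0.15),
      response = stats::rbinom(length(z), 1, 0.45),
      metastasis = stats::rbinom(length(z), 1, 0.22),
      stringsAsFactors = FALSE
    )
  })
}

#' Write a phantom case to NIfTI files
#'
#' Writes `case_<id>_dwi.nii.gz` (4-D), `case_<id>_labels.nii.gz`, one mask
#' per method/reader, and an FSL-style `case_<id>.bval` sidecar (single
#' space-separated line).
#'
#' @param case a `phantom_case`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_phantom_case <- function(case, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sp <- case$dwi$voxel_spacing
  id <- case$case_id
  paths <- character(0)
  nii <- function(arr, path) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- c(sp, rep(1, length(dim(arr)) - 3))
    RNifti::writeNifti(img, path)
    path
  }
  paths <- c(paths, nii(case$dwi$signal, file.path(dir, paste0(id, "_dwi.nii.gz"))))
  paths <- c(paths, nii(case$label_map, file.path(dir, paste0(id, "_labels.nii.gz"))))
  for (mk in c(case$precise_masks, case$nonprecise_masks)) {
    p <- file.path(dir, sprintf("%s_mask_%s_%s.nii.gz", id, mk$method, mk$reader_id))
    paths <- c(paths, nii(array(as.integer(mk$mask), dim = dim(mk$mask)), p))
  }
  bval <- file.path(dir, paste0(id, ".bval"))
  writeLines(paste(format(case$dwi$b_values, trim = TRUE), collapse = " "), bval)
  invisible(c(paths, bval))
}
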