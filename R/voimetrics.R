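# First-order histogram metrics of ADC values inside a VOI, plus VOI volume.
# All ADC values are reported in units of 1e-3 mm^2/s, matching the scale on
# which tumor ADC is conventionally printed (e.g. a mean of 1.44).

#' Extract the ADC value sample of a VOI
#'
#' Returns the ADC values (in 1e-3 mm^2/s) at mask voxels with a valid fit;
#' voxels excluded because their fit was invalid are counted separately.
#'
#' @param adc_map an `adc_map`.
#' @param voi a `voi_mask` on the same grid.
#' @return list with `values` (numeric vector, 1e-3 mm^2/s) and
#'   `n_excluded` (mask voxels dropped for invalid fits).
#' @export
extract_voi_values <- function(adc_map, voi) {
  if (!identical(dim(adc_map$adc), dim(voi$mask)))
    input_error("ADC map and VOI mask grids do not match")
  if (!any(voi$mask)) input_error("VOI mask is empty")
  sel <- voi$mask & adc_map$fit_valid
  if (!any(sel))
    input_error("VOI has no voxels with a valid ADC fit")
  list(values = adc_map$adc[sel] * 1000,
       n_excluded = sum(voi$mask & !adc_map$fit_valid))
}

#' Percentile grid used throughout: every fifth percentile, 5th to 95th
#' @noRd
percentile_probs <- function() seq(5, 95, by = 5)

#' First-order histogram metrics of a value sample
#'
#' Computes minimum, maximum, mean, median, SD (n-1 denominator), skewness
#' (biased population coefficient m3 / m2^1.5), kurtosis in the Pearson
#' non-excess convention (m4 / m2^2; normal samples give ~3), and every
#' fifth percentile (5th-95th) by linear interpolation between order
#' statistics. Skewness and kurtosis need at least 3 values and are NA
#' below that. The VOI volume is the *total* mask voxel count times the
#' voxel volume - delineated voxels whose fit failed still count toward
#' volume, while `n_voxels` is the metric sample size.
#'
#' @param sample numeric vector of ADC values (1e-3 mm^2/s), length >= 1.
#' @param voxel_volume_mm3 volume of one voxel in mm^3.
#' @param n_mask_voxels total voxels in the delineation (defaults to the
#'   sample size).
#' @return named list: `volume_cm3`, `n_voxels`, `min`, `max`, `mean`,
#'   `median`, `sd`, `skew`, `kurt`, `p5` ... `p95`.
#' @export
compute_histogram_metrics <- function(sample, voxel_volume_mm3,
                                      n_mask_voxels = length(sample)) {
  n <- length(sample)
  if (n < 1) input_error("empty sample")
  m <- mean(sample)
  ctr <- sample - m
  m2 <- mean(ctr^2)
  skew <- kurt <- NA_real_
  if (n >= 3 && m2 > 0) {
    skew <- mean(ctr^3) / m2^1.5
    kurt <- mean(ctr^4) / m2^2
  }
  q <- stats::quantile(sample, probs = percentile_probs() / 100,
                       names = FALSE, type = 7)
  out <- c(list(volume_cm3 = n_mask_voxels * voxel_volume_mm3 / 1000,
                n_voxels = n,
                min = min(sample), max = max(sample), mean = m,
                median = stats::median(sample),
                sd = if (n > 1) stats::sd(sample) else 0,
                skew = skew, kurt = kurt),
           stats::setNames(as.list(q), paste0("p", percentile_probs())))
  out
}

#' VOI volume in cm^3
#'
#' @param voi a `voi_mask` with known voxel spacing.
#' @return volume in cm^3 (voxel count x voxel volume / 1000).
#' @export
compute_volume <- function(voi) {
  sum(voi$mask) * prod(voi$voxel_spacing) / 1000
}

#' Histogram metrics for one (ADC map, VOI) pair
#'
#' @param adc_map an `adc_map`.
#' @param voi a `voi_mask`.
#' @return one-row data.frame with `method`, `reader` and all metric columns.
#' @export
voi_metrics <- function(adc_map, voi) {
  s <- extract_voi_values(adc_map, voi)
  met <- compute_histogram_metrics(s$values, prod(voi$voxel_spacing),
                                   n_mask_voxels = sum(voi$mask))
  cbind(data.frame(method = voi$method, reader = voi$reader_id,
                   n_excluded = s$n_excluded, stringsAsFactors = FALSE),
        as.data.frame(met))
}

#' Histogram metrics for every (case, method, reader) of a cohort
#'
#' Fits the ADC map of every case and extracts metrics for both precise and
#' both non-precise reader masks.
#'
#' @param cases list of `phantom_case`.
#' @return data.frame, one row per case x method x reader, with a `case_id`
#'   column followed by the columns of [voi_metrics()].
#' @export
cohort_metrics <- function(cases) {
  rows <- lapply(cases, function(cs) {
    amap <- compute_adc_map(cs$dwi)
    do.call(rbind, lapply(c(cs$precise_masks, cs$nonprecise_masks),
                          function(mk) {
      cbind(data.frame(case_id = cs$case_id, stringsAsFactors = FALSE),
            voi_metrics(amap, mk))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Average the two readers of each method
#'
#' Produces one row per case x method with every metric column averaged over
#' the method's two readers - the form used for between-method agreement and
#' for the prognostic group comparisons.
#'
#' @param metrics data.frame from [cohort_metrics()].
#' @return data.frame keyed by (case_id, method).
#' @export
reader_average <- function(metrics) {
  num_cols <- setdiff(names(metrics)[vapply(metrics, is.numeric, logical(1))],
                      character(0))
  agg <- stats::aggregate(metrics[num_cols],
                          by = list(case_id = metrics$case_id,
                                    method = metrics$method),
                          FUN = mean)
  agg[order(agg$method, agg$case_id), , drop = FALSE]
}

#' Read a VOI mask from NIfTI
#'
#' @param path path to a mask volume (non-zero = inside).
#' @param method `"precise"` or `"nonprecise"`.
#' @param reader_id reader label.
#' @return a `voi_mask`.
#' @export
read_voi_mask <- function(path, method, reader_id) {
  img <- RNifti::readNifti(path)
  structure(list(mask = array(as.numeric(img) > 0, dim = dim(img)),
                 method = method, reader_id = reader_id,
                 voxel_spacing = RNifti::pixdim(img)[1:3]),
            class = "voi_mask")
}
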