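# Voxelwise ADC mapping from multi-b-value DWI via the mono-exponential
# decay model S(b) = S0 * exp(-b * ADC), fitted as ordinary least squares on
# ln S(b) vs b. A nonlinear least-squares variant is available for
# sensitivity checks.

#' Fit the mono-exponential decay model at a single voxel
#'
#' Log-linear OLS of ln S on b over all b-points with S > 0 (nonpositive
#' signals are dropped rather than invalidating the voxel). The fit is valid
#' when at least two positive signals remain. A negative fitted ADC
#' (increasing signal) is clipped to 0 and flagged.
#'
#' @param signals signal values, one per b-value.
#' @param b_values b-values in s/mm^2, same length as `signals`.
#' @param method `"loglinear"` (default) or `"nls"` for unweighted nonlinear
#'   least squares on the exponential model itself (initialised from the
#'   log-linear fit).
#' @return list with `adc` (mm^2/s, >= 0; 0 when invalid), `s0`, `valid`,
#'   `clipped`.
#' @export
fit_adc_voxel <- function(signals, b_values, method = c("loglinear", "nls")) {
  method <- match.arg(method)
  if (length(signals) != length(b_values) || length(b_values) < 2)
    input_error("signals and b_values must have equal length >= 2")
  ok <- is.finite(signals) & signals > 0
  if (sum(ok) < 2)
    return(list(adc = 0, s0 = NA_real_, valid = FALSE, clipped = FALSE))
  b <- b_values[ok]; l <- log(signals[ok])
  n <- length(b)
  den <- n * sum(b^2) - sum(b)^2
  slope <- (n * sum(b * l) - sum(b) * sum(l)) / den
  intercept <- (sum(l) - slope * sum(b)) / n
  adc <- -slope
  s0 <- exp(intercept)
  if (method == "nls") {
    df <- data.frame(S = signals[ok], b = b)
    fit <- try(stats::nls(S ~ s0 * exp(-b * adc), data = df,
                          start = list(s0 = s0, adc = max(adc, 1e-6)),
                          control = stats::nls.control(warnOnly = TRUE,
                                                       scaleOffset = 1)),
               silent = TRUE)
    if (!inherits(fit, "try-error")) {
      cf <- stats::coef(fit)
      s0 <- unname(cf["s0"]); adc <- unname(cf["adc"])
    }
  }
  clipped <- adc < 0
  list(adc = max(adc, 0), s0 = s0, valid = TRUE, clipped = clipped)
}

#' Compute a voxelwise ADC map from a DWI series
#'
#' Vectorised application of the per-voxel log-linear fit of
#' [fit_adc_voxel()] over the whole volume.
#'
#' @param dwi a `dwi_series` (4-D `signal` array, `b_values`,
#'   `voxel_spacing`), e.g. from [build_phantom_case()] or [read_dwi()].
#' @param method fit variant, as in [fit_adc_voxel()]; `"nls"` loops over
#'   voxels and is intended for small volumes only.
#' @return an `adc_map`: list with `adc` (3-D, mm^2/s), `s0`, `fit_valid`,
#'   `clipped` (3-D logical) and `voxel_spacing`.
#' @export
compute_adc_map <- function(dwi, method = c("loglinear", "nls")) {
  method <- match.arg(method)
  b <- dwi$b_values
  if (any(diff(b) <= 0)) input_error("b_values must be strictly increasing")
  dims <- dim(dwi$signal)
  if (length(dims) != 4 || dims[4] != length(b))
    input_error("signal must be 4-D with 4th dimension matching b_values")
  shape <- dims[1:3]
  nv <- prod(shape)
  X <- matrix(dwi$signal, nrow = nv, ncol = dims[4])

  if (method == "nls") {
    res <- apply(X, 1, function(s) {
      f <- fit_adc_voxel(s, b, method = "nls")
      c(f$adc, f$s0, f$valid, f$clipped)
    })
    out <- list(adc = array(res[1, ], shape),
                s0 = array(res[2, ], shape),
                fit_valid = array(as.logical(res[3, ]), shape),
                clipped = array(as.logical(res[4, ]), shape),
                voxel_spacing = dwi$voxel_spacing)
    class(out) <- "adc_map"
    return(out)
  }

  ok <- is.finite(X) & X > 0
  L <- log(ifelse(ok, X, 1))          # zeros where invalid: drop from sums
  okn <- ok * 1
  n <- rowSums(okn)
  sb <- okn %*% b
  sb2 <- okn %*% (b^2)
  sl <- rowSums(L)
  sbl <- L %*% b
  den <- n * sb2 - sb^2
  valid <- n >= 2
  den[!valid] <- 1
  slope <- (n * sbl - sb * sl) / den
  intercept <- (sl - slope * sb) / pmax(n, 1)
  adc_raw <- -slope
  clipped <- valid & adc_raw < 0
  adc <- pmax(adc_raw, 0)
  adc[!valid] <- 0
  s0 <- exp(intercept)
  s0[!valid] <- NA_real_
  out <- list(adc = array(adc, shape),
              s0 = array(s0, shape),
              fit_valid = array(valid, shape),
              clipped = array(as.vector(clipped), shape),
              voxel_spacing = dwi$voxel_spacing)
  class(out) <- "adc_map"
  out
}

#' Read a 4-D DWI NIfTI plus FSL-style bval sidecar
#'
#' @param nii_path path to the 4-D NIfTI file.
#' @param bval_path path to the single-line space-separated b-value file.
#' @return a `dwi_series`.
#' @export
read_dwi <- function(nii_path, bval_path) {
  img <- RNifti::readNifti(nii_path)
  b <- scan(bval_path, quiet = TRUE)
  arr <- array(as.numeric(img), dim = dim(img))
  sp <- RNifti::pixdim(img)[1:3]
  structure(list(signal = arr, b_values = b, voxel_spacing = sp),
            class = "dwi_series")
}

#' Write an ADC map (and its validity mask) as NIfTI
#'
#' @param adc_map an `adc_map`.
#' @param adc_path output path for the float ADC volume.
#' @param valid_path optional output path for the uint8 fit-validity mask.
#' @return invisibly, the paths written.
#' @export
write_adc_map <- function(adc_map, adc_path, valid_path = NULL) {
  sp <- adc_map$voxel_spacing
  img <- RNifti::asNifti(adc_map$adc)
  RNifti::pixdim(img) <- sp
  RNifti::writeNifti(img, adc_path)
  paths <- adc_path
  if (!is.null(valid_path)) {
    vm <- RNifti::asNifti(array(as.integer(adc_map$fit_valid),
                                dim = dim(adc_map$fit_valid)))
    RNifti::pixdim(vm) <- sp
    RNifti::writeNifti(vm, valid_path, datatype = "uint8")
    paths <- c(paths, valid_path)
  }
  invisible(paths)
}

#' Read an ADC map (plus optional validity mask) from NIfTI
#'
#' @param adc_path path to the 3-D float ADC volume (mm^2/s).
#' @param valid_path optional path to the uint8 fit-validity mask; when
#'   absent every voxel is treated as valid.
#' @return an `adc_map`.
#' @export
read_adc_map <- function(adc_path, valid_path = NULL) {
  img <- RNifti::readNifti(adc_path)
  arr <- array(as.numeric(img), dim = dim(img))
  valid <- if (is.null(valid_path)) {
    array(TRUE, dim = dim(arr))
  } else {
    v <- RNifti::readNifti(valid_path)
    array(as.numeric(v) > 0, dim = dim(arr))
  }
  structure(list(adc = arr, voxel_spacing = RNifti::pixdim(img)[1:3],
                 fit_valid = valid, s0 = NULL,
                 clipped = array(FALSE, dim = dim(arr))),
            class = "adc_map")
}
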