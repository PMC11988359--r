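## 6-connected neighbour count via shifted copies; out-of-volume counts as
## background.
neighbor6_all <- function(mask) {
  d <- dim(mask)
  out <- array(TRUE, d)
  m <- mask
  out[-1, , ] <- out[-1, , ] & m[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] & m[-1, , ]
  out[1, , ] <- FALSE; out[d[1], , ] <- FALSE
  out[, -1, ] <- out[, -1, ] & m[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] & m[, -1, ]
  out[, 1, ] <- FALSE; out[, d[2], ] <- FALSE
  out[, , -1] <- out[, , -1] & m[, , -d[3]]
  out[, , -d[3]] <- out[, , -d[3]] & m[, , -1]
  out[, , 1] <- FALSE; out[, , d[3]] <- FALSE
  out
}

#' Morphological erosion / dilation of a binary 3D mask
#'
#' 6-connected (face-neighbour) structuring element; voxels touching the
#' volume border are treated as adjacent to background. Erosion that would
#' leave fewer than `min_voxels` voxels is skipped with a warning, so small
#' ROIs are never emptied.
#'
#' @param mask 3D logical array.
#' @param iterations number of erosion/dilation passes (0 = identity).
#' @param min_voxels smallest allowed eroded mask.
#' @return Logical array of the same shape.
#' @export
erode_mask <- function(mask, iterations = 1L, min_voxels = 5L) {
  stopifnot(length(dim(mask)) == 3L, iterations >= 0)
  mask <- mask & !is.na(mask)
  for (i in seq_len(iterations)) {
    cand <- mask & neighbor6_all(mask)
    if (sum(cand) < min_voxels) {
      warning("erosion skipped: would leave fewer than ", min_voxels,
              " voxels")
      return(mask)
    }
    mask <- cand
  }
  mask
}

#' @rdname erode_mask
#' @export
dilate_mask <- function(mask, iterations = 1L) {
  stopifnot(length(dim(mask)) == 3L, iterations >= 0)
  d <- dim(mask)
  mask <- mask & !is.na(mask)
  for (i in seq_len(iterations)) {
    out <- mask
    out[-1, , ] <- out[-1, , ] | mask[-d[1], , ]
    out[-d[1], , ] <- out[-d[1], , ] | mask[-1, , ]
    out[, -1, ] <- out[, -1, ] | mask[, -d[2], ]
    out[, -d[2], ] <- out[, -d[2], ] | mask[, -1, ]
    out[, , -1] <- out[, , -1] | mask[, , -d[3]]
    out[, , -d[3]] <- out[, , -d[3]] | mask[, , -1]
    mask <- out
  }
  mask
}

#' ROI summary of fitted parameter maps
#'
#' Per-map mean over the (optionally eroded) mask intersected with the
#' converged-voxel mask, mirroring the reader workflow: draw ROI, erode to
#' avoid partial-volume edges, average each parametric map.
#'
#' @param maps a `param_maps` object from [fit_volume()].
#' @param mask 3D logical ROI.
#' @param erode_iterations erosion passes applied before averaging.
#' @param reader_id optional reader tag carried into the record.
#' @return One-row data.frame (a lesion record): `d`, `v_in`, `d_ex`,
#'   `cellularity`, one `adc_<label>` per sequence, `n_voxels`, `reader_id`.
#' @export
roi_summary <- function(maps, mask, erode_iterations = 1L, reader_id = NA) {
  stopifnot(inherits(maps, "param_maps"))
  if (!identical(dim(mask), dim(maps$d))) stop("mask does not match maps")
  roi <- erode_mask(mask, erode_iterations) & maps$converged
  if (!any(roi))
    stop("ROI contains no converged voxels")
  rec <- data.frame(d = mean(maps$d[roi]), v_in = mean(maps$v_in[roi]),
                    d_ex = mean(maps$d_ex[roi]),
                    cellularity = mean(maps$cellularity[roi]))
  for (lab in maps$labels)
    rec[[paste0("adc_", lab)]] <- mean(maps[[paste0("adc_", lab)]][roi])
  rec$n_voxels <- sum(roi)
  rec$reader_id <- reader_id
  rec
}

#' Emulate two readers' ROI masks
#'
#' Reader 1 uses the mask as drawn; reader 2's mask differs by a one-voxel
#' morphological perturbation (erosion or dilation, chosen at random), the
#' scale of boundary disagreement seen between human readers.
#'
#' @param mask 3D logical array.
#' @param seed RNG seed.
#' @return List of two masks.
#' @export
reader_masks <- function(mask, seed = 1L) {
  set.seed(seed)
  alt <- if (stats::runif(1) < 0.5) erode_mask(mask, 1L)
         else dilate_mask(mask, 1L)
  list(reader1 = mask, reader2 = alt)
}

#' Two-reader intraclass correlation coefficient
#'
#' ICC(A,1): two-way random effects, absolute agreement, single measures,
#' estimated from the two-way ANOVA mean squares, with the F-based
#' confidence interval of McGraw and Wong.
#'
#' @param values_reader1,values_reader2 paired measurements, length >= 3.
#' @param alpha confidence level is `1 - alpha`.
#' @return List with `icc`, `ci_low`, `ci_high`, `n`, `k`.
#' @export
icc_two_reader <- function(values_reader1, values_reader2, alpha = 0.05) {
  x <- cbind(values_reader1, values_reader2)
  if (nrow(x) < 3L) stop("need at least 3 paired measurements")
  if (anyNA(x)) stop("missing values not supported")
  n <- nrow(x); k <- ncol(x)
  grand <- mean(x)
  ms_r <- k * sum((rowMeans(x) - grand)^2) / (n - 1)       # subjects
  ms_c <- n * sum((colMeans(x) - grand)^2) / (k - 1)       # raters
  sse <- sum((x - outer(rowMeans(x), rep(1, k)) -
                outer(rep(1, n), colMeans(x)) + grand)^2)
  ms_e <- sse / ((n - 1) * (k - 1))
  denom <- ms_r + (k - 1) * ms_e + k * (ms_c - ms_e) / n
  icc <- if (denom <= 0) 1 else (ms_r - ms_e) / denom
  ## McGraw & Wong F-based interval
  if (ms_e == 0 && ms_c == 0) return(list(icc = 1, ci_low = 1, ci_high = 1,
                                          n = n, k = k))
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * ms_c + b * ms_e)^2 /
    ((a * ms_c)^2 / (k - 1) + (b * ms_e)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lo <- n * (ms_r - f_l * ms_e) /
    (f_l * (k * ms_c + (k * n - k - n) * ms_e) + n * ms_r)
  hi <- n * (f_u * ms_r - ms_e) /
    (k * ms_c + (k * n - k - n) * ms_e + n * f_u * ms_r)
  list(icc = icc, ci_low = lo, ci_high = hi, n = n, k = k)
}
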