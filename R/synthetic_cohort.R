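#' Group-level microstructure distribution
#'
#' Describes the per-group distribution from which lesion ground truths are
#' drawn (independent truncated normals over the fitting bounds).
#'
#' @param label `"malignant"` or `"benign"`.
#' @param d_mean,d_sd cell diameter, um.
#' @param v_in_mean,v_in_sd intracellular volume fraction.
#' @param d_ex_mean,d_ex_sd extracellular diffusivity, um^2/ms.
#' @param n_lesions number of lesions in the group.
#' @return A `group_distribution`.
#' @export
group_distribution <- function(label = c("malignant", "benign"),
                               d_mean, d_sd, v_in_mean, v_in_sd,
                               d_ex_mean, d_ex_sd, n_lesions) {
  label <- match.arg(label)
  stopifnot(d_sd >= 0, v_in_sd >= 0, d_ex_sd >= 0, n_lesions >= 1)
  structure(list(label = label, d_mean = d_mean, d_sd = d_sd,
                 v_in_mean = v_in_mean, v_in_sd = v_in_sd,
                 d_ex_mean = d_ex_mean, d_ex_sd = d_ex_sd,
                 n_lesions = as.integer(n_lesions)),
            class = "group_distribution")
}

#' Default two-group cohort configuration
#'
#' The published breast cohort structure: 27 malignant lesions with
#' d = 17.26 +/- 2.88 um, v_in = 0.38 +/- 0.10, D_ex = 1.88 +/- 0.25
#' um^2/ms, and 18 benign lesions with d = 24.13 +/- 4.54 um,
#' v_in = 0.24 +/- 0.10, D_ex = 2.24 +/- 0.17 um^2/ms.
#'
#' @return Named list of two [group_distribution()] objects.
#' @export
default_cohort_config <- function() {
  list(
    malignant = group_distribution("malignant", 17.26, 2.88, 0.38, 0.10,
                                   1.88, 0.25, 27L),
    benign = group_distribution("benign", 24.13, 4.54, 0.24, 0.10,
                                2.24, 0.17, 18L))
}

## Published per-group ADC distributions (1e-3 mm^2/s), used for drawing
## lesion-level ADC scores without rendering images.
adc_group_reference <- function() {
  data.frame(
    group = rep(c("malignant", "benign"), each = 3),
    adc = rep(c("adc_pgse", "adc_ogse25", "adc_ogse50"), 2),
    mean = c(0.88, 1.30, 1.81, 1.24, 1.77, 2.16),
    sd = c(0.12, 0.19, 0.28, 0.21, 0.18, 0.24),
    stringsAsFactors = FALSE)
}

## Truncated normal draws via inverse CDF; sd = 0 collapses to the clamped
## mean.
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(min(max(mean, lo), hi), n))
  p <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(p, mean, sd)
}

## Marginal immunohistochemistry frequencies among the malignant lesions:
## ER+ 14/27, PR+ 11/27, HER2+ 11/27, Ki67 >= 14% in 23/27.
ihc_marginals <- function() {
  c(er = 14 / 27, pr = 11 / 27, her2 = 11 / 27, ki67_high = 23 / 27)
}

#' Draw a synthetic lesion cohort
#'
#' Independent truncated-normal draws of (d, v_in, D_ex) per lesion from the
#' group distributions, truncated to the fitting bounds so every truth is
#' recoverable. Malignant lesions get independent ER/PR/HER2 labels and a
#' numeric Ki67 index with the published marginal frequencies. An optional
#' `ihc_effect` couples one marker level to a parameter shift (e.g. raising
#' v_in of PR-negative lesions) for exercising the subgroup-comparison
#' harness.
#'
#' @param config named list of [group_distribution()]s; default
#'   [default_cohort_config()].
#' @param seed integer seed; the cohort is fully reproducible.
#' @param d_in intrinsic intracellular diffusivity stored in each truth,
#'   um^2/ms.
#' @param ihc_effect optional list(`marker`, `level`, `param`, `shift`).
#' @return List of `synthetic_lesion` objects (fields `lesion_id`, `group`,
#'   `truth`, `ihc`).
#' @export
draw_cohort <- function(config = default_cohort_config(), seed = 1L,
                        d_in = 1.56, ihc_effect = NULL) {
  set.seed(seed)
  bounds <- fit_bounds()
  lesions <- list()
  id <- 0L
  for (g in config) {
    n <- g$n_lesions
    d <- rtrunc_norm(n, g$d_mean, g$d_sd, bounds$lower["d"], bounds$upper["d"])
    v <- rtrunc_norm(n, g$v_in_mean, g$v_in_sd, bounds$lower["v_in"],
                     bounds$upper["v_in"])
    dx <- rtrunc_norm(n, g$d_ex_mean, g$d_ex_sd, bounds$lower["d_ex"],
                      bounds$upper["d_ex"])
    pm <- ihc_marginals()
    for (i in seq_len(n)) {
      id <- id + 1L
      ihc <- if (g$label == "malignant") {
        list(er = if (stats::runif(1) < pm[["er"]]) "positive" else "negative",
             pr = if (stats::runif(1) < pm[["pr"]]) "positive" else "negative",
             her2 = if (stats::runif(1) < pm[["her2"]]) "positive" else
               "negative",
             ki67 = round(if (stats::runif(1) < pm[["ki67_high"]])
               stats::runif(1, 14, 90) else stats::runif(1, 1, 13.9), 1))
      } else list(er = NA, pr = NA, her2 = NA, ki67 = NA)
      truth <- c(d = d[i], v_in = v[i], d_ex = dx[i])
      if (!is.null(ihc_effect) && g$label == "malignant" &&
          identical(ihc[[ihc_effect$marker]], ihc_effect$level)) {
        truth[ihc_effect$param] <- min(
          max(truth[ihc_effect$param] + ihc_effect$shift,
              bounds$lower[ihc_effect$param]),
          bounds$upper[ihc_effect$param])
      }
      lesions[[id]] <- structure(
        list(lesion_id = id, group = g$label,
             truth = microstructure_params(truth["d"], truth["v_in"],
                                           truth["d_ex"], d_in = d_in),
             ihc = ihc),
        class = "synthetic_lesion")
    }
  }
  lesions
}

## Ellipsoid voxel mask centred in a box.
ellipsoid_mask <- function(box, semiaxes) {
  ctr <- (box + 1) / 2
  idx <- expand.grid(i = seq_len(box[1]), j = seq_len(box[2]),
                     k = seq_len(box[3]))
  r2 <- ((idx$i - ctr[1]) / semiaxes[1])^2 +
        ((idx$j - ctr[2]) / semiaxes[2])^2 +
        ((idx$k - ctr[3]) / semiaxes[3])^2
  array(r2 <= 1, dim = box)
}

#' Render a phantom DWI stack from a lesion cohort
#'
#' Places each lesion as an ellipsoid (>= 30 voxels by default) in its own
#' cell of a 3D lattice on a free-water background (D = 3.0 um^2/ms).
#' Voxel-level truths are the lesion truth plus truncated Gaussian jitter
#' (default 10% coefficient of variation); signals come from
#' [impulsed_signal()] per acquisition, and Rician noise is added per
#' acquisition as \eqn{S' = \sqrt{(S + \epsilon_1)^2 + \epsilon_2^2}} with
#' \eqn{\epsilon \sim N(0, \sigma/\sqrt{nsa})}, \eqn{\sigma = S(0)/snr}.
#'
#' @param lesions list from [draw_cohort()].
#' @param prot a `dwi_protocol`.
#' @param snr signal-to-noise ratio at b = 0 (before averaging); `Inf`
#'   disables noise.
#' @param seed RNG seed.
#' @param semiaxes lesion ellipsoid semi-axes in voxels.
#' @param jitter_cv intra-lesion coefficient of variation of the voxel
#'   truths.
#' @param bg_diffusivity background free-water diffusivity, um^2/ms.
#' @return A list: `stack` ([dwi_stack()]), `labelmap` (3D integer array of
#'   lesion ids, 0 = background), `lesions` (input lesions augmented with a
#'   `voxel_truth` data.frame), `snr`, `seed`.
#' @export
render_phantom <- function(lesions, prot, snr = 25, seed = 1L,
                           semiaxes = c(2.6, 2.1, 1.7), jitter_cv = 0.10,
                           bg_diffusivity = 3.0) {
  stopifnot(length(lesions) >= 1L, inherits(prot, "dwi_protocol"))
  set.seed(seed + 1000003L)
  bounds <- fit_bounds()
  box <- 2L * ceiling(semiaxes) + 3L
  n <- length(lesions)
  nx <- ceiling(sqrt(n))
  ny <- ceiling(n / nx)
  dims <- c(nx * box[1], ny * box[2], box[3])
  base_mask <- ellipsoid_mask(box, semiaxes)
  if (sum(base_mask) < 30)
    stop("lesion ellipsoid has fewer than 30 voxels; enlarge `semiaxes`")

  labelmap <- array(0L, dims)
  idx <- protocol_index(prot)
  nvol <- nrow(idx)
  volume <- array(0, c(dims, nvol))
  ## background: free water
  bg <- exp(-idx$b * 1e-3 * bg_diffusivity)
  for (a in seq_len(nvol)) volume[, , , a] <- bg[a]

  d_in <- lesions[[1]]$truth$d_in
  seqs <- prot$sequences
  for (li in seq_len(n)) {
    cell <- c((li - 1) %% nx, (li - 1) %/% nx)
    off <- c(cell[1] * box[1], cell[2] * box[2], 0)
    where <- which(base_mask, arr.ind = TRUE)
    where <- sweep(where, 2, off, "+")
    nvox <- nrow(where)
    tr <- lesions[[li]]$truth
    vt <- data.frame(
      lesion_id = lesions[[li]]$lesion_id,
      i = where[, 1], j = where[, 2], k = where[, 3],
      d = rtrunc_norm(nvox, tr$d, jitter_cv * tr$d,
                      bounds$lower["d"], bounds$upper["d"]),
      v_in = rtrunc_norm(nvox, tr$v_in, jitter_cv * tr$v_in,
                         bounds$lower["v_in"], bounds$upper["v_in"]),
      d_ex = rtrunc_norm(nvox, tr$d_ex, jitter_cv * tr$d_ex,
                         bounds$lower["d_ex"], bounds$upper["d_ex"]))
    vt$cellularity <- vt$v_in / vt$d * 100
    lesions[[li]]$voxel_truth <- vt
    lin <- where[, 1] + (where[, 2] - 1) * dims[1] +
      (where[, 3] - 1) * dims[1] * dims[2]
    labelmap[lin] <- lesions[[li]]$lesion_id
    ## per-sequence intracellular attenuation for the voxel diameters
    for (a in seq_len(nvol)) {
      s <- seqs[[idx$label[a]]]
      A <- intra_adc(vt$d, s, d_in = d_in)
      S <- vt$v_in * exp(-idx$b[a] * 1e-3 * A) +
        (1 - vt$v_in) * exp(-idx$b[a] * 1e-3 * vt$d_ex)
      volume[lin + (a - 1) * prod(dims)] <- S
    }
  }
  if (is.finite(snr)) {
    for (a in seq_len(nvol)) {
      sigma <- 1 / (snr * sqrt(idx$nsa[a]))
      nn <- prod(dims)
      e1 <- stats::rnorm(nn, 0, sigma)
      e2 <- stats::rnorm(nn, 0, sigma)
      volume[, , , a] <- sqrt((volume[, , , a] + e1)^2 + e2^2)
    }
  }
  list(stack = dwi_stack(volume, idx), labelmap = labelmap,
       lesions = lesions, snr = snr, seed = seed)
}

#' Ground-truth lesion summary table
#'
#' One row per lesion with the truth parameter means and labels. When voxel
#' truths are present (after [render_phantom()]) the means are voxelwise and
#' cellularity is the mean of voxelwise v_in/d x 100; otherwise the
#' lesion-level truth is used directly.
#'
#' @param lesions list of `synthetic_lesion`s.
#' @return data.frame with columns `lesion_id`, `group`, `d`, `v_in`,
#'   `d_ex`, `cellularity`, `er`, `pr`, `her2`, `ki67`.
#' @export
summarize_truth <- function(lesions) {
  rows <- lapply(lesions, function(L) {
    if (!is.null(L$voxel_truth)) {
      vt <- L$voxel_truth
      data.frame(lesion_id = L$lesion_id, group = L$group,
                 d = mean(vt$d), v_in = mean(vt$v_in), d_ex = mean(vt$d_ex),
                 cellularity = mean(vt$cellularity),
                 er = L$ihc$er, pr = L$ihc$pr, her2 = L$ihc$her2,
                 ki67 = L$ihc$ki67, stringsAsFactors = FALSE)
    } else {
      data.frame(lesion_id = L$lesion_id, group = L$group,
                 d = L$truth$d, v_in = L$truth$v_in, d_ex = L$truth$d_ex,
                 cellularity = L$truth$v_in / L$truth$d * 100,
                 er = L$ihc$er, pr = L$ihc$pr, her2 = L$ihc$her2,
                 ki67 = L$ihc$ki67, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
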