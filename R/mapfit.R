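#' Multi-sequence DWI stack
#'
#' Container for a 4D diffusion-weighted volume plus its acquisition index.
#'
#' @param volume 4D array, (x, y, z, acquisition).
#' @param index data.frame with one row per acquisition: `label` (sequence
#'   label), `b` (s/mm^2), `nsa`.
#' @param affine 4x4 spatial transform (default identity).
#' @return A `dwi_stack`.
#' @export
dwi_stack <- function(volume, index, affine = diag(4)) {
  stopifnot(length(dim(volume)) == 4L,
            nrow(index) == dim(volume)[4],
            all(c("label", "b", "nsa") %in% names(index)))
  for (lab in unique(index$label))
    if (!any(index$b[index$label == lab] == 0))
      stop("sequence ", lab, " has no b = 0 acquisition")
  structure(list(volume = volume, index = index, affine = affine),
            class = "dwi_stack")
}

## Acquisition index implied by a protocol: one volume per (sequence, b).
protocol_index <- function(prot) {
  do.call(rbind, lapply(unname(prot$sequences), function(s)
    data.frame(label = s$label, b = s$b_values, nsa = s$nsa,
               stringsAsFactors = FALSE)))
}

#' Normalise signals to the per-sequence b = 0 reference
#'
#' Divides every voxel's signal by the mean of that voxel's b = 0
#' acquisitions of the same sequence, so normalised b = 0 equals 1 and the
#' result is invariant to voxelwise intensity scaling.
#'
#' @param stack a [dwi_stack()].
#' @return A normalised `dwi_stack`.
#' @export
normalize_signals <- function(stack) {
  stopifnot(inherits(stack, "dwi_stack"))
  idx <- stack$index
  dims <- dim(stack$volume)
  mat <- matrix(stack$volume, ncol = dims[4])   # voxels x acquisitions
  for (lab in unique(idx$label)) {
    sel <- idx$label == lab
    b0 <- which(sel & idx$b == 0)
    s0 <- rowMeans(mat[, b0, drop = FALSE])
    mat[, sel] <- mat[, sel, drop = FALSE] / s0
  }
  dwi_stack(array(mat, dims), idx, stack$affine)
}

#' Fitting bounds for the microstructure parameters
#'
#' Physiologically motivated box constraints: 5 <= d <= 50 um,
#' 0 <= v_in <= 1, 0 <= D_ex <= 3 um^2/ms.
#'
#' @return A list with `lower` and `upper` named vectors over
#'   `(d, v_in, d_ex)`.
#' @export
fit_bounds <- function() {
  list(lower = c(d = 5, v_in = 0, d_ex = 0),
       upper = c(d = 50, v_in = 1, d_ex = 3))
}

## Fixed multi-start grid (48 points).
default_start_grid <- function() {
  as.matrix(expand.grid(d = c(8, 15, 25, 40),
                        v_in = c(0.1, 0.3, 0.5, 0.7),
                        d_ex = c(0.5, 1.5, 2.5)))
}

## Model signal for stacked observations. `A_fun(d)` returns the
## per-sequence apparent intracellular diffusivity for the observation rows.
impulsed_model_signal <- function(theta, b, seq_of, seqs, d_in, K) {
  A <- vapply(seqs, function(s) intra_adc(theta[1], s, d_in = d_in, K = K),
              numeric(1))
  theta[2] * exp(-b * 1e-3 * A[seq_of]) +
    (1 - theta[2]) * exp(-b * 1e-3 * theta[3])
}

#' Fit the IMPULSED model in one voxel
#'
#' Bounded nonlinear least squares for `(d, v_in, d_ex)` with `d_in` fixed,
#' minimising the `nsa`-weighted residual sum of squares. A fixed grid of 48
#' starting points is screened by initial RSS and Levenberg-Marquardt runs
#' are launched from the `n_starts` best; the solution with the lowest final
#' RSS wins (ties broken by the smaller `d`). Entirely deterministic.
#'
#' @param signals data.frame with columns `label`, `b` (s/mm^2), `signal`
#'   (normalised to S(0) = 1) and optionally `nsa`.
#' @param prot a `dwi_protocol` containing every label in `signals`.
#' @param d_in fixed intracellular diffusivity, um^2/ms.
#' @param bounds parameter box, see [fit_bounds()].
#' @param n_starts number of screened starts refined by Levenberg-Marquardt.
#' @param weighting `"nsa"` weights squared residuals by the number of
#'   averages (inverse-variance under averaging), `"sqrt_nsa"` by its square
#'   root, `"none"` unweighted.
#' @param K eigenmode truncation order of the forward model.
#' @return A list: `params` ([microstructure_params()]), `cellularity`
#'   (v_in/d x 100, 1/um), `rss`, `converged`, `at_bound` (named logical).
#' @export
fit_voxel <- function(signals, prot, d_in = 1.56, bounds = fit_bounds(),
                      n_starts = 6L, weighting = c("nsa", "sqrt_nsa", "none"),
                      K = 20L) {
  weighting <- match.arg(weighting)
  stopifnot(all(c("label", "b", "signal") %in% names(signals)))
  if (is.null(signals$nsa)) signals$nsa <- 1
  fit_rows <- signals$b > 0
  obs <- signals[fit_rows, , drop = FALSE]
  if (nrow(obs) < 6L || length(unique(obs$label)) < 2L)
    stop("need >= 6 b > 0 measurements spanning >= 2 diffusion times")
  seqs <- prot$sequences[unique(obs$label)]
  if (any(vapply(seqs, is.null, logical(1))))
    stop("signals contain labels missing from the protocol")
  seq_of <- match(obs$label, names(seqs))
  w <- switch(weighting, nsa = sqrt(obs$nsa), sqrt_nsa = obs$nsa^0.25,
              none = rep(1, nrow(obs)))
  resid_fun <- function(theta)
    w * (impulsed_model_signal(theta, obs$b, seq_of, seqs, d_in, K) -
           obs$signal)
  rss_fun <- function(theta) sum(resid_fun(theta)^2)

  grid <- default_start_grid()
  grid_rss <- apply(grid, 1L, rss_fun)
  take <- order(grid_rss)[seq_len(min(n_starts, nrow(grid)))]

  best <- NULL
  for (i in take) {
    fit <- try(minpack.lm::nls.lm(
      par = grid[i, ], lower = bounds$lower, upper = bounds$upper,
      fn = resid_fun,
      control = minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                           maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    ok <- fit$info %in% 1:4
    if (!ok) next
    rss <- fit$deviance
    if (is.null(best) || rss < best$rss - 1e-15 ||
        (abs(rss - best$rss) <= 1e-15 && fit$par[1] < best$par[1]))
      best <- list(par = fit$par, rss = rss)
  }
  if (is.null(best))
    return(list(params = NULL, cellularity = NA_real_, rss = NA_real_,
                converged = FALSE,
                at_bound = c(d = NA, v_in = NA, d_ex = NA)))
  par <- unname(pmin(pmax(best$par, bounds$lower), bounds$upper))
  tol_b <- 1e-6 * (bounds$upper - bounds$lower)
  at_bound <- (par - bounds$lower) < tol_b | (bounds$upper - par) < tol_b
  list(params = microstructure_params(par[1], par[2], par[3], d_in = d_in),
       cellularity = par[2] / par[1] * 100,
       rss = best$rss, converged = TRUE, at_bound = at_bound)
}

#' Apparent diffusion coefficient of one sequence
#'
#' Weighted linear regression of \eqn{-\ln S} on b over the full b-value
#' list of the sequence (weights = number of averages); the slope is the
#' ADC.
#'
#' @param signal normalised signals (S(0) = 1 scale).
#' @param b b-values, s/mm^2.
#' @param nsa per-b averages used as regression weights.
#' @return ADC in 1e-3 mm^2/s (numerically equal to um^2/ms).
#' @export
fit_adc <- function(signal, b, nsa = rep(1, length(b))) {
  stopifnot(length(signal) == length(b), length(b) >= 2L, any(b == 0))
  keep <- signal > 0
  y <- -log(signal[keep])
  fit <- stats::lm.wfit(cbind(1, b[keep]), y, w = nsa[keep])
  unname(fit$coefficients[2]) * 1e3
}

#' Fit parameter and ADC maps over a masked volume
#'
#' Applies [fit_voxel()] and [fit_adc()] to every masked voxel of a
#' (normalised) [dwi_stack()] and assembles the voxelwise maps. Cellularity
#' is computed voxelwise as v_in/d x 100 before any ROI averaging.
#'
#' @param stack a [dwi_stack()]; normalised internally.
#' @param mask 3D logical array of voxels to fit.
#' @param prot the acquisition `dwi_protocol`.
#' @param d_in fixed intracellular diffusivity, um^2/ms.
#' @param n_starts,weighting,K passed to [fit_voxel()].
#' @param verbose log voxel counts and convergence rate.
#' @return A `param_maps` object: 3D maps `d`, `v_in`, `d_ex`,
#'   `cellularity`, `rss`, logical `converged` and `at_bound` (any
#'   parameter at a box bound), and one `adc_<label>` map per sequence
#'   (1e-3 mm^2/s), plus the input affine.
#' @export
fit_volume <- function(stack, mask, prot, d_in = 1.56, n_starts = 6L,
                       weighting = "nsa", K = 20L, verbose = FALSE) {
  stopifnot(inherits(stack, "dwi_stack"))
  dims <- dim(stack$volume)[1:3]
  if (!identical(dim(mask), dims)) stop("mask dimensions do not match volume")
  mask <- mask & !is.na(mask)
  vox <- which(mask)
  if (length(vox) == 0L) stop("empty mask")
  norm <- normalize_signals(stack)
  idx <- norm$index
  nvol <- nrow(idx)
  sig_mat <- matrix(norm$volume, ncol = nvol)[vox, , drop = FALSE]

  empty <- array(NA_real_, dims)
  maps <- list(d = empty, v_in = empty, d_ex = empty, cellularity = empty,
               rss = empty, converged = array(FALSE, dims),
               at_bound = array(FALSE, dims))
  labels <- unique(idx$label)
  for (lab in labels) maps[[paste0("adc_", lab)]] <- empty

  n_conv <- 0L
  base <- data.frame(label = idx$label, b = idx$b, nsa = idx$nsa,
                     stringsAsFactors = FALSE)
  for (v in seq_along(vox)) {
    base$signal <- sig_mat[v, ]
    fit <- fit_voxel(base, prot, d_in = d_in, n_starts = n_starts,
                     weighting = weighting, K = K)
    p <- vox[v]
    if (fit$converged) {
      n_conv <- n_conv + 1L
      maps$d[p] <- fit$params$d
      maps$v_in[p] <- fit$params$v_in
      maps$d_ex[p] <- fit$params$d_ex
      maps$cellularity[p] <- fit$cellularity
      maps$rss[p] <- fit$rss
      maps$converged[p] <- TRUE
      maps$at_bound[p] <- any(fit$at_bound)
    }
    for (lab in labels) {
      sel <- idx$label == lab
      maps[[paste0("adc_", lab)]][p] <-
        fit_adc(base$signal[sel], idx$b[sel], idx$nsa[sel])
    }
  }
  if (verbose)
    message(sprintf("fit_volume: %d voxels, %d converged (%.1f%%)",
                    length(vox), n_conv, 100 * n_conv / length(vox)))
  structure(c(maps, list(affine = stack$affine, labels = labels)),
            class = "param_maps")
}
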