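#' Forward-model signal table for a whole protocol
#'
#' Evaluates [impulsed_signal()] at every (sequence, b) acquisition of a
#' protocol — the noiseless signal a voxel with the given microstructure
#' would produce.
#'
#' @param params a [microstructure_params()].
#' @param prot a `dwi_protocol`.
#' @return data.frame with columns `label`, `b`, `nsa`, `signal`.
#' @export
forward_signal_table <- function(params, prot) {
  idx <- protocol_index(prot)
  idx$signal <- NA_real_
  for (lab in unique(idx$label)) {
    sel <- idx$label == lab
    idx$signal[sel] <- impulsed_signal(params, prot$sequences[[lab]],
                                       idx$b[sel])
  }
  idx
}

#' Run the full simulate - fit - ROI pipeline on a synthetic cohort
#'
#' Renders a phantom from a drawn cohort, fits microstructure and ADC maps
#' over the lesion voxels, summarises each lesion ROI (after the standard
#' one-voxel erosion) and joins the records with the ground-truth table.
#'
#' @param cohort list of lesions from [draw_cohort()].
#' @param prot a `dwi_protocol`; default [breast_protocol()].
#' @param snr phantom signal-to-noise ratio at b = 0.
#' @param seed seed for rendering (phantom noise and jitter).
#' @param erode_iterations ROI erosion passes before averaging.
#' @param n_starts fit starts refined per voxel, see [fit_voxel()].
#' @param verbose log fitting progress.
#' @return data.frame with one row per lesion: fitted ROI means (`d`,
#'   `v_in`, `d_ex`, `cellularity`, `adc_<label>`), labels, `n_voxels`, and
#'   truth columns prefixed `truth_`.
#' @export
run_cohort_pipeline <- function(cohort, prot = breast_protocol(), snr = 25,
                                seed = 1L, erode_iterations = 1L,
                                n_starts = 6L, verbose = FALSE) {
  ph <- render_phantom(cohort, prot, snr = snr, seed = seed)
  maps <- fit_volume(ph$stack, ph$labelmap > 0L, prot,
                     n_starts = n_starts, verbose = verbose)
  truth <- summarize_truth(ph$lesions)
  recs <- lapply(ph$lesions, function(L) {
    rec <- roi_summary(maps, ph$labelmap == L$lesion_id,
                       erode_iterations = erode_iterations)
    cbind(data.frame(lesion_id = L$lesion_id, group = L$group,
                     stringsAsFactors = FALSE), rec)
  })
  recs <- do.call(rbind, recs)
  tr <- truth[match(recs$lesion_id, truth$lesion_id), ]
  recs$er <- tr$er; recs$pr <- tr$pr; recs$her2 <- tr$her2
  recs$ki67 <- tr$ki67
  for (col in c("d", "v_in", "d_ex", "cellularity"))
    recs[[paste0("truth_", col)]] <- tr[[col]]
  recs
}
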