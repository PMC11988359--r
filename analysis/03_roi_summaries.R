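#!/usr/bin/env Rscript
## Step 3 — ROI summaries and inter-reader agreement.
##
## Emulates the two-reader workflow: each lesion ROI is measured once on
## the drawn mask and once on a one-voxel morphological perturbation of it
## (both eroded before averaging, as in the clinical workflow), ICC(A,1)
## quantifies agreement per parameter, and the two readers' records are
## averaged for the downstream group statistics.

suppressPackageStartupMessages(library(impulsed))

phantom <- readRDS("scratch/phantom.rds")
maps <- readRDS("scratch/param_maps.rds")
truth <- summarize_truth(phantom$lesions)

read_one <- function(mask, reader) {
  roi_summary(maps, mask, erode_iterations = 1L, reader_id = reader)
}

records <- lapply(phantom$lesions, function(L) {
  mask <- phantom$labelmap == L$lesion_id
  rm <- reader_masks(mask, seed = 1000L + L$lesion_id)
  r1 <- suppressWarnings(read_one(rm$reader1, 1L))
  r2 <- suppressWarnings(read_one(rm$reader2, 2L))
  list(lesion_id = L$lesion_id, group = L$group, r1 = r1, r2 = r2)
})

params <- c("d", "v_in", "d_ex", "cellularity",
            grep("^adc_", names(records[[1]]$r1), value = TRUE))

icc_tab <- do.call(rbind, lapply(params, function(p) {
  v1 <- vapply(records, function(r) r$r1[[p]], numeric(1))
  v2 <- vapply(records, function(r) r$r2[[p]], numeric(1))
  ic <- icc_two_reader(v1, v2)
  data.frame(parameter = p, icc = ic$icc, ci_low = ic$ci_low,
             ci_high = ic$ci_high)
}))
write.table(icc_tab, "results/inter_reader_icc.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
message("inter-reader ICC:")
print(icc_tab, digits = 3)

## reader-averaged lesion records, joined with labels and truth
avg <- do.call(rbind, lapply(records, function(r) {
  num <- (r$r1[params] + r$r2[params]) / 2
  cbind(data.frame(lesion_id = r$lesion_id, group = r$group), num)
}))
avg$er <- truth$er[match(avg$lesion_id, truth$lesion_id)]
avg$pr <- truth$pr[match(avg$lesion_id, truth$lesion_id)]
avg$her2 <- truth$her2[match(avg$lesion_id, truth$lesion_id)]
avg$ki67 <- truth$ki67[match(avg$lesion_id, truth$lesion_id)]
write.table(avg, "results/lesion_records.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
message(sprintf("wrote %d reader-averaged lesion records", nrow(avg)))
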