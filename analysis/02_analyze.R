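#!/usr/bin/env Rscript
# Read the sync-level experiment back from disk and run the full inference
# chain: polymorphism filtering, per-parent polarization and conditioning,
# selection-coefficient estimation over the mixture and parental windows,
# frequency-binned response, cost of pleiotropy, parental FST, and PCA.
# Writes tidy TSV tables under results/.

source(file.path("analysis", "params.R"))

design <- experiment_plan()
ds <- read_experiment_files(EXPERIMENT_DIR)

set.seed(MASTER_SEED)
an <- analyze_experiment(ds, analysis_thresholds(), design = design,
                         coverage = experiment_psc()$coverage)

message("filter chain: ", an$log$n_loci, " loci -> ",
        an$log$n_polymorphic, " polymorphic; conditioned per parent: ",
        paste(an$log$conditioned, collapse = ", "))

write.tsv <- function(df, name) {
  path <- file.path(RESULTS_DIR, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
}

write.tsv(an$estimates, "selection_estimates.tsv")

pair_summary <- do.call(rbind, lapply(names(an$pairs), function(lbl) {
  p <- an$pairs[[lbl]]
  data.frame(pair = lbl,
             afc_immigrant = p$afc_immigrant_f1_f20$mean,
             afc_immigrant_lo = p$afc_immigrant_f1_f20$ci[1],
             afc_immigrant_hi = p$afc_immigrant_f1_f20$ci[2],
             afc_recipient = p$afc_recipient_f1_f20$mean,
             afc_immigrant_late = p$afc_immigrant_f20_f29$mean,
             rho = p$bins$correlation, rho_p = p$bins$p_perm,
             cost = p$cost$cost, cost_lo = p$cost$ci[1],
             cost_hi = p$cost$ci[2], realized_s = p$realized_s,
             cost_to_realized = p$cost_to_realized_ratio,
             control_afc = p$control_afc$mean)
}))
write.tsv(pair_summary, "pair_summary.tsv")

bins <- do.call(rbind, lapply(names(an$pairs), function(lbl) {
  cbind(pair = lbl, an$pairs[[lbl]]$bins$bins)
}))
write.tsv(bins, "frequency_bins.tsv")

fst <- as.data.frame(an$fst_parental)
fst <- cbind(population = rownames(fst), fst)
write.tsv(fst, "fst_parental.tsv")

write.tsv(an$pca$coordinates, "pca_coordinates.tsv")

message("early vs late response (immigrant class, pooled): ")
sm <- pooled_summary(an)
message(sprintf("  F1->F20 %.4f [%.4f, %.4f];  F20->F29 %.4f",
                sm$afc_immigrant$mean, sm$afc_immigrant$ci[1],
                sm$afc_immigrant$ci[2], sm$afc_immigrant_late$mean))
message(sprintf("  recipient class F1->F20 %.4f; cost %.4f vs realized %.4f",
                sm$afc_recipient$mean, sm$cost$cost, sm$realized_s))
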