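#!/usr/bin/env Rscript
# Clean the simulated sessions: channel exclusion by PSD criteria,
# amplitude/zero/saturation masking, and (rat) cortical scratch/HVS
# removal. Masked sessions are re-saved; the report records what was
# removed and why.

suppressMessages(library(thetaquant))

dir.create("results", showWarnings = FALSE)
ids <- paste0(rep(c("rat", "ferret", "atropine"), each = 2), "_",
              c("a", "b"))
reports <- list()
for (id in ids) {
  s <- load_session(file.path("scratch/sessions", id))
  out <- suppressWarnings(clean_session(s))
  save_session(out$session,
               file.path("scratch/sessions", paste0(id, "_clean")),
               overwrite = TRUE)
  r <- out$report
  cat(sprintf("%-10s: %d/%d channels retained, %.2f%% masked (%s)\n",
              id, sum(r$include), length(r$include),
              100 * r$masked_fraction,
              paste(names(r$masked_fraction_by_label),
                    sprintf("%.2f%%", 100 * r$masked_fraction_by_label),
                    collapse = ", ")))
  reports[[id]] <- list(
    include = r$include, reasons = r$reasons,
    masked_fraction = r$masked_fraction,
    by_label = as.list(r$masked_fraction_by_label),
    amplitude_threshold_uV = r$amplitude_threshold)
}
jsonlite::write_json(reports, "results/clean_report.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("report written to results/clean_report.json\n")
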