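#!/usr/bin/env Rscript
# Behavioural trial-epoch analysis: Hold / Run / Reward windows per
# correct trial, peak range per window per layer channel, and the
# behavioural performance summary.

suppressMessages(library(thetaquant))
dir.create("results", showWarnings = FALSE)

banks <- list(rat = sine_bank(species_profile("rat"), 1000),
              ferret = sine_bank(species_profile("ferret"), 1000))
tabs <- list()
for (name in c("rat", "ferret")) {
  for (subj in c("a", "b")) {
    id <- paste0(name, "_", subj)
    s <- load_session(file.path("scratch/sessions", paste0(id, "_clean")))
    w <- extract_trial_epochs(s$trials, s$speed, s$recording$fs)
    cfg <- jsonlite::fromJSON(s$meta$generator_config)
    spacing <- cfg$channel_spacing_um
    chans <- c(cfg$sp_channel - round(200 / spacing),
               cfg$sp_channel + round(400 / spacing))
    res <- epoch_condition_table(s, w, channels = chans,
                                 bank = banks[[name]])
    tab <- res$table
    tab$species <- name
    tab$layer <- ifelse(tab$channel == chans[1], "SO", "SRSLM")
    tabs[[id]] <- tab
    cat(sprintf("%-9s: %d windows over %d trials (%d dropped for masked LFP)\n",
                id, nrow(tab), length(unique(tab$trial)), res$n_dropped))
    bp <- behavioural_performance(s$trials,
                                  n_choices = cfg$trial_spec$n_locations)
    cat(sprintf("           proportion correct %.2f (chance %.2f)\n",
                mean(bp$per_session$prop_correct), bp$chance))
  }
}
cond <- do.call(rbind, tabs)
export_epoch_table(cond, "results/trial_conditions.csv")

med <- aggregate(peak_range ~ species + layer + condition, data = cond,
                 FUN = function(x) round(median(x, na.rm = TRUE), 2))
print(med, row.names = FALSE)
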