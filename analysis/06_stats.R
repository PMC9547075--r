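#!/usr/bin/env Rscript
# Mixed-effects comparisons of the epoch peak range:
#  - locomotor state x species with nested random intercepts, split by
#    species when the interaction is significant (the full-model protocol)
#  - drug x state for the atropine condition
#  - trial epoch (Hold/Run/Reward, Run as reference) per layer with
#    Tukey post-hoc contrasts
# Epoch tables come from analysis/04 and 05.

suppressMessages(library(thetaquant))
dir.create("results", showWarnings = FALSE)

state <- read.csv("results/state_epochs.csv")
state <- state[state$valid & state$state %in% c("immobile", "moving"), ]
state$MovFlag <- state$state
state$Species <- ifelse(state$condition == "rat", "rat", "ferret")
state$DrugFlag <- ifelse(state$condition == "atropine", "atropine", "none")
state$Chan <- state$layer
state$PeakRange <- state$peak_range
state$ID <- state$subject
# each recording is one session; split into thirds as pseudo-sessions so
# the session-level variance is estimable from two recordings per animal
state$Session <- paste0(state$session, "_t", 1 + (state$start %/% 80))

cat("== locomotor state x species (no-drug sessions) ==\n")
nodrug <- state[state$DrugFlag == "none", ]
pr <- lmm_split_protocol(nodrug, "eq1", c("eq2", "eq3"))
print(pr$full)
if (!is.null(pr$split)) {
  for (sp in names(pr$split)) {
    cf <- pr$split[[sp]]$coefficients
    mv <- cf[cf$term == "MovFlagmoving", ]
    cat(sprintf("  %s: locomotion effect beta = %+.3f (t = %.1f, p = %.2g)\n",
                sp, mv$beta, mv$t, mv$p))
  }
}

cat("\n== drug x state (ferret sessions) ==\n")
fer <- state[state$Species == "ferret", ]
pr4 <- lmm_split_protocol(fer, "eq4", c("eq5", "eq6"))
if (!is.null(pr4$split)) {
  for (st in names(pr4$split)) {
    cf <- pr4$split[[st]]$coefficients
    dr <- cf[grepl("DrugFlag", cf$term), ]
    cat(sprintf("  %s: atropine effect beta = %+.3f (t = %.1f, p = %.2g)\n",
                st, dr$beta, dr$t, dr$p))
  }
} else cat("  interaction not significant; no split fits\n")

cat("\n== trial epochs (Hold/Run/Reward; Run reference) ==\n")
cond <- read.csv("results/trial_conditions.csv")
cond <- cond[!is.na(cond$peak_range), ]
cond$PeakRange <- cond$peak_range
cond$Epoch <- cond$condition
cond$Chan <- cond$layer
cond$ID <- cond$subject
cond$Session <- paste0(cond$session, "_t", 1 + (cond$trial %% 3))
out <- list(state_species = pr$full$coefficients,
            interaction_p = pr$interaction_p)
for (sp in c("rat", "ferret")) {
  d <- cond[cond$species == sp, ]
  fit7 <- fit_lmm(d, "eq7")
  for (chan in c("SO", "SRSLM")) {
    f <- fit_lmm(d, if (chan == "SO") "eq8" else "eq9")
    tk <- tukey_contrasts(f, "Epoch")
    hr <- tk[tk$contrast == "Hold - Reward", ]
    cat(sprintf("  %s %s: Hold - Reward = %+.3f (Tukey p = %.2g)\n",
                sp, chan, hr$estimate, hr$p_adj))
    out[[paste(sp, chan, sep = "_")]] <- tk
  }
}
jsonlite::write_json(out, "results/lmm_results.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
cat("\nmodel outputs written to results/lmm_results.json\n")
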