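# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small 8-channel sessions (SP at channel 5) used across test files
fix_session <- function(mode = c("ferret", "rat", "atropine"),
                        duration_s = 120, artifacts = FALSE, seed = 11) {
  mode <- match.arg(mode)
  key <- paste("sess", mode, duration_s, artifacts, seed, sep = "_")
  cached(key, {
    cfg <- generator_config(
      species_mode = if (mode == "rat") "rat" else "ferret",
      drug_mode = if (mode == "atropine") "atropine" else "none",
      duration_s = duration_s, n_channels = 8, sp_channel = 4, seed = seed)
    generate_session(cfg, artifacts = artifacts)
  })
}

fix_bank <- function(species = "ferret", fs = 1000) {
  cached(paste("bank", species, fs, sep = "_"),
         sine_bank(species_profile(species), fs))
}
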