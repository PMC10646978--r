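# Shared fixtures, built lazily and memoized for the whole run.

.fx <- new.env(parent = emptyenv())

# 60-molecule synthetic library with SELFIES tokens (bridge-backed; ~2 calls)
fx_small_library <- function() {
  if (is.null(.fx$small_lib)) {
    cfg <- synthetic_screen_config(library_size = 60, seed = 101)
    .fx$small_lib <- generate_library(cfg, encode_selfies = TRUE)
  }
  .fx$small_lib
}

# 400-molecule library without tokens, plus a planted SAR: the workhorse for
# HTS / surrogate / design-rule tests
fx_screen <- function() {
  if (is.null(.fx$screen)) {
    cfg <- synthetic_screen_config(library_size = 400, seed = 202,
                                   noise_sd = 0.15, plate_effect_sd = 0.1)
    lib <- generate_library(cfg)
    sar <- planted_sar(lib, seed = 7)
    .fx$screen <- list(cfg = cfg, lib = lib, sar = sar)
  }
  .fx$screen
}

# deterministic toy profiles with hand-set folds on all six channels
fx_toy_profiles <- function(folds_by_molecule, conf = NULL) {
  ch <- measured_channels()$key
  n <- length(folds_by_molecule)
  prof <- data.frame(molecule_id = names(folds_by_molecule))
  for (k in ch) {
    prof[[paste0("fold_", k)]] <-
      vapply(folds_by_molecule, function(f) if (k %in% names(f)) f[[k]] else 1, 0)
    prof[[paste0("err_", k)]] <- 0
  }
  prof$complete <- TRUE
  if (is.null(conf)) {
    prof$conf1 <- 1; prof$conf2 <- 1
  } else {
    prof$conf1 <- conf[, 1]; prof$conf2 <- conf[, 2]
  }
  prof <- apply_viability_filter(prof)
  class(prof) <- c("modulation_profile", "data.frame")
  prof
}
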