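# Synthetic stand-in for the wet-lab screen.
#
# Molecules are assembled from a scaffold + substituent grammar so that the
# RDKit fr_* fragment counters vary across the library; a planted sparse
# linear structure-activity map over those counters defines the true log2
# fold change per pathway-agonist channel; plate readings add a per-plate
# multiplicative factor and log-normal replicate noise (Gaussian on the log2
# scale, keeping folds positive); a configurable fraction of molecules is
# rendered non-viable through sub-threshold confluency masks.

.scaffolds <- c(
  "c1cc({R1})cc({R2})c1{T}",
  "c1c({R1})cc({R2})nc1{T}",
  "c1cc({R1})cnc1{T}",
  "c1cc({R1})sc1{T}",
  "c1cc({R1})oc1{T}",
  "C1CCC({R1})CC1{T}",
  "C1CCN({R1})CC1{T}",
  "O=C(N1CCN({R1})CC1){T}",
  "c1ccc2cc({R1})ccc2c1{T}",
  "c1ccc(-c2cc({R1})ccc2{T})cc1",
  "O=C(Nc1cc({R1})ccc1{T})C",
  "c1cc({R1})c(cc1{T})OC",
  "c1nc({R1})ncc1{T}",
  "c1nc({R1})[nH]c1{T}",
  "C({R1})C(=O)N({R2})c1ccccc1{T}",
  "O=S(=O)(c1ccc({R1})cc1)N{T}")

.substituents <- c(
  "", "C", "CC", "CCC", "C(C)C", "Cl", "F", "Br", "I", "O", "OC", "OCC",
  "N", "NC", "N(C)C", "C#N", "[N+](=O)[O-]", "C(=O)O", "C(=O)C", "C(=O)N",
  "C(=O)NC", "S(=O)(=O)N", "S(=O)(=O)C", "C(F)(F)F", "OC(=O)C", "SC",
  "CO", "CN", "CCl", "C=C")

.sub_seed <- function(seed, k) (as.integer(seed) %% 94007L) * 22811L + k

.fill_template <- function(tpl, subs) {
  for (k in seq_along(subs)) {
    slot <- paste0("({R", k, "})")
    rep <- if (nzchar(subs[k])) paste0("(", subs[k], ")") else ""
    tpl <- sub(slot, rep, tpl, fixed = TRUE)
  }
  sub("{T}", subs[length(subs)], tpl, fixed = TRUE)
}

#' Synthetic screen configuration
#'
#' @param library_size number of distinct molecules to generate.
#' @param wells_per_plate sample wells per simulated plate (default 300,
#'   i.e. a 384-well plate minus edge wells and controls).
#' @param replicates replicate plates per measurement (default 2).
#' @param controls_per_plate positive-control wells per plate (default 8).
#' @param noise_sd replicate noise SD on the log2 scale (default 0.2).
#' @param plate_effect_sd SD of the per-plate log-normal factor (default 0.1).
#' @param nonviable_fraction expected non-viable fraction (default 0.10,
#'   the scale observed in real confluency-mask screens).
#' @param seed master seed; library, SAR, plate and viability randomness use
#'   independent derived streams.
#' @return a config list.
#' @export
synthetic_screen_config <- function(library_size = 1000L,
                                    wells_per_plate = 300L,
                                    replicates = 2L,
                                    controls_per_plate = 8L,
                                    noise_sd = 0.2,
                                    plate_effect_sd = 0.1,
                                    nonviable_fraction = 0.10,
                                    seed = 1L) {
  stopifnot(library_size >= 1, controls_per_plate >= 1, replicates >= 1,
            noise_sd >= 0, plate_effect_sd >= 0,
            nonviable_fraction >= 0, nonviable_fraction <= 1)
  list(library_size = as.integer(library_size),
       wells_per_plate = as.integer(wells_per_plate),
       replicates = as.integer(replicates),
       controls_per_plate = as.integer(controls_per_plate),
       noise_sd = noise_sd, plate_effect_sd = plate_effect_sd,
       nonviable_fraction = nonviable_fraction, seed = as.integer(seed))
}

#' Generate a synthetic candidate library
#'
#' Seeded and reproducible; all generated SMILES are valid by construction
#' of the grammar and are canonicalized and deduplicated on ingestion.  The
#' returned library carries the fr_* fragment-count matrix as attribute
#' `"fragments"`.
#'
#' @param cfg a [synthetic_screen_config()].
#' @param encode_selfies tokenize molecules (slower; needed only for the
#'   VAE embedding route).
#' @return a `candidate_library`.
#' @export
generate_library <- function(cfg, encode_selfies = FALSE) {
  set.seed(.sub_seed(cfg$seed, 1L))
  n <- cfg$library_size
  smis <- character(0)     # canonical, unique
  seen <- character(0)     # raw template strings already canonicalized
  tries <- 0L
  while (length(smis) < n && tries < 12L) {
    tries <- tries + 1L
    m <- ceiling((n - length(smis)) * 1.8) + 64L
    tpl <- sample(.scaffolds, m, replace = TRUE)
    new <- vapply(tpl, function(t) {
      k <- length(gregexpr("\\{R", t)[[1]]) + 1L
      .fill_template(t, sample(.substituents, k, replace = TRUE))
    }, "", USE.NAMES = FALSE)
    new <- setdiff(unique(new), seen)
    seen <- c(seen, new)
    if (!length(new)) next
    can <- canonical_smiles(new, strip_stereo = TRUE)
    smis <- unique(c(smis, can[!is.na(can)]))
  }
  if (length(smis) < n) {
    stop("size error: grammar yielded only ", length(smis), " of ", n,
         " requested molecules")
  }
  smis <- sort(smis)[seq_len(n)]
  lib <- build_library(smis, sprintf("syn_%05d", seq_len(n)),
                       vendor = rep("synthetic", n),
                       encode_selfies = encode_selfies)
  attr(lib, "fragments") <- fragment_counts_raw(lib$smiles)
  rownames(attr(lib, "fragments")) <- lib$id
  lib
}

#' Plant a sparse structure-activity map
#'
#' Per measured channel, `n_active` fragment counters (chosen among
#' counters that actually vary in the library) receive nonzero log2-scale
#' coefficients; everything else is inert.  Supports and signs are recorded
#' as ground truth for recovery tests.
#'
#' @param library a [generate_library()] result (its fragment matrix defines
#'   the usable counters).
#' @param n_active active fragments per channel (default 8).  With too few
#'   active substructures the discrete global optimum is shared by many
#'   molecules and a small random bootstrap already contains it, which no
#'   real screen exhibits; eight planted effects keep top performers rare
#'   and the achievable fold range near a real campaign's (~0.06-16x).
#' @param coef_range absolute-coefficient range (default `c(0.4, 1)` log2
#'   units per fragment count).
#' @param seed seed for support/sign/magnitude draws.
#' @param force named numeric vector of fragment codes to force into every
#'   NFKB channel with the given coefficient (e.g.
#'   `c(fr_halogen = -0.8)` to plant halogen-driven suppression).
#' @param pool optional restriction of the candidate fragment codes (e.g.
#'   the filter-retained catalogue columns, so recovery tests are
#'   well-posed).
#' @return object of class `planted_sar`: list with `coef` (matrix
#'   fragment x channel) and `channels`.
#' @export
planted_sar <- function(library, n_active = 8L, coef_range = c(0.4, 1),
                        seed = 1L, force = NULL, pool = NULL) {
  M <- attr(library, "fragments")
  stopifnot(!is.null(M))
  # active fragments must vary in at least 10% of the library, so every
  # planted effect is identifiable and enrichment has signal to find
  usable <- colnames(M)[apply(M, 2, function(x) {
    tb <- table(x)
    (1 - max(tb) / sum(tb)) >= 0.10
  })]
  if (!is.null(pool)) usable <- intersect(usable, pool)
  ch <- measured_channels()$key
  coef <- matrix(0, nrow = ncol(M), ncol = length(ch),
                 dimnames = list(colnames(M), ch))
  set.seed(.sub_seed(seed, 2L))
  for (c0 in ch) {
    pick <- sample(usable, min(n_active, length(usable)))
    mag <- stats::runif(length(pick), coef_range[1], coef_range[2])
    sgn <- sample(c(-1, 1), length(pick), replace = TRUE)
    coef[pick, c0] <- mag * sgn
    if (!is.null(force) && startsWith(c0, "NFKB")) {
      coef[names(force), c0] <- force
    }
  }
  structure(list(coef = coef, channels = ch), class = "planted_sar")
}

#' Noiseless oracle response
#'
#' True log2 fold change of each molecule on one channel: the linear
#' combination of its fragment counts with the channel's planted
#' coefficients.
#'
#' @param library a library carrying a `"fragments"` attribute.
#' @param sar a [planted_sar()].
#' @param channel a channel key from [measured_channels()].
#' @return numeric vector of log2 fold changes (named by molecule id).
#' @export
oracle_response <- function(library, sar, channel) {
  M <- attr(library, "fragments")
  stopifnot(channel %in% sar$channels)
  drop(M %*% sar$coef[, channel])
}

#' True goal targets under the planted map
#'
#' @param library,sar as in [oracle_response()].
#' @param aggregate generalist averaging mode (see [goal_score()]).
#' @return matrix molecules x 12 goals of signed log2 targets.
#' @export
oracle_goal_targets <- function(library, sar, aggregate = "arithmetic") {
  gs <- goal_specs()
  lfc <- vapply(sar$channels, function(ch) oracle_response(library, sar, ch),
                numeric(nrow(library)))
  out <- matrix(NA_real_, nrow(library), nrow(gs),
                dimnames = list(library$id, gs$goal_id))
  for (i in seq_len(nrow(gs))) {
    cols <- channel_key(gs$pathway[i], gs$agonists[[i]])
    f <- 2^lfc[, cols, drop = FALSE]
    base <- if (aggregate == "arithmetic") rowMeans(f) else 2^rowMeans(log2(f))
    s <- log2(base)
    out[, i] <- if (gs$direction[i] == "SUPPRESS") -s else s
  }
  out
}

#' Simulate raw plate readings
#'
#' Per molecule, channel and replicate: `raw = control_level * plate_factor
#' * 2^(true_lfc + N(0, noise_sd^2))`; positive-control wells on every plate
#' read `control_level * plate_factor * 2^(N(0, noise_sd^2))`.  Replicates
#' live on distinct plates; molecules are assigned round-robin.
#'
#' @param library the candidate library (or a subset data.frame with `id`).
#' @param sar a [planted_sar()].
#' @param cfg a [synthetic_screen_config()].
#' @param ids optionally restrict to these molecule ids.
#' @param control_level baseline instrument reading (default 1000).
#' @return long data.frame of plate readings (see [normalize_plate()]).
#' @export
simulate_plate_readings <- function(library, sar, cfg, ids = library$id,
                                    control_level = 1000) {
  set.seed(.sub_seed(cfg$seed, 3L))
  M <- attr(library, "fragments")
  idx <- match(ids, library$id)
  stopifnot(!anyNA(idx))
  ch <- measured_channels()
  out <- vector("list", nrow(ch) * cfg$replicates)
  k <- 0L
  for (i in seq_len(nrow(ch))) {
    lfc <- drop(M[idx, , drop = FALSE] %*% sar$coef[, ch$key[i]])
    plate_no <- ((seq_along(ids) - 1L) %/% cfg$wells_per_plate) + 1L
    for (r in seq_len(cfg$replicates)) {
      pid <- sprintf("%s_p%d_r%d", ch$key[i], plate_no, r)
      pf <- 2^stats::rnorm(max(plate_no), 0, cfg$plate_effect_sd)
      raw <- control_level * pf[plate_no] *
        2^(lfc + stats::rnorm(length(ids), 0, cfg$noise_sd))
      samp <- data.frame(plate_id = pid,
                         well = sprintf("w%03d", ((seq_along(ids) - 1L) %%
                                                    cfg$wells_per_plate) + 1L),
                         molecule_id = ids, pathway = ch$pathway[i],
                         agonist = ch$agonist[i], raw_value = raw,
                         stringsAsFactors = FALSE)
      ctrl <- do.call(rbind, lapply(unique(plate_no), function(p) {
        data.frame(plate_id = sprintf("%s_p%d_r%d", ch$key[i], p, r),
                   well = sprintf("c%02d", seq_len(cfg$controls_per_plate)),
                   molecule_id = CONTROL_POSITIVE, pathway = ch$pathway[i],
                   agonist = ch$agonist[i],
                   raw_value = control_level * pf[p] *
                     2^stats::rnorm(cfg$controls_per_plate, 0, cfg$noise_sd),
                   stringsAsFactors = FALSE)
      }))
      k <- k + 1L
      out[[k]] <- rbind(samp, ctrl)
    }
  }
  do.call(rbind, out)
}

#' Simulate confluency-mask viability scores
#'
#' A seeded random subset of expected size `nonviable_fraction * n` receives
#' one mask score below the 0.70 threshold; all other scores are drawn above
#' it.
#'
#' @param library the candidate library (uses its ids).
#' @param cfg a [synthetic_screen_config()].
#' @param ids optional id subset.
#' @return data.frame `molecule_id`, `conf1`, `conf2`.
#' @export
simulate_viability <- function(library, cfg, ids = library$id) {
  set.seed(.sub_seed(cfg$seed, 4L))
  n <- length(ids)
  conf1 <- stats::runif(n, 0.85, 1.10)
  conf2 <- stats::runif(n, 0.85, 1.10)
  dead <- stats::runif(n) < cfg$nonviable_fraction
  which_mask <- sample(1:2, n, replace = TRUE)
  lo <- stats::runif(n, 0.25, 0.695)
  conf1[dead & which_mask == 1] <- lo[dead & which_mask == 1]
  conf2[dead & which_mask == 2] <- lo[dead & which_mask == 2]
  data.frame(molecule_id = ids, conf1 = conf1, conf2 = conf2,
             stringsAsFactors = FALSE)
}

#' Run the simulated assay end to end for a set of molecules
#'
#' Convenience wrapper: simulate readings, normalize, merge replicates and
#' attach viability — the synthetic counterpart of one wet-lab submission.
#'
#' @inheritParams simulate_plate_readings
#' @param round_tag integer mixed into the plate-noise stream so successive
#'   rounds get fresh noise.
#' @return a [build_profiles()] data.frame for `ids`.
#' @export
simulate_screen <- function(library, sar, cfg, ids = library$id,
                            round_tag = 0L) {
  cfg_r <- cfg
  cfg_r$seed <- .sub_seed(cfg$seed, 100L + round_tag)
  readings <- simulate_plate_readings(library, sar, cfg_r, ids = ids)
  merged <- merge_replicates(normalize_plate(readings),
                             n_replicates = cfg$replicates)
  conf <- simulate_viability(library, cfg_r, ids = ids)
  build_profiles(merged, conf)
}
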