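# HTS plate processing and the 12 functional objectives.
#
# Raw per-well readings (SEAP absorbance for NF-kB, luciferase luminescence
# for IRF) are normalized per plate against positive-control wells (agonist
# present, no modulator), replicate plates are averaged with standard-error
# propagation, and a confluency-based viability verdict is attached.  The six
# measured pathway-agonist channels are NFKB x {LPS, MPLA, CPG} and
# IRF x {LPS, MPLA, CGAMP}; together with the two generalist aggregates they
# form the eight agonist-pathway combinations, and enhancement/suppression
# directions yield the twelve functional goals.

#' Sentinel molecule ids for control wells
#'
#' `CONTROL_POSITIVE` marks agonist-only wells (the normalization baseline;
#' in `agonist == "NONE"` groups it marks resting-cell wells).
#' `CONTROL_MODULATOR_ONLY` marks modulator-without-agonist wells, which are
#' normalized but excluded from the twelve goals.
#' @export
CONTROL_POSITIVE <- "CONTROL_POSITIVE"

#' @rdname CONTROL_POSITIVE
#' @export
CONTROL_MODULATOR_ONLY <- "CONTROL_MODULATOR_ONLY"

PATHWAYS <- c("NFKB", "IRF")
NFKB_AGONISTS <- c("LPS", "MPLA", "CPG")
IRF_AGONISTS <- c("LPS", "MPLA", "CGAMP")

channel_key <- function(pathway, agonist) paste(pathway, agonist, sep = "_")

#' The six measured pathway-agonist channels
#' @return data.frame with columns `pathway`, `agonist`, `key`.
#' @export
measured_channels <- function() {
  df <- rbind(
    data.frame(pathway = "NFKB", agonist = NFKB_AGONISTS),
    data.frame(pathway = "IRF", agonist = IRF_AGONISTS))
  df$key <- channel_key(df$pathway, df$agonist)
  df
}

#' The eight agonist-pathway combinations
#'
#' Four per pathway: the three specialists plus the generalist aggregate.
#' cGAMP (STING) is never paired with NF-kB and CpG (TLR9) never with IRF.
#' @return data.frame with columns `combo_id`, `pathway`, `agonists`
#'   (list-column).
#' @export
combination_specs <- function() {
  combos <- list(
    list("NFKB_LPS", "NFKB", "LPS"), list("NFKB_MPLA", "NFKB", "MPLA"),
    list("NFKB_CPG", "NFKB", "CPG"), list("NFKB_GEN", "NFKB", NFKB_AGONISTS),
    list("IRF_LPS", "IRF", "LPS"), list("IRF_MPLA", "IRF", "MPLA"),
    list("IRF_CGAMP", "IRF", "CGAMP"), list("IRF_GEN", "IRF", IRF_AGONISTS))
  data.frame(
    combo_id = vapply(combos, `[[`, "", 1),
    pathway = vapply(combos, `[[`, "", 2),
    agonists = I(lapply(combos, `[[`, 3)))
}

#' The twelve functional goals
#'
#' NF-kB combinations are optimized in both directions (enhance and
#' suppress); IRF combinations are enhance-only.
#'
#' @return data.frame with columns `goal_id`, `pathway`, `direction`
#'   (`"ENHANCE"`/`"SUPPRESS"`) and list-column `agonists`.
#' @export
goal_specs <- function() {
  cmb <- combination_specs()
  rows <- list()
  for (i in seq_len(nrow(cmb))) {
    dirs <- if (cmb$pathway[i] == "NFKB") c("ENHANCE", "SUPPRESS") else "ENHANCE"
    for (d in dirs) {
      rows[[length(rows) + 1L]] <- data.frame(
        goal_id = paste0(cmb$combo_id[i], "_", substr(d, 1, 3)),
        combo_id = cmb$combo_id[i],
        pathway = cmb$pathway[i], direction = d,
        agonists = I(cmb$agonists[i]))
    }
  }
  do.call(rbind, rows)
}

#' Normalize raw plate readings to fold changes
#'
#' Each well is divided by the mean reading of the positive-control wells
#' (agonist present, modulator absent) on the same plate for the same
#' pathway channel and agonist.  Wells with `agonist == "NONE"`
#' (modulator-only) are normalized against the same-plate no-agonist control
#' wells, which carry the same `CONTROL_POSITIVE` sentinel.
#'
#' @param readings data.frame with columns `plate_id`, `well`, `molecule_id`,
#'   `pathway`, `agonist`, `raw_value`.
#' @return the input with a `fold` column added; control wells are retained
#'   (their folds average 1 per group by construction).
#' @export
normalize_plate <- function(readings) {
  req <- c("plate_id", "well", "molecule_id", "pathway", "agonist", "raw_value")
  if (!all(req %in% names(readings))) {
    stop("schema error: plate readings need columns ",
         paste(setdiff(req, names(readings)), collapse = ", "))
  }
  if (any(readings$raw_value < 0)) stop("negative raw reading")
  grp <- interaction(readings$plate_id, readings$pathway, readings$agonist,
                     drop = TRUE)
  ctrl <- readings$molecule_id == CONTROL_POSITIVE
  ctrl_mean <- tapply(readings$raw_value[ctrl], grp[ctrl], mean)
  base <- ctrl_mean[as.character(grp)]
  bad <- is.na(base) | base <= 0
  if (any(bad)) {
    stop("normalization error: missing or all-zero positive controls on plate(s) ",
         paste(unique(readings$plate_id[bad]), collapse = ", "))
  }
  readings$fold <- readings$raw_value / as.numeric(base)
  readings
}

#' Merge replicate plates into mean fold changes with standard errors
#'
#' The replicate folds for each molecule-pathway-agonist triple are averaged
#' and the error is the standard deviation of the mean (for the default two
#' replicates: `|a - b| / 2`).  Molecules missing replicates are flagged
#' incomplete and excluded from modeling downstream.
#'
#' @param normalized output of [normalize_plate()] (control wells ignored).
#' @param n_replicates expected replicate count (default 2).
#' @return data.frame `molecule_id`, `pathway`, `agonist`, `fold`,
#'   `fold_err`, `n_rep`, `complete`.
#' @export
merge_replicates <- function(normalized, n_replicates = 2L) {
  x <- normalized[!(normalized$molecule_id %in%
                      c(CONTROL_POSITIVE, CONTROL_MODULATOR_ONLY)), ]
  key <- paste(x$molecule_id, x$pathway, x$agonist, sep = "\r")
  ord <- !duplicated(key)
  n <- tapply(x$fold, key, length)
  mu <- tapply(x$fold, key, mean)
  se <- tapply(x$fold, key, stats::sd) / sqrt(n)
  k <- key[ord]
  out <- data.frame(molecule_id = x$molecule_id[ord],
                    pathway = x$pathway[ord], agonist = x$agonist[ord],
                    fold = as.numeric(mu[k]), fold_err = as.numeric(se[k]),
                    n_rep = as.integer(n[k]), stringsAsFactors = FALSE)
  out$fold_err[is.na(out$fold_err)] <- 0
  out$complete <- out$n_rep == n_replicates
  out
}

#' Propagate a fold-change error onto the log2 scale
#'
#' Delta method: `err(log2 f) = err(f) / (f * ln 2)`.
#' @param fold,fold_err fold change and its standard error.
#' @return standard error of `log2(fold)`.
#' @export
log2_fold_error <- function(fold, fold_err) fold_err / (fold * log(2))

#' Assemble wide modulation profiles
#'
#' One row per molecule with `fold_<CH>` / `err_<CH>` columns for the six
#' measured channels, confluency scores and the viability verdict.
#'
#' @param merged output of [merge_replicates()].
#' @param confluency data.frame `molecule_id`, `conf1`, `conf2` (fractions of
#'   resting-cell confluency); molecules without scores are marked
#'   viability-unknown and treated as non-viable in rankings.
#' @param viability_threshold both masks must exceed this (default 0.70,
#'   strict inequality).
#' @return data.frame of class `modulation_profile`.
#' @export
build_profiles <- function(merged, confluency = NULL,
                           viability_threshold = 0.70) {
  ch <- measured_channels()
  keep <- merged[channel_key(merged$pathway, merged$agonist) %in% ch$key, ]
  ids <- sort(unique(keep$molecule_id))
  prof <- data.frame(molecule_id = ids, stringsAsFactors = FALSE)
  key <- channel_key(keep$pathway, keep$agonist)
  for (k in ch$key) {
    sel <- key == k
    m <- match(ids, keep$molecule_id[sel])
    prof[[paste0("fold_", k)]] <- keep$fold[sel][m]
    prof[[paste0("err_", k)]] <- keep$fold_err[sel][m]
  }
  fold_cols <- paste0("fold_", ch$key)
  prof$complete <- stats::complete.cases(prof[fold_cols])
  if (!is.null(confluency)) {
    m <- match(ids, confluency$molecule_id)
    prof$conf1 <- confluency$conf1[m]
    prof$conf2 <- confluency$conf2[m]
  } else {
    prof$conf1 <- NA_real_; prof$conf2 <- NA_real_
  }
  prof <- apply_viability_filter(prof, viability_threshold)
  class(prof) <- c("modulation_profile", "data.frame")
  prof
}

#' Viability verdict from confluency-mask scores
#'
#' Viable iff both mask scores are strictly greater than the threshold
#' (default 70% of resting-cell confluency).  Non-viable molecules are
#' retained with a flag, not deleted; missing scores give `viable = NA`
#' (treated as non-viable wherever a ranking needs a verdict).
#'
#' @param profiles data.frame with `conf1`, `conf2` columns.
#' @param threshold viability threshold (default 0.70).
#' @return `profiles` with a logical `viable` column.
#' @export
apply_viability_filter <- function(profiles, threshold = 0.70) {
  lo <- pmin(profiles$conf1, profiles$conf2)
  profiles$viable <- ifelse(is.na(lo), NA, lo > threshold)
  profiles
}

.goal_spec <- function(goal) {
  if (is.character(goal)) {
    gs <- goal_specs()
    i <- match(goal, gs$goal_id)
    if (is.na(i)) stop("unknown goal: ", goal)
    goal <- gs[i, ]
  }
  goal
}

#' Signed log2 target of a goal for each profile
#'
#' Specialists use the channel fold change directly; generalists aggregate
#' over the goal's agonist group (arithmetic mean of fold changes by
#' default, geometric mean — i.e. mean of log2 folds — as an alternative).
#' The target is `log2(base)` for ENHANCE goals and `-log2(base)` for
#' SUPPRESS goals, so larger is always better for the optimizer.
#'
#' @param profiles a [build_profiles()] result.
#' @param goal a `goal_id` string or a row of [goal_specs()].
#' @param aggregate `"arithmetic"` (default) or `"geometric"` generalist
#'   averaging.
#' @return numeric vector of signed log2 targets (NA where folds missing).
#' @export
goal_score <- function(profiles, goal, aggregate = c("arithmetic", "geometric")) {
  aggregate <- match.arg(aggregate)
  goal <- .goal_spec(goal)
  ags <- goal$agonists[[1]]
  cols <- paste0("fold_", channel_key(goal$pathway, ags))
  f <- as.matrix(profiles[, cols, drop = FALSE])
  if (any(f <= 0, na.rm = TRUE)) stop("data error: nonpositive fold change")
  base <- if (aggregate == "arithmetic") rowMeans(f) else 2^rowMeans(log2(f))
  s <- log2(base)
  if (goal$direction == "SUPPRESS") -s else s
}

#' Count molecules modulating any goal beyond a fold threshold
#'
#' A viable molecule is counted once if, for any of the twelve goals, its
#' goal base fold is `>= threshold` (ENHANCE goals) or `<= 1/threshold`
#' (SUPPRESS goals).
#'
#' @param profiles a [build_profiles()] result.
#' @param threshold fold multiple, must exceed 1.
#' @param aggregate generalist averaging mode, see [goal_score()].
#' @return integer count.
#' @export
count_modulators <- function(profiles, threshold,
                             aggregate = "arithmetic") {
  if (threshold <= 1) stop("threshold must exceed 1")
  gs <- goal_specs()
  hit <- rep(FALSE, nrow(profiles))
  for (i in seq_len(nrow(gs))) {
    sc <- goal_score(profiles, gs[i, ], aggregate = aggregate)
    hit <- hit | (!is.na(sc) & sc >= log2(threshold))
  }
  viable <- !is.na(profiles$viable) & profiles$viable
  sum(hit & viable)
}

#' Rank viable molecules on one goal
#'
#' Sorted by goal score descending with ties broken by `molecule_id`
#' (lexicographic) for reproducibility.
#'
#' @param profiles a [build_profiles()] result.
#' @param goal goal id or spec row.
#' @param k rank to return (default 1); must not exceed the number of viable
#'   scored molecules.
#' @param aggregate generalist averaging mode.
#' @return one-row data.frame `molecule_id`, `score` (signed log2),
#'   `base_fold`.
#' @export
top_performers <- function(profiles, goal, k = 1L, aggregate = "arithmetic") {
  goal <- .goal_spec(goal)
  sc <- goal_score(profiles, goal, aggregate = aggregate)
  ok <- !is.na(sc) & !is.na(profiles$viable) & profiles$viable
  if (sum(ok) < k) stop("range error: k exceeds viable profile count")
  ord <- order(-sc[ok], profiles$molecule_id[ok])
  idx <- which(ok)[ord[k]]
  sign <- if (goal$direction == "SUPPRESS") -1 else 1
  data.frame(molecule_id = profiles$molecule_id[idx], score = sc[idx],
             base_fold = 2^(sign * sc[idx]), stringsAsFactors = FALSE)
}
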