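# Campaign-level summaries: threshold counts, top-k folds, viability
# tallies, sampled fraction and novelty against the bootstrap screen.

#' Write / read wide modulation-profile CSVs
#'
#' The on-disk dialect: one row per molecule; `molecule_id`, optional
#' `smiles`, `fold_<CH>` and `err_<CH>` for the six measured channels,
#' `conf1`, `conf2`.
#'
#' @param profiles a [build_profiles()] data.frame (plus optional `smiles`).
#' @param path CSV path.
#' @export
write_profiles <- function(profiles, path) {
  drop <- intersect(c("viable", "complete"), names(profiles))
  data.table::fwrite(profiles[setdiff(names(profiles), drop)], path)
  invisible(path)
}

#' @rdname write_profiles
#' @return `read_profiles`: the profiles with viability re-derived.
#' @export
read_profiles <- function(path) {
  x <- data.table::fread(path, data.table = FALSE)
  need <- c("molecule_id", paste0("fold_", measured_channels()$key))
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("schema error: missing columns ",
                         paste(miss, collapse = ", "))
  if (!"conf1" %in% names(x)) x$conf1 <- NA_real_
  if (!"conf2" %in% names(x)) x$conf2 <- NA_real_
  x$complete <- stats::complete.cases(x[paste0("fold_", measured_channels()$key)])
  x <- apply_viability_filter(x)
  class(x) <- c("modulation_profile", "data.frame")
  x
}

#' Summarize a screening campaign
#'
#' Deterministic recomputation of the campaign's headline statistics from
#' per-round profile tables: viability tallies, the merged
#' distinct-viable count (canonical-SMILES dedup after the viability
#' filter), modulator counts at the 1.5/2/5/10-fold thresholds, per-round
#' per-goal top-k folds, the sampled fraction of the library, and — when a
#' bootstrap screen is supplied — the distribution of each strong hit's
#' maximum Tanimoto similarity to the bootstrap set.
#'
#' @param rounds list of profile data.frames (or CSV paths), one per round,
#'   each with a `smiles` column for dedup/novelty.
#' @param library_size total candidate-library size (for the sampled
#'   fraction); `NA` to skip.
#' @param bootstrap optional prior-screen data.frame or CSV with `smiles`.
#' @param thresholds fold thresholds for the modulator counts.
#' @param topk ranks reported per goal.
#' @param novelty_min_fold hits stronger than this (any goal) enter the
#'   novelty analysis (default 2).
#' @return a `campaign_summary` list.
#' @export
summarize_campaign <- function(rounds, library_size = NA_integer_,
                               bootstrap = NULL,
                               thresholds = c(1.5, 2, 5, 10),
                               topk = c(1L, 5L, 20L),
                               novelty_min_fold = 2) {
  rounds <- lapply(rounds, function(r) if (is.character(r)) read_profiles(r) else r)
  all <- do.call(rbind, lapply(rounds, as.data.frame))
  all <- apply_viability_filter(all)
  n_screened <- nrow(all)
  viable <- sum(all$viable, na.rm = TRUE)
  nonviable <- sum(!all$viable, na.rm = TRUE)
  unknown <- sum(is.na(all$viable))
  merged <- all[!is.na(all$viable) & all$viable, ]
  if ("smiles" %in% names(merged)) {
    merged <- merged[!duplicated(merged$smiles), ]
  }
  class(merged) <- c("modulation_profile", "data.frame")
  counts <- vapply(thresholds, function(th) count_modulators(merged, th), 0L)
  names(counts) <- paste0("ge_", thresholds, "x")
  gs <- goal_specs()
  top <- list()
  for (i in seq_len(nrow(gs))) {
    sc <- try(silent = TRUE, vapply(topk, function(k) {
      if (sum(merged$viable, na.rm = TRUE) >= k)
        top_performers(merged, gs[i, ], k = k)$base_fold else NA_real_
    }, 0))
    top[[gs$goal_id[i]]] <- if (inherits(sc, "try-error"))
      rep(NA_real_, length(topk)) else stats::setNames(sc, paste0("k", topk))
  }
  novelty <- NULL
  if (!is.null(bootstrap) && "smiles" %in% names(all)) {
    if (is.character(bootstrap)) bootstrap <- data.table::fread(bootstrap, data.table = FALSE)
    strong <- rep(FALSE, nrow(merged))
    for (i in seq_len(nrow(gs))) {
      sc <- goal_score(merged, gs[i, ])
      strong <- strong | (!is.na(sc) & sc >= log2(novelty_min_fold))
    }
    if (any(strong)) {
      nts <- nearest_training_similarity(merged$smiles[strong],
                                         bootstrap$smiles,
                                         query_ids = merged$molecule_id[strong])
      novelty <- list(n_hits = sum(strong),
                      quantiles = stats::quantile(nts$similarity,
                                                  c(0, .1, .25, .5, .75, .9, 1)),
                      table = nts)
    }
  }
  structure(list(
    n_screened = n_screened, viable = viable, nonviable = nonviable,
    viability_unknown = unknown, distinct_viable = nrow(merged),
    threshold_counts = counts, top_folds = top,
    sampled_fraction = if (is.na(library_size)) NA_real_ else
      n_screened / library_size,
    rounds = length(rounds), novelty = novelty), class = "campaign_summary")
}

#' @export
print.campaign_summary <- function(x, ...) {
  cat("Campaign summary\n")
  cat(sprintf("  screened: %d in %d round(s); viable %d, non-viable %d, unknown %d\n",
              x$n_screened, x$rounds, x$viable, x$nonviable, x$viability_unknown))
  cat(sprintf("  distinct viable after merge/dedup: %d\n", x$distinct_viable))
  if (!is.na(x$sampled_fraction)) {
    cat(sprintf("  sampled fraction of library: %.2f%%\n", 100 * x$sampled_fraction))
  }
  cat("  modulators by threshold: ",
      paste(sprintf("%s=%d", names(x$threshold_counts), x$threshold_counts),
            collapse = ", "), "\n")
  if (!is.null(x$novelty)) {
    cat(sprintf("  novelty: %d hits; median max-Tanimoto to bootstrap %.2f\n",
                x$novelty$n_hits, x$novelty$quantiles[["50%"]]))
  }
  invisible(x)
}

#' Render a campaign summary as Markdown tables
#'
#' @param x a `campaign_summary`.
#' @return character vector of Markdown lines.
#' @export
report_markdown <- function(x) {
  lines <- c("# Campaign summary", "",
             sprintf("- screened: %d (%d rounds)", x$n_screened, x$rounds),
             sprintf("- viable / non-viable / unknown: %d / %d / %d",
                     x$viable, x$nonviable, x$viability_unknown),
             sprintf("- distinct viable: %d", x$distinct_viable),
             if (!is.na(x$sampled_fraction))
               sprintf("- sampled fraction: %.2f%%", 100 * x$sampled_fraction),
             "", "| threshold | count |", "|---|---|",
             sprintf("| >= %s-fold | %d |",
                     sub("^ge_(.*)x$", "\\1", names(x$threshold_counts)),
                     x$threshold_counts),
             "", "| goal | top-1 fold |", "|---|---|",
             sprintf("| %s | %.3g |", names(x$top_folds),
                     vapply(x$top_folds, `[[`, 0, 1L)))
  lines[!is.na(lines)]
}
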