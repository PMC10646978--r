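# Interpretable fragment-level design rules.
#
# Molecules are featurized as counts over the 85 RDKit fr_* substructure
# descriptors; zero-variance and highly correlated columns are removed; rows
# (per-molecule feature vectors) are normalized to unit Euclidean length;
# and one LASSO model per agonist-pathway combination maps features to the
# log2 fold change, with the L1 weight chosen by 5-fold cross-validation.
# Positive coefficients mark enhancer-promoting fragments, negative ones
# suppressor-promoting fragments.

#' The 85-fragment catalogue
#'
#' Code-to-description glossary of the RDKit `fr_*` substructure counters
#' used for featurization, shipped as
#' `inst/extdata/fragment_catalogue.csv`.
#'
#' @return data.frame with `fragment_code` and `description`.
#' @export
fragment_catalogue <- function() {
  p <- system.file("extdata", "fragment_catalogue.csv",
                   package = "immunoloop")
  utils::read.csv(p, stringsAsFactors = FALSE)
}

#' Fragment-count featurization
#'
#' One row per molecule over the fixed 85-counter fr_* catalogue;
#' multi-component molecules are featurized as a single entity.
#' Unparseable molecules are dropped with a log entry (attribute
#' `"dropped"`).
#'
#' @param smiles character vector of SMILES (or a `candidate_library`).
#' @return integer matrix with class `fragment_features`; attribute
#'   `"catalogue"` holds the full descriptor name list.
#' @export
featurize_fragments <- function(smiles) {
  ids <- NULL
  if (inherits(smiles, "candidate_library")) {
    ids <- smiles$id
    smiles <- smiles$smiles
  }
  M <- fragment_counts_raw(smiles)
  dropped <- which(apply(M, 1, anyNA))
  if (length(dropped)) {
    message("featurize_fragments: dropped ", length(dropped),
            " unparseable molecule(s)")
    M <- M[-dropped, , drop = FALSE]
    if (!is.null(ids)) ids <- ids[-dropped]
  }
  rownames(M) <- if (!is.null(ids)) ids else NULL
  structure(M, dropped = dropped, catalogue = colnames(M))
}

#' Remove uninformative and redundant feature columns
#'
#' First drops zero-variance columns, then scans the remaining columns in
#' catalogue order and drops any column whose Pearson correlation with an
#' already-retained column exceeds `rho_max` in magnitude (the earlier
#' catalogue column of a redundant pair is kept).
#'
#' @param M feature matrix (molecules x fragment counters).
#' @param rho_max correlation threshold (default 0.95).
#' @param use_abs compare `|rho|` (default) or signed `rho` against the
#'   threshold.
#' @return the reduced matrix; attribute `"retained"` is the logical mask
#'   over the input columns.
#' @export
filter_features <- function(M, rho_max = 0.95, use_abs = TRUE) {
  if (nrow(M) < 2L) stop("need at least 2 molecules to filter features")
  v <- apply(M, 2, stats::var)
  retained <- v > 0
  keep_idx <- integer(0)
  for (j in which(retained)) {
    drop <- FALSE
    if (length(keep_idx)) {
      r <- suppressWarnings(stats::cor(M[, j], M[, keep_idx, drop = FALSE]))
      r[is.na(r)] <- 0
      if (use_abs) r <- abs(r)
      drop <- any(r > rho_max)
    }
    if (drop) retained[j] <- FALSE else keep_idx <- c(keep_idx, j)
  }
  out <- M[, retained, drop = FALSE]
  attr(out, "retained") <- retained
  out
}

#' Normalize feature rows to unit Euclidean length
#'
#' All-zero rows are left untouched and flagged.
#'
#' @param M feature matrix (already filtered).
#' @return row-normalized numeric matrix; attribute `"zero_rows"` lists
#'   untouched rows.
#' @export
normalize_rows <- function(M) {
  nrm <- sqrt(rowSums(M^2))
  zero <- nrm == 0
  out <- M / ifelse(zero, 1, nrm)
  attr(out, "zero_rows") <- which(zero)
  out
}

#' Fit a LASSO design-rule model with cross-validated penalty
#'
#' Coordinate-descent LASSO (glmnet) over a 50-point log-spaced grid from
#' `lambda_max` (the smallest penalty giving the all-zero model) down to
#' `lambda_max * 1e-4`; the penalty with the lowest cross-validated mean
#' absolute error is chosen and the final model is refitted on all data.
#'
#' @param M normalized feature matrix.
#' @param targets log2 fold-change response, one per row of `M`.
#' @param combination label for the agonist-pathway combination being
#'   modeled.
#' @param folds CV folds (default 5).
#' @param seed seed for the fold assignment.
#' @param n_lambda grid size (default 50).
#' @param standardize column-standardize inside glmnet (default `FALSE`:
#'   the row-normalization convention is used as-is; set `TRUE` for the
#'   textbook column-scaling comparison).
#' @param lambda optional explicit penalty grid (decreasing; may end in 0,
#'   in which case the fit degenerates to least squares there).
#' @param thresh coordinate-descent convergence threshold.
#' @return object of class `lasso_rule_model`.
#' @export
fit_lasso_cv <- function(M, targets, combination = "combo", folds = 5L,
                         seed = 1L, n_lambda = 50L, standardize = FALSE,
                         lambda = NULL, thresh = 1e-10) {
  stopifnot(nrow(M) == length(targets), all(is.finite(targets)))
  if (stats::var(targets) == 0) {
    warning("degenerate all-equal targets: intercept-only model")
    coefs <- stats::setNames(rep(0, ncol(M)), colnames(M))
    return(structure(list(combination = combination, coefficients = coefs,
                          intercept = mean(targets), lambda = Inf,
                          cv_mae = 0, nonzero = 0L,
                          lambda_grid = numeric(0), cv_curve = NULL),
                     class = "lasso_rule_model"))
  }
  n <- nrow(M)
  if (is.null(lambda)) {
    # lambda_max: smallest penalty that zeroes every coefficient
    yc <- targets - mean(targets)
    Ms <- if (standardize) scale(M) else M
    lambda_max <- max(abs(crossprod(Ms, yc))) / n
    grid <- exp(seq(log(lambda_max), log(lambda_max * 1e-4),
                    length.out = n_lambda))
  } else {
    grid <- sort(lambda, decreasing = TRUE)
  }
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(folds), n))
  cvfit <- glmnet::cv.glmnet(M, targets, alpha = 1, lambda = grid,
                             foldid = foldid, type.measure = "mae",
                             standardize = standardize, thresh = thresh)
  lam <- cvfit$lambda.min
  fit <- glmnet::glmnet(M, targets, alpha = 1, lambda = grid,
                        standardize = standardize, thresh = thresh)
  cf <- stats::coef(fit, s = lam)
  coefs <- stats::setNames(as.numeric(cf)[-1], rownames(cf)[-1])
  structure(list(combination = combination, coefficients = coefs,
                 intercept = as.numeric(cf)[1], lambda = lam,
                 cv_mae = cvfit$cvm[match(lam, cvfit$lambda)],
                 nonzero = sum(coefs != 0), lambda_grid = grid,
                 cv_curve = data.frame(lambda = cvfit$lambda,
                                       cv_error = cvfit$cvm,
                                       nonzero = cvfit$nzero)),
            class = "lasso_rule_model")
}

#' @export
print.lasso_rule_model <- function(x, ...) {
  cat("<lasso_rule_model>", x$combination, " lambda =", format(x$lambda),
      " nonzero =", x$nonzero, " cv_mae =", format(x$cv_mae), "\n")
  invisible(x)
}

#' Ranked nonzero coefficients
#'
#' @param model a `lasso_rule_model`.
#' @param top_n how many to return (default 6, the figure-style cap).
#' @return data.frame `fragment`, `theta`, `role`
#'   (enhancer-/suppressor-promoting), sorted by `|theta|` descending with
#'   catalogue-order tie-break.
#' @export
rank_coefficients <- function(model, top_n = 6L) {
  th <- model$coefficients
  nz <- which(th != 0)
  if (length(nz) == 0L) {
    return(data.frame(fragment = character(0), theta = numeric(0),
                      role = character(0)))
  }
  ord <- nz[order(-abs(th[nz]), nz)]
  ord <- utils::head(ord, top_n)
  data.frame(fragment = names(th)[ord], theta = unname(th[ord]),
             role = ifelse(th[ord] > 0, "enhancer-promoting",
                           "suppressor-promoting"),
             stringsAsFactors = FALSE)
}

#' Extract design rules for all eight agonist-pathway combinations
#'
#' Runs the full §-style pipeline: drop non-viable and duplicate molecules,
#' featurize, filter, row-normalize, and fit one LASSO per combination with
#' the combination's log2 fold change (enhance-positive) as target.
#'
#' @param library a `candidate_library` (for canonical-SMILES dedup).
#' @param profiles a [build_profiles()] result covering the library subset.
#' @param rho_max,folds,seed,aggregate passed through.
#' @return named list of `lasso_rule_model`, one per combination.
#' @export
extract_design_rules <- function(library, profiles, rho_max = 0.95,
                                 folds = 5L, seed = 1L,
                                 aggregate = "arithmetic") {
  keep <- !is.na(profiles$viable) & profiles$viable & profiles$complete
  prof <- profiles[keep, ]
  m <- match(prof$molecule_id, library$id)
  dup <- duplicated(library$smiles[m])
  prof <- prof[!dup, ]
  feats <- featurize_fragments(library$smiles[match(prof$molecule_id, library$id)])
  rownames(feats) <- prof$molecule_id
  Mf <- filter_features(feats, rho_max = rho_max)
  Mn <- normalize_rows(Mf)
  cmb <- combination_specs()
  out <- list()
  for (i in seq_len(nrow(cmb))) {
    spec <- data.frame(goal_id = cmb$combo_id[i], combo_id = cmb$combo_id[i],
                       pathway = cmb$pathway[i], direction = "ENHANCE",
                       agonists = I(cmb$agonists[i]))
    y <- goal_score(prof, spec, aggregate = aggregate)
    ok <- is.finite(y)
    out[[cmb$combo_id[i]]] <- fit_lasso_cv(Mn[ok, , drop = FALSE], y[ok],
                                           combination = cmb$combo_id[i],
                                           folds = folds, seed = seed)
  }
  out
}
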