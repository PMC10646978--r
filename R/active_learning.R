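# Acquisition scoring, Kriging-believer batch construction, round
# orchestration, and the two convergence monitors (stabilizing predictions
# via Bhattacharyya distance over a frozen stop set; performance difference
# via cross-validated MAE).

#' Expected Improvement
#'
#' `EI = (mu - f* - xi) * Phi(u) + sigma * phi(u)`, `u = (mu - f* - xi)/sigma`
#' for `sigma > 0`, and `max(0, mu - f* - xi)` in the deterministic limit.
#'
#' @param mu,var posterior mean and variance (vectorized).
#' @param incumbent best observed target `f*`.
#' @param xi exploration offset (>= 0, default 0: pure EI).
#' @return nonnegative EI values.
#' @export
expected_improvement <- function(mu, var, incumbent, xi = 0) {
  if (anyNA(mu) || anyNA(var)) stop("NaN inputs rejected")
  stopifnot(all(var >= 0), xi >= 0)
  d <- mu - incumbent - xi
  s <- sqrt(var)
  ei <- pmax(0, d)                         # sigma = 0 branch
  pos <- s > 0
  u <- d[pos] / s[pos]
  ei[pos] <- d[pos] * stats::pnorm(u) + s[pos] * stats::dnorm(u)
  pmax(ei, 0)
}

#' Bhattacharyya distance between univariate Gaussians
#'
#' `D_B = (mu1-mu2)^2 / (4*(v1+v2)) + log((v1+v2) / (2*sqrt(v1*v2))) / 2`.
#'
#' @param mu1,var1,mu2,var2 means and (strictly positive) variances;
#'   vectorized.
#' @return nonnegative distances.
#' @export
bhattacharyya_gaussian <- function(mu1, var1, mu2, var2) {
  if (any(var1 <= 0) || any(var2 <= 0)) stop("domain error: nonpositive variance")
  0.25 * (mu1 - mu2)^2 / (var1 + var2) +
    0.5 * log((var1 + var2) / (2 * sqrt(var1 * var2)))
}

#' Stabilizing-predictions monitor
#'
#' Mean Bhattacharyya distance (with standard error) between two rounds'
#' posterior Gaussians over the frozen stop set, per goal.
#'
#' @param prev,curr lists with one element per goal, each a list with
#'   `mean` and `var` vectors over the same stop set.
#' @return data.frame `goal`, `mean_db`, `se_db`.
#' @export
stabilizing_predictions <- function(prev, curr) {
  if (!identical(names(prev), names(curr))) stop("integrity error: goal mismatch")
  if (!all(lengths(lapply(prev, `[[`, "mean")) ==
           lengths(lapply(curr, `[[`, "mean")))) {
    stop("integrity error: stop-set size mismatch")
  }
  rows <- lapply(names(prev), function(g) {
    db <- bhattacharyya_gaussian(prev[[g]]$mean, prev[[g]]$var,
                                 curr[[g]]$mean, curr[[g]]$var)
    data.frame(goal = g, mean_db = mean(db),
               se_db = stats::sd(db) / sqrt(length(db)))
  })
  do.call(rbind, rows)
}

# ---------------------------------------------------------------------------
# incremental GP posterior workspace over a fixed candidate matrix
#
# Maintains, for one goal model with frozen hyperparameters, the Cholesky
# factor of the training kernel and A = L^-1 K(train, all); conditioning on
# new (possibly believed) points is a block update, after which posterior
# means and variances over all candidates refresh in O(m * N).  Buffers
# (L, A, b, Xtr) are preallocated at `capacity` rows and mutated in place
# inside an environment — growing them with rbind dominated campaign-scale
# runtime — and full-capacity BLAS products over zero-padded rows replace
# row-subset copies.

ws_init <- function(Xtr, y, ids, Xall, sf2, ell, sn2, mu_y, sd_y,
                    capacity = nrow(Xtr), jitter = 1e-8) {
  n <- nrow(Xtr); N <- nrow(Xall)
  capacity <- max(capacity, n)
  K <- .rbf(.sq_dist(Xtr, Xtr), sf2, ell) + diag(sn2, n)
  ch <- .chol_jitter(K, jitter)
  ws <- new.env(parent = emptyenv())
  ws$L <- matrix(0, capacity, capacity)
  ws$L[1:n, 1:n] <- ch$L
  if (capacity > n) {
    pad <- (n + 1L):capacity
    ws$L[cbind(pad, pad)] <- 1           # inert padding keeps solves defined
  }
  A1 <- forwardsolve(ch$L, .rbf(.sq_dist(Xtr, Xall), sf2, ell))
  ws$A_blocks <- list(A1)                # A = L^-1 K(train, all), row blocks
  ws$row_blocks <- list(1:n)
  ws$b <- numeric(capacity)
  ws$b[1:n] <- forwardsolve(ch$L, (y - mu_y) / sd_y)
  ws$Xtr <- matrix(0, capacity, ncol(Xtr)); ws$Xtr[1:n, ] <- Xtr
  ws$ids <- character(capacity); ws$ids[1:n] <- ids
  ws$n <- n; ws$n_real <- n; ws$n_believed <- 0L
  ws$sf2 <- sf2; ws$ell <- ell; ws$sn2 <- sn2
  ws$mu_y <- mu_y; ws$sd_y <- sd_y; ws$jitter <- ch$jitter
  ws$qf <- colSums(A1^2)
  ws$mu <- mu_y + sd_y * drop(crossprod(A1, ws$b[1:n]))
  ws$var <- sd_y^2 * pmax(sf2 + sn2 - ws$qf, 1e-12)
  ws
}

# M (m x capacity) times the block-stored A, restricted to live rows
.ws_matprod_A <- function(ws, M) {
  out <- 0
  for (k in seq_along(ws$A_blocks)) {
    out <- out + M[, ws$row_blocks[[k]], drop = FALSE] %*% ws$A_blocks[[k]]
  }
  out
}

# D2_tr_new (capacity x m) / D2_new_all (m x N): squared distances computed
# once per sweep and shared across the twelve models.
ws_add <- function(ws, Xnew, ynew, ids, D2_tr_new, D2_new_all,
                   believed = TRUE) {
  m <- nrow(Xnew); n <- ws$n
  if (n + m > nrow(ws$L)) stop("workspace capacity exceeded")
  K12f <- .rbf(D2_tr_new, ws$sf2, ws$ell)
  if (n < nrow(K12f)) K12f[(n + 1L):nrow(K12f), ] <- 0
  L21f <- t(forwardsolve(ws$L, K12f))                    # m x capacity
  S <- .rbf(.sq_dist(Xnew, Xnew), ws$sf2, ws$ell) +
    diag(ws$sn2 + ws$jitter, m) - tcrossprod(L21f)
  L22 <- t(chol(S))
  A2 <- forwardsolve(L22, .rbf(D2_new_all, ws$sf2, ws$ell) -
                       .ws_matprod_A(ws, L21f))
  b2 <- forwardsolve(L22, (ynew - ws$mu_y) / ws$sd_y - drop(L21f %*% ws$b))
  idx <- (n + 1L):(n + m)
  ws$L[idx, ] <- L21f
  ws$L[idx, idx] <- L22
  ws$A_blocks[[length(ws$A_blocks) + 1L]] <- A2
  ws$row_blocks[[length(ws$row_blocks) + 1L]] <- idx
  ws$b[idx] <- b2
  ws$Xtr[idx, ] <- Xnew
  ws$ids[idx] <- ids
  ws$n <- n + m
  ws$qf <- ws$qf + colSums(A2^2)
  ws$mu <- ws$mu + ws$sd_y * drop(crossprod(A2, b2))
  ws$var <- ws$sd_y^2 * pmax(ws$sf2 + ws$sn2 - ws$qf, 1e-12)
  if (believed) ws$n_believed <- ws$n_believed + m else ws$n_real <- ws$n_real + m
  invisible(ws)
}

# swap all labels (believed -> measured) without touching the factorization;
# valid only while hyperparameters stay frozen, since the training points
# are identical and only y changes.
ws_refresh_labels <- function(ws, y) {
  n <- ws$n
  stopifnot(length(y) == n)
  ws$b[1:n] <- forwardsolve(ws$L[1:n, 1:n, drop = FALSE],
                            (y - ws$mu_y) / ws$sd_y)
  mu <- 0
  for (k in seq_along(ws$A_blocks)) {
    mu <- mu + drop(crossprod(ws$A_blocks[[k]], ws$b[ws$row_blocks[[k]]]))
  }
  ws$mu <- ws$mu_y + ws$sd_y * mu
  ws$n_real <- n; ws$n_believed <- 0L
  invisible(ws)
}

# ---------------------------------------------------------------------------

#' Start an active-learning campaign
#'
#' The embedding is frozen for the whole campaign: `X` holds the latent
#' coordinates of every candidate (tested or not), one row per id.
#'
#' @param X latent coordinate matrix for the full library.
#' @param ids molecule ids, one per row of `X`.
#' @param B batch size per round (the full-scale campaign used 720; scaled
#'   presets use proportionally smaller values, e.g. 72 for a 14,000-molecule
#'   library).
#' @param xi EI exploration offset (default 0).
#' @param stop_set_size size of the frozen random stop set used by the
#'   convergence monitor (full scale: 100,000).
#' @param seed campaign seed; all randomness derives from it.
#' @param hyper_strategy per-round GP hyperparameter strategy (see
#'   [fit_gpr()]); `"median"` is the fast campaign-scale default, `"ml"` the
#'   small-data default of the standalone surrogate API.
#' @param restarts optimizer restarts when `hyper_strategy = "ml"`.
#' @param refit `"each_round"` re-derives hyperparameters and rebuilds the
#'   posterior factorization every round; `"first_round"` freezes the
#'   hyperparameters after round 1 and extends the factorization across
#'   rounds (identical posterior maths, much faster at campaign scale).
#' @param rounds_planned expected number of rounds (sizes the preallocated
#'   workspace when `refit = "first_round"`).
#' @param goal_ids goals to run (default: all twelve).
#' @param cv_folds per-round CV-MAE folds (0 disables the monitor).
#' @return campaign state list (class `al_campaign`).
#' @export
al_campaign <- function(X, ids, B = 720L, xi = 0, stop_set_size = 1000L,
                        seed = 1L, hyper_strategy = "median", restarts = 3L,
                        refit = c("each_round", "first_round"),
                        rounds_planned = 4L,
                        goal_ids = goal_specs()$goal_id, cv_folds = 0L) {
  X <- as.matrix(X)
  refit <- match.arg(refit)
  stopifnot(nrow(X) == length(ids), !anyDuplicated(ids), B >= 1, xi >= 0)
  state <- list(X = X, ids = ids, B = as.integer(B), xi = xi, seed = seed,
                hyper_strategy = hyper_strategy, restarts = restarts,
                refit = refit, rounds_planned = as.integer(rounds_planned),
                goal_ids = goal_ids, cv_folds = cv_folds,
                emb_hash = .emb_hash(X),
                labels = matrix(NA_real_, nrow(X), length(goal_ids),
                                dimnames = list(ids, goal_ids)),
                tested = stats::setNames(rep(FALSE, length(ids)), ids),
                pending = character(0), round = 0L,
                stop_ids = NULL, prev_post = NULL, workspaces = NULL,
                history = list())
  set.seed(seed)
  state$stop_ids <- sample(ids, min(stop_set_size, length(ids)))
  class(state) <- "al_campaign"
  state
}

.emb_hash <- function(X) sum(X * rep_len(c(1, -0.5, 0.25), length(X)))

#' Ingest measured labels
#'
#' Supplies real goal targets for molecules (bootstrap set or a selected
#' batch).  A campaign refuses to run a round while selections remain
#' unlabeled.
#'
#' @param state an `al_campaign`.
#' @param ids molecule ids being labeled.
#' @param Y matrix `length(ids) x n_goals` of signed log2 targets, columns
#'   in campaign goal order.
#' @return updated state.
#' @export
al_ingest <- function(state, ids, Y) {
  Y <- as.matrix(Y)
  stopifnot(nrow(Y) == length(ids), ncol(Y) == length(state$goal_ids))
  idx <- match(ids, state$ids)
  if (anyNA(idx)) stop("unknown molecule ids in labels")
  state$labels[idx, ] <- Y
  state$tested[idx] <- TRUE
  state$pending <- setdiff(state$pending, ids)
  state
}

#' Select a batch with the multi-objective Kriging-believer protocol
#'
#' Sweep: every goal model nominates its top-EI untested, not-yet-selected
#' candidate against the same availability snapshot (so two goals can
#' nominate the same molecule in one sweep); the deduplicated nominees are
#' appended to every model's training set with that model's own posterior
#' mean as the believed label; posteriors update and the sweep repeats until
#' at least `B` molecules are selected.  Believed labels never move the
#' incumbent `f*` and are discarded when real measurements arrive.
#'
#' @param workspaces list of per-goal posterior workspaces (internal).
#' @param state campaign state (uses `X`, `B`, `xi`).
#' @param excluded logical vector over candidates: tested or already
#'   selected.
#' @param fstar named incumbent list per goal.
#' @return list with `entries` (data.frame id, source_goal, ei, believed),
#'   the `selected` ids, and the updated workspaces.
#' @keywords internal
kriging_believer_batch <- function(workspaces, state, excluded, fstar) {
  entries <- list()
  selected <- character(0)
  avail <- !excluded
  while (length(selected) < state$B && any(avail)) {
    nominees <- integer(0); src <- character(0); eis <- numeric(0)
    for (g in names(workspaces)) {
      ws <- workspaces[[g]]
      ei <- expected_improvement(ws$mu, ws$var, fstar[[g]], state$xi)
      ei[!avail] <- -Inf
      j <- which.max(ei)
      if (!avail[j]) next
      nominees <- c(nominees, j); src <- c(src, g); eis <- c(eis, ei[j])
    }
    if (length(nominees) == 0L) break
    entries[[length(entries) + 1L]] <- data.frame(
      id = state$ids[nominees], source_goal = src, ei = eis,
      believed = vapply(seq_along(nominees),
                        function(k) workspaces[[src[k]]]$mu[nominees[k]], 0),
      stringsAsFactors = FALSE)
    uniq <- unique(nominees)
    Xnew <- state$X[uniq, , drop = FALSE]
    D2_tr_new <- .sq_dist(workspaces[[1]]$Xtr, Xnew)   # Xtr buffer is shared
    D2_new_all <- .sq_dist(Xnew, state$X)
    for (g in names(workspaces)) {
      believed <- workspaces[[g]]$mu[uniq]   # each model believes itself
      ws_add(workspaces[[g]], Xnew, believed, state$ids[uniq],
             D2_tr_new, D2_new_all, believed = TRUE)
    }
    avail[uniq] <- FALSE
    selected <- c(selected, state$ids[uniq])
  }
  if (length(selected) < state$B) {
    warning("candidate pool exhausted: partial batch of ", length(selected))
  }
  list(entries = do.call(rbind, entries), selected = selected,
       workspaces = workspaces)
}

#' Run one active-learning round
#'
#' Refits all goal surrogates on the accumulated real labels (believed
#' labels from earlier batch construction are purged), records the
#' convergence monitors against the previous round's posterior over the
#' stop set, and selects the next batch.
#'
#' @param state an `al_campaign` with all previous selections labeled.
#' @return updated state; the new batch is in `state$last_batch` and the
#'   per-round record in `state$history`.
#' @export
run_round <- function(state) {
  if (length(state$pending)) {
    stop("data-integrity guard: unlabeled prior selections: ",
         paste(utils::head(state$pending, 5), collapse = ", "))
  }
  if (!identical(state$emb_hash, .emb_hash(state$X))) {
    stop("integrity error: embedding changed between rounds")
  }
  tested_idx <- which(state$tested)
  if (length(tested_idx) < 2L) stop("need labeled bootstrap data before a round")
  state$round <- state$round + 1L
  round_seed <- state$seed + 7919L * state$round
  stop_idx <- match(state$stop_ids, state$ids)
  reuse <- state$refit == "first_round" && !is.null(state$workspaces)

  if (reuse) {
    workspaces <- state$workspaces
    for (g in state$goal_ids) {
      ws <- workspaces[[g]]
      y <- state$labels[ws$ids[1:ws$n], g]   # believed -> measured swap
      if (anyNA(y)) stop("integrity error: unlabeled workspace point")
      ws_refresh_labels(ws, y)
    }
  } else {
    Xtr <- state$X[tested_idx, , drop = FALSE]
    ng <- length(state$goal_ids)
    capacity <- if (state$refit == "first_round") {
      length(tested_idx) + state$rounds_planned * (state$B + ng) + ng
    } else {
      length(tested_idx) + state$B + 2L * ng
    }
    workspaces <- list()
    for (g in state$goal_ids) {
      y <- state$labels[tested_idx, g]
      set.seed(round_seed + match(g, state$goal_ids))
      mu_y <- mean(y); sd_y <- stats::sd(y)
      if (!is.finite(sd_y) || sd_y == 0) sd_y <- 1
      if (state$hyper_strategy == "median") {
        h <- .heuristic_hyper(Xtr, (y - mu_y) / sd_y)
      } else {
        fit <- fit_gpr(Xtr, y, hyper_strategy = state$hyper_strategy,
                       restarts = state$restarts, seed = round_seed)
        h <- c(sf2 = fit$sf2, ell = fit$ell, sn2 = fit$sn2)
        mu_y <- fit$mu_y; sd_y <- fit$sd_y
      }
      workspaces[[g]] <- ws_init(Xtr, y, state$ids[tested_idx], state$X,
                                 h[["sf2"]], h[["ell"]], h[["sn2"]],
                                 mu_y, sd_y, capacity = capacity)
    }
  }

  fstar <- list(); post <- list(); cvrows <- list()
  for (g in state$goal_ids) {
    y <- state$labels[tested_idx, g]
    fstar[[g]] <- max(y)                      # real observations only
    ws <- workspaces[[g]]
    post[[g]] <- list(mean = ws$mu[stop_idx], var = ws$var[stop_idx])
    if (state$cv_folds > 0L) {
      cv <- cv_mae(state$X[tested_idx, , drop = FALSE], y,
                   folds = state$cv_folds, seed = round_seed,
                   hyper_strategy = if (state$hyper_strategy == "median")
                     "median" else "ml",
                   restarts = state$restarts)
      cvrows[[g]] <- data.frame(goal = g, round = state$round,
                                mae = cv$mae, fold_sd = cv$fold_sd)
    }
  }
  convergence <- if (!is.null(state$prev_post)) {
    cbind(round = state$round, stabilizing_predictions(state$prev_post, post))
  } else NULL
  state$prev_post <- post

  excluded <- state$tested
  sel <- kriging_believer_batch(workspaces, state, excluded, fstar)
  if (state$refit == "first_round") {
    state$workspaces <- sel$workspaces       # believed rows refreshed next round
  } else {
    # believer hygiene: workspaces (and their believed rows) are discarded
    state$workspaces <- NULL
  }
  state$last_batch <- sel$entries
  state$last_selected <- sel$selected
  state$pending <- sel$selected
  state$history[[state$round]] <- list(
    round = state$round, batch = sel$entries, selected = sel$selected,
    fstar = unlist(fstar), convergence = convergence,
    cv = if (length(cvrows)) do.call(rbind, cvrows) else NULL,
    n_labeled = length(tested_idx))
  state
}

#' Convergence report across rounds
#'
#' @param state an `al_campaign` after one or more rounds.
#' @return list with data.frames stacking the per-round
#'   stabilizing-predictions (`bhattacharyya`) and CV-MAE (`cv_mae`)
#'   monitors.
#' @export
convergence_report <- function(state) {
  db <- do.call(rbind, lapply(state$history, `[[`, "convergence"))
  cv <- do.call(rbind, lapply(state$history, `[[`, "cv"))
  list(bhattacharyya = db, cv_mae = cv)
}
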