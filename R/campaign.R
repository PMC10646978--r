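# End-to-end synthetic campaign driver: the scaled-down counterpart of the
# full screening loop, wiring the synthetic oracle to the active-learning
# engine so enrichment and convergence behaviour can be measured against
# ground truth.

#' Run a synthetic active-learning campaign
#'
#' Generates labels by running the simulated assay (plate readings ->
#' normalization -> replicate merge -> goal scores) for a random bootstrap
#' set and then for each selected batch, mirroring the real campaign where
#' surrogates are retrained on accumulated measurements each round.
#'
#' @param library a [generate_library()] result.
#' @param sar a [planted_sar()].
#' @param cfg the [synthetic_screen_config()] used for the assay noise.
#' @param embedding latent coordinate matrix for the library (VAE or
#'   fingerprint route).
#' @param bootstrap_n size of the random pre-screen that seeds round 1.
#' @param rounds number of active-learning rounds.
#' @param B batch size per round.
#' @param seed campaign seed (bootstrap draw, GP refits, stop set).
#' @param stop_set_size convergence-monitor stop set size.
#' @param hyper_strategy GP refit strategy per round.
#' @param refit hyperparameter refit schedule (see [al_campaign()]; the
#'   scaled preset freezes after round 1 for speed).
#' @param cv_folds per-round CV-MAE folds (0 = off).
#' @return list with the final `state`, the `tested` id list per round, a
#'   `top1` matrix (rounds+1) x goals of the best oracle target discovered
#'   so far, and the bootstrap ids.
#' @export
run_synthetic_campaign <- function(library, sar, cfg, embedding,
                                   bootstrap_n = 268L, rounds = 4L, B = 72L,
                                   seed = 1L, stop_set_size = 1000L,
                                   hyper_strategy = "median",
                                   refit = "first_round", cv_folds = 0L) {
  gs <- goal_specs()
  truth <- oracle_goal_targets(library, sar)
  label_ids <- function(ids, tag) {
    prof <- simulate_screen(library, sar, cfg, ids = ids, round_tag = tag)
    Y <- vapply(seq_len(nrow(gs)),
                function(i) goal_score(prof, gs[i, ]), numeric(nrow(prof)))
    rownames(Y) <- prof$molecule_id; colnames(Y) <- gs$goal_id
    Y
  }
  state <- al_campaign(embedding, library$id, B = B,
                       stop_set_size = stop_set_size, seed = seed,
                       hyper_strategy = hyper_strategy, refit = refit,
                       rounds_planned = rounds, cv_folds = cv_folds)
  set.seed(seed)
  boot <- sample(library$id, bootstrap_n)
  Yb <- label_ids(boot, 0L)
  state <- al_ingest(state, rownames(Yb), Yb)
  top1 <- matrix(NA_real_, rounds + 1L, nrow(gs),
                 dimnames = list(paste0("round", 0:rounds), gs$goal_id))
  tested_rounds <- list(boot)
  top1[1, ] <- apply(truth[boot, , drop = FALSE], 2, max)
  for (r in seq_len(rounds)) {
    state <- run_round(state)
    sel <- state$last_selected
    Yr <- label_ids(sel, r)
    state <- al_ingest(state, rownames(Yr), Yr)
    tested_rounds[[r + 1L]] <- sel
    tested_all <- unlist(tested_rounds)
    top1[r + 1L, ] <- apply(truth[tested_all, , drop = FALSE], 2, max)
  }
  state$workspaces <- NULL      # drop the (large) posterior factorizations
  list(state = state, tested = tested_rounds, top1 = top1,
       bootstrap = boot, truth = truth)
}

#' Random-selection baseline with a matched budget
#'
#' @param library,sar as in [run_synthetic_campaign()].
#' @param bootstrap ids of the shared bootstrap set.
#' @param n_select how many additional molecules to draw at random.
#' @param seed draw seed.
#' @return named vector: best oracle target per goal over
#'   bootstrap + random picks.
#' @export
random_baseline_top1 <- function(library, sar, bootstrap, n_select, seed = 1L) {
  truth <- oracle_goal_targets(library, sar)
  set.seed(seed + 104729L)
  pool <- setdiff(library$id, bootstrap)
  picks <- sample(pool, min(n_select, length(pool)))
  apply(truth[c(bootstrap, picks), , drop = FALSE], 2, max)
}
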