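# EI, Bhattacharyya, Kriging-believer batching, round orchestration.

test_that("expected improvement matches its closed form and limits", {
  # deterministic limit
  expect_equal(expected_improvement(0.5, 0, incumbent = 1), 0)
  expect_equal(expected_improvement(1.5, 0, incumbent = 1), 0.5)
  # mu = f*, sigma = 1, xi = 0 -> phi(0)
  expect_equal(expected_improvement(0, 1, incumbent = 0), dnorm(0),
               tolerance = 1e-12)
  # strictly increasing in sigma at fixed mu = f*
  eis <- expected_improvement(rep(0, 5), c(0.1, 0.5, 1, 2, 4), incumbent = 0)
  expect_true(all(diff(eis) > 0))
  # xi shifts the improvement threshold
  expect_lt(expected_improvement(0, 1, 0, xi = 0.5),
            expected_improvement(0, 1, 0, xi = 0))
  expect_error(expected_improvement(NaN, 1, 0), "NaN")
})

test_that("EI agrees with Monte-Carlo integration over a parameter sweep", {
  set.seed(1)
  n_mc <- 2e5
  for (case in list(c(mu = 0.3, s2 = 0.8, f = 0.5, xi = 0),
                    c(mu = -1, s2 = 2.0, f = 0.2, xi = 0.1),
                    c(mu = 1.4, s2 = 0.3, f = 1.0, xi = 0))) {
    draws <- rnorm(n_mc, case["mu"], sqrt(case["s2"]))
    mc <- mean(pmax(0, draws - case["f"] - case["xi"]))
    se <- sd(pmax(0, draws - case["f"] - case["xi"])) / sqrt(n_mc)
    ei <- expected_improvement(case["mu"], case["s2"], case["f"], case["xi"])
    expect_lt(abs(ei - mc), 4 * se)
  }
})

test_that("Gaussian Bhattacharyya distance matches quadrature", {
  expect_equal(bhattacharyya_gaussian(1.3, 0.7, 1.3, 0.7), 0)
  expect_equal(bhattacharyya_gaussian(0, 1, 2, 1), 0.5)
  expect_equal(bhattacharyya_gaussian(1, 1, 1, 4), 0.5 * log(5 / 4))
  # numerical-integration oracle: D_B = -log int sqrt(p q)
  quad_db <- function(m1, v1, m2, v2) {
    f <- function(x) sqrt(dnorm(x, m1, sqrt(v1)) * dnorm(x, m2, sqrt(v2)))
    -log(integrate(f, -Inf, Inf, rel.tol = 1e-10)$value)
  }
  for (case in list(c(0, 1, 2, 1), c(1, 1, 1, 4), c(-0.5, 0.3, 1.2, 2.5))) {
    expect_equal(bhattacharyya_gaussian(case[1], case[2], case[3], case[4]),
                 quad_db(case[1], case[2], case[3], case[4]),
                 tolerance = 1e-6)
  }
  expect_error(bhattacharyya_gaussian(0, 0, 0, 1), "domain error")
})

test_that("stabilizing_predictions is zero for identical posteriors and its
           SE is the textbook formula", {
  set.seed(2)
  post <- list(g1 = list(mean = rnorm(100), var = runif(100, 0.5, 2)),
               g2 = list(mean = rnorm(100), var = runif(100, 0.5, 2)))
  z <- stabilizing_predictions(post, post)
  expect_equal(z$mean_db, c(0, 0))
  post2 <- lapply(post, function(p) list(mean = p$mean + rnorm(100, 0, 0.3),
                                         var = p$var))
  s <- stabilizing_predictions(post, post2)
  db <- bhattacharyya_gaussian(post$g1$mean, post$g1$var,
                               post2$g1$mean, post2$g1$var)
  expect_equal(s$mean_db[1], mean(db))
  expect_equal(s$se_db[1], sd(db) / sqrt(100))
  expect_error(stabilizing_predictions(post, post[1]), "integrity")
})

test_that("incremental believer updates equal a from-scratch refit", {
  set.seed(3)
  Xall <- matrix(runif(60), 30, 2)
  ids <- sprintf("m%02d", 1:30)
  tr <- 1:8
  y <- rnorm(8)
  ws <- immunoloop:::ws_init(Xall[tr, ], y, ids[tr], Xall,
                             sf2 = 1, ell = 0.6, sn2 = 0.05,
                             mu_y = 0, sd_y = 1, capacity = 20)
  new1 <- 9:11; ynew <- rnorm(3)
  immunoloop:::ws_add(ws, Xall[new1, ], ynew, ids[new1],
                      immunoloop:::.sq_dist(ws$Xtr, Xall[new1, ]),
                      immunoloop:::.sq_dist(Xall[new1, ], Xall))
  ws2 <- immunoloop:::ws_init(Xall[c(tr, new1), ], c(y, ynew),
                              ids[c(tr, new1)], Xall,
                              sf2 = 1, ell = 0.6, sn2 = 0.05,
                              mu_y = 0, sd_y = 1)
  expect_equal(ws$mu, ws2$mu, tolerance = 1e-8)
  expect_equal(ws$var, ws2$var, tolerance = 1e-8)
  # label refresh replays the same factorization with new responses
  y_real <- c(y, rnorm(3))
  immunoloop:::ws_refresh_labels(ws, y_real)
  ws3 <- immunoloop:::ws_init(Xall[c(tr, new1), ], y_real, ids[c(tr, new1)],
                              Xall, sf2 = 1, ell = 0.6, sn2 = 0.05,
                              mu_y = 0, sd_y = 1)
  expect_equal(ws$mu, ws3$mu, tolerance = 1e-8)
  expect_equal(ws$n_believed, 0L)
})

test_that("kriging-believer selection replays an independent simulation of
           the protocol", {
  set.seed(4)
  Xall <- matrix(runif(24), 12, 2)
  ids <- sprintf("c%02d", 1:12)
  tr <- 1:4
  Y <- cbind(gA = rnorm(4), gB = rnorm(4))
  h <- c(sf2 = 1, ell = 0.5, sn2 = 0.01)
  mk_ws <- function(g) {
    immunoloop:::ws_init(Xall[tr, ], Y[, g], ids[tr], Xall,
                         h[["sf2"]], h[["ell"]], h[["sn2"]],
                         mu_y = 0, sd_y = 1, capacity = 12)
  }
  workspaces <- list(gA = mk_ws("gA"), gB = mk_ws("gB"))
  state <- list(X = Xall, ids = ids, B = 4L, xi = 0)
  excluded <- seq_len(12) %in% tr
  fstar <- list(gA = max(Y[, "gA"]), gB = max(Y[, "gB"]))
  sel <- immunoloop:::kriging_believer_batch(workspaces, state, excluded, fstar)

  # --- independent oracle: full GP refits with believed labels ---------
  oracle_sel <- character(0)
  otr <- list(gA = list(X = Xall[tr, ], y = Y[, "gA"]),
              gB = list(X = Xall[tr, ], y = Y[, "gB"]))
  avail <- !excluded
  while (length(oracle_sel) < 4 && any(avail)) {
    noms <- integer(0)
    preds <- list()
    for (g in c("gA", "gB")) {
      m <- fit_gpr(otr[[g]]$X, otr[[g]]$y, "fixed", hyper = h)
      # align with the workspace's unstandardized formulation
      m$mu_y <- 0; m$sd_y <- 1
      m$alpha <- backsolve(t(m$L), forwardsolve(m$L, otr[[g]]$y))
      p <- predict(m, Xall)
      preds[[g]] <- p
      ei <- expected_improvement(p$mean, p$var, fstar[[g]], 0)
      ei[!avail] <- -Inf
      noms <- c(noms, which.max(ei))
    }
    uniq <- unique(noms)
    for (g in c("gA", "gB")) {
      otr[[g]]$X <- rbind(otr[[g]]$X, Xall[uniq, , drop = FALSE])
      otr[[g]]$y <- c(otr[[g]]$y, preds[[g]]$mean[uniq])
    }
    avail[uniq] <- FALSE
    oracle_sel <- c(oracle_sel, ids[uniq])
  }
  expect_equal(sel$selected, oracle_sel)
  # a candidate nominated by both goals in one sweep is selected once
  expect_equal(anyDuplicated(sel$selected), 0)
  expect_true(all(table(sel$entries$id) <= 2))
})

test_that("degenerate batch: B = 1 with one goal picks the global EI argmax", {
  set.seed(5)
  Xall <- matrix(runif(30), 15, 2)
  ids <- sprintf("c%02d", 1:15)
  tr <- 1:5; y <- rnorm(5)
  ws <- immunoloop:::ws_init(Xall[tr, ], y, ids[tr], Xall, 1, 0.5, 0.01,
                             0, 1, capacity = 10)
  ei <- expected_improvement(ws$mu, ws$var, max(y), 0)
  ei[tr] <- -Inf
  sel <- immunoloop:::kriging_believer_batch(
    list(g = ws), list(X = Xall, ids = ids, B = 1L, xi = 0),
    seq_len(15) %in% tr, list(g = max(y)))
  expect_equal(sel$selected, ids[which.max(ei)])
})

test_that("campaign rounds are deterministic, never reselect, and audit
           believer hygiene", {
  cfg <- synthetic_screen_config(library_size = 300, seed = 71, noise_sd = 0.15)
  lib <- generate_library(cfg)
  sar <- planted_sar(lib, seed = 8)
  emb <- fingerprint_embedding(lib, n_bits = 64)
  run_once <- function(refit) {
    run_synthetic_campaign(lib, sar, cfg, emb, bootstrap_n = 40, rounds = 3,
                           B = 12, seed = 9, stop_set_size = 100,
                           refit = refit)
  }
  r1 <- run_once("first_round")
  r2 <- run_once("first_round")
  expect_identical(lapply(r1$tested, sort), lapply(r2$tested, sort))
  expect_identical(r1$state$last_batch, r2$state$last_batch)
  # global exclusion: no molecule tested twice across the campaign
  all_ids <- unlist(r1$tested)
  expect_equal(anyDuplicated(all_ids), 0)
  # cumulative discovered optimum never decreases
  expect_true(all(diff(r1$top1) >= -1e-12))
  # the each-round refit route runs too and obeys the same invariants
  r3 <- run_once("each_round")
  expect_equal(anyDuplicated(unlist(r3$tested)), 0)
  expect_null(r3$state$workspaces)
  # data-integrity guard: a round cannot run with unlabeled selections
  st <- r3$state
  st$pending <- "syn_00001"
  expect_error(run_round(st), "data-integrity")
})

test_that("an unlabelable embedding change is refused", {
  cfg <- synthetic_screen_config(library_size = 60, seed = 81)
  lib <- generate_library(cfg)
  emb <- fingerprint_embedding(lib, n_bits = 32)
  st <- al_campaign(emb, lib$id, B = 5, stop_set_size = 20, seed = 1)
  Y <- matrix(rnorm(10 * 12), 10, 12)
  st <- al_ingest(st, lib$id[1:10], Y)
  st$X[1, 1] <- st$X[1, 1] + 1
  expect_error(run_round(st), "embedding changed")
})
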