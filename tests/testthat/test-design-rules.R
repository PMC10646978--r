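# Fragment featurization, filtering, row normalization, LASSO design rules.

test_that("fragment featurization matches known substructure chemistry", {
  M <- featurize_fragments(c("c1ccccc1", "Clc1ccccc1", "CC(=O)C", "CC(=O)O"))
  expect_equal(ncol(M), 85)
  expect_true(all(M >= 0))
  expect_equal(unname(M[1, "fr_benzene"]), 1)
  expect_equal(unname(M[1, "fr_halogen"]), 0)
  expect_equal(unname(M[2, "fr_halogen"]), 1)
  # acetone vs acetic acid separate the carbonyl counters:
  # fr_C_O counts both, fr_C_O_noCOO excludes the carboxylic acid
  expect_equal(unname(M[3, "fr_C_O"]), 1); expect_equal(unname(M[3, "fr_C_O_noCOO"]), 1)
  expect_equal(unname(M[4, "fr_C_O"]), 1); expect_equal(unname(M[4, "fr_C_O_noCOO"]), 0)
  expect_equal(unname(M[4, "fr_COO"]), 1)
  # unparseable molecules dropped with a message
  expect_message(M2 <- featurize_fragments(c("CCO", "xxx")), "dropped 1")
  expect_equal(nrow(M2), 1)
})

test_that("feature filtering drops zero-variance and correlated columns in
           catalogue order", {
  set.seed(10)
  base <- matrix(rpois(10 * 4, 2), 10, 4)
  M <- cbind(base, dup = base[, 2], const = 7)
  colnames(M) <- c("a", "b", "c", "d", "dup", "const")
  out <- filter_features(M, rho_max = 0.95)
  expect_equal(colnames(out), c("a", "b", "c", "d"))   # later duplicate dropped
  retained <- attr(out, "retained")
  expect_false(retained["dup"]); expect_false(retained["const"])
  # brute-force oracle: every retained pair correlates at most 0.95
  cm <- abs(cor(out))
  expect_true(all(cm[upper.tri(cm)] <= 0.95))
  # and each dropped non-constant column violates the bound vs some retained
  expect_gt(max(abs(cor(M[, "dup"], out))), 0.95)
})

test_that("row normalization yields unit rows and flags zero rows", {
  M <- rbind(c(3, 4), c(1, 0), c(0, 0))
  out <- normalize_rows(M)
  expect_equal(out[1, ], c(0.6, 0.8))
  expect_equal(out[2, ], c(1, 0))
  expect_equal(out[3, ], c(0, 0))
  expect_equal(attr(out, "zero_rows"), 3L)
})

test_that("LASSO shrinkage limits behave analytically", {
  set.seed(20)
  n <- 120; p <- 8
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  beta <- c(2, -1.5, 0.8, rep(0, p - 3))
  y <- drop(X %*% beta)
  # lambda -> infinity: all coefficients zero, intercept = mean(y)
  m_inf <- fit_lasso_cv(X, y, lambda = c(1e6, 1e5), folds = 4, seed = 1)
  expect_equal(m_inf$nonzero, 0)
  expect_equal(m_inf$intercept, mean(y), tolerance = 1e-8)
  # lambda = 0 on a noiseless over-determined system: least-squares recovery
  m0 <- fit_lasso_cv(X, y, lambda = c(0.5, 0.1, 0.01, 0), folds = 4, seed = 1,
                     thresh = 1e-12)
  ls <- coef(lm(y ~ X))
  expect_equal(unname(m0$coefficients), unname(ls[-1]), tolerance = 1e-6)
  # degenerate all-equal targets
  expect_warning(md <- fit_lasso_cv(X, rep(3, n)), "degenerate")
  expect_equal(md$intercept, 3)
  expect_equal(md$nonzero, 0L)
})

test_that("the regularization path is monotone and CV picks a sparse truth", {
  set.seed(21)
  n <- 500; p <- 70
  X <- matrix(rpois(n * p, 1.2), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  Xn <- normalize_rows(X)
  # magnitudes sit at the package's planted-effect scale (~1 log2 unit per
  # molecule once row normalization shrinks count entries to ~0.1)
  planted <- c(f3 = 1.2, f10 = -1.0, f25 = 0.8, f40 = -1.4, f66 = 0.9)
  recov <- 0L
  for (s in 1:20) {
    set.seed(100 + s)
    y <- drop(Xn[, names(planted)] %*% planted) + rnorm(n, 0, 0.3)
    m <- fit_lasso_cv(Xn, y, folds = 5, seed = s)
    ok <- all(sign(m$coefficients[names(planted)]) == sign(planted))
    recov <- recov + ok
    if (s == 1) {
      # nonzero count non-increasing in lambda along the fixed grid
      nz <- m$cv_curve$nonzero[order(m$cv_curve$lambda, decreasing = TRUE)]
      expect_true(all(diff(nz) >= 0))
    }
  }
  expect_gte(recov, 18)     # sign recovery in >= 90% of replicates
})

test_that("rank_coefficients orders by |theta| with catalogue tie-break", {
  m <- structure(list(combination = "NFKB_LPS",
                      coefficients = c(a = 0.5, b = -0.9, c = 0),
                      intercept = 0, lambda = 0.1, cv_mae = 0.2,
                      nonzero = 2L), class = "lasso_rule_model")
  rk <- rank_coefficients(m, top_n = 2)
  expect_equal(rk$fragment, c("b", "a"))
  expect_equal(rk$theta, c(-0.9, 0.5))
  expect_equal(rk$role, c("suppressor-promoting", "enhancer-promoting"))
  m$coefficients[] <- 0
  expect_equal(nrow(rank_coefficients(m)), 0)
})

test_that("a planted halogen-suppression screen surfaces fr_halogen with
           negative weight in the NF-kB rules", {
  sc <- fx_screen()
  sar <- planted_sar(sc$lib, n_active = 3, seed = 13,
                     force = c(fr_halogen = -0.8))
  prof <- simulate_screen(sc$lib, sar, sc$cfg)
  prof$smiles <- sc$lib$smiles[match(prof$molecule_id, sc$lib$id)]
  rules <- extract_design_rules(sc$lib, prof, seed = 3)
  expect_length(rules, 8)
  for (cm in c("NFKB_LPS", "NFKB_MPLA", "NFKB_CPG")) {
    expect_lt(rules[[cm]]$coefficients["fr_halogen"], 0)
  }
  # ranked view reports it as suppressor-promoting
  rk <- rank_coefficients(rules$NFKB_LPS, top_n = 6)
  expect_true("fr_halogen" %in% rk$fragment)
})
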