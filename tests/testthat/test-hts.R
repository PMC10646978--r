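# Plate normalization, replicate merging, viability, goals.

mk_readings <- function(rows) {
  do.call(rbind, lapply(rows, function(r) {
    data.frame(plate_id = r[[1]], well = r[[2]], molecule_id = r[[3]],
               pathway = r[[4]], agonist = r[[5]],
               raw_value = as.numeric(r[[6]]), stringsAsFactors = FALSE)
  }))
}

test_that("normalize_plate divides by the same-plate positive-control mean", {
  rd <- mk_readings(list(
    list("p1", "c1", CONTROL_POSITIVE, "NFKB", "LPS", 10),
    list("p1", "c2", CONTROL_POSITIVE, "NFKB", "LPS", 20),
    list("p1", "w1", "m1", "NFKB", "LPS", 45),
    list("p1", "w2", "m2", "NFKB", "LPS", 15)))
  out <- normalize_plate(rd)
  expect_equal(out$fold[out$molecule_id == "m1"], 3)       # 45 / 15
  expect_equal(out$fold[out$molecule_id == "m2"], 1)       # equals ctrl mean
  expect_equal(mean(out$fold[out$molecule_id == CONTROL_POSITIVE]), 1)
  # modulator-only wells normalize against the same-plate no-agonist controls
  rd2 <- mk_readings(list(
    list("p1", "c1", CONTROL_POSITIVE, "NFKB", "NONE", 8),
    list("p1", "w1", "m1", "NFKB", "NONE", 4)))
  expect_equal(normalize_plate(rd2)$fold[2], 0.5)
  # missing controls is an error naming the plate
  rd3 <- mk_readings(list(list("pX", "w1", "m1", "NFKB", "LPS", 5)))
  expect_error(normalize_plate(rd3), "pX")
})

test_that("plate-scale invariance: rescaling one plate changes no fold", {
  sc <- fx_screen()
  rd <- simulate_plate_readings(sc$lib, sc$sar, sc$cfg, ids = sc$lib$id[1:40])
  f1 <- normalize_plate(rd)
  one_plate <- rd$plate_id == rd$plate_id[1]
  rd2 <- rd; rd2$raw_value[one_plate] <- rd2$raw_value[one_plate] * 37.5
  f2 <- normalize_plate(rd2)
  expect_equal(f1$fold, f2$fold, tolerance = 1e-12)
})

test_that("replicate merging averages and propagates the error of the mean", {
  rd <- mk_readings(list(
    list("p1", "c", CONTROL_POSITIVE, "NFKB", "LPS", 10),
    list("p2", "c", CONTROL_POSITIVE, "NFKB", "LPS", 10),
    list("p1", "w", "m1", "NFKB", "LPS", 10),
    list("p2", "w", "m1", "NFKB", "LPS", 30),
    list("p1", "w2", "m2", "NFKB", "LPS", 20),
    list("p2", "w2", "m2", "NFKB", "LPS", 20),
    list("p1", "w3", "m3", "NFKB", "LPS", 20)))
  mg <- merge_replicates(normalize_plate(rd))
  m1 <- mg[mg$molecule_id == "m1", ]
  expect_equal(m1$fold, 2)                 # (1 + 3) / 2
  expect_equal(m1$fold_err, 1)             # |1 - 3| / 2
  m2 <- mg[mg$molecule_id == "m2", ]
  expect_equal(m2$fold_err, 0)             # identical replicates
  expect_false(mg$complete[mg$molecule_id == "m3"])  # missing replicate
  # delta-method propagation onto log2: err / (fold * ln 2)
  expect_equal(log2_fold_error(2, 1), 1 / (2 * log(2)))
  expect_equal(log2_fold_error(2, 1), 0.7213475, tolerance = 1e-6)
})

test_that("viability requires both masks strictly above 70%", {
  prof <- fx_toy_profiles(
    list(a = c(), b = c(), c = c(), d = c()),
    conf = rbind(c(1.00, 0.95), c(0.90, 0.69), c(0.71, 0.701), c(NA, 0.9)))
  expect_equal(prof$viable, c(TRUE, FALSE, TRUE, NA))
  # boundary: exactly 0.70 fails (strict inequality)
  p2 <- apply_viability_filter(data.frame(conf1 = 0.70, conf2 = 1))
  expect_false(p2$viable)
})

test_that("the twelve goals and eight combinations are exactly as specified", {
  gs <- goal_specs()
  expect_equal(nrow(gs), 12)
  expect_equal(sum(gs$pathway == "NFKB"), 8)
  expect_equal(sum(gs$pathway == "IRF" & gs$direction == "ENHANCE"), 4)
  # cGAMP never with NFKB, CpG never with IRF
  for (i in seq_len(nrow(gs))) {
    ags <- gs$agonists[[i]]
    if (gs$pathway[i] == "NFKB") expect_false("CGAMP" %in% ags)
    if (gs$pathway[i] == "IRF") expect_false("CPG" %in% ags)
  }
  expect_equal(nrow(combination_specs()), 8)
})

test_that("goal_score signs, logs, and aggregates correctly", {
  prof <- fx_toy_profiles(list(
    m1 = c(NFKB_LPS = 2.0),
    m2 = c(NFKB_LPS = 0.25),
    m3 = c(NFKB_LPS = 2, NFKB_MPLA = 4, NFKB_CPG = 2)))
  expect_equal(goal_score(prof, "NFKB_LPS_ENH")[1], 1)
  expect_equal(goal_score(prof, "NFKB_LPS_SUP")[2], 2)
  expect_equal(goal_score(prof, "NFKB_GEN_ENH")[3], log2(8 / 3))
  expect_equal(goal_score(prof, "NFKB_GEN_ENH", aggregate = "geometric")[3],
               mean(log2(c(2, 4, 2))))
  # suppress = -enhance on the same channel
  expect_equal(goal_score(prof, "NFKB_GEN_SUP"), -goal_score(prof, "NFKB_GEN_ENH"))
})

test_that("count_modulators counts viable molecules once, inclusively", {
  prof <- fx_toy_profiles(list(
    hit_enh = c(NFKB_LPS = 2.0),             # exactly at threshold
    hit_sup = c(IRF_LPS = 0.9, NFKB_MPLA = 0.5),
    near = c(NFKB_LPS = 1.9, NFKB_MPLA = 1.9, NFKB_CPG = 1.9,
             IRF_LPS = 1.9, IRF_MPLA = 1.9, IRF_CGAMP = 1.9),
    dead = c(NFKB_LPS = 10)),
    conf = rbind(c(1, 1), c(1, 1), c(1, 1), c(0.2, 1)))
  expect_equal(count_modulators(prof, 2), 2)
  expect_equal(count_modulators(prof, 1.5), 3)
  expect_equal(count_modulators(prof, 10), 0)   # the 10x hit is non-viable
  # monotone non-increasing in threshold
  cts <- vapply(c(1.2, 1.5, 2, 5, 10), function(t) count_modulators(prof, t), 0L)
  expect_true(all(diff(cts) <= 0))
  expect_error(count_modulators(prof, 1), "exceed")
})

test_that("top_performers matches a full sort with id tie-breaks", {
  set.seed(12)
  folds <- lapply(1:50, function(i) c(NFKB_LPS = round(2^runif(1, -2, 2), 2)))
  names(folds) <- sprintf("m%02d", 1:50)
  prof <- fx_toy_profiles(folds)
  sc <- goal_score(prof, "NFKB_LPS_ENH")
  ord <- order(-sc, prof$molecule_id)
  for (k in c(1, 3, 17, 50)) {
    expect_equal(top_performers(prof, "NFKB_LPS_ENH", k)$molecule_id,
                 prof$molecule_id[ord[k]])
  }
  expect_error(top_performers(prof, "NFKB_LPS_ENH", 51), "range error")
  # simple 3-molecule identity case
  p3 <- fx_toy_profiles(list(a = c(NFKB_LPS = 3), b = c(NFKB_LPS = 2),
                             c = c(NFKB_LPS = 1)))
  expect_equal(top_performers(p3, "NFKB_LPS_ENH", 1)$molecule_id, "a")
  expect_equal(top_performers(p3, "NFKB_LPS_ENH", 1)$base_fold, 3)
})
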