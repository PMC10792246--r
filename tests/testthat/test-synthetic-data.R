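test_that("simulate_plate is deterministic and leaves the global RNG alone", {
  cfg <- noisy_config(seed = 1)
  w1 <- simulate_plate(cfg)
  set.seed(999)   # unrelated global state must not leak in
  w2 <- simulate_plate(cfg)
  expect_identical(w1, w2)
  expect_false(identical(simulate_plate(noisy_config(seed = 2)), w1))
})

test_that("noiseless plates recover true activities exactly through the pipeline", {
  acts <- c(z = 0, lo = 25, mid = 65, hi = 100, over = 120)
  rel <- relative_activities(noiseless_config(acts))
  expect_equal(rel[names(acts)], acts, tolerance = 1e-12,
               ignore_attr = FALSE)
  expect_equal(unname(rel["WT"]), 100)
  # zero-activity construct has exactly zero specific efflux
  eff <- process_efflux(simulate_plate(noiseless_config(acts)))
  expect_equal(eff$specific_efflux[eff$construct == "z"], rep(0, 4))
})

test_that("well layout contains mock wells and respects configuration", {
  cfg <- noisy_config(seed = 3)
  w <- simulate_plate(cfg)
  for (e in seq_len(cfg$n_experiments)) {
    we <- w[w$experiment == e, ]
    expect_true(any(we$construct == "MOCK" & we$condition == "no_acceptor"))
    expect_true(any(we$construct == "MOCK" & we$condition == "with_acceptor"))
    expect_true(any(we$construct == "WT"))
  }
  expect_true(all(is.na(w$renilla[w$construct == "MOCK"])))
  expect_true(all(w$medium >= 0 & w$lysate > 0))
})

test_that("impossible efflux budgets are rejected with a bounds error", {
  expect_error(
    sim_config(constructs = data.frame(name = "x", activity = 400),
               wt_true_specific_efflux = 0.3),
    "bounds error")
  expect_error(sim_config(wt_true_specific_efflux = 0.9,
                          leakage_fraction = 0.2),
               "< 1")
  expect_error(sim_config(n_experiments = 1), "n_experiments")
})

test_that("simulate_blots: band sum tracks protein level; mock lane is empty", {
  cfg <- noiseless_config(c(v = 50), protein_levels = c(v = 0.5),
                          wt_band_actin_ratio = 1.5)
  b <- simulate_blots(cfg)
  wt <- b[b$construct == "WT", ][1, ]
  v <- b[b$construct == "v", ][1, ]
  expect_equal((wt$band1 + wt$band2) / wt$actin, 1.5)
  expect_equal((v$band1 + v$band2) / v$actin, 0.75)
  mock <- b[b$construct == "MOCK", ]
  expect_true(all(mock$band1 == 0 & mock$band2 == 0))
  expect_identical(simulate_blots(cfg), b)
})

test_that("simulate_msa plants exact support counts and a clean human row", {
  msa <- simulate_msa(n_species = 29, seed = 4,
                      variant_support = list(p.R130K = 3, p.P250L = 0,
                                             p.V589I = 5))
  expect_length(msa, 30L)      # 29 species + human
  expect_identical(species_with_alt_as_reference(msa, "p.R130K"), 3L)
  expect_identical(species_with_alt_as_reference(msa, "p.P250L"), 0L)
  expect_identical(species_with_alt_as_reference(msa, "p.V589I"), 5L)
  human <- strsplit(msa[["Homo_sapiens"]], "")[[1]]
  expect_identical(human[130], "R")
  expect_identical(human[589], "V")
  expect_error(simulate_msa(5, list(p.R130K = 6)), "support")
  expect_error(simulate_msa(5, list(p.R130K = 3), seq_length = 100),
               "outside")
})

test_that("simulate_image_pair hits exact and population correlations", {
  # degenerate limits are exact even in population mode
  p1 <- simulate_image_pair(1, shape = c(32, 32), seed = 1, clip = FALSE)
  expect_equal(pearson_coloc(p1)$r, 1, tolerance = 1e-9)
  pm <- simulate_image_pair(-1, shape = c(32, 32), seed = 1, clip = FALSE)
  expect_equal(pearson_coloc(pm)$r, -1, tolerance = 1e-9)
  # exact construction pins the sample correlation at any target
  pe <- simulate_image_pair(0.26, shape = c(32, 32), seed = 2, exact = TRUE,
                            clip = FALSE)
  expect_equal(pearson_coloc(pe)$r, 0.26, tolerance = 1e-9)
  expect_error(simulate_image_pair(1.2), "target_r")
  expect_error(simulate_image_pair(0.5, shape = c(1, 1)), "degenerate")
})

test_that("population-mode correlation is calibrated at target 0 and 0.26", {
  rs0 <- vapply(1:100, function(s) {
    pearson_coloc(simulate_image_pair(0, shape = c(256, 256), seed = s))$r
  }, numeric(1))
  expect_gte(mean(abs(rs0) <= 0.02), 0.95)
  rs26 <- vapply(1:100, function(s) {
    pearson_coloc(simulate_image_pair(0.26, shape = c(256, 256),
                                      seed = 100 + s))$r
  }, numeric(1))
  expect_gte(mean(rs26), 0.24)
  expect_lte(mean(rs26), 0.28)
})
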