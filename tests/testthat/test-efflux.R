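test_that("efflux fraction arithmetic and scale invariance", {
  expect_equal(compute_efflux_fraction(300, 700), 0.3)
  expect_equal(compute_efflux_fraction(0, 500), 0)
  expect_equal(compute_efflux_fraction(300, 700),
               compute_efflux_fraction(600, 1400))
  expect_error(compute_efflux_fraction(0, 0), "degenerate")
  expect_error(compute_efflux_fraction(-1, 5), ">= 0")
})

test_that("corrections subtract and deliberately do not clamp", {
  expect_equal(correct_leakage(0.30, 0.05), 0.25)
  expect_equal(correct_leakage(0.05, 0.05), 0)
  expect_equal(correct_leakage(0.03, 0.05), -0.02)
  expect_equal(compute_specific_efflux(0.25, 0.05), 0.20)
  expect_equal(compute_specific_efflux(0.05, 0.05), 0)
  expect_equal(compute_specific_efflux(0.04, 0.05), -0.01)
  expect_error(compute_specific_efflux(0.2, numeric()), "pairing")
})

test_that("WT normalization: identity, clamp rule, invalid experiment", {
  expect_equal(normalize_to_wt(0.20, 0.40), 50)
  expect_equal(normalize_to_wt(0.40, 0.40), 100)
  expect_equal(normalize_to_wt(-0.01, 0.40), -2.5)  # raw kept, clamp is reporting-only
  expect_error(normalize_to_wt(0.2, 0), "invalid")
  w <- simulate_plate(noiseless_config(c(neg = 0),
                                       mock_unspecific_efflux = 0.05))
  w$medium[w$construct == "neg"] <- w$medium[w$construct == "neg"] * 0.5
  eff <- process_efflux(w)
  neg <- eff[eff$construct == "neg", ]
  expect_true(all(neg$relative_activity_raw < 0))
  expect_true(all(neg$relative_activity == 0))
})

test_that("renilla adjustment rescales to common transfection efficiency", {
  expect_equal(renilla_adjust(0.2, 500, 500), 0.2)
  expect_equal(renilla_adjust(0.2, 1000, 500), 0.1)
  expect_error(renilla_adjust(0.2, 0, 500), "positive")
  # transfection variation alone is removed exactly by the adjustment
  cfg <- noiseless_config(c(v = 60), seed = 5, renilla_cv = 0.3)
  raw <- relative_activities(cfg, renilla_normalize = FALSE)
  adj <- relative_activities(cfg, renilla_normalize = TRUE)
  expect_false(isTRUE(all.equal(unname(raw["v"]), 60, tolerance = 1e-6)))
  expect_equal(unname(adj["v"]), 60, tolerance = 1e-9)
})

test_that("replicate aggregation uses the sample SD", {
  expect_equal(aggregate_replicates(c(79, 81)),
               list(mean = 80, sd = sqrt(2), n = 2L))
  expect_equal(aggregate_replicates(rep(50, 4))$sd, 0)
  # hand oracle: deviations (-14, 12, -1, 3), SS = 350, sd = sqrt(350/3)
  s <- aggregate_replicates(c(66, 92, 79, 83))
  expect_equal(s$mean, 80)
  expect_equal(s$sd, sqrt(350 / 3))  # 10.8012...
  expect_equal(round(s$sd, 2), 10.80)
  expect_error(aggregate_replicates(42), "insufficient")
})

test_that("pipeline order is fixed: WT-normalizing before mock subtraction differs", {
  cfg <- noisy_config(seed = 11)
  w <- simulate_plate(cfg)
  eff <- process_efflux(w)
  # wrong order: normalize raw fractions by the WT fraction first, apply the
  # corrections afterwards on the percent scale
  wrong <- lapply(split(as.data.frame(w), w$experiment), function(we) {
    frac <- we$medium / (we$medium + we$lysate)
    leak <- mean(frac[we$construct == "MOCK" & we$condition == "no_acceptor"])
    mock <- mean(frac[we$construct == "MOCK" & we$condition == "with_acceptor"])
    wt <- mean(frac[we$construct == "WT" & we$condition == "with_acceptor"])
    keep <- we$construct %in% c("lof", "vus", "ben") &
      we$condition == "with_acceptor"
    100 * frac[keep] / wt - 100 * leak - 100 * (mock - leak)
  })
  right <- eff$relative_activity_raw[eff$construct != "WT"]
  expect_false(isTRUE(all.equal(sort(unlist(wrong)), sort(right))))
})

test_that("normalization is per experiment and scale invariant", {
  cfg <- noisy_config(seed = 12)
  w <- simulate_plate(cfg)
  eff <- process_efflux(w)
  expect_true(all(eff$relative_activity[eff$construct == "WT"] == 100))
  # scaling every signal of one experiment leaves all activities unchanged
  w2 <- w
  idx <- w2$experiment == 2
  w2$medium[idx] <- w2$medium[idx] * 37.5
  w2$lysate[idx] <- w2$lysate[idx] * 37.5
  expect_equal(process_efflux(w2)$relative_activity,
               eff$relative_activity, tolerance = 1e-12)
  # WT of experiment k never normalizes experiment j: distorting exp 1's WT
  # changes only exp 1 rows
  w3 <- w
  wt1 <- w3$construct == "WT" & w3$experiment == 1
  w3$medium[wt1] <- w3$medium[wt1] * 2
  eff3 <- process_efflux(w3)
  expect_equal(eff3$relative_activity[eff3$experiment != 1],
               eff$relative_activity[eff$experiment != 1], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(
    eff3$relative_activity[eff3$experiment == 1 & eff3$construct == "vus"],
    eff$relative_activity[eff$experiment == 1 & eff$construct == "vus"])))
})

test_that("missing control wells raise stage-specific errors", {
  w <- simulate_plate(noisy_config(seed = 13))
  expect_error(process_efflux(w[!(w$construct == "MOCK" &
                                    w$condition == "no_acceptor"), ]),
               "mock/no-acceptor")
  expect_error(process_efflux(w[!(w$construct == "MOCK" &
                                    w$condition == "with_acceptor"), ]),
               "pairing")
  expect_error(process_efflux(w[w$construct != "WT", ]), "WT")
})
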