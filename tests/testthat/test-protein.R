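test_that("total-protein quantification uses the band sum over actin", {
  expect_equal(quantify_total(c(500, 300), 400, c(800, 0), 400), 100)
  expect_equal(quantify_total(c(0, 0), 400, c(800, 0), 400), 0)
  # band split is irrelevant, only the sum enters
  expect_equal(quantify_total(c(600, 200), 500, c(400, 400), 500), 100)
  set.seed(31)
  for (i in 1:20) {
    tot <- runif(1, 100, 1000); s <- runif(1)
    expect_equal(quantify_total(c(tot * s, tot * (1 - s)), 300,
                                c(500, 250), 300),
                 quantify_total(c(tot, 0), 300, c(250, 500), 300))
  }
  expect_error(quantify_total(c(1, 2), 0, c(1, 2), 5), "actin")
  expect_error(quantify_total(c(1, 2, 3), 5, c(1, 2), 5), "1-2")
})

test_that("blot tables quantify within blot and demand a WT lane", {
  cfg <- noiseless_config(c(v = 50), protein_levels = c(v = 0.5))
  q <- quantify_blots(simulate_blots(cfg))
  expect_equal(q$total_pct_wt[q$construct == "v"], rep(50, 4))
  expect_equal(q$total_pct_wt[q$construct == "MOCK"], rep(0, 4))
  b <- simulate_blots(cfg)
  expect_error(quantify_blots(b[b$construct != "WT", ]), "WT lane")
})

test_that("surface expression is a ratio of ratios", {
  expect_equal(surface_expression(50, 0.5, 100, 1.0), 100)
  expect_equal(surface_expression(0, 0.5, 100, 1.0), 0)
  expect_equal(surface_expression(80, 2, 100, 1), surface_expression(160, 4, 100, 1))
  expect_error(surface_expression(50, 0, 100, 1), "> 0")
})

test_that("treatment response: fold, direction gate, permutation-checked p", {
  treated <- c(150, 160, 155); mock <- c(100, 95, 105)
  tr <- treatment_response(treated, mock, direction = "increase")
  expect_equal(tr$fold_change, mean(treated) / mean(mock), tolerance = 1e-12)
  expect_equal(round(tr$fold_change, 2), 1.55)
  # the exact 20-split permutation oracle agrees this is a real increase
  perm <- permutation_t_test(treated, mock, tails = 1, direction = "greater")
  expect_lt(perm, 0.1)   # smallest attainable one-sided mid-p at n=3+3 is 1/40
  expect_true(tr$responder)
  expect_lt(tr$p_value, 0.05)
  # no effect -> fold 1, non-responder
  same <- treatment_response(c(100, 95, 105), c(100, 95, 105))
  expect_equal(same$fold_change, 1)
  expect_false(same$responder)
  # significant change in the wrong direction is gated out
  down <- treatment_response(c(50, 52, 48), c(100, 95, 105),
                             direction = "increase")
  expect_false(down$responder)
  expect_lt(down$fold_change, 1)
  expect_error(treatment_response(100, c(1, 2)), "n >= 2")
})

test_that("stabilization call is a one-tailed increase on surface expression", {
  up <- stabilization_call(c(150, 145, 160), c(100, 102, 98))
  expect_true(up$responder)
  expect_identical(up$condition, "apoa1")
  flat <- stabilization_call(c(101, 99, 100), c(100, 102, 98))
  expect_false(flat$responder)
  expect_error(stabilization_call(150, 100), "n >= 2")
})

test_that("responder calls recover configured treatment effects (property)", {
  # 200 simulated stabilization experiments at noise_cv = 0.10, n = 3:
  # accuracy of responder calls vs ground truth must reach 95%. The true
  # effect is a 3-fold surface increase — the lower end of the 3-8-fold
  # chaperone-induced surface changes the emulated study reports — and the
  # null arm leaves the surface untouched.
  effects <- list(pba_4 = list(
    resp = c(total = 1, surface = 3, activity = 1),
    null = c(total = 1, surface = 1, activity = 1)))
  hits <- 0L; total <- 0L
  for (i in 1:200) {
    cfg <- sim_config(seed = 4000 + i, n_experiments = 3,
                      constructs = data.frame(name = c("resp", "null"),
                                              activity = c(30, 30)),
                      noise_cv = 0.10, load_cv = 0.15,
                      treatment_effects = effects)
    s <- quantify_surface(simulate_surface(cfg, c("mock_treated", "pba_4")))
    for (nm in c("resp", "null")) {
      trt <- s$surface_pct_wt[s$construct == nm & s$condition == "pba_4"]
      mock <- s$surface_pct_wt[s$construct == nm &
                                 s$condition == "mock_treated"]
      call <- treatment_response(trt, mock)$responder
      hits <- hits + (call == (nm == "resp"))
      total <- total + 1L
    }
  }
  expect_gte(hits / total, 0.95)
})
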