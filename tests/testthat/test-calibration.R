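test_that("HGVS p. parsing accepts missense and rejects everything else", {
  v <- parse_hgvs_p(c("p.E284K", "K939M"))
  expect_equal(v$ref_aa, c("E", "K"))
  expect_equal(v$position, c(284L, 939L))
  expect_equal(v$alt_aa, c("K", "M"))
  expect_equal(v$hgvs_p, c("p.E284K", "p.K939M"))
  expect_error(parse_hgvs_p("p.E284X"), "parse error")
  expect_error(parse_hgvs_p("p.Glu284Lys"), "parse error")
  expect_error(parse_hgvs_p("p.E284fs"), "parse error")
  expect_error(parse_hgvs_p("p.E284E"), "synonymous")
})

test_that("conservation counting maps through the gapped human row", {
  # toy 6-row alignment, counts checked by hand: human ungapped position 3
  # maps to column 4 (human column 2 is a gap); alt 'K' appears in sp1, sp4;
  # the gapped sp5 row counts as non-matching
  msa <- structure(c(
    Homo_sapiens = "A-CDE",
    sp1          = "AxCKE",
    sp2          = "AxCDE",
    sp3          = "AxCDE",
    sp4          = "AxCKE",
    sp5          = "AxC-E"), class = "msa", human_id = "Homo_sapiens")
  expect_identical(species_with_alt_as_reference(msa, "p.D3K"), 2L)
  expect_identical(species_with_alt_as_reference(msa, "p.E4W"), 0L)
  expect_error(species_with_alt_as_reference(msa, "p.D9K"), "mapping error")
  bad <- msa; attr(bad, "human_id") <- "missing"
  expect_error(species_with_alt_as_reference(bad, "p.D3K"), "mapping error")
  # generator round-trip: planted support is recovered
  sim <- simulate_msa(10, list(p.A5C = 4), seed = 9)
  expect_identical(species_with_alt_as_reference(sim, "p.A5C"), 4L)
})

test_that("calibration eligibility is a strict 'more than' rule", {
  expect_true(calibration_eligible(3))
  expect_false(calibration_eligible(2))
  expect_false(calibration_eligible(0))
  expect_equal(calibration_eligible(c(0, 2, 3, 29)),
               c(FALSE, FALSE, TRUE, TRUE))
})

test_that("benevolent threshold: mean of the k lowest, rounded", {
  expect_equal(derive_benevolent_threshold(
    c(79, 80, 82, 95, 101, 88, 110, 97, 85, 93)), 80)
  expect_equal(derive_benevolent_threshold(c(80, 80, 80)), 80)
  expect_equal(derive_benevolent_threshold(c(70, 80, 96)), 82)
  expect_error(derive_benevolent_threshold(c(80, 90)), "calibration error")
  # permutation invariance and dependence only on the k smallest
  set.seed(5)
  v <- c(79, 80, 82, 95, 101, 88, 110, 97, 85, 93)
  for (i in 1:10) {
    expect_equal(derive_benevolent_threshold(sample(v)), 80)
  }
  v2 <- v; v2[v2 > 82] <- v2[v2 > 82] + 500
  expect_equal(derive_benevolent_threshold(v2), 80)
})

test_that("pathogenic threshold anchors on the strongest control", {
  expect_equal(derive_pathogenic_threshold(c(30, 42, 50, 18)), 50)
  expect_equal(derive_pathogenic_threshold(35), 35)
  expect_equal(derive_pathogenic_threshold(c(40, 40, 40)), 40)
  expect_error(derive_pathogenic_threshold(numeric()), "calibration error")
})

test_that("classification partitions activity and is monotone", {
  ths <- threshold_set(50, 80)
  expect_equal(as.character(classify_activity(c(49, 65, 80), ths)),
               c("loss_of_function", "uncertain", "benevolent"))
  # boundary semantics: main-text >= versus figure-legend >
  expect_equal(as.character(classify_activity(
    80, threshold_set(50, 80, benevolent_boundary = "gt"))), "uncertain")
  # partition + monotonicity over a grid
  grid <- seq(0, 150, by = 0.5)
  cls <- classify_activity(grid, ths)
  expect_false(anyNA(cls))
  expect_true(all(diff(as.integer(cls)) >= 0))
  expect_error(threshold_set(80, 50), "benevolent_cutoff")
})

test_that("domain annotation matches the printed residue sets", {
  expect_true("gateway" %in% annotate_domains("p.R579Q"))
  expect_false("gateway" %in% annotate_domains("p.G616V"))
  expect_true("annulus_central" %in% annotate_domains(375))
  expect_true("annulus" %in% annotate_domains(375))
  expect_identical(annotate_domains(2000), character(0))
  expect_setequal(names(domain_map()),
                  c("ECD1", "ECD2", "gateway", "annulus", "annulus_central"))
})
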