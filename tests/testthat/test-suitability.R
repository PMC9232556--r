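test_that("default bins use 0.05 widths up to the data maximum", {
  b <- default_bins("velocity", max_value = 0.58)
  expect_equal(b$n, 12)
  expect_equal(b$edges, seq(0, 0.60, 0.05))
  deg <- default_bins("depth", max_value = 0.03)
  expect_equal(deg$n, 1)
  expect_equal(deg$edges, c(0, 0.05))
  sub <- default_bins("substrate")
  expect_equal(sub$kind, "categorical")
  expect_equal(sub$n, 6)
  # exact multiple of the width does not spawn an empty extra bin
  expect_equal(default_bins("velocity", max_value = 0.60)$n, 12)
})

test_that("bin assignment is half-open with a closed last bin", {
  b <- bin_scheme("velocity", edges = c(0, 0.05, 0.10))
  expect_equal(bin_index(c(0, 0.049, 0.05, 0.10), b), c(1, 1, 2, 2))
  expect_error(bin_index(0.11, b), "outside")
  s <- bin_scheme("substrate", categories = c("a", "e"))
  expect_equal(bin_index(c("e", "a"), s), c(2, 1))
  expect_error(bin_index("zz", s), "outside")
})

test_that("standardization divides by each campaign's maximum", {
  traits <- mini_traits()
  long <- data.frame(
    sample_id = c("s1", "s2", "s3", "s4"),
    campaign_id = c("A", "A", "B", "B"),
    velocity_m_s = 0.1, depth_m = 0.2, substrate = "a", area_m2 = 1,
    taxon = "Chironomidae", count = c(100, 25, 10, 5),
    stringsAsFactors = FALSE)
  ds <- validate_dataset(as_samples(long), traits)
  m <- assign_ffg(traits)
  std <- standardize_by_campaign(ds, m, "COMMUNITY")
  expect_equal(unname(std[c("s1", "s2", "s3", "s4")]),
               c(1.0, 0.25, 1.0, 0.5))
  # group absent from a campaign -> zeros with a warning per campaign
  expect_warning(expect_warning(
    std_ff <- standardize_by_campaign(ds, m, "PRE"), "absent"), "absent")
  expect_true(all(std_ff == 0))
})

test_that("availability and utilization curves normalize weighted tallies", {
  b <- bin_scheme("velocity", edges = c(0, 0.05, 0.10))
  env <- data.frame(sample_id = c("s1", "s2", "s3"), campaign_id = "A",
                    velocity = c(0.02, 0.07, 0.08), depth = 0.2,
                    substrate = "a", area = c(1, 1, 2),
                    stringsAsFactors = FALSE)
  expect_equal(availability_curve(env, b), c(0.25, 0.75))
  expect_equal(utilization_curve(env, b, c(s1 = 1.0, s2 = 0.5, s3 = 0)),
               c(2 / 3, 1 / 3))
  expect_error(utilization_curve(env, b, c(s1 = 0, s2 = 0, s3 = 0),
                                 group = "FF"), "FF")
})

test_that("preference masks unavailable bins and rejects inconsistent use", {
  expect_equal(preference_curve(c(0.25, 0.25, 0.25, 0.25),
                                c(0.25, 0.25, 0.25, 0.25)),
               rep(1, 4))
  expect_equal(preference_curve(c(0.6, 0.4), c(0.8, 0.2)), c(0.75, 2.0))
  hpc <- preference_curve(c(0.5, 0.5, 0), c(0.5, 0.5, 0))
  expect_true(is.na(hpc[3]))  # undefined, not zero
  expect_error(preference_curve(c(0.5, 0.5), c(1, 0)), "zero availability")
})

test_that("SI rescaling puts the best defined bin at 1", {
  expect_equal(to_si(c(0.75, 2.0)), c(0.375, 1.0))
  expect_equal(to_si(c(0.4, 0.4, 0.4)), rep(1, 3))
  expect_equal(to_si(c(NA, 0.7), defined = c(FALSE, TRUE)), c(NA, 1.0))
  expect_error(to_si(c(0, 0)), "zero")
})

test_that("availability-use excess flags candidate troughs", {
  ex <- huc_hac_excess(hac = c(0.6, 0.4), huc = c(0.3, 0.7))
  expect_equal(ex$difference, c(0.3, -0.3))
  expect_equal(ex$troughs, 1L)
  none <- huc_hac_excess(hac = c(0.4, 0.6), huc = c(0.4, 0.6))
  expect_length(none$troughs, 0)
  weird <- huc_hac_excess(hac = c(0, 1), huc = c(0.2, 0.8))
  expect_equal(weird$unavailable_use, 1L)
})

test_that("constructed curve sets conserve mass and respect scaling", {
  ds <- rand_dataset(15, seed = 31)
  m <- assign_ffg(ds$traits)
  for (param in c("velocity", "depth", "substrate")) {
    cs <- suitability_curves(ds, m, "COMMUNITY", param)
    expect_equal(sum(cs$hac), 1, tolerance = 1e-9)
    expect_equal(sum(cs$huc), 1, tolerance = 1e-9)
    expect_equal(max(cs$si_hpc[cs$defined]), 1)
    expect_true(all(is.na(cs$hpc[!cs$defined])))
  }
  # areas scaled by a constant leave availability unchanged
  ds2 <- ds; ds2$env$area <- ds$env$area * 7
  b <- default_bins("velocity", values = ds$env$velocity)
  expect_equal(availability_curve(ds2$env, b), availability_curve(ds$env, b))
  # one campaign's counts scaled by a constant leave its curves unchanged
  ds3 <- ds
  sel <- ds3$env$campaign_id == "c1"
  ds3$comm[sel, ] <- ds3$comm[sel, ] * 5
  cs0 <- suitability_curves(ds, m, "COMMUNITY", "velocity", bins = b)
  cs5 <- suitability_curves(ds3, m, "COMMUNITY", "velocity", bins = b)
  expect_equal(cs5$huc, cs0$huc, tolerance = 1e-12)
  expect_equal(cs5$si_hpc, cs0$si_hpc, tolerance = 1e-12)
})

test_that("curve tallies match the loop oracle on small data", {
  for (seed in c(41, 42)) {
    ds <- rand_dataset(12, seed = seed)
    m <- assign_ffg(ds$traits)
    b <- default_bins("velocity", values = ds$env$velocity)
    expect_equal(availability_curve(ds$env, b),
                 oracle_bin_tally(ds$env$velocity, ds$env$area,
                                  edges = b$edges),
                 tolerance = 1e-12)
    std <- standardize_by_campaign(ds, m, "COMMUNITY")
    expect_equal(utilization_curve(ds$env, b, std),
                 oracle_bin_tally(ds$env$velocity, unname(std),
                                  edges = b$edges),
                 tolerance = 1e-12)
    sb <- default_bins("substrate")
    expect_equal(availability_curve(ds$env, sb),
                 oracle_bin_tally(ds$env$substrate, ds$env$area,
                                  categories = sb$categories),
                 tolerance = 1e-12)
  }
})

test_that("campaign combination bridges between qualifying bins", {
  pm <- combine_si(list(c(1.0, 0.2, 0.1), c(0.1, 0.2, 1.0)),
                   strategy = "pointwise_max")
  expect_equal(pm$si, c(1.0, 0.2, 1.0))
  ef <- combine_si(list(c(1.0, 0.2, 0.1), c(0.1, 0.2, 1.0)),
                   strategy = "envelope_fill", fill_threshold = 0.8)
  expect_equal(ef$si, c(1, 1, 1))
  expect_error(combine_si(list(c(1, 0.5)), strategy = "envelope_fill",
                          continuous = FALSE), "categorical|continuous")
  # single curve set: pointwise max of its own si_huc and si_hpc
  ds <- rand_dataset(10, seed = 51)
  m <- assign_ffg(ds$traits)
  cs <- suitability_curves(ds, m, "COMMUNITY", "velocity")
  fin <- combine_campaigns(list(cs), strategy = "pointwise_max")
  expect_equal(fin$si, pmax(cs$si_huc, cs$si_hpc))
})

test_that("masked bins survive combination only if masked everywhere", {
  res <- combine_si(list(c(NA, 0.5, NA), c(NA, NA, 0.9)),
                    strategy = "pointwise_max")
  expect_true(is.na(res$si[1]))
  expect_equal(res$si[2:3], c(0.5, 0.9))
})
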