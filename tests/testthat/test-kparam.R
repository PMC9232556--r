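test_that("K components are computed per microhabitat", {
  traits <- as_traits(data.frame(
    taxon = c("Caenis sp.", "Chironomidae"),
    order = c("Ephemeroptera", "Diptera"),
    family = c("Caenidae", "Chironomidae"),
    gra = 0, shr = 0, gat = 10, ff = 0, pre = 0, par = 0, oth = 0))
  long <- data.frame(
    sample_id = c("s1", "s1", "s2"),
    campaign_id = "A", velocity_m_s = 0.2, depth_m = 0.3,
    substrate = "a", area_m2 = 1,
    taxon = c("Caenis sp.", "Chironomidae", "Caenis sp."),
    count = c(3, 3, 0), stringsAsFactors = FALSE)
  ds <- validate_dataset(as_samples(long), traits)
  comp <- k_components(ds)
  s1 <- comp[comp$sample_id == "s1", ]
  expect_equal(s1$n_fam, 2)
  expect_equal(s1$shannon, log(2))
  expect_equal(s1$ept, 3)
  expect_equal(s1$density, 6)
  s2 <- comp[comp$sample_id == "s2", ]  # empty microhabitat
  expect_equal(unlist(s2[c("n_fam", "shannon", "ept", "density")]),
               c(n_fam = 0, shannon = 0, ept = 0, density = 0))
})

test_that("two taxa of one family count as one family", {
  traits <- as_traits(data.frame(
    taxon = c("A", "B"), order = "Diptera", family = "Chironomidae",
    gra = 0, shr = 0, gat = 10, ff = 0, pre = 0, par = 0, oth = 0))
  long <- data.frame(sample_id = "s1", campaign_id = "A",
                     velocity_m_s = 0.1, depth_m = 0.2, substrate = "a",
                     area_m2 = 1, taxon = c("A", "B"), count = c(2, 3),
                     stringsAsFactors = FALSE)
  ds <- validate_dataset(as_samples(long), traits)
  expect_equal(k_components(ds)$n_fam, 1)
})

test_that("k is the fixed weighted sum normalized by the dataset maximum", {
  comp <- data.frame(sample_id = c("s1", "s2"),
                     n_fam = c(5, 1), shannon = c(1.0, 0),
                     ept = c(3, 0), density = c(40, 2))
  kr <- k_values(comp)
  expect_equal(kr$k_raw[1], 0.4 * 5 + 0.3 * 1 + 0.2 * 3 + 0.1 * 40)  # 6.9
  expect_equal(max(kr$k), 1)
  expect_equal(kr$k[1], 1)
  single <- k_values(data.frame(sample_id = "s", n_fam = 1, shannon = 0,
                                ept = 0, density = 3))
  expect_equal(single$k, 1)
  expect_warning(zero <- k_values(data.frame(sample_id = "s", n_fam = 0,
                                             shannon = 0, ept = 0,
                                             density = 0)), "empty")
  expect_equal(zero$k, 0)
})

test_that("adding a new family never decreases k_raw", {
  ds <- rand_dataset(10, seed = 61)
  kr <- k_coefficients(ds)
  # add individuals of an unused family to the first sample
  long <- data.frame(sample_id = ds$env$sample_id[1],
                     campaign_id = ds$env$campaign_id[1],
                     velocity_m_s = ds$env$velocity[1],
                     depth_m = ds$env$depth[1],
                     substrate = ds$env$substrate[1],
                     area_m2 = ds$env$area[1],
                     taxon = "Erpobdella sp.", count = 4,
                     stringsAsFactors = FALSE)
  ds2 <- ds
  ds2$comm[1, "Erpobdella sp."] <- ds2$comm[1, "Erpobdella sp."] + 4
  kr2 <- k_coefficients(ds2)
  expect_gte(kr2$k_raw[1], kr$k_raw[1])
})

test_that("component normalization bounds the weighted sum by 1", {
  ds <- rand_dataset(8, seed = 62)
  kr <- k_coefficients(ds, normalize_components = TRUE)
  expect_true(all(kr$k_raw <= 1 + 1e-12))
  expect_equal(max(kr$k), 1)
})

test_that("the binned K envelope matches a brute-force loop", {
  ds <- rand_dataset(14, seed = 63)
  kr <- k_coefficients(ds)
  b <- default_bins("velocity", values = ds$env$velocity)
  env <- k_upper_envelope(kr, ds, b)
  for (i in seq_len(b$n)) {
    lo <- b$edges[i]; hi <- b$edges[i + 1]
    last <- i == b$n
    sel <- sapply(seq_len(nrow(ds$env)), function(s) {
      v <- ds$env$velocity[s]
      if (last) v >= lo && v <= hi else v >= lo && v < hi
    })
    if (any(sel)) expect_equal(env$envelope[i], max(kr$k[sel]))
    else expect_true(is.na(env$envelope[i]))
  }
})

test_that("K envelope tracks utilization on suitability-driven data", {
  sc <- default_scenario()
  g <- generate(sc$config, sc$truth, seed = 77)
  m <- assign_ffg(g$dataset$traits)
  b <- default_bins("velocity", values = g$dataset$env$velocity)
  cs <- suitability_curves(g$dataset, m, "COMMUNITY", "velocity", bins = b)
  kr <- k_coefficients(g$dataset)
  env <- k_upper_envelope(kr, g$dataset, b, si_huc = cs$si_huc)
  ok <- env$defined & cs$defined
  rho <- cor(env$envelope[ok], cs$si_huc[ok], method = "spearman")
  expect_gt(rho, 0)
})
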