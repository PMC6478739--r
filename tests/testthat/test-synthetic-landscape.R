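test_that("generated bundles satisfy the co-registration and nesting invariants", {
  b <- small_bundle()
  shp <- dim(b$elevation)
  for (g in list(b$road_mask, b$urban_mask, b$water_mask, b$countries,
                 b$provinces, b$ecozones, b$geographies, b$ifl, b$pa,
                 b$agb_t0, b$agb_t1, b$landcover[[1]], b$landcover[[3]]))
    expect_equal(dim(g), shp)
  # urban and water are disjoint; forest codes never coincide with either
  expect_equal(sum(b$urban_mask == 1 & b$water_mask == 1), 0)
  lc <- b$landcover[[3]]
  expect_true(all(lc[b$urban_mask == 1] == 190))
  expect_true(all(lc[b$water_mask == 1] == 210))
  # every province nests inside exactly one country
  nest <- tapply(as.vector(b$countries), as.vector(b$provinces),
                 function(v) length(unique(v)))
  expect_true(all(nest == 1))
  # AGB is zero outside the forest of its epoch
  f_mid <- b$landcover[[2]] == 50
  f_end <- b$landcover[[3]] == 50
  expect_true(all(b$agb_t0[!f_mid] == 0))
  expect_true(all(b$agb_t1[!f_end] == 0))
  expect_true(all(b$agb_t1[f_end] > 0))
})

test_that("generation is deterministic under a seed and distinct across seeds", {
  a <- generate_landscape(c(32, 32), seed = 5)
  b <- generate_landscape(c(32, 32), seed = 5)
  expect_identical(a, b)
  c <- generate_landscape(c(32, 32), seed = 6)
  expect_false(identical(a$landcover[[3]], c$landcover[[3]]))
})

test_that("degenerate requests are handled explicitly", {
  expect_error(generate_landscape(c(16, 16)), "too small")
  z <- generate_landscape(c(32, 32), seed = 2, forest_fraction = 0)
  expect_equal(sum(z$landcover[[1]] == 50), 0)
  expect_equal(sum(z$landcover[[3]] == 50), 0)
  expect_true(all(z$agb_t1 == 0))
})

test_that("evolution respects eligibility and honours requested fractions", {
  b <- small_bundle()
  lc <- b$landcover[[1]]
  p <- change_process_params(loss_frac = 0.1, gain_frac = 0.03)
  series <- evolve_landcover(lc, p, epochs = 2, road_mask = b$road_mask,
                             seed = 3)
  lc2 <- series[[2]]
  lost <- lc == 50 & lc2 != 50
  gained <- lc != 50 & lc2 == 50
  # no loss outside forest, no gain on urban/water -- exhaustive
  expect_true(all(lc[lost] == 50))
  expect_true(all(lc[gained] == 10))
  n_forest <- sum(lc == 50)
  expect_equal(sum(lost), round(0.1 * n_forest))
  expect_equal(sum(gained), round(0.03 * n_forest))
  # zero fractions: next epoch identical
  same <- evolve_landcover(lc, change_process_params(loss_frac = 0,
                                                     gain_frac = 0),
                           epochs = 2, road_mask = b$road_mask, seed = 3)
  expect_identical(same[[2]], lc)
})

test_that("road-seeking coefficients put losses closer to roads than persistence", {
  b <- small_bundle()
  lc <- b$landcover[[1]]
  p <- change_process_params(beta_road = -2, beta_edge = 0, loss_frac = 0.1,
                             gain_frac = 0)
  lc2 <- evolve_landcover(lc, p, epochs = 2, road_mask = b$road_mask,
                          seed = 8)[[2]]
  droad <- euclidean_distance(b$road_mask, b$cell_size)
  lost <- lc == 50 & lc2 != 50
  persist <- lc == 50 & lc2 == 50
  expect_lt(mean(droad[lost]), mean(droad[persist]))
})

test_that("synthetic biomass encodes ages exactly and inverts per pixel", {
  csr <- default_csr_table()
  eco <- matrix(1L, 4, 4); geo <- matrix(2L, 4, 4)
  age <- matrix(10, 4, 4)
  f <- fnf_grid(matrix(1L, 4, 4))
  agb <- generate_agb(f, age, csr, eco, geo)
  rate <- csr_lookup(csr, "young_secondary", 1L, 2L)
  expect_equal(agb[1, 1], 2 * 10 * rate)   # ACD = age x CSR, AGB = 2 x ACD
  expect_equal(acd_from_agb(agb)[2, 2] / rate, 10)  # age round trip
  # non-forest pixels carry zero biomass
  f0 <- fnf_grid(matrix(0L, 4, 4))
  expect_true(all(generate_agb(f0, age, csr, eco, geo) == 0))
  # exhaustive per-pixel age recovery on a full bundle (noise-free)
  b <- small_bundle()
  sec <- b$landcover[[3]] == 50 & b$ifl == 0
  acd <- acd_from_agb(b$agb_t1)
  rate <- csr_lookup(b$csr, rep("young_secondary", sum(sec)),
                     b$ecozones[sec], b$geographies[sec])
  expect_equal(acd[sec] / rate, b$age_t1[sec], tolerance = 1e-12)
  # missing stratum errors by name
  expect_error(generate_agb(f, age, csr, matrix(9L, 4, 4), geo),
               "young_secondary 9")
})
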