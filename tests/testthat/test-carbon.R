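test_that("carbon density is half of biomass, linearly", {
  expect_equal(acd_from_agb(200), 100)
  expect_equal(acd_from_agb(0), 0)
  a <- matrix(stats::runif(16, 0, 400), 4)
  b <- matrix(stats::runif(16, 0, 400), 4)
  expect_equal(acd_from_agb(a + b), acd_from_agb(a) + acd_from_agb(b))
  expect_error(acd_from_agb(-1), ">= 0")
})

test_that("forest sub-classification follows the IFL/ACD/age rules", {
  csr <- csr_table(data.frame(
    forest_class = c("old_growth", "old_secondary", "young_secondary"),
    ecozone = 1L, geography = 1L, csr = c(0.5, 1.2, 3)))
  eco <- matrix(1L, 2, 3); geo <- matrix(1L, 2, 3)
  fnf <- fnf_grid(matrix(c(1L, 1L, 1L, 1L, 0L, 1L), 2, 3))
  ifl <- matrix(c(1L, 0L, 0L, 0L, 0L, 0L), 2, 3)
  acd <- matrix(c(150, 30, 90, 63.01, 0, 40), 2, 3)
  cl <- classify_forest(fnf, ifl, acd, csr, eco, geo, og_floor = 100)
  codes <- forest_class_codes()
  expect_equal(cl$class[1, 1], codes[["old_growth"]])       # in IFL, above floor
  expect_equal(cl$class[2, 1], codes[["young_secondary"]])  # 30/3 = 10 <= 20
  expect_equal(cl$age[2, 1], 10)
  expect_equal(cl$class[1, 2], codes[["old_secondary"]])    # 90/3 = 30 > 20
  expect_equal(cl$class[2, 2], codes[["old_secondary"]])    # 63.01/3 = 21.003
  expect_equal(cl$class[1, 3], codes[["nonforest"]])
  expect_equal(cl$class[2, 3], codes[["young_secondary"]])  # 40/3 = 13.3
  # ifl_only drops the floor
  low <- acd; low[1, 1] <- 10
  expect_equal(classify_forest(fnf, ifl, low, csr, eco, geo,
                               og_floor = 100)$class[1, 1],
               codes[["young_secondary"]])
  expect_equal(classify_forest(fnf, ifl, low, csr, eco, geo, og_floor = 100,
                               ifl_only = TRUE)$class[1, 1],
               codes[["old_growth"]])
})

test_that("old-forest projection adds CSR x growth period", {
  expect_equal(project_acd_old(100, 0.5), 120)
  expect_equal(project_acd_old(100, 0), 100)
  expect_equal(project_acd_old(100, 0.5, gp = 0), 100)
})

test_that("young-forest projection follows the two-phase aging model", {
  # age 10: grow at 3 for 11 yr to age 21, then at 0.6 for the remaining 29 yr
  expect_equal(project_acd_young(30, 3, 0.6), 30 + 3 * 11 + 0.6 * 29)
  expect_equal(project_acd_young(30, 3, 0.6), 80.4)
  # near the transition age the young phase vanishes: limit of the old form
  eps <- 1e-9
  g <- 21 - eps
  expect_equal(project_acd_young(3 * g, 3, 0.6),
               project_acd_old(3 * g, 0.6, gp = 40), tolerance = 1e-6)
  expect_error(project_acd_young(3 * 25, 3, 0.6), "old secondary")
})

test_that("new forest is credited half the scenario window", {
  expect_equal(acd_new_forest(2), 35)
  expect_equal(acd_new_forest(0.0), 0)
  expect_equal(acd_new_forest(4), 2 * acd_new_forest(2))
})

test_that("the grid projection equals the per-pixel closed forms exactly", {
  b <- generate_landscape(c(32, 32), seed = 21)
  fnf <- reclassify_to_fnf(b$landcover[[3]], cell_size = b$cell_size)
  acd <- acd_from_agb(b$agb_t1)
  cl <- classify_forest(fnf, b$ifl, acd, b$csr, b$ecozones, b$geographies,
                        og_floor = b$og_floor)
  proj <- project_acd_2050(cl, acd, b$csr, b$ecozones, b$geographies)
  codes <- forest_class_codes()
  for (i in seq_along(acd)) {
    cls <- cl$class[i]
    expected <-
      if (cls == codes[["nonforest"]]) 0 else {
        nm <- names(codes)[match(cls, codes)]
        if (nm == "young_secondary") {
          oracle_acd_young(acd[i],
                           csr_lookup(b$csr, "young_secondary",
                                      b$ecozones[i], b$geographies[i]),
                           csr_lookup(b$csr, "old_secondary",
                                      b$ecozones[i], b$geographies[i]))
        } else {
          oracle_acd_old(acd[i], csr_lookup(b$csr, nm, b$ecozones[i],
                                            b$geographies[i]))
        }
      }
    if (abs(proj[i] - expected) > 1e-9)
      fail(sprintf("pixel %d (class %d): %g vs %g", i, cls, proj[i], expected))
  }
  succeed()
})

test_that("projected carbon is monotone in every CSR", {
  b <- generate_landscape(c(32, 32), seed = 22)
  fnf <- reclassify_to_fnf(b$landcover[[3]], cell_size = b$cell_size)
  acd <- acd_from_agb(b$agb_t1)
  cl <- classify_forest(fnf, b$ifl, acd, b$csr, b$ecozones, b$geographies,
                        og_floor = b$og_floor)
  base <- project_acd_2050(cl, acd, b$csr, b$ecozones, b$geographies)
  for (row in seq_len(nrow(b$csr))) {
    up <- b$csr
    up$csr[row] <- up$csr[row] * 1.2
    bumped <- project_acd_2050(cl, acd, csr_table(up), b$ecozones,
                               b$geographies)
    expect_true(all(bumped - base > -1e-12))
  }
})

test_that("zonal ledgers sum ACD x area and partition exactly", {
  cs <- 300
  ctry <- matrix(1L, 4, 4)
  prov <- matrix(rep(c(101L, 102L), each = 8), 4)
  f1 <- fnf_grid(matrix(1L, 4, 4), cs)
  f2m <- matrix(1L, 4, 4); f2m[c(1, 2, 9)] <- 0L
  ch <- detect_change(f1, fnf_grid(f2m, cs))
  acd <- matrix(100, 4, 4)
  led <- afcs_change_detect(ch, acd, cell_size = cs,
                            zones = list(country = ctry, province = prov))
  tot <- led$afcs_tg_c[led$zone_type == "region"]
  expect_equal(tot, 3 * 100 * 9 / 1e6)          # 2700 Mg C = 2.7e-3 Tg
  by_prov <- led$afcs_tg_c[led$zone_type == "province"]
  expect_equal(sum(by_prov), tot)
  expect_equal(led$afcs_tg_c[led$zone_type == "country"], tot)
  # single-pixel arithmetic: ACD 100, 9 ha -> 900 Mg C
  one <- detect_change(f1, fnf_grid({m <- matrix(1L, 4, 4); m[5] <- 0L; m}, cs))
  expect_equal(afcs_change_detect(one, acd, cell_size = cs)$afcs_tg_c,
               9e-4)
  # empty loss set -> 0
  expect_equal(afcs_change_detect(detect_change(f1, f1), acd,
                                  cell_size = cs)$afcs_tg_c, 0)
})

test_that("gain ledgers mirror loss ledgers over gain pixels", {
  cs <- 300
  f1 <- fnf_grid(matrix(0L, 4, 4), cs)
  f2m <- matrix(0L, 4, 4); f2m[7] <- 1L
  ch <- detect_change(f1, fnf_grid(f2m, cs))
  acd_new <- matrix(35, 4, 4)
  led <- afcs_gain_projected(ch, acd_new, cell_size = cs)
  expect_equal(led$afcs_tg_c, 35 * 9 / 1e6)     # 315 Mg C
})

test_that("CSR table validation and lookup fail informatively", {
  bad <- data.frame(forest_class = c("young_secondary", "old_secondary"),
                    ecozone = 1L, geography = 1L, csr = c(1, 2))
  expect_error(csr_table(bad), "young-secondary CSR below")
  tab <- default_csr_table()
  expect_error(csr_lookup(tab, "old_growth", 7L, 1L), "old_growth 7 1")
  expect_equal(length(csr_lookup(tab, rep("old_growth", 3), c(1L, 2L, 1L),
                                 c(1L, 1L, 2L))), 3)
})

test_that("annualisation and CO2 conversion use the 35-year window and 3.67 ratio", {
  r <- annualize_and_convert(700)
  expect_equal(r$rate_tg_c_yr, 20)
  expect_equal(r$total_pg_co2, 700 * 3.67 / 1000)
  expect_equal(r$rate_tg_co2_yr, 700 * 3.67 / 35)
  z <- annualize_and_convert(0)
  expect_equal(unlist(z), c(rate_tg_c_yr = 0, total_pg_co2 = 0,
                            rate_tg_co2_yr = 0))
  expect_error(annualize_and_convert(1, horizon = 0), "horizon")
})
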