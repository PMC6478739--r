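test_that("transition matrices express demand as source-class proportions", {
  m <- build_transition_matrix(100, "loss", n_forest = 1000, n_nonforest = 500)
  expect_equal(m["forest", "nonforest"], 0.10)
  expect_equal(m["forest", "forest"], 0.90)
  expect_equal(unname(rowSums(m)), c(1, 1))
  g <- build_transition_matrix(50, "gain", n_forest = 100, n_nonforest = 200)
  expect_equal(g["nonforest", "forest"], 0.25)
  expect_equal(build_transition_matrix(0, "loss", 10, 10), diag(2),
               ignore_attr = TRUE)
  expect_error(build_transition_matrix(11, "loss", 10, 10), "exceeds")
})

test_that("allocation selects exactly the top-potential pixels", {
  tpm <- matrix(c(0.9, 0.8, 0.7, 0.6), 2)
  f <- fnf_grid(matrix(1L, 2, 2))
  r <- allocate(tpm, f, 2, "loss")
  expect_setequal(r$selected, which(tpm >= 0.8))
  expect_equal(r$realised, 2L)
  expect_equal(sum(unclass(r$fnf_end)), 2)
  # demand 0: identity
  r0 <- allocate(tpm, f, 0, "loss")
  expect_equal(unclass(r0$fnf_end), unclass(f), ignore_attr = TRUE)
})

test_that("allocation equals brute-force top-k on random small grids", {
  for (i in 1:50) {
    set.seed(i)
    nr <- sample(4:20, 1); nc <- sample(4:20, 1)
    f <- fnf_grid(matrix(rbinom(nr * nc, 1, 0.6), nr, nc))
    tpm <- matrix(round(stats::runif(nr * nc), 2), nr, nc)  # coarse: forces ties
    k <- sample.int(max(1, sum(unclass(f) == 1)), 1)
    r <- allocate(tpm, f, k, "loss", tie_seed = i)
    pool <- which(unclass(f) == 1)
    expect_setequal(r$selected, bf_topk(tpm, pool, k, tie_seed = i))
    # optimality: no unselected eligible pixel beats the worst selected one
    if (length(r$selected) < length(pool))
      expect_lte(max(tpm[setdiff(pool, r$selected)]), min(tpm[r$selected]))
  }
})

test_that("ties at the cut are resolved reproducibly", {
  tpm <- matrix(0.5, 2, 2); tpm[1, 1] <- 0.9
  f <- fnf_grid(matrix(1L, 2, 2))
  r1 <- allocate(tpm, f, 2, "loss", tie_seed = 7)
  r2 <- allocate(tpm, f, 2, "loss", tie_seed = 7)
  expect_identical(r1$selected, r2$selected)
  expect_equal(length(r1$selected), 2L)
})

test_that("growing demand nests previous selections", {
  set.seed(3)
  f <- fnf_grid(matrix(1L, 8, 8))
  tpm <- matrix(round(stats::runif(64), 1), 8, 8)
  prev <- allocate(tpm, f, 10, "loss", tie_seed = 1)$selected
  for (k in 11:20) {
    cur <- allocate(tpm, f, k, "loss", tie_seed = 1)$selected
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("shortfalls are reported, never silently dropped, and exclusions hold", {
  f <- fnf_grid(matrix(c(1L, 1L, 0L, 0L), 2))
  tpm <- matrix(0.5, 2, 2)
  r <- allocate(tpm, f, 5, "loss")
  expect_equal(r$realised, 2L)
  expect_equal(r$shortfall, 3L)
  expect_equal(r$realised + r$shortfall, r$demanded)
  # gains never land on excluded (urban/water) pixels
  excl <- matrix(c(FALSE, FALSE, TRUE, FALSE), 2)
  g <- allocate(tpm, f, 2, "gain", exclusion = excl)
  expect_false(3 %in% g$selected)
  expect_equal(g$realised, 1L)
})

test_that("mosaicked countries are additive and overlap is rejected", {
  f <- fnf_grid(matrix(1L, 4, 4))
  left <- matrix(FALSE, 4, 4); left[, 1:2] <- TRUE
  tpmL <- matrix(NA_real_, 4, 4); tpmL[left] <- 0.6
  tpmR <- matrix(NA_real_, 4, 4); tpmR[!left] <- 0.4
  rL <- allocate(tpmL, f, 3, "loss", tie_seed = 1)
  rR <- allocate(tpmR, f, 2, "loss", tie_seed = 2)
  m <- mosaic(f, list(`1` = rL, `2` = rR))
  expect_equal(change_counts(m$change)[["loss"]], 5L)
  expect_equal(sum(m$log$realised), 5)
  expect_equal(sum(unclass(m$fnf_end) == 0), 5)
  # one-country mosaic is the country result
  m1 <- mosaic(f, list(rL))
  expect_equal(change_counts(m1$change)[["loss"]], 3L)
  expect_error(mosaic(f, list(rL, rL)), "overlap")
})
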