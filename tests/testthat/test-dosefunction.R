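# masks for a simple two-lung geometry with a PTV block
dose_fixture <- function() {
  lungs <- cuboid_lungs()
  d <- lungs$dim
  ptv <- array(FALSE, d); ptv[3:4, 4:7, 5:9] <- TRUE
  gtv <- array(FALSE, d); gtv[3, 5:6, 6:8] <- TRUE
  list(d = d, masks = list(lung_L = lungs$left, lung_R = lungs$right,
                           ptv = ptv, gtv = gtv))
}

test_that("uniform doses give the textbook metric values", {
  fx <- dose_fixture()
  dv <- array(0, fx$d); dv[fx$masks$ptv] <- 60
  dose <- image_volume(dv, c(1, 1, 1), unit = "Gy")
  s <- dose_volume_metrics(dose, fx$masks, prescription_gy = 60)
  # Dx is interpolated within a 0.1 Gy DVH bin, so HI is 1 to bin accuracy
  expect_equal(s$hi, 1, tolerance = 2 * 0.1 / 60)
  expect_equal(s$ptv_min, 60)
  expect_equal(s$ptv_max, 60)

  dv2 <- array(10, fx$d)
  s2 <- dose_volume_metrics(image_volume(dv2, unit = "Gy"), fx$masks, 60)
  expect_equal(s2$mld, 10)
  expect_equal(s2$lung_v20, 0)
})

test_that("Vx and mean match direct counting on a two-voxel structure", {
  d <- c(4, 4, 4)
  m <- array(FALSE, d); m[1, 1, 1] <- TRUE; m[2, 1, 1] <- TRUE
  dv <- array(0, d); dv[1, 1, 1] <- 10; dv[2, 1, 1] <- 30
  masks <- list(ptv = m, lung_L = m, lung_R = array(FALSE, d))
  s <- dose_volume_metrics(image_volume(dv, unit = "Gy"), masks, 20,
                           exclude_gtv_from_lung = FALSE)
  expect_equal(s$mld, 20)
  expect_equal(s$lung_v20, 50)
})

test_that("binned DVH Dx/Vx agree with exhaustive voxel counting", {
  set.seed(15)
  doses <- rgamma(5000, shape = 2, scale = 8)
  dvh <- ventavoid:::cumulative_dvh(doses, 0.1)
  for (x in c(5, 10, 20, 30, 40)) {
    exact <- mean(doses >= x) * 100
    binned <- dvh$volume_pct[which.min(abs(dvh$dose - x))]
    expect_lt(abs(binned - exact), mean(doses >= x - 0.1 & doses < x + 0.1) * 100 + 1e-9)
    expect_equal(ventavoid:::vx_pct(doses, x), exact)
  }
  for (p in c(5, 50, 90, 95)) {
    dx <- ventavoid:::dvh_dx(dvh, p)
    exact_q <- quantile(doses, 1 - p / 100, names = FALSE, type = 1)
    expect_lt(abs(dx - exact_q), 0.1 + 1e-9)   # within one bin width
    # self-consistency: the volume at Dx brackets p within a bin
    expect_lt(abs(mean(doses >= dx) * 100 - p), 2)
  }
})

test_that("structure dose-function metrics on controlled masks", {
  d <- c(6, 6, 6)
  mask <- array(FALSE, d); mask[2:5, 2:5, 2:5] <- TRUE
  av <- structure(list(mask = mask, threshold = 0.15,
                       volume_cm3 = sum(mask) * 1e-3,
                       provenance = list()), class = "avoid_structure")
  dv <- array(0, d); dv[mask] <- 12
  sf <- structure_dose_function_metrics(image_volume(dv, unit = "Gy"), av)
  expect_equal(sf$sf_mld, 12)
  expect_equal(unname(sf$sf_v[c("5", "10", "20")]), c(100, 100, 0))

  av_empty <- av; av_empty$mask <- array(FALSE, d)
  sf0 <- structure_dose_function_metrics(image_volume(dv, unit = "Gy"), av_empty)
  expect_true(is.na(sf0$sf_mld))
  expect_true(all(is.na(sf0$sf_v)))
})

test_that("image dose-function metrics match hand-evaluated weighted sums", {
  # 3-voxel toy: (w, D) = (1,5), (2,10), (1,40)
  d <- c(3, 1, 1)
  lung <- array(TRUE, d)
  raw <- array(c(1, 2, 1), d)
  dv <- array(c(5, 10, 40), d)
  vm <- make_vent_map(raw, valid = lung)
  imf <- image_dose_function_metrics(image_volume(dv, unit = "Gy"), vm,
                                     lung, array(FALSE, d))
  expect_equal(imf$imf_mld, 16.25)
  expect_equal(unname(imf$imf_v["10"]), 75)
  expect_equal(unname(imf$imf_v["5"]), 100)
  expect_equal(unname(imf$imf_v["30"]), 25)
})

test_that("all ventilation in one voxel collapses the metrics onto its dose", {
  d <- c(4, 4, 4)
  lung <- array(TRUE, d)
  raw <- array(0, d); raw[2, 2, 2] <- 3
  dv <- array(runif(prod(d), 0, 50), d); dv[2, 2, 2] <- 17
  vm <- make_vent_map(raw, valid = lung)
  imf <- image_dose_function_metrics(image_volume(dv, unit = "Gy"), vm,
                                     lung, array(FALSE, d))
  expect_equal(imf$imf_mld, 17)
  expect_equal(unname(imf$imf_v), c(100, 100, 0, 0))
})

test_that("imf metrics equal unweighted lung metrics under uniform ventilation", {
  set.seed(16)
  fx <- dose_fixture()
  lung <- fx$masks$lung_L | fx$masks$lung_R
  dv <- array(runif(prod(fx$d), 0, 45), fx$d)
  raw <- array(NA_real_, fx$d); raw[lung] <- 0.37
  vm <- make_vent_map(raw, valid = lung)
  imf <- image_dose_function_metrics(image_volume(dv, unit = "Gy"), vm,
                                     fx$masks$lung_L, fx$masks$lung_R)
  lung_d <- dv[lung]
  expect_equal(imf$imf_mld, mean(lung_d), tolerance = 1e-12)
  for (x in c(5, 10, 20, 30))
    expect_equal(unname(imf$imf_v[as.character(x)]),
                 mean(lung_d >= x) * 100, tolerance = 1e-12)
})

test_that("imf metrics are invariant to positive rescaling of the weights", {
  set.seed(18)
  fx <- dose_fixture()
  lung <- fx$masks$lung_L | fx$masks$lung_R
  dv <- array(runif(prod(fx$d), 0, 45), fx$d)
  raw <- array(NA_real_, fx$d); raw[lung] <- rgamma(sum(lung), 2, 4)
  dose <- image_volume(dv, unit = "Gy")
  i1 <- image_dose_function_metrics(dose, make_vent_map(raw, valid = lung),
                                    fx$masks$lung_L, fx$masks$lung_R)
  i2 <- image_dose_function_metrics(dose,
                                    make_vent_map(raw * 73.2, valid = lung),
                                    fx$masks$lung_L, fx$masks$lung_R)
  expect_equal(i1$imf_mld, i2$imf_mld, tolerance = 1e-12)
  expect_equal(i1$imf_v, i2$imf_v, tolerance = 1e-12)
})

test_that("fVx curves are nonincreasing, start at 100, and bound imf_mld", {
  set.seed(19)
  fx <- dose_fixture()
  lung <- fx$masks$lung_L | fx$masks$lung_R
  dv <- array(runif(prod(fx$d), 0, 60), fx$d)
  raw <- array(NA_real_, fx$d); raw[lung] <- rgamma(sum(lung), 2, 4)
  vm <- make_vent_map(raw, valid = lung)
  imf <- image_dose_function_metrics(image_volume(dv, unit = "Gy"), vm,
                                     fx$masks$lung_L, fx$masks$lung_R,
                                     levels = c(0, 5, 10, 20, 30))
  expect_equal(unname(imf$imf_v["0"]), 100)
  expect_true(all(diff(imf$imf_v) <= 1e-12))
  expect_true(all(diff(imf$dfh$function_pct) <= 1e-12))
  lung_d <- dv[lung]
  expect_gte(imf$imf_mld, min(lung_d))
  expect_lte(imf$imf_mld, max(lung_d))
})

test_that("plan comparison handles identical pairs with the zero-variance convention", {
  fx <- dose_fixture()
  dv <- array(runif(prod(fx$d), 0, 50), fx$d)
  dose <- image_volume(dv, unit = "Gy")
  s <- dose_volume_metrics(dose, fx$masks, 60)
  cmp <- compare_plans(list(s, s, s), list(s, s, s))
  tab <- cmp$table
  expect_true(all(tab$mean_diff[is.finite(tab$mean_diff)] == 0))
  expect_true(all(tab$p_value[is.finite(tab$p_value)] == 1))
  expect_error(compare_plans(list(s), list(s, s)), "paired")
  expect_error(compare_plans(list(s), list(s)), "at least 2")
})

test_that("paired t-test recovers a known simulated shift", {
  set.seed(20)
  fx <- dose_fixture()
  base <- array(runif(prod(fx$d), 5, 40), fx$d)
  n <- 25
  delta <- rnorm(n, -2.8, 2)
  clin <- list(); fun <- list()
  for (i in seq_len(n)) {
    jitter <- array(rnorm(prod(fx$d), 0, 0.01), fx$d)
    dc <- image_volume(base + jitter, unit = "Gy")
    df <- image_volume(pmax(base + jitter + delta[i], 0), unit = "Gy")
    clin[[i]] <- dose_volume_metrics(dc, fx$masks, 60,
                                     exclude_gtv_from_lung = FALSE)
    fun[[i]] <- dose_volume_metrics(df, fx$masks, 60,
                                    exclude_gtv_from_lung = FALSE)
  }
  tab <- compare_plans(clin, fun)$table
  row <- tab[tab$metric == "mld", ]
  expect_lt(row$p_value, 0.01)
  expect_equal(row$mean_diff, mean(delta), tolerance = 0.05)
  expect_lt(abs(row$mean_diff - (-2.8)), 2 * 2 / sqrt(n) + 0.1)
})
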