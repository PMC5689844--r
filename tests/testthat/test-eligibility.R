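test_that("equal-height slabs split a 90-slice lung into 30/30/30", {
  d <- c(6, 6, 96)
  left <- array(FALSE, d); left[2:3, 2:5, 4:93] <- TRUE    # 90 slices
  right <- array(FALSE, d); right[4:5, 2:5, 4:93] <- TRUE
  gtv <- array(FALSE, d); gtv[2, 3, 10] <- TRUE
  part <- partition_thirds(left, right, gtv)
  counts <- sapply(1:3, function(t) sum(part$labels == t))
  expect_equal(counts, rep(sum(left) / 3, 3))
})

test_that("tumor-third adjacency follows the superior/inferior/contralateral rule", {
  # enumeration of the rule for all six thirds
  expect_equal(ventavoid:::third_neighbours(2), c(1, 3, 5))
  expect_equal(ventavoid:::third_neighbours(1), c(2, 4))   # no superior member
  expect_equal(ventavoid:::third_neighbours(3), c(2, 6))
  expect_equal(ventavoid:::third_neighbours(5), c(2, 4, 6))
  expect_equal(ventavoid:::third_neighbours(4), c(1, 5))
  expect_equal(ventavoid:::third_neighbours(6), c(3, 5))

  lungs <- cuboid_lungs()
  gtv <- array(FALSE, lungs$dim); gtv[3, 5, 7] <- TRUE     # left middle
  part <- partition_thirds(lungs$left, lungs$right, gtv)
  expect_equal(part$tumor_third, 2L)
  expect_equal(part$adjacency, c(1, 3, 5))
  expect_equal(part$ipsilateral, "left")

  gtv2 <- array(FALSE, lungs$dim); gtv2[9, 5, 12] <- TRUE  # right upper
  part2 <- partition_thirds(lungs$left, lungs$right, gtv2)
  expect_equal(part2$tumor_third, 4L)
  expect_equal(length(part2$adjacency), 2L)
})

test_that("a GTV centroid outside the lungs falls back to the nearest lung voxel", {
  lungs <- cuboid_lungs()
  gtv <- array(FALSE, lungs$dim); gtv[1, 1, 13] <- TRUE
  expect_warning(part <- partition_thirds(lungs$left, lungs$right, gtv),
                 "nearest")
  expect_true(part$tumor_third %in% 1:6)
})

test_that("percent ventilation by third: conservation, uniformity, concentration", {
  lungs <- cuboid_lungs()
  lung <- lungs$left | lungs$right
  gtv <- array(FALSE, lungs$dim); gtv[3, 5, 7] <- TRUE
  part <- partition_thirds(lungs$left, lungs$right, gtv)

  raw <- array(NA_real_, lungs$dim); raw[lung] <- 0.4
  vm <- make_vent_map(raw, valid = lung)
  pct <- percent_ventilation_by_third(vm, part)
  expect_equal(sum(pct), 100, tolerance = 1e-9)
  expect_equal(unname(pct), rep(100 / 6, 6), tolerance = 1e-9)

  raw2 <- array(NA_real_, lungs$dim); raw2[lung] <- 0
  raw2[part$labels == 5] <- 0.7
  vm2 <- make_vent_map(raw2, valid = lung)
  pct2 <- percent_ventilation_by_third(vm2, part)
  expect_equal(unname(pct2[5]), 100)
  expect_equal(sum(pct2[-5]), 0)

  # negative voxels are floored, never subtract mass
  raw3 <- raw; raw3[part$labels == 1] <- -0.2
  pct3 <- percent_ventilation_by_third(make_vent_map(raw3, valid = lung), part)
  expect_equal(unname(pct3[1]), 0)
  expect_equal(sum(pct3), 100, tolerance = 1e-9)
})

test_that("percentages sum to 100 on random phantoms", {
  for (s in 1:8) {
    case <- generate_phantom(small_phantom_spec(seed = s, noise_sd = 10))
    scr <- ventavoid:::screen_patient(case, NA_integer_)
    expect_equal(sum(scr$metrics$pct_by_third), 100, tolerance = 1e-6)
  }
})

test_that("heterogeneity metrics follow their definitions on controlled maps", {
  lungs <- cuboid_lungs()
  lung <- lungs$left | lungs$right
  gtv <- array(FALSE, lungs$dim); gtv[3, 5, 7] <- TRUE     # left middle
  part <- partition_thirds(lungs$left, lungs$right, gtv)

  raw <- array(NA_real_, lungs$dim); raw[lung] <- 0.4
  m <- compute_heterogeneity_metrics(make_vent_map(raw, valid = lung), part)
  expect_equal(m$vtt, 100 / 6, tolerance = 1e-9)
  expect_equal(m$vta, 100 / 6, tolerance = 1e-9)
  expect_equal(m$ic, 1, tolerance = 1e-9)   # equal-volume lungs
  expect_equal(m$cov, 0, tolerance = 1e-12)

  # defect exactly in the tumor third -> vta attained there, vta = vtt
  raw2 <- raw; raw2[part$labels == 2] <- 0.05
  m2 <- compute_heterogeneity_metrics(make_vent_map(raw2, valid = lung), part)
  expect_equal(m2$vta, m2$vtt, tolerance = 1e-12)
  expect_lt(m2$vtt, 100 / 6)
})

test_that("vta is the min over tumor and adjacent thirds only", {
  # worked 6-tuple: thirds (20, 15, 15, 20, 18, 12), tumor third 2,
  # adjacency {1, 3, 5}: label 6 excluded, so vta = min(15, 20, 15, 18) = 15
  lungs <- cuboid_lungs()
  lung <- lungs$left | lungs$right
  gtv <- array(FALSE, lungs$dim); gtv[3, 5, 7] <- TRUE
  part <- partition_thirds(lungs$left, lungs$right, gtv)
  shares <- c(20, 15, 15, 20, 18, 12)
  raw <- array(NA_real_, lungs$dim)
  for (t in 1:6) {
    n_t <- sum(part$labels == t)
    raw[part$labels == t] <- shares[t] / n_t
  }
  m <- compute_heterogeneity_metrics(make_vent_map(raw, valid = lung), part)
  expect_equal(unname(m$pct_by_third), shares, tolerance = 1e-9)
  expect_equal(m$vta, 15, tolerance = 1e-9)
  expect_equal(m$vtt, 15, tolerance = 1e-9)
})

test_that("vta never exceeds vtt", {
  set.seed(31)
  lungs <- cuboid_lungs()
  lung <- lungs$left | lungs$right
  for (i in 1:20) {
    gidx <- sample(which(lung), 1)
    gtv <- array(FALSE, lungs$dim); gtv[gidx] <- TRUE
    part <- partition_thirds(lungs$left, lungs$right, gtv)
    raw <- array(NA_real_, lungs$dim)
    raw[lung] <- rgamma(sum(lung), 2, 5)
    m <- compute_heterogeneity_metrics(make_vent_map(raw, valid = lung), part)
    expect_lte(m$vta, m$vtt + 1e-12)
  }
})

test_that("AUC equals brute-force all-pairs concordance", {
  set.seed(17)
  for (i in 1:50) {
    n <- sample(6:50, 1)
    scores <- round(rnorm(n), sample(0:2, 1))  # rounding induces ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    r <- roc_analysis(scores, labels)
    expect_equal(r$auc, auc_pairs(scores, labels), tolerance = 1e-12)
  }
})

test_that("perfect separation gives AUC 1 and a Youden threshold between classes", {
  r <- roc_analysis(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(r$auc, 1)
  expect_gt(r$threshold, 2)
  expect_lte(r$threshold, 3)
  expect_equal(r$youden, 1)

  set.seed(8)
  sep <- c(rnorm(20, -3), rnorm(20, 3))
  expect_equal(roc_analysis(sep, rep(c(0, 1), each = 20))$auc, 1)
})

test_that("AUC under the null is near one half", {
  set.seed(99)
  scores <- rnorm(1000)
  labels <- rbinom(1000, 1, 0.5)
  r <- roc_analysis(scores, labels)
  expect_gt(r$auc, 0.45)
  expect_lt(r$auc, 0.55)
})

test_that("roc_analysis honours the direction argument and rejects degenerate input", {
  set.seed(12)
  x <- c(rnorm(30, 0), rnorm(30, 2))
  lab <- rep(c(0, 1), each = 30)
  r_gt <- roc_analysis(x, lab, direction = ">")
  r_lt <- roc_analysis(-x, lab, direction = "<")
  expect_equal(r_lt$auc, r_gt$auc, tolerance = 1e-12)
  expect_equal(r_lt$threshold, -r_gt$threshold, tolerance = 1e-12)
  expect_error(roc_analysis(1:5, rep(1, 5)), "both classes")
})

test_that("logistic slope direction and significance track separation", {
  set.seed(13)
  x <- c(rnorm(40, 0), rnorm(40, 1.5))
  lab <- rep(c(0, 1), each = 40)
  r <- roc_analysis(x, lab)
  expect_gt(r$logistic$slope, 0)
  expect_lt(r$logistic$p_value, 0.01)
})

test_that("eligibility rule applies the cutoff and the observer label", {
  m <- structure(list(vta = 5, defect_label = NA_integer_),
                 class = "het_metrics")
  expect_true(assess_eligibility(m, 15)$eligible)
  m$vta <- 16.7
  expect_false(assess_eligibility(m, 15)$eligible)
  m$defect_label <- 1L
  a <- assess_eligibility(m, 15)
  expect_true(a$eligible)
  expect_match(a$reason, "observer")
  expect_false(assess_eligibility(m, 15, use_label = FALSE)$eligible)
})
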