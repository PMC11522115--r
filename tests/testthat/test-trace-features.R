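test_that("freeze AUC integrates the sub-zero area exactly", {
  expect_equal(freeze_auc(trace_triangle()), 2400)           # 1/2 * 120 * 40
  expect_equal(freeze_auc(trace_piecewise()), 200 + 4000 + 400)
  warm <- data.frame(time_s = 0:10, temp_c = rep(5, 11))
  expect_warning(a <- freeze_auc(warm), "never falls below")
  expect_equal(a, 0)
})

test_that("freeze magnitude is the AUC per second below zero", {
  expect_equal(freeze_magnitude(trace_triangle()), 2400 / 120)
  expect_equal(freeze_magnitude(trace_piecewise()), 4600 / 130)
  # constant sub-zero trace: magnitude equals |temperature|
  flat <- data.frame(time_s = c(0, 57), temp_c = c(-38, -38))
  expect_equal(freeze_magnitude(flat), 38)
  warm <- data.frame(time_s = 0:5, temp_c = rep(2, 6))
  expect_warning(m <- freeze_magnitude(warm), "undefined")
  expect_true(is.na(m))
})

test_that("temperature_at interpolates linearly and never extrapolates", {
  tr <- data.frame(time_s = c(0, 10), temp_c = c(0, -20))
  expect_equal(temperature_at(tr, 5), -10)
  expect_equal(temperature_at(tr, 10), -20)
  expect_warning(out <- temperature_at(tr, 11), "outside")
  expect_true(is.na(out))
  # dense exponential-cooling trace matches the generating closed form
  tau <- 20; nadir <- -47; amp <- 20 - nadir
  tt <- seq(0, 120, by = 0.25)
  tr2 <- data.frame(time_s = tt, temp_c = nadir + amp * exp(-tt / tau))
  expect_equal(temperature_at(tr2, 30), nadir + amp * exp(-30 / tau),
               tolerance = 1e-4)
})

test_that("warming times are crossing times from the nadir, with truncation", {
  v <- trace_v()
  w0 <- warming_time_to(v, 0)
  w20 <- warming_time_to(v, 20)
  expect_equal(as.numeric(w0), 40)
  expect_equal(as.numeric(w20), 60)
  expect_false(attr(w20, "truncated"))
  # truncated at t=150 (temp +10): threshold 20 never reached
  v_cut <- trace_v(end_time = 150)
  w <- warming_time_to(v_cut, 20, deflation_truncated = TRUE)
  expect_equal(as.numeric(w), 50)
  expect_true(attr(w, "truncated"))
  expect_warning(warming_time_to(v_cut, 20), "never reached")
  expect_error(warming_time_to(v, -45), "below the trace nadir")
})

test_that("warming times are monotone in the threshold over random traces", {
  set.seed(101)
  for (i in 1:200) {
    tr <- generate_trace(tti_s = runif(1, 20, 90),
                         nadir_temp_c = runif(1, -55, -35),
                         noise_sd = 0.3)
    f <- extract_features(tr)
    w <- c(f$warming_time_to_0, f$warming_time_to_15, f$warming_time_to_20)
    expect_false(is.unsorted(w))
  }
})

test_that("features are invariant to grid refinement and time shifts", {
  tr <- trace_piecewise()
  # refine: insert midpoints of every segment (still the same polyline)
  refine <- function(d) {
    mid_t <- (head(d$time_s, -1) + tail(d$time_s, -1)) / 2
    mid_y <- approx(d$time_s, d$temp_c, xout = mid_t)$y
    out <- rbind(d, data.frame(time_s = mid_t, temp_c = mid_y))
    out[order(out$time_s), ]
  }
  fine <- refine(refine(tr))
  expect_equal(freeze_auc(fine), freeze_auc(tr))
  expect_equal(freeze_magnitude(fine), freeze_magnitude(tr))
  shifted <- transform(tr, time_s = time_s + 1234)
  expect_equal(freeze_auc(shifted), freeze_auc(tr))
  expect_equal(freeze_magnitude(shifted), freeze_magnitude(tr))
  expect_equal(as.numeric(warming_time_to(shifted, 0)),
               as.numeric(warming_time_to(tr, 0)))
})

test_that("freeze magnitude stays within [0, |nadir|] for arbitrary traces", {
  set.seed(202)
  for (i in 1:100) {
    n <- sample(5:60, 1)
    tr <- data.frame(time_s = cumsum(runif(n, 0.5, 3)),
                     temp_c = runif(n, -60, 25))
    if (all(tr$temp_c >= 0)) next
    m <- suppressWarnings(freeze_magnitude(tr))
    expect_gte(m, 0)
    expect_lte(m, abs(min(tr$temp_c)))
  }
})

test_that("extract_features composes the individual features", {
  f <- extract_features(trace_triangle())
  expect_equal(f$nadir_temp_c, -40)
  expect_equal(f$freeze_auc, 2400)
  expect_equal(f$freeze_magnitude, 20)
  expect_true(is.na(f$temp_at_tti))      # no TTI annotation supplied
  f2 <- extract_features(trace_triangle(), tti_s = 50)
  expect_equal(f2$temp_at_tti, -20)
  # invalid traces are rejected
  expect_error(extract_features(data.frame(time_s = 1, temp_c = -5)),
               "at least 2 samples")
  expect_error(extract_features(data.frame(time_s = c(1, 1), temp_c = c(0, -5))),
               "strictly increasing")
})

test_that("manifest-driven batch extraction returns one row per application", {
  dir <- withr::local_tempdir()
  t1 <- generate_trace(tti_s = 35, nadir_temp_c = -45)
  t2 <- generate_trace(tti_s = 60, nadir_temp_c = -50,
                       deflation_truncated = TRUE)
  readr::write_csv(t1, file.path(dir, "app1.csv"))
  readr::write_csv(t2, file.path(dir, "app2.csv"))
  manifest <- tibble::tibble(trace_file = c("app1.csv", "app2.csv"),
                             tti_s = c(35, 60),
                             deflation_truncated = c(FALSE, TRUE))
  feats <- extract_features_from_manifest(manifest, dir = dir)
  expect_equal(nrow(feats), 2)
  expect_false(feats$warming_truncated[1])
  expect_true(feats$warming_truncated[2])
  expect_equal(feats$nadir_temp_c[2], -50, tolerance = 0.2)
})
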