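# build a tiny in-memory run directly from scan arrays
manual_run <- function(rt, mz, intensity) {
  mampep:::new_run(tibble::tibble(rt_min = rt, mz = mz, intensity = intensity),
                   lab = 1, replicate = 1)
}

gaussian_run <- function(apex_rt = 10, mz = 500, height = 1e5, sigma = 0.25,
                         dt = 2 / 60, t_max = 20, noise_cv = 0, seed = 1) {
  t <- seq(0, t_max, by = dt)
  y <- height * exp(-(t - apex_rt)^2 / (2 * sigma^2))
  if (noise_cv > 0) {
    set.seed(seed)
    sl <- sqrt(log(1 + noise_cv^2))
    y <- y * stats::rlnorm(length(y), -sl^2 / 2, sl)
  }
  manual_run(t, purrr::map(y, ~mz), purrr::map(y, ~.x))
}

test_that("XIC tolerance boundaries behave exactly at the ppm cutoff", {
  mz0 <- 500
  off6 <- mz0 * (1 + 6e-6)
  run <- manual_run(c(1, 2), list(mz0, off6), list(10, 20))
  x5 <- extract_xic(run, mz0, ppm = 5)
  expect_equal(x5$intensity, c(10, 0))
  x7 <- extract_xic(run, mz0, ppm = 7)
  expect_equal(x7$intensity, c(10, 20))
  # co-tolerant centroids in one scan are summed; matches a per-scan loop
  run2 <- manual_run(1:3, list(c(499.999, 500.001), 500, 600),
                     list(c(5, 7), 11, 13))
  x <- extract_xic(run2, 500, ppm = 5)
  brute <- vapply(seq_len(3), function(i) {
    m <- run2$scans$mz[[i]]; it <- run2$scans$intensity[[i]]
    sum(it[abs(m - 500) / 500 * 1e6 <= 5])
  }, numeric(1))
  expect_equal(x$intensity, brute)
})

test_that("a clean Gaussian peak is integrated to its analytic area", {
  h <- 2e5; sigma <- 0.25
  run <- gaussian_run(apex_rt = 10, height = h, sigma = sigma)
  pk <- detect_peak(extract_xic(run, 500), expected_rt = 10, window = 1.5)
  expect_true(pk$found)
  expect_lt(abs(pk$apex_rt - 10), 2 / 60 + 1e-9)
  analytic <- h * sigma * 60 * sqrt(2 * pi)
  expect_lt(abs(pk$area - analytic) / analytic, 0.01)
})

test_that("flat and empty traces yield not-found, never an error", {
  run <- manual_run(seq(0, 5, by = 0.05), purrr::map(1:101, ~numeric(0)),
                    purrr::map(1:101, ~numeric(0)))
  pk <- detect_peak(extract_xic(run, 500), expected_rt = 2, window = 1)
  expect_false(pk$found)
  expect_equal(pk$area, 0)
})

test_that("the candidate nearest the expected RT wins deterministically", {
  t <- seq(0, 10, by = 2 / 60)
  y <- 1e5 * exp(-(t - 4.5)^2 / (2 * 0.04)) + 1e5 * exp(-(t - 5.5)^2 / (2 * 0.04))
  run <- manual_run(t, purrr::map(y, ~500), purrr::map(y, ~.x))
  pk <- detect_peak(extract_xic(run, 500), expected_rt = 4.8, window = 1)
  expect_lt(abs(pk$apex_rt - 4.5), 0.1)
  pk2 <- detect_peak(extract_xic(run, 500), expected_rt = 5.2, window = 1)
  expect_lt(abs(pk2$apex_rt - 5.5), 0.1)
})

test_that("component areas are linear in intensity and monotone in tolerance", {
  tr <- make_ground_truth(table = tibble::tibble(
    attribute = "ox", mode = "pairwise", site_label = "s",
    sequence = "DTLMISR", modification = "oxidation", true_fraction = 0.1))
  comp <- build_component_table(truth = tr)
  sc <- scenario_config(labs = 1, replicates = 1, noise_cv = 0.05, seed = 6)
  run <- simulate_run(tr, comp, sc)
  run2 <- run
  run2$scans$intensity <- purrr::map(run$scans$intensity, ~ .x * 2)
  q1 <- quantify_components(run, comp) |> component_areas()
  q2 <- quantify_components(run2, comp) |> component_areas()
  expect_equal(q2$area, 2 * q1$area, tolerance = 1e-12)
  q7 <- quantify_components(run, comp, ppm = 7) |> component_areas()
  expect_true(all(q7$area >= q1$area - 1e-9))
})

test_that("summed component areas match a brute-force windowed integrator", {
  tr <- make_ground_truth(table = tibble::tibble(
    attribute = c("a", "b"), mode = "pairwise", site_label = c("a", "b"),
    sequence = c("DTLMISR", "EEQYNSTYR"),
    modification = c("oxidation", "deamidation"), true_fraction = c(0.2, 0.1)))
  comp <- build_component_table(truth = tr)
  sc <- scenario_config(labs = 1, replicates = 1, noise_cv = 0, seed = 8)
  run <- simulate_run(tr, comp, sc)
  q <- quantify_components(run, comp, isotope_correct = FALSE)
  for (i in seq_len(nrow(q))) {
    cidx <- match(q$component_id[i], comp$component_id)
    mz0 <- mz_for_charge(comp$mono_mass[cidx], q$charge[i])
    tol <- mz0 * 5 / 1e6
    # brute force: loop scans, window sum, trapezoid between detected bounds
    rts <- run$scans$rt_min
    vals <- vapply(seq_along(rts), function(s) {
      m <- run$scans$mz[[s]]; it <- run$scans$intensity[[s]]
      sum(it[abs(m - mz0) <= tol])
    }, numeric(1))
    pk <- detect_peak(tibble::tibble(rt_min = rts, intensity = vals),
                      comp$expected_rt_min[cidx],
                      window = comp$rt_window_min[cidx])
    expect_equal(q$area[i], pk$area, tolerance = 1e-9)
  }
})

test_that("retention-time shift estimation recovers the simulated drift", {
  tr <- make_ground_truth("nist_table1", lab = "ireland",
                          attributes = c("HC M255+Oxid", "HC Q1+Gln->PyroGlu",
                                         "HC N318+Succ", "HC K450 Lys loss"))
  comp <- build_component_table(truth = tr)
  sc <- scenario_config(labs = 2, replicates = 1, noise_cv = 0.02,
                        rt_drift_min = 1.9, seed = 10)
  run_drift <- simulate_run(tr, comp, sc, lab = 2)
  expect_lt(abs(estimate_rt_shift(run_drift, comp) - 1.9), 0.05)
  run_zero <- simulate_run(tr, comp, sc, lab = 1)
  expect_lt(abs(estimate_rt_shift(run_zero, comp)), sc$scan_interval_s / 60 + 1e-9)
  # all landmarks missing: an empty run cannot anchor the shift
  empty <- manual_run(seq(0, 105, by = 0.1),
                      purrr::map(seq(0, 105, by = 0.1), ~numeric(0)),
                      purrr::map(seq(0, 105, by = 0.1), ~numeric(0)))
  expect_error(estimate_rt_shift(empty, comp), "manual")
})
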