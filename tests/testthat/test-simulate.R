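simple_truth <- function(frac = 0.12, loading = 1e6) {
  make_ground_truth(table = tibble::tibble(
    attribute = "LC N30+deamidation", mode = "pairwise", site_label = "LC N30",
    sequence = "ASQDINNYLNWYQQKPGK", modification = "deamidation",
    true_fraction = frac), loading = loading)
}

test_that("noiseless XIC area is proportional to loading within 0.1%", {
  tr1 <- simple_truth(loading = 1e6)
  tr2 <- simple_truth(loading = 3e6)
  comp <- build_component_table(truth = tr1)
  sc <- scenario_config(labs = 1, replicates = 1, noise_cv = 0, seed = 1)
  q1 <- quantify_components(simulate_run(tr1, comp, sc), comp) |> component_areas()
  q2 <- quantify_components(simulate_run(tr2, comp, sc), comp) |> component_areas()
  expect_true(all(q1$found), all(q2$found))
  expect_equal(q2$area / q1$area, rep(3, nrow(q1)), tolerance = 1e-3)
})

test_that("per-lab RT drift shifts every apex by the configured offset", {
  tr <- simple_truth()
  comp <- build_component_table(truth = tr)
  sc <- scenario_config(labs = 2, replicates = 1, noise_cv = 0,
                        rt_drift_min = 1.9, seed = 2)
  r1 <- simulate_run(tr, comp, sc, lab = 1)
  r2 <- simulate_run(tr, comp, sc, lab = 2)
  q1 <- quantify_components(r1, comp) |> component_areas()
  q2 <- quantify_components(r2, comp, rt_shift = 1.9) |> component_areas()
  expect_true(all(q1$found) && all(q2$found))
  d <- q2$apex_rt - q1$apex_rt
  expect_true(all(abs(d - 1.9) <= sc$scan_interval_s / 60 + 1e-9))
})

test_that("a 12% true fraction is recovered as 12.0% end to end (noiseless)", {
  tr <- simple_truth(0.12)
  comp <- build_component_table(truth = tr)
  sc <- scenario_config(labs = 1, replicates = 1, noise_cv = 0, seed = 3)
  q <- quantify_components(simulate_run(tr, comp, sc), comp) |> component_areas()
  ra <- relative_abundance(q, comp)
  expect_equal(ra$value, 12.0, tolerance = 1e-3)
})

test_that("glycoform site areas conserve the site loading (noiseless)", {
  tr <- make_ground_truth("nist_table1", lab = "ireland")
  comp <- build_component_table(truth = tr)
  comp <- comp[comp$role == "profile" & comp$missed_cleavages == 0 &
                 !comp$isobaric_group, ]
  sc <- scenario_config(labs = 1, replicates = 1, noise_cv = 0, seed = 4)
  run <- simulate_run(tr, comp, sc)
  q <- quantify_components(run, comp) |> component_areas()
  ab <- mampep:::component_abundances(tr, comp)
  # corrected areas are proportional to true abundances with one common factor
  ratio <- q$area[match(ab$component_id, q$component_id)] / ab$abundance
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-3)
})

test_that("identical truth, scenario and seed give byte-identical peak lists", {
  tr <- simple_truth()
  comp <- build_component_table(truth = tr)
  sc <- scenario_config(labs = 1, replicates = 2, noise_cv = 0.05, seed = 9)
  a <- simulate_run(tr, comp, sc, replicate = 2)
  b <- simulate_run(tr, comp, sc, replicate = 2)
  expect_identical(a$scans, b$scans)
  c <- simulate_run(tr, comp, sc, replicate = 1)
  expect_false(identical(a$scans, c$scans))
})

test_that("mzML round trip preserves scans and intensities", {
  tr <- simple_truth()
  comp <- build_component_table(truth = tr)
  sc <- scenario_config(labs = 1, replicates = 1, noise_cv = 0.02, seed = 5,
                        gradient_min = 30)
  run <- simulate_run(tr, comp, sc)
  path <- withr::local_tempfile(fileext = ".mzML")
  write_mzml(run, path)
  back <- read_mzml(path, lab = 1, replicate = 1)
  expect_equal(nrow(back$scans), nrow(run$scans))
  expect_equal(back$scans$rt_min, run$scans$rt_min, tolerance = 1e-9)
  i0 <- unlist(run$scans$intensity)
  i1 <- unlist(back$scans$intensity)
  expect_lt(max(abs(i1 - i0) / pmax(i0, 1e-12)), 1e-6)
})

test_that("degenerate runs are rejected, not written or silently read", {
  run0 <- mampep:::new_run(tibble::tibble(rt_min = numeric(),
                                          mz = list(), intensity = list()),
                           lab = 1, replicate = 1)
  expect_error(write_mzml(run0, withr::local_tempfile(fileext = ".mzML")),
               "no scans")
  expect_error(read_mzml(withr::local_tempfile(fileext = ".mzML")), "not found")
})
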