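#' Scenario configuration for the synthetic study generator
#'
#' Defines the acquisition and study-design conditions the generator
#' emulates: number of laboratories and replicate digests per laboratory
#' (the study design uses triplicates), the per-laboratory retention-time
#' drift (near-constant offsets of up to about 2 min between sites), the
#' multiplicative intensity noise CV, the 105-min gradient, the MS1 scan
#' interval and the acquired m/z range (200-2000).
#'
#' @param labs Number of laboratories.
#' @param replicates Replicate digests per laboratory.
#' @param rt_drift_min Either a single maximum drift (labs get evenly spaced
#'   offsets from 0 to this value) or a vector of per-lab offsets in minutes.
#' @param noise_cv Coefficient of variation of the multiplicative log-normal
#'   intensity noise applied to every sampled centroid.
#' @param gradient_min Gradient length in minutes.
#' @param scan_interval_s MS1 scan interval in seconds.
#' @param mz_range Acquired m/z range.
#' @param peak_sigma_min Gaussian elution peak sigma in minutes.
#' @param n_isotopes Isotopologue peaks simulated per form and charge.
#' @param seed Mandatory integer seed; every stochastic call derives its
#'   stream from it.
#' @return An object of class `mam_scenario`.
#' @export
scenario_config <- function(labs = 1, replicates = 3, rt_drift_min = 0,
                            noise_cv = 0, gradient_min = 105,
                            scan_interval_s = 2, mz_range = c(200, 2000),
                            peak_sigma_min = 0.25, n_isotopes = 4, seed) {
  stopifnot(labs >= 1, replicates >= 1, noise_cv >= 0, n_isotopes >= 3)
  if (missing(seed)) abort("a seed is mandatory for every stochastic call")
  drifts <- if (length(rt_drift_min) == labs) rt_drift_min
            else if (labs == 1) rt_drift_min[1] * 0
            else seq(0, rt_drift_min[1], length.out = labs)
  structure(list(labs = labs, replicates = replicates, rt_drift_min = drifts,
                 noise_cv = noise_cv, gradient_min = gradient_min,
                 scan_interval_s = scan_interval_s, mz_range = mz_range,
                 peak_sigma_min = peak_sigma_min, n_isotopes = n_isotopes,
                 seed = as.integer(seed)),
            class = "mam_scenario")
}

derive_seed <- function(seed, lab, replicate) {
  (abs(as.integer(seed)) %% 1000000L) * 1000L + lab * 37L + replicate
}

new_run <- function(scans, lab, replicate, sample_id = NA_character_,
                    timepoint = NA, source = "simulated") {
  stopifnot(all(diff(scans$rt_min) > 0))
  structure(list(scans = scans, lab = lab, replicate = replicate,
                 sample_id = sample_id, timepoint = timepoint, source = source),
            class = "mam_run")
}

#' @export
print.mam_run <- function(x, ...) {
  cat("<mam_run> ", nrow(x$scans), " MS1 scans, RT ",
      round(min(x$scans$rt_min), 2), "-", round(max(x$scans$rt_min), 2),
      " min, lab=", x$lab, " replicate=", x$replicate,
      " (", x$source, ")\n", sep = "")
  invisible(x)
}

#' Simulate one centroided MS1 run of a tryptic digest
#'
#' Places, for every component form and charge state, an isotope envelope at
#' the form's m/z values and a Gaussian elution profile (fixed sigma) at its
#' predicted retention time plus the laboratory's drift, samples it on the
#' scan grid, multiplies each sampled centroid by log-normal noise at the
#' configured CV, and assembles sorted centroid arrays per scan. Charge
#' weights are renormalised over the charges inside the acquired m/z range,
#' so the total XIC area of a form is proportional to its true abundance.
#'
#' @param truth `mam_truth` ground truth.
#' @param components Component table from [build_component_table()].
#' @param scenario `mam_scenario` configuration.
#' @param lab Laboratory index (1-based).
#' @param replicate Replicate index (1-based).
#' @param sample_id,timepoint Optional metadata carried on the run.
#' @return A `mam_run`: ordered MS1 scans (RT in minutes, sorted centroid
#'   m/z and intensity arrays) with lab/replicate/sample metadata.
#' @export
simulate_run <- function(truth, components, scenario, lab = 1, replicate = 1,
                         sample_id = NA_character_, timepoint = NA) {
  stopifnot(inherits(truth, "mam_truth"), inherits(scenario, "mam_scenario"))
  comp <- component_abundances(truth, components)
  drift <- scenario$rt_drift_min[lab]
  sigma <- scenario$peak_sigma_min
  t_grid <- seq(0, scenario$gradient_min, by = scenario$scan_interval_s / 60)
  nscan <- length(t_grid)

  # expand components x charges x isotopologues into (mz, rt_apex, amplitude)
  peaks <- purrr::map_dfr(seq_len(nrow(comp)), function(i) {
    zs <- parse_charges(comp$charges[i])[[1]]
    zs <- zs[mz_for_charge(comp$mono_mass[i], zs) >= scenario$mz_range[1] &
               mz_for_charge(comp$mono_mass[i], zs) <= scenario$mz_range[2]]
    if (length(zs) == 0) return(NULL)
    w <- rep(1 / length(zs), length(zs))
    env <- isotope_envelope(peptide_composition(comp$sequence[i], comp$modification[i]),
                            scenario$n_isotopes)
    purrr::map_dfr(seq_along(zs), function(k) {
      tibble(mz = mz_for_charge(comp$mono_mass[i] +
                                  (seq_along(env) - 1) * ISOTOPE_SPACING, zs[k]),
             amp = comp$abundance[i] * w[k] * env,
             rt = comp$expected_rt_min[i] + drift,
             component_id = comp$component_id[i], charge = zs[k])
    })
  })
  peaks <- peaks[peaks$mz >= scenario$mz_range[1] & peaks$mz <= scenario$mz_range[2], ]
  peaks <- peaks[order(peaks$component_id, peaks$charge, peaks$mz), ]

  # sample each peak on the scan grid within +/- 4 sigma of its apex
  set.seed(derive_seed(scenario$seed, lab, replicate))
  pieces <- vector("list", nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    lo <- max(1L, ceiling((peaks$rt[i] - 4 * sigma) / (scenario$scan_interval_s / 60)) + 1L)
    hi <- min(nscan, floor((peaks$rt[i] + 4 * sigma) / (scenario$scan_interval_s / 60)) + 1L)
    if (lo > hi) next
    idx <- lo:hi
    y <- peaks$amp[i] * exp(-((t_grid[idx] - peaks$rt[i])^2) / (2 * sigma^2))
    if (scenario$noise_cv > 0) {
      sl <- sqrt(log(1 + scenario$noise_cv^2))
      y <- y * stats::rlnorm(length(y), meanlog = -sl^2 / 2, sdlog = sl)
    }
    pieces[[i]] <- tibble(scan = idx, mz = peaks$mz[i], intensity = y)
  }
  cent <- bind_rows(pieces)
  cent <- cent[order(cent$scan, cent$mz), ]
  by_scan <- split(cent, factor(cent$scan, levels = seq_len(nscan)))
  scans <- tibble(
    rt_min = t_grid,
    mz = purrr::map(by_scan, "mz"),
    intensity = purrr::map(by_scan, "intensity")
  )
  new_run(scans, lab = lab, replicate = replicate, sample_id = sample_id,
          timepoint = timepoint)
}

#' Simulate a full multi-laboratory study
#'
#' Runs [simulate_run()] for every laboratory and replicate of the scenario.
#'
#' @inheritParams simulate_run
#' @return A list with `runs` (list of `mam_run`) and `metadata` (tibble with
#'   `run_id`, `lab`, `replicate`).
#' @export
simulate_study <- function(truth, components, scenario,
                           sample_id = NA_character_, timepoint = NA) {
  grid <- tidyr::expand_grid(lab = seq_len(scenario$labs),
                             replicate = seq_len(scenario$replicates))
  runs <- purrr::pmap(grid, function(lab, replicate) {
    simulate_run(truth, components, scenario, lab = lab, replicate = replicate,
                 sample_id = sample_id, timepoint = timepoint)
  })
  metadata <- grid |> mutate(run_id = paste0("lab", .data$lab, "_rep", .data$replicate),
                             .before = 1)
  list(runs = runs, metadata = metadata)
}
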