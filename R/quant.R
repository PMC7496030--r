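# Flatten a run's centroids into parallel vectors sorted by m/z, cached on
# the run object's environment-free list via attribute.
flatten_run <- function(run) {
  idx <- attr(run, "flat_index")
  if (!is.null(idx)) return(idx)
  scan <- rep.int(seq_len(nrow(run$scans)),
                  vapply(run$scans$mz, length, integer(1)))
  mz <- unlist(run$scans$mz, use.names = FALSE)
  it <- unlist(run$scans$intensity, use.names = FALSE)
  o <- order(mz)
  list(scan = scan[o], mz = mz[o], intensity = it[o], nscan = nrow(run$scans))
}

#' Extract an ion chromatogram at ppm tolerance
#'
#' Per MS1 scan, sums the intensities of all centroids whose m/z lies
#' within `ppm` parts per million of the target (tolerance computed on m/z,
#' not neutral mass); scans with no matching centroid contribute zero.
#'
#' @param run A `mam_run`.
#' @param mz Target m/z.
#' @param ppm Mass tolerance in ppm (the monitoring method uses 5).
#' @return An `xic_trace`: tibble with columns `rt_min`, `intensity`, and
#'   attributes `mz` and `ppm`.
#' @export
extract_xic <- function(run, mz, ppm = 5) {
  stopifnot(ppm > 0)
  flat <- flatten_run(run)
  tol <- mz * ppm / 1e6
  lo <- findInterval(mz - tol, flat$mz, left.open = TRUE) + 1L
  hi <- findInterval(mz + tol, flat$mz)
  intensity <- numeric(flat$nscan)
  if (hi >= lo) {
    sel <- lo:hi
    agg <- rowsum(flat$intensity[sel], group = flat$scan[sel])
    intensity[as.integer(rownames(agg))] <- agg[, 1]
  }
  structure(tibble(rt_min = run$scans$rt_min, intensity = intensity),
            mz = mz, ppm = ppm, class = c("xic_trace", "tbl_df", "tbl", "data.frame"))
}

moving_mean <- function(x, width = 3) {
  if (length(x) < width) return(x)
  k <- rep(1 / width, width)
  y <- stats::filter(x, k, sides = 2)
  y[is.na(y)] <- x[is.na(y)]
  as.numeric(y)
}

#' Detect and integrate the chromatographic peak in an RT window
#'
#' A documented stand-in for the vendor's (unpublished) MS peak detection:
#' within `expected_rt` +/- `window`, the trace is smoothed with a fixed
#' 3-point moving mean; the baseline is the median of the lowest decile of
#' the windowed trace and the noise level a robust high-frequency estimate
#' (median absolute successive difference scaled to a white-noise sigma);
#' candidate apexes are local maxima exceeding baseline + k * noise; the
#' chosen apex is the candidate closest to the expected retention time
#' (ties break to the larger height); peak bounds extend from the apex to
#' the first significant valley (a rise above the running minimum exceeding
#' `valley_frac` of the apex height, so noise wiggles do not truncate the
#' peak) or baseline crossing, and the area is the trapezoidal integral of
#' the raw trace between the bounds, in intensity * seconds.
#'
#' The baseline, the noise level and the bound extension use a wider
#' context region (`baseline_window`, at least 1 min half-width) than the
#' candidate search: a window narrow enough to isolate an isobaric pair is
#' mostly peak, and a baseline estimated inside it would sit far above
#' zero and mask the peak itself.
#'
#' @param trace An `xic_trace` from [extract_xic()].
#' @param expected_rt Expected apex retention time (minutes).
#' @param window Search window half-width (minutes).
#' @param k Signal-to-noise multiplier for candidate apexes.
#' @param smooth_width Moving-mean width in scans.
#' @param valley_frac Fraction of the apex height a rise must exceed to
#'   count as a bounding valley.
#' @param baseline_window Half-width of the context region used for
#'   baseline/noise estimation and bound extension; defaults to
#'   `max(window, 1)` minutes.
#' @return A one-row tibble with `found`, `apex_rt`, `left_rt`, `right_rt`,
#'   `area`, `height`, `snr`; `found = FALSE` (with zero area) when no
#'   candidate passes — a value, not an error.
#' @export
detect_peak <- function(trace, expected_rt, window = 1.5, k = 3, smooth_width = 3,
                        valley_frac = 0.05, baseline_window = NULL) {
  stopifnot(window > 0)
  baseline_window <- baseline_window %||% max(window, 1)
  not_found <- tibble(found = FALSE, apex_rt = NA_real_, left_rt = NA_real_,
                      right_rt = NA_real_, area = 0, height = NA_real_,
                      snr = NA_real_)
  sel <- which(trace$rt_min >= expected_rt - baseline_window &
                 trace$rt_min <= expected_rt + baseline_window)
  if (length(sel) < 3) return(not_found)
  t <- trace$rt_min[sel]
  y_raw <- trace$intensity[sel]
  y <- moving_mean(y_raw, smooth_width)
  low <- sort(y_raw)[seq_len(max(1L, floor(length(y_raw) / 10)))]
  baseline <- stats::median(low)
  # robust high-frequency noise: median absolute successive difference,
  # scaled to a white-noise sigma; unlike a whole-trace MAD it is not
  # inflated by a large genuine peak elsewhere in the context region
  noise <- stats::median(abs(diff(y_raw))) / (0.6745 * sqrt(2))
  thr <- baseline + k * noise
  n <- length(y)
  in_window <- abs(t - expected_rt) <= window
  is_max <- y > c(-Inf, y[-n]) & y >= c(y[-1], -Inf) & y > thr & y > baseline &
    in_window
  cand <- which(is_max)
  if (length(cand) == 0) return(not_found)
  d <- abs(t[cand] - expected_rt)
  best <- cand[order(d, -y[cand])][1]
  extend <- function(dir) {
    i <- best
    vmin <- y[best]
    bound <- best
    repeat {
      j <- i + dir
      if (j < 1 || j > n) break
      if (y[j] <= baseline) { if (y[j] < vmin) bound <- j; break }
      if (y[j] < vmin) { vmin <- y[j]; bound <- j }
      else if (y[j] - vmin > valley_frac * y[best]) break
      i <- j
    }
    bound
  }
  left <- extend(-1L)
  right <- extend(1L)
  # a candidate that does not rise meaningfully above both its bounds is a
  # shoulder on an unresolved neighbour (or a noise bump), not a peak
  prominence <- y[best] - max(y[left], y[right])
  if (prominence < valley_frac * (y[best] - baseline)) return(not_found)
  bounds <- left:right
  area <- sum(diff(t[bounds]) * 60 *
                (utils::head(y_raw[bounds], -1) + utils::tail(y_raw[bounds], -1)) / 2)
  tibble(found = TRUE, apex_rt = t[best], left_rt = t[left], right_rt = t[right],
         area = area, height = y_raw[best],
         snr = if (noise > 0) (y_raw[best] - baseline) / noise else Inf)
}

#' Quantify a component table against one run
#'
#' For every component and charge state, extracts the XIC at the form's
#' monoisotopic m/z (optionally summing the first isotopologues) and
#' integrates the peak at the expected retention time plus `rt_shift`.
#' Per-charge areas are summed per component; a component whose charges all
#' miss is reported with `found = FALSE` and zero area, never dropped.
#'
#' @param run A `mam_run`.
#' @param components Component table from [build_component_table()].
#' @param ppm XIC tolerance in ppm.
#' @param rt_shift Single affine retention-time shift in minutes (e.g. from
#'   [estimate_rt_shift()]).
#' Areas of different peptide forms are only comparable if each is scaled
#' to its full isotope envelope: the monoisotopic peak carries ~53% of the
#' signal of a small tryptic peptide but only ~26% of its glycoforms. With
#' `isotope_correct = TRUE` (default) every area is divided by the
#' theoretical fraction of the envelope the XIC targeted, so corrected
#' areas estimate total form abundance regardless of composition.
#'
#' @param sum_isotopes If `TRUE`, adds XICs of `n_isotopes` isotopologue
#'   peaks per charge instead of the monoisotopic peak only (off by
#'   default; documented sensitivity flag).
#' @param n_isotopes Isotopologue peaks of the theoretical envelope (summed
#'   when `sum_isotopes` is on; always used for the envelope-fraction
#'   correction).
#' @param isotope_correct Divide each area by the targeted fraction of the
#'   component's theoretical isotope envelope.
#' @return A tibble with one row per component x charge: `component_id`,
#'   `charge`, `area`, `apex_rt`, `found`, plus run metadata columns `lab`
#'   and `replicate`.
#' @export
quantify_components <- function(run, components, ppm = 5, rt_shift = 0,
                                sum_isotopes = FALSE, n_isotopes = 4,
                                isotope_correct = TRUE) {
  out <- purrr::map_dfr(seq_len(nrow(components)), function(i) {
    zs <- parse_charges(components$charges[i])[[1]]
    env <- isotope_envelope(
      peptide_composition(components$sequence[i], components$modification[i]),
      n_isotopes)
    frac <- if (!isotope_correct) 1 else if (sum_isotopes) sum(env) else env[1]
    purrr::map_dfr(zs, function(z) {
      mzs <- mz_for_charge(components$mono_mass[i], z)
      if (sum_isotopes) {
        mzs <- mz_for_charge(components$mono_mass[i] +
                               (0:(n_isotopes - 1)) * ISOTOPE_SPACING, z)
      }
      trace <- extract_xic(run, mzs[1], ppm)
      if (length(mzs) > 1) {
        for (m in mzs[-1]) trace$intensity <- trace$intensity +
            extract_xic(run, m, ppm)$intensity
      }
      pk <- detect_peak(trace, components$expected_rt_min[i] + rt_shift,
                        window = components$rt_window_min[i])
      tibble(component_id = components$component_id[i], charge = z,
             area = pk$area / frac, apex_rt = pk$apex_rt, found = pk$found)
    })
  })
  out$lab <- run$lab
  out$replicate <- run$replicate
  out
}

#' Sum per-charge areas into per-component areas
#'
#' @param quant Output of [quantify_components()] (possibly several runs
#'   bound together).
#' @return A tibble per run x component with `area` (sum over charges),
#'   `found` (any charge found), `apex_rt` (area-weighted mean).
#' @export
component_areas <- function(quant) {
  quant |>
    group_by(.data$lab, .data$replicate, .data$component_id) |>
    summarise(
      apex_rt = if (any(.data$found)) sum(.data$apex_rt[.data$found] * .data$area[.data$found]) /
        sum(.data$area[.data$found]) else NA_real_,
      area = sum(.data$area),
      found = any(.data$found),
      .groups = "drop"
    )
}

#' Estimate the per-run retention-time shift from landmark components
#'
#' The inter-laboratory drift is a near-constant offset, so a single affine
#' shift is estimated as the median difference between observed and
#' expected apex retention times over landmark components searched with
#' wide windows.
#'
#' @param run A `mam_run`.
#' @param components Component table; landmarks are its non-isobaric,
#'   fully cleaved components (or pass a pre-filtered subset).
#' @param ppm XIC tolerance.
#' @param window Wide search window half-width in minutes.
#' @return The estimated shift in minutes.
#' @export
estimate_rt_shift <- function(run, components, ppm = 5, window = 3) {
  lm <- components[!components$isobaric_group & components$missed_cleavages == 0, ]
  if (nrow(lm) < 3) abort("need at least 3 landmark components; update retention times manually")
  obs <- purrr::map_dbl(seq_len(nrow(lm)), function(i) {
    z <- parse_charges(lm$charges[i])[[1]][1]
    trace <- extract_xic(run, mz_for_charge(lm$mono_mass[i], z), ppm)
    pk <- detect_peak(trace, lm$expected_rt_min[i], window = window)
    if (pk$found) pk$apex_rt - lm$expected_rt_min[i] else NA_real_
  })
  obs <- obs[!is.na(obs)]
  if (length(obs) < 3) {
    abort("fewer than 3 landmark components found; update retention times manually")
  }
  stats::median(obs)
}

#' Quantify all runs of a study with per-run shift correction
#'
#' @param runs List of `mam_run` (e.g. from [simulate_study()]).
#' @param components Component table.
#' @param ppm XIC tolerance in ppm.
#' @param rt_correct Estimate and apply a per-run affine RT shift before
#'   quantifying.
#' @param sum_isotopes Passed to [quantify_components()].
#' @return Per-component areas (see [component_areas()]) for all runs.
#' @export
quantify_study <- function(runs, components, ppm = 5, rt_correct = TRUE,
                           sum_isotopes = FALSE) {
  purrr::map_dfr(runs, function(run) {
    shift <- if (rt_correct) estimate_rt_shift(run, components, ppm = ppm) else 0
    quantify_components(run, components, ppm = ppm, rt_shift = shift,
                        sum_isotopes = sum_isotopes)
  }) |>
    component_areas()
}
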