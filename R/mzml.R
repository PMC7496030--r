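#' Write a run to mzML
#'
#' Writes the run's centroided MS1 scans to a standard-conformant mzML file
#' (via the proteowizard-backed writer in \pkg{mzR}), retention times stored
#' in seconds per the controlled vocabulary.
#'
#' @param run A `mam_run`.
#' @param path Output path (`.mzML`).
#' @return The path, invisibly.
#' @export
write_mzml <- function(run, path) {
  stopifnot(inherits(run, "mam_run"))
  n <- nrow(run$scans)
  if (n == 0) abort("refusing to write a run with no scans")
  if (!dir.exists(dirname(path))) abort(paste0("unwritable path: ", path))
  pks <- purrr::map2(run$scans$mz, run$scans$intensity, function(mz, it) {
    cbind(mz = as.numeric(mz), intensity = as.numeric(it))
  })
  counts <- vapply(pks, nrow, integer(1))
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
    polarity = 1L, peaksCount = counts,
    totIonCurrent = vapply(run$scans$intensity, function(x) sum(x), numeric(1)),
    retentionTime = run$scans$rt_min * 60,
    basePeakMZ = vapply(seq_len(n), function(i) {
      if (counts[i] == 0) 0 else run$scans$mz[[i]][which.max(run$scans$intensity[[i]])]
    }, numeric(1)),
    basePeakIntensity = vapply(run$scans$intensity, function(x) {
      if (length(x) == 0) 0 else max(x)
    }, numeric(1)),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = vapply(run$scans$mz, function(x) if (length(x) == 0) 0 else min(x), numeric(1)),
    highMZ = vapply(run$scans$mz, function(x) if (length(x) == 0) 0 else max(x), numeric(1)),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)), centroided = TRUE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_,
    stringsAsFactors = FALSE
  )
  mzR::writeMSData(pks, file = path, header = hdr, outformat = "mzml")
  invisible(path)
}

#' Read a centroided MS1 run from mzML
#'
#' Reads MS1 scans, enforces the run invariants (strictly increasing
#' retention times, centroid arrays sorted by m/z, non-negative
#' intensities) and rejects profile-mode input.
#'
#' @param path Path to an mzML file.
#' @param lab,replicate,sample_id,timepoint Run metadata (mzML does not
#'   carry study design, so it is supplied here).
#' @return A `mam_run`.
#' @export
read_mzml <- function(path, lab = NA_integer_, replicate = NA_integer_,
                      sample_id = NA_character_, timepoint = NA) {
  if (!file.exists(path)) abort(paste0("mzML file not found: ", path))
  f <- mzR::openMSfile(path)
  on.exit(mzR::close(f), add = TRUE)
  hdr <- mzR::header(f)
  ms1 <- which(hdr$msLevel == 1L)
  if (length(ms1) == 0) abort(paste0("no MS1 scans in ", path))
  if (any(hdr$centroided[ms1] %in% FALSE)) {
    abort(paste0("profile-mode spectra in ", path,
                 " (scan ", ms1[which(hdr$centroided[ms1] %in% FALSE)[1]],
                 "); centroided MS1 input is required"))
  }
  pks <- mzR::peaks(f)
  if (is.matrix(pks)) pks <- list(pks)
  scans <- tibble(
    rt_min = hdr$retentionTime[ms1] / 60,
    mz = purrr::map(pks[ms1], function(m) {
      o <- order(m[, 1]); as.numeric(m[o, 1])
    }),
    intensity = purrr::map(pks[ms1], function(m) {
      o <- order(m[, 1]); as.numeric(m[o, 2])
    })
  )
  if (any(vapply(scans$intensity, function(x) any(x < 0), logical(1)))) {
    abort("negative intensities in input")
  }
  new_run(scans, lab = lab, replicate = replicate, sample_id = sample_id,
          timepoint = timepoint, source = path)
}
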