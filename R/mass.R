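mod_names <- function() modification_table()$name
glycan_names <- function() glycan_table()$name

no_mod_names <- c("none", "unmodified", "unglycosylated", "")

#' Look up a modification by name
#'
#' Resolves a modification name to its elemental delta (fixed modifications)
#' or monosaccharide composition (glycans), together with its target
#' residues, terminal constraint, retention-time offset and the flag marking
#' forms that are isobaric with another species and resolved only by
#' retention time.
#'
#' @param modification Modification name; `"none"` / `"unglycosylated"` mean
#'   no mass change.
#' @return A list with elements `name`, `type` (`"none"`, `"fixed"` or
#'   `"glycan"`), `delta` (named elemental delta counts), `delta_mass`,
#'   `targets`, `terminal`, `rt_offset_min`, `rt_resolved`.
#' @export
modification_info <- function(modification) {
  em <- element_mono_mass()
  if (is.na(modification) || modification %in% no_mod_names) {
    return(list(name = "none", type = "none",
                delta = c(C = 0, H = 0, N = 0, O = 0, S = 0), delta_mass = 0,
                targets = NULL, terminal = "none", rt_offset_min = 0,
                rt_resolved = FALSE))
  }
  mods <- modification_table()
  if (modification %in% mods$name) {
    row <- mods[mods$name == modification, ]
    delta <- c(C = row$dC, H = row$dH, N = row$dN, O = row$dO, S = row$dS)
    return(list(name = modification, type = "fixed", delta = delta,
                delta_mass = sum(delta * em[names(delta)]),
                targets = strsplit(row$targets, "")[[1]],
                terminal = row$terminal, rt_offset_min = row$rt_offset_min,
                rt_resolved = row$rt_resolved))
  }
  glys <- glycan_table()
  if (modification %in% glys$name) {
    row <- glys[glys$name == modification, ]
    mono <- monosaccharide_table()
    counts <- c(hex = row$hex, hexnac = row$hexnac, fuc = row$fuc, neuac = row$neuac)
    delta <- c(C = 0, H = 0, N = 0, O = 0, S = 0)
    for (el in c("C", "H", "N", "O")) {
      delta[el] <- sum(counts * mono[[el]][match(names(counts), mono$name)])
    }
    return(list(name = modification, type = "glycan", delta = delta,
                delta_mass = sum(delta * em[names(delta)]),
                targets = "N", terminal = "none",
                rt_offset_min = row$rt_offset_min, rt_resolved = row$rt_resolved))
  }
  abort(paste0("unknown modification: '", modification, "'"))
}

residue_counts <- function(sequence) {
  aa <- amino_acid_table()
  res <- strsplit(sequence, "")[[1]]
  idx <- match(res, aa$letter)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    abort(paste0("non-standard residue '", res[bad], "' at position ", bad,
                 " of '", sequence, "'"))
  }
  idx
}

#' Elemental composition of a (modified) peptide
#'
#' Sum of the residue compositions plus one water, plus the elemental delta
#' of the modification (glycan compositions included).
#'
#' @param sequence Peptide sequence.
#' @param modification Modification name (default `"none"`).
#' @return Named numeric vector with counts of C, H, N, O, S.
#' @export
peptide_composition <- function(sequence, modification = "none") {
  aa <- amino_acid_table()
  idx <- residue_counts(sequence)
  comp <- c(C = sum(aa$C[idx]), H = sum(aa$H[idx]) + 2, N = sum(aa$N[idx]),
            O = sum(aa$O[idx]) + 1, S = sum(aa$S[idx]))
  comp <- comp + modification_info(modification)$delta
  if (any(comp < 0)) abort("modification removes more atoms than the peptide has")
  comp
}

#' Monoisotopic mass of a (modified) peptide
#'
#' Sum of monoisotopic residue masses plus water plus the modification delta.
#'
#' @inheritParams peptide_composition
#' @return Monoisotopic mass in Da (vectorised over `sequence` and
#'   `modification`).
#' @examples
#' mono_mass("EEQYNSTYR") # 1188.5047
#' @export
mono_mass <- function(sequence, modification = "none") {
  aa <- amino_acid_table()
  masses <- stats::setNames(aa$mono_mass, aa$letter)
  modification <- rep_len(modification, length(sequence))
  vapply(seq_along(sequence), function(i) {
    idx <- residue_counts(sequence[i])
    sum(aa$mono_mass[idx]) + WATER_MASS + modification_info(modification[i])$delta_mass
  }, numeric(1))
}

#' m/z of a peptide ion
#'
#' Standard electrospray relation: `(mass + z * 1.007276) / z`.
#'
#' @param mass Neutral monoisotopic mass (Da).
#' @param z Positive integer charge.
#' @return m/z value(s).
#' @export
mz_for_charge <- function(mass, z) {
  if (any(z < 1)) abort("charge must be a positive integer")
  (mass + z * PROTON_MASS) / z
}

conv_trunc <- function(a, b, n) {
  # truncated linear convolution of two abundance vectors (index 0..n-1)
  out <- numeric(n)
  for (i in seq_along(a)) {
    jmax <- min(length(b), n - i + 1L)
    if (jmax < 1) break
    j <- seq_len(jmax)
    out[i + j - 1L] <- out[i + j - 1L] + a[i] * b[j]
  }
  out
}

element_dist <- function(element, n) {
  iso <- isotope_table()
  rows <- iso[iso$element == element, ]
  d <- numeric(n)
  keep <- rows$nominal_shift < n
  d[rows$nominal_shift[keep] + 1L] <- rows$abundance[keep]
  d / sum(rows$abundance)
}

power_dist <- function(d, k, n) {
  # d^(*k) by binary exponentiation with truncation to the first n peaks
  out <- c(1, numeric(n - 1L))
  base <- d
  while (k > 0) {
    if (k %% 2 == 1) out <- conv_trunc(out, base, n)
    base <- conv_trunc(base, base, n)
    k <- k %/% 2
  }
  out
}

#' Isotopologue abundance envelope of an elemental composition
#'
#' Computes relative abundances of the first `n_peaks` isotopologues
#' (aggregated by nominal mass shift) by convolving the per-element isotope
#' distributions, and renormalises the returned peaks to sum to 1.
#'
#' @param composition Named vector of element counts (C, H, N, O, S), e.g.
#'   from [peptide_composition()].
#' @param n_peaks Number of isotopologue peaks to return.
#' @return Numeric vector of length `n_peaks` summing to 1; element `k` is
#'   the relative abundance of the peak `k - 1` nominal mass units above the
#'   monoisotopic peak.
#' @export
isotope_envelope <- function(composition, n_peaks = 4) {
  stopifnot(n_peaks >= 1)
  if (any(composition < 0)) abort("negative element count")
  out <- c(1, numeric(n_peaks - 1L))
  for (el in names(composition)) {
    k <- composition[[el]]
    if (k == 0) next
    out <- conv_trunc(out, power_dist(element_dist(el, n_peaks), k, n_peaks), n_peaks)
  }
  out / sum(out)
}

#' Apply a modification to digested peptides
#'
#' Annotates rows of a peptide tibble with a modification, validating that
#' the site (if given, in chain coordinates) falls inside the peptide, that
#' the residue at the site is a valid target, and that terminal
#' modifications sit at the right terminus (`Gln->PyroGlu` at the peptide
#' N-terminus, `Lys loss` at the chain C-terminus).
#'
#' @param peptides Peptide tibble from [digest_chains()].
#' @param modification Modification name.
#' @param site Optional integer vector of candidate chain positions
#'   (ambiguous deamidation sites carry two or more; the attribute is then
#'   reported at peptide level, since MS1 data cannot localise it).
#' @param chains Optional chain tibble, required to validate chain C-terminal
#'   modifications.
#' @return The peptide tibble with added columns `modification`,
#'   `delta_mass`, `mono_mass`, `rt_resolved`.
#' @export
apply_modification <- function(peptides, modification, site = NULL, chains = NULL) {
  info <- modification_info(modification)
  out <- peptides
  for (i in seq_len(nrow(out))) {
    seqi <- out$sequence[i]
    if (info$type != "none") {
      if (!is.null(site)) {
        inside <- site >= out$start[i] & site <= out$end[i]
        if (!any(inside)) {
          abort(paste0("site ", paste(site, collapse = "/"),
                       " lies outside peptide ", out$start[i], "-", out$end[i]))
        }
        res <- substr(seqi, site[inside] - out$start[i] + 1L, site[inside] - out$start[i] + 1L)
        if (!any(res %in% info$targets)) {
          abort(paste0("residue '", res[1], "' at site ", site[inside][1],
                       " is not a valid target for ", modification))
        }
      } else if (!is.null(info$targets) &&
                 !any(strsplit(seqi, "")[[1]] %in% info$targets)) {
        abort(paste0("peptide ", seqi, " has no target residue for ", modification))
      }
      if (identical(info$terminal, "peptide_n") &&
          substr(seqi, 1, 1) != info$targets[1]) {
        abort(paste0(modification, " requires an N-terminal ", info$targets[1]))
      }
      if (identical(info$terminal, "chain_c")) {
        last <- substr(seqi, nchar(seqi), nchar(seqi))
        if (!(last %in% info$targets)) {
          abort(paste0(modification, " requires a C-terminal ", paste(info$targets, collapse = "/")))
        }
        if (!is.null(chains)) {
          len <- nchar(chains$sequence[match(out$chain_id[i], chains$chain_id)])
          if (!is.na(len) && out$end[i] != len) {
            abort(paste0(modification, " applies only to the chain C-terminal peptide"))
          }
        }
      }
    }
  }
  out$modification <- info$name
  out$delta_mass <- info$delta_mass
  out$mono_mass <- mono_mass(out$sequence, info$name)
  out$rt_resolved <- info$rt_resolved
  out
}
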