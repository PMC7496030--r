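component_id <- function(sequence, modification, missed_cleavages) {
  paste0(sequence, "|", modification, "|mc", missed_cleavages)
}

choose_charges <- function(mass, len, mz_range) {
  cand <- if (len < 15) 1:2 else 2:3
  keep <- cand[mz_for_charge(mass, cand) >= mz_range[1] &
                 mz_for_charge(mass, cand) <= mz_range[2]]
  if (length(keep) == 0) {
    all_z <- 1:6
    ok <- all_z[mz_for_charge(mass, all_z) >= mz_range[1] &
                  mz_for_charge(mass, all_z) <= mz_range[2]]
    if (length(ok) == 0) abort(paste0("no charge state places mass ", round(mass, 2),
                                      " inside the acquired m/z range"))
    keep <- ok[seq_len(min(2, length(ok)))]
  }
  keep
}

#' Build a target component table
#'
#' Assembles the "target peptide workbook" driving targeted quantitation:
#' one row per peptide form (sequence x modification x missed-cleavage
#' state) with its charge states, expected retention time and RT window.
#' Components come from a ground-truth attribute panel (modified forms,
#' their unmodified reference forms, glycoform profile members, and listed
#' single missed-cleavage partners) and/or from a digested peptide set
#' (unmodified monitoring components, e.g. for sequence-coverage maps).
#'
#' Charge states follow a fixed length rule (length < 15: z 1-2, else
#' z 2-3), restricted to the acquired m/z range. Components that are
#' isobaric with another form of the same parent peptide (isomerisation,
#' A2Ga1G1F vs A2G2F) are distinguished only chromatographically and get a
#' narrow RT window so each is integrated from its own peak.
#'
#' @param truth Optional `mam_truth` from [make_ground_truth()].
#' @param peptides Optional peptide tibble from [digest_chains()] and/or
#'   [enumerate_semi_specific()].
#' @param mz_range Acquired m/z range (instrument mass range).
#' @param gradient_min Gradient length in minutes (used for validation).
#' @param rt_window_min Default RT window half-width after shift correction.
#' @param isobaric_window_min Narrow half-width used for RT-resolved
#'   isobaric groups.
#' @param rule Cleavage rule used to annotate missed cleavages of listed
#'   missed-cleavage partner sequences.
#' @param chains Optional chain tibble; components whose sequence occurs in
#'   a chain get chain coordinates filled in (used by coverage maps).
#' @return A tibble of components; see Details for columns.
#' @export
build_component_table <- function(truth = NULL, peptides = NULL,
                                  mz_range = c(200, 2000), gradient_min = 105,
                                  rt_window_min = 1.5, isobaric_window_min = 0.35,
                                  rule = cleavage_rule(), chains = NULL) {
  rows <- list()
  add_row <- function(sequence, modification, role, attribute, mode, site_label,
                      pair_key, mc, mc_parent = NA_character_, specific = TRUE,
                      chain_id = NA_character_, start = NA_integer_, end = NA_integer_,
                      abundance_scale = 1) {
    rows[[length(rows) + 1L]] <<- tibble(
      component_id = component_id(sequence, modification, mc),
      chain_id = chain_id, start = start, end = end,
      sequence = sequence, modification = modification,
      site_label = site_label, attribute = attribute, mode = mode, role = role,
      pair_key = pair_key, missed_cleavages = mc, specific = specific,
      mc_parent = mc_parent, include_in_rollup = !is.na(attribute) || role == "reference",
      abundance_scale = abundance_scale
    )
  }
  if (!is.null(truth)) {
    for (i in seq_len(nrow(truth$attributes))) {
      a <- truth$attributes[i, ]
      modname <- if (a$modification %in% no_mod_names) "none" else a$modification
      role <- if (a$mode == "profile") "profile" else "modified"
      add_row(a$sequence, modname, role, a$attribute, a$mode, a$site_label,
              pair_key = a$sequence, mc = 0L)
      if (a$mode == "pairwise") {
        add_row(a$sequence, "none", "reference", NA_character_, "pairwise",
                a$site_label, pair_key = a$sequence, mc = 0L)
      }
      if (!is.na(a$mc_partner) && nzchar(a$mc_partner)) {
        mc <- length(cut_points(a$mc_partner, rule))
        add_row(a$mc_partner, modname, role, a$attribute, a$mode, a$site_label,
                pair_key = a$sequence, mc = mc,
                mc_parent = component_id(a$sequence, modname, 0L))
        if (a$mode == "pairwise") {
          add_row(a$mc_partner, "none", "reference", NA_character_, "pairwise",
                  a$site_label, pair_key = a$sequence, mc = mc,
                  mc_parent = component_id(a$sequence, "none", 0L))
        }
      }
    }
  }
  if (!is.null(peptides)) {
    for (i in seq_len(nrow(peptides))) {
      p <- peptides[i, ]
      add_row(p$sequence, "none", "none", NA_character_, NA_character_,
              NA_character_, pair_key = p$sequence, mc = p$missed_cleavages,
              specific = p$specific, chain_id = p$chain_id,
              start = p$start, end = p$end)
    }
  }
  if (length(rows) == 0) abort("supply truth and/or peptides")
  comp <- bind_rows(rows) |> distinct(.data$component_id, .keep_all = TRUE)
  if (!is.null(chains)) {
    for (i in which(is.na(comp$start))) {
      for (j in seq_len(nrow(chains))) {
        pos <- regexpr(comp$sequence[i], chains$sequence[j], fixed = TRUE)
        if (pos > 0) {
          comp$chain_id[i] <- chains$chain_id[j]
          comp$start[i] <- as.integer(pos)
          comp$end[i] <- as.integer(pos + nchar(comp$sequence[i]) - 1L)
          break
        }
      }
    }
  }
  comp$mono_mass <- mono_mass(comp$sequence, comp$modification)
  comp$rt_resolved <- vapply(comp$modification,
                             function(m) isTRUE(modification_info(m)$rt_resolved),
                             logical(1))
  comp$expected_rt_min <- predict_rt(comp$sequence, comp$modification)
  comp$charges <- vapply(seq_len(nrow(comp)), function(i) {
    paste(choose_charges(comp$mono_mass[i], nchar(comp$sequence[i]), mz_range),
          collapse = ";")
  }, character(1))
  # isobaric groups of the same parent peptide share a mass: give every
  # member a narrow window so each is integrated from its own RT peak
  comp <- comp |>
    group_by(.data$pair_key, mass_key = round(.data$mono_mass, 2),
             .data$missed_cleavages) |>
    mutate(isobaric_group = n() > 1) |>
    ungroup() |>
    select(-"mass_key") |>
    mutate(rt_window_min = ifelse(.data$isobaric_group, isobaric_window_min, rt_window_min))
  bad_rt <- comp$expected_rt_min > gradient_min
  if (any(bad_rt)) abort("expected retention time beyond the gradient")
  comp
}

parse_charges <- function(charges) lapply(strsplit(charges, ";"), as.integer)

#' Register additional parent-peptide loadings on a ground truth
#'
#' Components can only be simulated if their parent peptide has a base
#' loading in the ground truth; this registers sequences (e.g. a digested
#' peptide set used for coverage runs) at a common loading.
#'
#' @param truth A `mam_truth` object.
#' @param sequences Character vector of peptide sequences.
#' @param loading Base loading in arbitrary abundance units.
#' @return The updated `mam_truth`.
#' @export
add_loadings <- function(truth, sequences, loading = 1e6) {
  new <- tibble(sequence = setdiff(unique(sequences), truth$loadings$sequence),
                loading = loading)
  truth$loadings <- bind_rows(truth$loadings, new)
  truth
}

# True abundance of every component under the ground truth: reference/plain
# forms carry the parent loading L; a pairwise modified form carries
# L * f / (1 - f) so that mod / (mod + ref) recovers f exactly; a profile
# member carries L * f; missed-cleavage forms carry mc_fraction times their
# parent form's abundance.
component_abundances <- function(truth, components) {
  att <- truth$attributes
  L <- stats::setNames(truth$loadings$loading, truth$loadings$sequence)
  base_of <- function(i) {
    key <- components$pair_key[i]
    if (!key %in% names(L)) {
      abort(paste0("peptide '", key, "' is absent from the ground-truth loadings"))
    }
    L[[key]]
  }
  frac_of <- function(i) {
    hit <- att$attribute == components$attribute[i] &
      att$sequence == components$pair_key[i]
    if (!any(hit)) abort(paste0("attribute '", components$attribute[i],
                                "' is absent from the ground truth"))
    att$true_fraction[which(hit)[1]]
  }
  ab <- numeric(nrow(components))
  for (i in seq_len(nrow(components))) {
    Lb <- base_of(i)
    ab[i] <- switch(components$role[i],
      modified = { f <- frac_of(i); Lb * f / (1 - f) },
      profile = Lb * frac_of(i),
      reference = Lb,
      none = Lb,
      abort(paste0("unknown component role '", components$role[i], "'"))
    )
    ab[i] <- ab[i] * components$abundance_scale[i]
    if (components$missed_cleavages[i] > 0) ab[i] <- ab[i] * truth$mc_fraction
  }
  components$abundance <- ab
  components
}
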