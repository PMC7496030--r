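#' Pairwise relative abundance of modified attributes
#'
#' For each pairwise attribute, per run: `100 * sum(areas of the modified
#' component set) / (sum(modified) + sum(reference))`, sums spanning all
#' charge states and all listed peptide forms including the single
#' missed-cleavage partners. A run where both sums are zero yields an
#' undefined value: it is flagged (`defined = FALSE`, `value = NA`) and must
#' be excluded from precision statistics, never reported as 0.
#'
#' @param quant Per-component areas from [quantify_study()] /
#'   [component_areas()].
#' @param components Component table the areas were quantified against.
#' @return A tibble per run x attribute: `lab`, `replicate`, `attribute`,
#'   `value` (%), `modified_area`, `reference_area`, `defined`.
#' @export
relative_abundance <- function(quant, components) {
  attrs <- components |>
    filter(.data$role == "modified", !is.na(.data$attribute)) |>
    distinct(.data$attribute, .data$pair_key)
  if (nrow(attrs) == 0) return(tibble())
  q <- quant |> left_join(select(components, "component_id", "role",
                                 "attribute", "pair_key"),
                          by = "component_id")
  purrr::map_dfr(seq_len(nrow(attrs)), function(i) {
    a <- attrs$attribute[i]
    pk <- attrs$pair_key[i]
    q |>
      group_by(.data$lab, .data$replicate) |>
      summarise(
        modified_area = sum(.data$area[.data$role == "modified" &
                                         .data$attribute %in% a]),
        reference_area = sum(.data$area[.data$role == "reference" &
                                          .data$pair_key %in% pk]),
        .groups = "drop"
      ) |>
      mutate(attribute = a,
             defined = (.data$modified_area + .data$reference_area) > 0,
             value = ifelse(.data$defined,
                            100 * .data$modified_area /
                              (.data$modified_area + .data$reference_area),
                            NA_real_)) |>
      select("lab", "replicate", "attribute", "value",
             "modified_area", "reference_area", "defined")
  })
}

#' Glycoform profile at a glycosylation site
#'
#' Per run, each profile member (each glycoform plus the unglycosylated
#' form) is reported as `100 * member area / total site area`, member areas
#' combining the fully cleaved peptide and its single missed-cleavage
#' partner across all charge states. Members with identical mass but
#' distinct retention time (A2G2F vs A2Ga1G1F) are quantified from their
#' separate RT-window peaks; when such a pair is not chromatographically
#' resolved (one member has no detectable peak of its own), both members
#' are flagged `unresolved` rather than guessed. A zero site total flags
#' every member undefined.
#'
#' @inheritParams relative_abundance
#' @param site Site label (default: the single profile site present).
#' @return A tibble per run x member attribute with `value` (%), summing to
#'   100 per run within numerical tolerance.
#' @export
glycan_profile <- function(quant, components, site = NULL) {
  mem <- components |> filter(.data$role == "profile")
  if (!is.null(site)) mem <- mem |> filter(.data$site_label %in% site)
  if (nrow(mem) == 0) abort("no profile-mode components at this site")
  q <- quant |>
    inner_join(select(mem, "component_id", "attribute", "site_label",
                      "isobaric_group"),
               by = "component_id") |>
    group_by(.data$lab, .data$replicate, .data$site_label, .data$attribute) |>
    summarise(area = sum(.data$area),
              member_found = any(.data$found),
              isobaric = any(.data$isobaric_group), .groups = "drop_last") |>
    group_by(.data$lab, .data$replicate, .data$site_label) |>
    mutate(
      total = sum(.data$area),
      # an isobaric member that was not found means its RT-window peak was
      # not chromatographically resolved from its mass-identical partner:
      # the whole isobaric set is flagged, since the found partner's area
      # absorbs the missing one
      unresolved = .data$isobaric &
        any(.data$isobaric & !.data$member_found),
      defined = .data$total > 0 & .data$member_found,
      value = ifelse(.data$total > 0, 100 * .data$area / .data$total, NA_real_)
    ) |>
    ungroup() |>
    select("lab", "replicate", "site_label", "attribute", "value", "area",
           "defined", "unresolved")
  q
}

coverage_classes <- c(">50%", ">20%", ">10%", ">5%", ">2%", ">1%", "<=1%")

#' Per-residue sequence coverage map with recovery classes
#'
#' A residue is covered when at least one identified (found) peptide
#' component spans it. The recovery class bins the residue's summed MS1
#' area (over all spanning found peptides) relative to the chain's
#' most-covered residue, at the thresholds 50/20/10/5/2/1 percent.
#'
#' @param quant Per-component areas.
#' @param components Component table with chain coordinates (`chain_id`,
#'   `start`, `end` set, e.g. built from [digest_chains()] output).
#' @param chains Chain tibble.
#' @return A list with `residues` (tibble: `chain_id`, `position`, `covered`,
#'   `rel_area`, `class`) and `summary` (tibble: `chain_id`, `coverage_pct`).
#' @export
coverage_map <- function(quant, components, chains) {
  comp <- components |> filter(!is.na(.data$start))
  areas <- quant |>
    group_by(.data$component_id) |>
    summarise(area = sum(.data$area), found = any(.data$found), .groups = "drop") |>
    inner_join(select(comp, "component_id", "chain_id", "start", "end"),
               by = "component_id") |>
    filter(.data$found)
  residues <- purrr::pmap_dfr(chains, function(chain_id, sequence, role, ...) {
    n <- nchar(sequence)
    cov <- logical(n)
    area <- numeric(n)
    here <- areas[areas$chain_id == chain_id, ]
    for (i in seq_len(nrow(here))) {
      span <- here$start[i]:here$end[i]
      cov[span] <- TRUE
      area[span] <- area[span] + here$area[i]
    }
    ref <- if (any(area > 0)) max(area) else 1
    rel <- 100 * area / ref
    cls <- cut(rel, breaks = c(-Inf, 1, 2, 5, 10, 20, 50, Inf),
               labels = rev(coverage_classes), right = TRUE)
    tibble(chain_id = chain_id, position = seq_len(n), covered = cov,
           rel_area = rel, class = as.character(cls))
  })
  summary <- residues |>
    group_by(.data$chain_id) |>
    summarise(coverage_pct = 100 * mean(.data$covered), .groups = "drop")
  list(residues = residues, summary = summary)
}

#' Area-based missed-cleavage rate
#'
#' `100 * sum(areas of specific peptides with >= 1 missed cleavage) /
#' sum(areas of all identified specific peptides)`.
#'
#' @inheritParams relative_abundance
#' @return A tibble per run with `rate_pct` and `defined`.
#' @export
missed_cleavage_rate <- function(quant, components) {
  q <- quant |>
    inner_join(select(components, "component_id", "missed_cleavages", "specific"),
               by = "component_id") |>
    filter(.data$specific)
  q |>
    group_by(.data$lab, .data$replicate) |>
    summarise(
      mc_area = sum(.data$area[.data$missed_cleavages >= 1]),
      total = sum(.data$area), .groups = "drop"
    ) |>
    mutate(defined = .data$total > 0,
           rate_pct = ifelse(.data$defined, 100 * .data$mc_area / .data$total,
                             NA_real_)) |>
    select("lab", "replicate", "rate_pct", "defined")
}

#' Area-based non-specific (semi-tryptic) cleavage rate
#'
#' `100 * sum(areas of specific = FALSE peptides) / sum(areas of all
#' identified peptides)`.
#'
#' @inheritParams relative_abundance
#' @return A tibble per run with `rate_pct` and `defined`.
#' @export
nonspecific_rate <- function(quant, components) {
  q <- quant |>
    inner_join(select(components, "component_id", "specific"),
               by = "component_id")
  q |>
    group_by(.data$lab, .data$replicate) |>
    summarise(
      ns_area = sum(.data$area[!.data$specific]),
      total = sum(.data$area), .groups = "drop"
    ) |>
    mutate(defined = .data$total > 0,
           rate_pct = ifelse(.data$defined, 100 * .data$ns_area / .data$total,
                             NA_real_)) |>
    select("lab", "replicate", "rate_pct", "defined")
}

#' Cross-laboratory peptide Venn membership
#'
#' Matches peptides across 2-4 laboratories by (sequence, modification)
#' identity with observed-mass agreement within a ppm tolerance, and counts
#' peptides per Venn intersection region. Charge state is ignored: a
#' peptide seen at different charges in different laboratories is the same
#' peptide.
#'
#' @param lab_peptides Named list (one element per laboratory) of tibbles
#'   with columns `sequence`, `modification`, `observed_mass`.
#' @param ppm Mass agreement tolerance in ppm.
#' @return A tibble with `region` (lab names joined by `&`) and `count`;
#'   region counts partition the union.
#' @export
venn_membership <- function(lab_peptides, ppm = 5) {
  k <- length(lab_peptides)
  if (k < 2 || k > 4) abort("Venn membership supports 2 to 4 laboratories")
  labs <- names(lab_peptides) %||% paste0("lab", seq_len(k))
  all_p <- purrr::imap_dfr(lab_peptides, function(df, nm) {
    tibble(lab = nm, sequence = df$sequence, modification = df$modification,
           observed_mass = df$observed_mass)
  }) |>
    mutate(key = paste0(.data$sequence, "|", .data$modification))
  keys <- all_p |> distinct(.data$key, .keep_all = TRUE)
  membership <- purrr::map_chr(seq_len(nrow(keys)), function(i) {
    rows <- all_p[all_p$key == keys$key[i], ]
    ref_mass <- rows$observed_mass[1]
    ok <- abs(rows$observed_mass - ref_mass) / ref_mass * 1e6 <= ppm
    present <- labs[labs %in% unique(rows$lab[ok])]
    paste(present, collapse = "&")
  })
  tibble(region = membership) |>
    count(.data$region, name = "count") |>
    arrange(.data$region)
}
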