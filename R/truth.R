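#' Ground truth for the synthetic LC-MS study generator
#'
#' Builds a validated ground-truth object: the set of monitored quality
#' attributes with their true modified fractions (pairwise attributes) or
#' glycoform fractions (profile sites, renormalised to sum to 1 including
#' the unglycosylated form), per-peptide base loadings, and the fraction of
#' each fully cleaved parent's loading carried by its single
#' missed-cleavage partner form.
#'
#' Two presets reproduce the printed multi-laboratory study values as true
#' fractions: `"nist_table1"` (per-laboratory NISTmAb attribute panel,
#' including the Fc glycoform profile) and `"stability_table2"` (forced
#' degradation series of a six-mAb mixture, per site and time point).
#'
#' @param preset `"nist_table1"`, `"stability_table2"`, or `NULL` when
#'   supplying `table`.
#' @param lab For `"nist_table1"`: one of `"ireland"`, `"denmark"`, `"uk"`,
#'   `"switzerland"`.
#' @param site For `"stability_table2"`: `"A"` or `"B"`.
#' @param months For `"stability_table2"`: 0, 3 or 6.
#' @param attributes Optional character vector restricting the preset to a
#'   subset of attribute labels.
#' @param table A user table with columns `attribute`, `mode`
#'   (`"pairwise"`/`"profile"`), `site_label`, `sequence`, `modification`,
#'   `true_fraction`, optional `mc_partner`.
#' @param loading Base loading (arbitrary abundance units) per parent
#'   peptide.
#' @param mc_fraction Missed-cleavage partner loading as a fraction of the
#'   parent's loading.
#' @return An object of class `mam_truth`: a list with tibbles `attributes`
#'   and `loadings` plus `mc_fraction`.
#' @examples
#' tr <- make_ground_truth("nist_table1", lab = "ireland")
#' subset(tr$attributes, attribute == "HC N300+A2G0F")$true_fraction
#' @export
make_ground_truth <- function(preset = NULL, lab = "ireland", site = "A",
                              months = 6, attributes = NULL, table = NULL,
                              loading = 1e6, mc_fraction = 0.15) {
  if (is.null(preset) && is.null(table)) abort("supply a preset name or a truth table")
  if (!is.null(preset)) {
    if (preset == "nist_table1") {
      raw <- read_constants("nist_table1.csv")
      lab <- match.arg(tolower(lab), c("ireland", "denmark", "uk", "switzerland"))
      tab <- raw |>
        mutate(true_fraction = .data[[lab]] / 100) |>
        select("attribute", "mode", "site_label", "sequence", "mc_partner",
               "modification", "true_fraction")
    } else if (preset == "stability_table2") {
      raw <- read_constants("stability_table2.csv")
      sel <- raw[raw$site == site & raw$months == months, ]
      sel <- sel[!is.na(sel$value), ]
      tab <- tibble(attribute = sel$attribute, mode = "pairwise",
                    site_label = sel$attribute, sequence = sel$sequence,
                    mc_partner = NA_character_, modification = sel$modification,
                    true_fraction = sel$value / 100)
    } else {
      abort(paste0("unknown preset '", preset, "'"))
    }
  } else {
    tab <- as_tibble(table)
    if (!"mc_partner" %in% names(tab)) tab$mc_partner <- NA_character_
    if (!"site_label" %in% names(tab)) tab$site_label <- tab$attribute
    tab <- tab[, c("attribute", "mode", "site_label", "sequence", "mc_partner",
                   "modification", "true_fraction")]
  }
  if (!is.null(attributes)) tab <- tab[tab$attribute %in% attributes, ]
  if (nrow(tab) == 0) abort("no attributes selected")
  if (any(tab$true_fraction < 0 | tab$true_fraction > 1)) {
    abort("true fractions must lie in [0, 1]")
  }
  if (any(tab$mode == "pairwise" & tab$true_fraction >= 1)) {
    abort("pairwise fractions must be < 1")
  }
  # renormalise profile sites so glycoform fractions sum to exactly 1
  tab <- tab |>
    group_by(.data$site_label) |>
    mutate(true_fraction = ifelse(.data$mode == "profile",
                                  .data$true_fraction / sum(.data$true_fraction[.data$mode == "profile"]),
                                  .data$true_fraction)) |>
    ungroup()
  loadings <- tibble(sequence = unique(tab$sequence), loading = loading)
  structure(list(attributes = tab, loadings = loadings,
                 mc_fraction = mc_fraction),
            class = "mam_truth")
}

#' @export
print.mam_truth <- function(x, ...) {
  cat("<mam_truth> ", nrow(x$attributes), " attributes, ",
      nrow(x$loadings), " parent peptides, mc_fraction = ",
      x$mc_fraction, "\n", sep = "")
  print(x$attributes, n = 8)
  invisible(x)
}
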