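#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Cache for the versioned constants tables shipped under inst/extdata.
.mampep_cache <- new.env(parent = emptyenv())

#' Physical constants used throughout the package
#'
#' Proton mass (Da) used for the electrospray m/z relation and the average
#' spacing between adjacent isotopologue peaks (Da).
#' @name mampep-constants
#' @keywords internal
PROTON_MASS <- 1.007276
ISOTOPE_SPACING <- 1.00335484
WATER_MASS <- 18.0105646

constants_file <- function(name) {
  path <- system.file("extdata", name, package = "mampep")
  if (!nzchar(path)) {
    # during development (pkgload) inst/ is on the path directly
    path <- system.file("inst", "extdata", name, package = "mampep")
  }
  if (!nzchar(path)) abort(paste0("constants file not found: ", name))
  path
}

read_constants <- function(name) {
  key <- paste0("tbl_", name)
  if (!is.null(.mampep_cache[[key]])) return(.mampep_cache[[key]])
  tbl <- readr::read_csv(constants_file(name), show_col_types = FALSE, progress = FALSE)
  .mampep_cache[[key]] <- tbl
  tbl
}

#' Residue-level amino acid table
#'
#' The 20 standard amino acid residues with elemental composition (residue,
#' i.e. amino acid minus water), monoisotopic residue mass (Da), and the
#' per-residue hydrophobicity coefficient used by [predict_rt()].
#'
#' @return A tibble with columns `letter`, `name`, `C`, `H`, `N`, `O`, `S`,
#'   `mono_mass`, `rt_coef`.
#' @export
amino_acid_table <- function() read_constants("amino_acids.csv")

#' Isotope masses and abundances
#'
#' IUPAC isotopic masses and abundances for C, H, N, O and S, indexed by the
#' nominal mass shift relative to the lightest isotope.
#'
#' @return A tibble with columns `element`, `nominal_shift`, `mass`, `abundance`.
#' @export
isotope_table <- function() read_constants("elements.csv")

#' Modification definitions
#'
#' Fixed-delta peptide modifications: elemental deltas, target residues,
#' terminal constraints, retention-time offsets for the synthetic generator
#' and the flag marking isobaric species that are resolved only
#' chromatographically (isomerisation).
#'
#' @return A tibble with columns `name`, `targets`, `dC`..`dS`,
#'   `rt_offset_min`, `rt_resolved`, `terminal`.
#' @export
modification_table <- function() read_constants("modifications.csv")

#' N-glycan compositions
#'
#' Monosaccharide compositions for the glycoforms monitored on the Fc
#' glycosylation site. `A2Ga1G1F` is intentionally identical in composition to
#' `A2G2F`: the two are isomers distinguished only by retention time.
#'
#' @return A tibble with columns `name`, `hex`, `hexnac`, `fuc`, `neuac`,
#'   `rt_offset_min`, `rt_resolved`.
#' @export
glycan_table <- function() read_constants("glycans.csv")

monosaccharide_table <- function() read_constants("monosaccharides.csv")

element_mono_mass <- function() {
  key <- "element_mono"
  if (is.null(.mampep_cache[[key]])) {
    iso <- isotope_table()
    m <- iso |> group_by(.data$element) |> slice_min(.data$nominal_shift, n = 1) |> ungroup()
    v <- stats::setNames(m$mass, m$element)
    .mampep_cache[[key]] <- v
  }
  .mampep_cache[[key]]
}
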