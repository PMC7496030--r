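#' Read mAb chain sequences from FASTA
#'
#' Reads protein chains (e.g. the heavy and light chain of a monoclonal
#' antibody) from a FASTA file, single-line or wrapped. The chain role is
#' inferred from `HC` / `LC` tokens in the header, or can be given explicitly.
#'
#' @param path Path to a FASTA file of amino acid sequences.
#' @param roles Optional named character vector mapping chain ids to
#'   `"heavy"`, `"light"` or `"other"`; overrides header inference.
#' @return A tibble with columns `chain_id`, `sequence`, `role` — one row per
#'   chain, residues numbered 1-based from the first residue of the sequence.
#' @examples
#' fasta <- system.file("extdata", "synthetic_igg1.fasta", package = "mampep")
#' read_chains(fasta)
#' @export
read_chains <- function(path, roles = NULL) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr_idx <- grep("^>", lines)
  if (length(hdr_idx) == 0) abort("no FASTA headers found")
  ends <- c(hdr_idx[-1] - 1L, length(lines))
  chains <- purrr::map2_dfr(hdr_idx, ends, function(h, e) {
    header <- sub("^>", "", lines[h])
    id <- strsplit(trimws(header), "\\s+")[[1]][1]
    seq <- toupper(paste0(lines[seq.int(h + 1L, e)], collapse = ""))
    seq <- gsub("\\s", "", seq)
    tibble(chain_id = id, sequence = seq, header = header)
  })
  infer_role <- function(id, header) {
    if (!is.null(roles) && id %in% names(roles)) return(roles[[id]])
    if (grepl("\\bHC\\b|heavy", header, ignore.case = TRUE)) return("heavy")
    if (grepl("\\bLC\\b|light", header, ignore.case = TRUE)) return("light")
    "other"
  }
  chains <- chains |>
    mutate(role = purrr::map2_chr(.data$chain_id, .data$header, infer_role)) |>
    select("chain_id", "sequence", "role")
  validate_chains(chains)
  chains
}

#' Construct a protein chain table directly from sequences
#'
#' @param chain_id Character vector of chain labels (e.g. `"HC"`, `"LC"`).
#' @param sequence Character vector of residue strings (standard 20 letters).
#' @param role Chain roles; one of `"heavy"`, `"light"`, `"other"`.
#' @return A validated chain tibble as returned by [read_chains()].
#' @export
protein_chain <- function(chain_id, sequence, role = "other") {
  chains <- tibble(chain_id = chain_id, sequence = toupper(sequence),
                   role = rep_len(role, length(chain_id)))
  validate_chains(chains)
  chains
}

validate_chains <- function(chains) {
  aa <- amino_acid_table()$letter
  for (i in seq_len(nrow(chains))) {
    s <- chains$sequence[i]
    if (!nzchar(s)) abort(paste0("chain '", chains$chain_id[i], "' has an empty sequence"))
    res <- strsplit(s, "")[[1]]
    bad <- which(!(res %in% aa))
    if (length(bad) > 0) {
      abort(paste0("chain '", chains$chain_id[i], "' has a non-standard residue '",
                   res[bad[1]], "' at position ", bad[1]))
    }
  }
  if (anyDuplicated(chains$chain_id)) abort("duplicate chain ids")
  invisible(chains)
}
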