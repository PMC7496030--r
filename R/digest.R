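#' Tryptic cleavage rule
#'
#' Trypsin cleaves C-terminal to lysine and arginine except when the next
#' residue is proline. Chain termini always count as canonical peptide
#' termini.
#'
#' @param cleave_after Residues after which the backbone is cut.
#' @param suppress_before Residues that suppress an otherwise valid cut when
#'   they follow the cleavage site.
#' @return A list of class `cleavage_rule`.
#' @export
cleavage_rule <- function(cleave_after = c("K", "R"), suppress_before = "P") {
  structure(list(cleave_after = cleave_after, suppress_before = suppress_before),
            class = "cleavage_rule")
}

# 0-based cut points: a cut after position p (1 <= p < n) is canonical when
# residue p is in cleave_after and residue p+1 is not in suppress_before.
cut_points <- function(sequence, rule) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  if (n < 2) return(integer(0))
  p <- seq_len(n - 1L)
  p[res[p] %in% rule$cleave_after & !(res[p + 1L] %in% rule$suppress_before)]
}

#' In-silico tryptic digestion with missed cleavages
#'
#' Enumerates all fully specific tryptic peptides of each chain with up to
#' `max_missed` internal missed cleavage sites. Coordinates are 1-based and
#' inclusive; output is ordered by chain, start, then end.
#'
#' @param chains Chain tibble from [read_chains()] or [protein_chain()].
#' @param max_missed Maximum number of internal missed cleavage sites
#'   (the monitoring workflow uses 1).
#' @param min_length Minimum peptide length to report; single residues are
#'   unobservable in the LC setup, so the default is 2.
#' @param rule Cleavage rule, default trypsin.
#' @return A tibble with columns `chain_id`, `start`, `end`, `sequence`,
#'   `missed_cleavages`, `specific` (always `TRUE` here).
#' @examples
#' digest_chains(protein_chain("X", "AAKAAR"), max_missed = 0)
#' @export
digest_chains <- function(chains, max_missed = 1, min_length = 2,
                          rule = cleavage_rule()) {
  stopifnot(max_missed >= 0)
  validate_chains(chains)
  purrr::pmap_dfr(chains, function(chain_id, sequence, role, ...) {
    n <- nchar(sequence)
    cuts <- cut_points(sequence, rule)
    bounds <- c(0L, cuts, n)          # fragment boundaries, 0-based cut points
    nb <- length(bounds)
    out <- list()
    for (i in seq_len(nb - 1L)) {
      for (m in 0:max_missed) {
        j <- i + 1L + m
        if (j > nb) break
        start <- bounds[i] + 1L
        end <- bounds[j]
        if (end - start + 1L < min_length) next
        out[[length(out) + 1L]] <- tibble(
          chain_id = chain_id,
          start = start, end = end,
          sequence = substr(sequence, start, end),
          missed_cleavages = m,
          specific = TRUE
        )
      }
    }
    bind_rows(out) |> arrange(.data$start, .data$end)
  })
}

#' Enumerate semi-specific (semi-tryptic) peptides
#'
#' Returns peptides with exactly one terminus at a canonical tryptic boundary
#' (or chain end) and the other terminus elsewhere. These are used only to
#' classify observed components when computing the non-specific cleavage
#' rate; they are flagged `specific = FALSE`.
#'
#' @param chains Chain tibble.
#' @param min_length,max_length Length range of enumerated peptides.
#' @param rule Cleavage rule, default trypsin.
#' @return A tibble with the same columns as [digest_chains()].
#' @export
enumerate_semi_specific <- function(chains, min_length = 2, max_length = 30,
                                    rule = cleavage_rule()) {
  stopifnot(min_length >= 1, min_length <= max_length)
  validate_chains(chains)
  purrr::pmap_dfr(chains, function(chain_id, sequence, role, ...) {
    n <- nchar(sequence)
    cuts <- cut_points(sequence, rule)
    start_canon <- c(1L, cuts + 1L)       # canonical N-terminal start positions
    end_canon <- c(cuts, n)               # canonical C-terminal end positions
    out <- list()
    for (start in 1:n) {
      for (len in min_length:max_length) {
        end <- start + len - 1L
        if (end > n) break
        sc <- start %in% start_canon
        ec <- end %in% end_canon
        if (xor(sc, ec)) {
          mm <- sum(cuts >= start & cuts < end)
          out[[length(out) + 1L]] <- tibble(
            chain_id = chain_id, start = start, end = end,
            sequence = substr(sequence, start, end),
            missed_cleavages = mm, specific = FALSE
          )
        }
      }
    }
    bind_rows(out) |> arrange(.data$start, .data$end)
  })
}
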