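# Independent oracles used by the tests. These deliberately re-derive
# results with different algorithms than the package (exhaustive
# enumeration, atom-by-atom convolution, per-scan loops).

# exhaustive tryptic digestion over all substrings
oracle_digest <- function(sequence, max_missed, min_length = 2) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  is_cut <- function(p) p >= 1 && p < n && res[p] %in% c("K", "R") && res[p + 1] != "P"
  out <- list()
  for (i in 1:n) {
    for (j in i:n) {
      if (j - i + 1 < min_length) next
      start_ok <- i == 1 || is_cut(i - 1)
      end_ok <- j == n || is_cut(j)
      if (!start_ok || !end_ok) next
      internal <- if (j > i) sum(vapply(i:(j - 1), is_cut, logical(1))) else 0
      if (internal <= max_missed) {
        out[[length(out) + 1]] <- data.frame(start = i, end = j,
                                             missed = internal)
      }
    }
  }
  do.call(rbind, out)
}

# exhaustive semi-specific substring count
oracle_semi_count <- function(sequence, min_length, max_length) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  is_cut <- function(p) p >= 1 && p < n && res[p] %in% c("K", "R") && res[p + 1] != "P"
  count <- 0
  for (i in 1:n) for (j in i:n) {
    len <- j - i + 1
    if (len < min_length || len > max_length) next
    start_ok <- i == 1 || is_cut(i - 1)
    end_ok <- j == n || is_cut(j)
    if (xor(start_ok, end_ok)) count <- count + 1
  }
  count
}

# peptide monoisotopic mass from elemental counts and isotope masses
oracle_mass <- function(sequence, extra = c(C = 0, H = 0, N = 0, O = 0, S = 0)) {
  aa <- amino_acid_table()
  iso <- isotope_table()
  lightest <- vapply(c("C", "H", "N", "O", "S"), function(el) {
    rows <- iso[iso$element == el, ]
    rows$mass[which.min(rows$nominal_shift)]
  }, numeric(1))
  idx <- match(strsplit(sequence, "")[[1]], aa$letter)
  counts <- c(C = sum(aa$C[idx]), H = sum(aa$H[idx]) + 2, N = sum(aa$N[idx]),
              O = sum(aa$O[idx]) + 1, S = sum(aa$S[idx])) + extra
  sum(counts * lightest[names(counts)])
}

# isotopologue envelope by direct atom-at-a-time polynomial convolution
oracle_envelope <- function(composition, n_peaks) {
  iso <- isotope_table()
  conv <- function(a, b) {
    out <- numeric(n_peaks)
    for (i in seq_along(a)) {
      for (j in seq_along(b)) {
        if (i + j - 1 <= n_peaks) out[i + j - 1] <- out[i + j - 1] + a[i] * b[j]
      }
    }
    out
  }
  v <- c(1, numeric(n_peaks - 1))
  for (el in names(composition)) {
    rows <- iso[iso$element == el, ]
    d <- numeric(n_peaks)
    keep <- rows$nominal_shift < n_peaks
    d[rows$nominal_shift[keep] + 1] <- rows$abundance[keep]
    d <- d / sum(rows$abundance)
    k <- composition[[el]]
    if (k > 0) for (a in seq_len(k)) v <- conv(v, d)
  }
  v / sum(v)
}

random_chain <- function(n, letters_pool = amino_acid_table()$letter) {
  paste0(sample(letters_pool, n, replace = TRUE), collapse = "")
}

toy_chains <- function() read_chains(system.file("extdata", "synthetic_igg1.fasta",
                                                 package = "mampep"))
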