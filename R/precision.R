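#' Relative standard deviation (percent)
#'
#' `100 * sample standard deviation / mean`, the precision metric of
#' analytical chemistry, using the sample (n - 1) standard deviation.
#' Fewer than two finite values, or a zero mean, give `NA` (undefined,
#' flagged) rather than an error.
#'
#' @param values Numeric vector.
#' @return RSD in percent, or `NA_real_` when undefined.
#' @examples
#' rsd(c(87.01, 88.49, 90.73, 88.79)) # about 1.72
#' @export
rsd <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 2) return(NA_real_)
  m <- mean(v)
  if (m == 0) return(NA_real_)
  100 * stats::sd(v) / m
}

#' Intra- and inter-laboratory precision by one-way ANOVA
#'
#' Fits, per attribute, a one-way ANOVA with laboratory as the factor and
#' derives: repeatability (within-laboratory) variance = within mean
#' square; between-laboratory variance component
#' `max(0, (between MS - within MS) / n0)` with `n0` the effective cell
#' size for unbalanced designs; intra-laboratory RSD from the within MS and
#' inter-laboratory RSD from the total (within + between) variance, both
#' relative to the grand mean. A second, simpler inter-laboratory figure —
#' the RSD of the laboratory means — is reported alongside, clearly
#' labelled, since published inter-laboratory RSDs are often computed that
#' way. Undefined attribute values (`NA`) are excluded; cells left with
#' fewer than two replicates are dropped and reported.
#'
#' @param data Tidy tibble with one row per replicate measurement.
#' @param value,lab,attribute Column names (strings) for the measured value,
#'   the laboratory factor and the attribute grouping.
#' @return A `mam_precision` tibble: one row per attribute with columns
#'   `grand_mean`, `intra_rsd`, `inter_rsd_means`, `inter_rsd_pooled`,
#'   `between_ms`, `within_ms`, `f_stat`, `p_value`, `var_within`,
#'   `var_between`, `n_labs`, `n_total`, `dropped_cells`. Per-laboratory
#'   means and RSDs are available via [generics::tidy()].
#' @export
anova_precision <- function(data, value = "value", lab = "lab",
                            attribute = "attribute") {
  df <- tibble(attribute = if (attribute %in% names(data)) data[[attribute]] else "attribute",
               lab = data[[lab]], value = data[[value]])
  df <- df[is.finite(df$value), ]
  if (nrow(df) == 0) abort("no usable values")
  per_attr <- function(d) {
    cell_n <- d |> count(.data$lab)
    keep <- cell_n$lab[cell_n$n >= 2]
    dropped <- setdiff(unique(d$lab), keep)
    d <- d[d$lab %in% keep, ]
    if (length(keep) < 2) abort("need at least 2 laboratories with >= 2 replicates each")
    k <- length(keep)
    N <- nrow(d)
    grand <- mean(d$value)
    lab_stats <- d |> group_by(.data$lab) |>
      summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                n = dplyr::n(), .groups = "drop") |>
      mutate(rsd = ifelse(.data$mean != 0, 100 * .data$sd / .data$mean, NA_real_))
    ss_between <- sum(lab_stats$n * (lab_stats$mean - grand)^2)
    ss_within <- sum((d$value - lab_stats$mean[match(d$lab, lab_stats$lab)])^2)
    ms_between <- ss_between / (k - 1)
    ms_within <- ss_within / (N - k)
    n0 <- (N - sum(lab_stats$n^2) / N) / (k - 1)
    var_within <- ms_within
    var_between <- max(0, (ms_between - ms_within) / n0)
    f_stat <- if (ms_within > 0) ms_between / ms_within else NA_real_
    p_value <- if (is.finite(f_stat)) stats::pf(f_stat, k - 1, N - k, lower.tail = FALSE)
               else NA_real_
    tibble(
      grand_mean = grand,
      intra_rsd = if (grand != 0) 100 * sqrt(var_within) / grand else NA_real_,
      inter_rsd_means = rsd(lab_stats$mean),
      inter_rsd_pooled = if (grand != 0) 100 * sqrt(var_within + var_between) / grand
                         else NA_real_,
      between_ms = ms_between, within_ms = ms_within,
      f_stat = f_stat, p_value = p_value,
      var_within = var_within, var_between = var_between,
      n_labs = k, n_total = N,
      dropped_cells = length(dropped),
      labs = list(lab_stats)
    )
  }
  out <- df |>
    group_by(attribute = .data$attribute) |>
    group_modify(~ per_attr(.x)) |>
    ungroup()
  class(out) <- c("mam_precision", class(out))
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-laboratory means and RSDs of a precision fit
#' @param x A `mam_precision` object.
#' @param ... Unused.
#' @method tidy mam_precision
#' @export
tidy.mam_precision <- function(x, ...) {
  x |>
    as_tibble() |>
    select("attribute", "labs") |>
    tidyr::unnest("labs")
}

#' One-row-per-attribute summary of a precision fit
#' @param x A `mam_precision` object.
#' @param ... Unused.
#' @method glance mam_precision
#' @export
glance.mam_precision <- function(x, ...) {
  x |> as_tibble() |> select(-"labs")
}

#' Degradation-series trend summary
#'
#' Per attribute (and optional site), summarises replicate attribute values
#' at each time point: mean, RSD, delta versus the first time point, and a
#' monotone-increase flag across time-point means. Missing first time
#' points flag the deltas rather than erroring.
#'
#' @param data Tidy tibble with columns for attribute, time point and value
#'   (replicates as repeated rows); time points are ordered numerically.
#' @param value,timepoint,attribute Column names (strings).
#' @return A tibble per attribute x timepoint with `mean`, `rsd`, `n`,
#'   `delta_vs_t0`, `monotone_increasing` (per attribute).
#' @export
trend_summary <- function(data, value = "value", timepoint = "timepoint",
                          attribute = "attribute") {
  df <- tibble(attribute = data[[attribute]], timepoint = data[[timepoint]],
               value = data[[value]])
  if (length(unique(df$timepoint)) < 2) abort("need at least 2 time points")
  out <- df |>
    group_by(.data$attribute, .data$timepoint) |>
    summarise(mean = mean(.data$value, na.rm = TRUE),
              rsd = rsd(.data$value), n = sum(is.finite(.data$value)),
              .groups = "drop_last") |>
    arrange(.data$timepoint, .by_group = TRUE) |>
    mutate(
      t0_mean = .data$mean[1],
      delta_vs_t0 = ifelse(is.finite(.data$t0_mean), .data$mean - .data$t0_mean, NA_real_),
      monotone_increasing = all(diff(.data$mean[is.finite(.data$mean)]) > 0)
    ) |>
    ungroup() |>
    select(-"t0_mean")
  out
}
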