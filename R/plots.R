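#' @import ggplot2
NULL

#' Plot a sequence coverage map with recovery classes
#'
#' One horizontal bar per chain, residues coloured by MS1 recovery class
#' (relative summed area of spanning identified peptides), red for the best
#' recovered stretches through grey for residues below 1 percent.
#'
#' @param coverage Output of [coverage_map()].
#' @return A ggplot object.
#' @export
plot_coverage_map <- function(coverage) {
  pal <- c(">50%" = "#c0392b", ">20%" = "#e67e22", ">10%" = "#f1c40f",
           ">5%" = "#27ae60", ">2%" = "#2980b9", ">1%" = "#5dade2",
           "<=1%" = "grey85")
  df <- coverage$residues |>
    mutate(class = factor(.data$class, levels = names(pal)))
  ggplot(df, aes(x = .data$position, y = .data$chain_id, fill = .data$class)) +
    geom_tile(height = 0.6) +
    scale_fill_manual(values = pal, drop = FALSE, name = "MS1 recovery") +
    labs(x = "Residue position", y = NULL,
         title = "Sequence coverage map") +
    theme_minimal()
}

#' Plot a glycoform profile across laboratories
#'
#' Grouped bars of the relative abundance of each glycoform (mean over
#' replicates per laboratory), mirroring the usual site-profile comparison
#' figure.
#'
#' @param profile Output of [glycan_profile()].
#' @return A ggplot object.
#' @export
plot_glycan_profile <- function(profile) {
  df <- profile |>
    filter(.data$defined) |>
    group_by(.data$lab, .data$attribute) |>
    summarise(value = mean(.data$value), .groups = "drop") |>
    mutate(lab = factor(.data$lab))
  ggplot(df, aes(x = .data$attribute, y = .data$value, fill = .data$lab)) +
    geom_col(position = position_dodge()) +
    labs(x = NULL, y = "Relative abundance (%)", fill = "Laboratory",
         title = "Glycoform profile") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' Plot degradation-series trends
#'
#' Attribute means against time point with one line per attribute.
#'
#' @param trend Output of [trend_summary()].
#' @return A ggplot object.
#' @export
plot_trend <- function(trend) {
  ggplot(trend, aes(x = .data$timepoint, y = .data$mean,
                    colour = .data$attribute, group = .data$attribute)) +
    geom_line() + geom_point() +
    labs(x = "Time point", y = "Relative abundance (%)", colour = NULL,
         title = "Forced-degradation trends") +
    theme_minimal()
}

#' Bar chart of per-laboratory attribute means from a precision fit
#'
#' @param object A `mam_precision` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mam_precision
#' @export
autoplot.mam_precision <- function(object, ...) {
  df <- tidy(object) |> mutate(lab = factor(.data$lab))
  ggplot(df, aes(x = .data$attribute, y = .data$mean, fill = .data$lab)) +
    geom_col(position = position_dodge()) +
    geom_errorbar(aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
                  position = position_dodge(width = 0.9), width = 0.3) +
    labs(x = NULL, y = "Relative abundance (%)", fill = "Laboratory") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
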