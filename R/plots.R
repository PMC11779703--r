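# ggplot2 views of the main result types.

#' Plot a diversity profile
#'
#' Per-position between-group divergence and within-group diversities,
#' with optional screen-threshold guides.
#'
#' @param profile a [diversity_profile()].
#' @param inter_min,intra_max optional horizontal guides at the screen
#'   thresholds (defaults 0.37 and 0.19; NULL omits them).
#' @return a ggplot object.
#' @export
plot_diversity_profile <- function(profile, inter_min = 0.37,
                                   intra_max = 0.19) {
  groups <- attr(profile, "groups")
  long <- profile |>
    select("position", "inter_pi", dplyr::all_of(paste0("intra_", groups))) |>
    tidyr::pivot_longer(-"position", names_to = "series",
                        values_to = "pi") |>
    mutate(series = sub("^intra_", "within ", .data$series),
           series = sub("^inter_pi$", "between groups", .data$series))
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$position, .data$pi,
                                          color = .data$series)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "alignment position", y = "nucleotide diversity",
                  color = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(inter_min)) {
    p <- p + ggplot2::geom_hline(yintercept = inter_min, linetype = "dashed")
  }
  if (!is.null(intra_max)) {
    p <- p + ggplot2::geom_hline(yintercept = intra_max, linetype = "dotted")
  }
  p
}

#' Plot a base-preference matrix as a logo-style tile map
#'
#' @param pref a [base_preference()] tibble.
#' @return a ggplot object (per-group facets, base frequency by position).
#' @export
plot_base_preference <- function(pref) {
  long <- tidyr::pivot_longer(pref, dplyr::all_of(c("A", "C", "G", "T")),
                              names_to = "base", values_to = "freq")
  ggplot2::ggplot(long, ggplot2::aes(factor(.data$position), .data$base,
                                     fill = .data$freq)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(.data$freq >= 0.5,
                                                   .data$base, "")),
                       size = 3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$species), ncol = 1) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "alignment position", y = NULL, fill = "frequency") +
    ggplot2::theme_minimal()
}

#' Plot digestion fragments as a schematic gel
#'
#' @param digests a [differential_digest()] tibble (or rows of it).
#' @return a ggplot object: one lane per allele per enzyme, bands at
#'   fragment lengths on a log scale.
#' @export
plot_digest <- function(digests) {
  lanes <- purrr::map_dfr(seq_len(nrow(digests)), function(i) {
    bind_rows(
      tibble(lane = paste(digests$enzyme[i], "allele A"),
             length = digests$fragments_a[[i]]),
      tibble(lane = paste(digests$enzyme[i], "allele B"),
             length = digests$fragments_b[[i]]),
      tibble(lane = paste(digests$enzyme[i], "hybrid"),
             length = digests$hybrid_bands[[i]])
    )
  })
  ggplot2::ggplot(lanes, ggplot2::aes(.data$lane, .data$length)) +
    ggplot2::geom_tile(width = 0.6, height = 6) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "fragment length (bp)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot a fitted Cq standard curve
#'
#' @param object a [fit_standard_curve()] object.
#' @param ... unused.
#' @return a ggplot object: points and fitted line of Cq against log10
#'   copies.
#' @export
autoplot.lamp_standard_curve <- function(object, ...) {
  d <- object$fit$model
  ggplot2::ggplot(d, ggplot2::aes(.data$log10_copies, .data$cq)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept,
                         slope = object$slope, color = "steelblue") +
    ggplot2::labs(
      x = "log10 template copies", y = "Cq (min)",
      subtitle = sprintf("Cq = %.2f %+.2f log10(copies), r^2 = %.3f",
                         object$intercept, object$slope, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
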