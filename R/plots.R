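#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an ANOSIM permutation null distribution
#'
#' Histogram of the permuted R values with the observed R marked.
#'
#' @param object A `prey_anosim` object with permutations run.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.prey_anosim <- function(object, ...) {
  if (length(object$perm_R) == 0L) {
    stop("no permutation null values stored; rerun with n_permutations > 0",
         call. = FALSE)
  }
  df <- tibble::tibble(R = object$perm_R)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$R)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$R, colour = "firebrick",
                        linewidth = 1) +
    ggplot2::labs(
      x = "ANOSIM R under permuted group labels",
      y = "count",
      title = sprintf("Observed R = %.3f, p = %.3g", object$R, object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-sample prey per cm by species
#'
#' Boxplot with jittered per-sample points, the package's analogue of a
#' prey-quantity comparison figure.
#'
#' @param object A `prey_quant` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.prey_quant <- function(object, ...) {
  ggplot2::ggplot(object$per_sample,
                  ggplot2::aes(x = .data$species, y = .data$prey_per_cm)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey85") +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.7) +
    ggplot2::labs(x = NULL, y = "prey items per cm leaf length") +
    ggplot2::theme_minimal()
}

#' Bar chart of per-taxon presence percentages
#'
#' The package's analogue of an order-level prey-spectrum figure: the
#' percentage of samples in which each taxon was detected, optionally per
#' species.
#'
#' @param pm A [build_presence_matrix()] result.
#' @param scope `"overall"` or `"per_species"`.
#' @param top_n Show only the `top_n` most frequent taxa (default all).
#' @return A ggplot object.
#' @export
plot_presence_percentages <- function(pm, scope = c("overall", "per_species"),
                                      top_n = Inf) {
  scope <- match.arg(scope)
  pct <- presence_percentages(pm, scope, digits = 1)
  keep <- utils::head(unique(pct$taxon), top_n)
  pct <- pct[pct$taxon %in% keep, ]
  pct$taxon <- factor(pct$taxon, levels = rev(keep))
  p <- ggplot2::ggplot(pct, ggplot2::aes(x = .data$percent, y = .data$taxon)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "% of samples with taxon detected", y = NULL) +
    ggplot2::theme_minimal()
  if (scope == "per_species") p <- p + ggplot2::facet_wrap(~species)
  p
}
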