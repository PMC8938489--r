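#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an ANOSIM result
#'
#' @param x A `prey_anosim` object.
#' @param ... Unused.
#' @return One-row tibble: `statistic` (R), `p.value`, `n.permutations`,
#'   `exact`, `n.samples`, `n.groups`.
#' @export
tidy.prey_anosim <- function(x, ...) {
  tibble::tibble(
    statistic = x$R, p.value = x$p_value, n.permutations = x$n_permutations,
    exact = x$exact, n.samples = x$n, n.groups = length(unique(x$groups))
  )
}

#' @rdname tidy.prey_anosim
#' @export
glance.prey_anosim <- function(x, ...) tidy.prey_anosim(x, ...)

#' Tidy a SIMPER decomposition
#'
#' @param x A `prey_simper` tibble.
#' @param ... Unused.
#' @return The taxon contribution table as a plain tibble.
#' @export
tidy.prey_simper <- function(x, ...) {
  out <- x
  attr(out, "average_dissimilarity") <- NULL
  attr(out, "pair") <- NULL
  class(out) <- setdiff(class(out), "prey_simper")
  tibble::as_tibble(out)
}

#' @rdname tidy.prey_simper
#' @export
glance.prey_simper <- function(x, ...) {
  tibble::tibble(
    average_dissimilarity = attr(x, "average_dissimilarity"),
    n_taxa = nrow(x),
    group_a = attr(x, "pair")[1],
    group_b = attr(x, "pair")[2]
  )
}

#' Tidy a prey-quantity result
#'
#' @param x A `prey_quant` object.
#' @param ... Unused.
#' @return `tidy()`: the Dunn-Bonferroni pairwise table. `glance()`: a
#'   one-row tibble with the Kruskal-Wallis `statistic`, `df` and
#'   `p.value`.
#' @export
tidy.prey_quant <- function(x, ...) x$pairwise

#' @rdname tidy.prey_quant
#' @export
glance.prey_quant <- function(x, ...) {
  tibble::tibble(statistic = x$kruskal$H, df = x$kruskal$df,
                 p.value = x$kruskal$p_value)
}
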