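#' Prey items per cm of trapping-leaf length
#'
#' Divides the per-sample photo prey count by the summed length of the
#' five collected leaves (equivalently count / (5 x mean leaf length)).
#' Doubling all leaf lengths halves the value.
#'
#' @param samples Sample metadata tibble: `sample_id`, `species`,
#'   `leaf_len_1_cm` ... `leaf_len_5_cm` (each > 0), `total_prey_count`.
#' @return The input tibble with `total_leaf_cm` and `prey_per_cm`
#'   columns added.
#' @examples
#' s <- tibble::tibble(sample_id = "x", species = "sp",
#'                     leaf_len_1_cm = 10, leaf_len_2_cm = 10,
#'                     leaf_len_3_cm = 10, leaf_len_4_cm = 10,
#'                     leaf_len_5_cm = 10, total_prey_count = 50L)
#' prey_per_cm(s)$prey_per_cm  # 1
#' @export
prey_per_cm <- function(samples) {
  leaf_cols <- grep("^leaf_len_\\d+_cm$", names(samples), value = TRUE)
  if (length(leaf_cols) == 0L) stop("no leaf_len_<i>_cm columns found", call. = FALSE)
  lm <- as.matrix(samples[leaf_cols])
  if (any(lm <= 0)) stop("leaf lengths must be positive", call. = FALSE)
  if (any(samples$total_prey_count < 0)) stop("prey counts must be >= 0", call. = FALSE)
  samples$total_leaf_cm <- rowSums(lm)
  samples$prey_per_cm <- samples$total_prey_count / samples$total_leaf_cm
  samples
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic with the chi-square approximation on
#' `length(groups) - 1` degrees of freedom (wraps [stats::kruskal.test()]).
#'
#' @param values_by_group Named list of numeric vectors, one per group.
#' @return Tibble with `H`, `df`, `p_value`.
#' @export
kruskal_wallis <- function(values_by_group) {
  check_groups(values_by_group)
  if (length(unique(unlist(values_by_group))) == 1L) {
    return(tibble::tibble(H = 0, df = length(values_by_group) - 1L, p_value = 1))
  }
  kt <- stats::kruskal.test(values_by_group)
  tibble::tibble(H = unname(kt$statistic), df = unname(kt$parameter),
                 p_value = kt$p.value)
}

check_groups <- function(values_by_group) {
  if (length(values_by_group) < 2L) stop("need at least two groups", call. = FALSE)
  sizes <- lengths(values_by_group)
  if (any(sizes < 2L)) {
    stop("every group needs at least two values; offending group(s): ",
         paste(names(values_by_group)[sizes < 2L], collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Dunn's post-hoc pairwise comparisons with Bonferroni correction
#'
#' Dunn's z on the pooled mid-ranks with tie correction:
#' `z = (rbar_i - rbar_j) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j))`
#' with `T = sum(t^3 - t)` over tie groups. Two-sided p-values are
#' multiplied by the number of pairs and capped at 1.
#'
#' @param values_by_group Named list of numeric vectors, one per group.
#' @return Tibble: `group_a`, `group_b`, `z`, `p_value` (unadjusted),
#'   `p_adjusted`.
#' @export
dunn_bonferroni <- function(values_by_group) {
  check_groups(values_by_group)
  k <- length(values_by_group)
  if (is.null(names(values_by_group))) {
    names(values_by_group) <- paste0("group", seq_len(k))
  }
  x <- unlist(values_by_group, use.names = FALSE)
  g <- rep(names(values_by_group), lengths(values_by_group))
  N <- length(x)
  rk <- rank(x)
  tie_tab <- table(x)
  tie_T <- sum(tie_tab^3 - tie_tab)
  var_term <- N * (N + 1) / 12 - tie_T / (12 * (N - 1))
  rbar <- tapply(rk, g, mean)
  nn <- tapply(rk, g, length)
  pairs <- utils::combn(names(values_by_group), 2, simplify = FALSE)
  n_pairs <- length(pairs)
  purrr::map_dfr(pairs, function(pr) {
    se <- sqrt(var_term * (1 / nn[[pr[1]]] + 1 / nn[[pr[2]]]))
    z <- if (se > 0) (rbar[[pr[1]]] - rbar[[pr[2]]]) / se else 0
    p <- 2 * stats::pnorm(-abs(z))
    tibble::tibble(group_a = pr[1], group_b = pr[2], z = z,
                   p_value = p, p_adjusted = min(1, p * n_pairs))
  })
}

#' Photo-derived prey quantification and group comparison
#'
#' Computes per-sample prey per cm of leaf length, per-species mean and
#' SD, the Kruskal-Wallis test across species and Dunn-Bonferroni
#' post-hoc pairwise comparisons.
#'
#' @param samples Sample metadata tibble (see [prey_per_cm()]).
#' @return A `prey_quant` object: list with `per_sample` (input plus
#'   `prey_per_cm`), `per_species` (`species`, `n`, `mean`, `sd`,
#'   `mean_leaf_cm`, `sd_leaf_cm`), `kruskal` (tibble `H`, `df`,
#'   `p_value`), `pairwise` (Dunn tibble).
#' @export
prey_quantity <- function(samples) {
  per_sample <- prey_per_cm(samples)
  leaf_cols <- grep("^leaf_len_\\d+_cm$", names(samples), value = TRUE)
  per_species <- dplyr::summarise(
    dplyr::group_by(per_sample, .data$species),
    n = dplyr::n(),
    mean = mean(.data$prey_per_cm),
    sd = stats::sd(.data$prey_per_cm),
    mean_leaf_cm = mean(rowMeans(dplyr::pick(dplyr::all_of(leaf_cols)))),
    sd_leaf_cm = stats::sd(rowMeans(dplyr::pick(dplyr::all_of(leaf_cols)))),
    .groups = "drop"
  )
  by_group <- split(per_sample$prey_per_cm, per_sample$species)
  structure(
    list(per_sample = per_sample,
         per_species = per_species,
         kruskal = kruskal_wallis(by_group),
         pairwise = dunn_bonferroni(by_group)),
    class = "prey_quant"
  )
}

#' @export
print.prey_quant <- function(x, ...) {
  cat("Prey quantity per cm leaf length\n")
  for (i in seq_len(nrow(x$per_species))) {
    cat(sprintf("  %-20s %.2f +/- %.2f (n = %d)\n",
                x$per_species$species[i], x$per_species$mean[i],
                x$per_species$sd[i], x$per_species$n[i]))
  }
  cat(sprintf("  Kruskal-Wallis H = %.2f, df = %d, p = %.3g\n",
              x$kruskal$H, x$kruskal$df, x$kruskal$p_value))
  invisible(x)
}
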