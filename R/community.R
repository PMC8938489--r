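#' Build a presence/absence matrix from a detection table
#'
#' A cell is `TRUE` iff the sample has at least one non-excluded
#' (candidate or confirmed) detection of the taxon. At `level = "order"`
#' family columns are OR-aggregated into their orders, with
#' `"Other <Order>"` pseudo-families contributing to their order.
#' Taxa never present are dropped (they cannot affect Bray-Curtis but
#' would distort taxon counts).
#'
#' @param dt Finalized detection tibble (statuses set).
#' @param level `"family"` or `"order"`.
#' @param groups Optional tibble (`sample_id`, `species`) or named
#'   character vector mapping sample ids to group labels; stored for the
#'   group-comparison statistics. Samples listed here but absent from `dt`
#'   get all-`FALSE` rows.
#' @return A `presence_matrix`: tibble with `sample_id` plus one logical
#'   column per taxon; attributes `level` and `groups` (named character
#'   vector or `NULL`).
#' @export
build_presence_matrix <- function(dt, level = c("family", "order"), groups = NULL) {
  level <- match.arg(level)
  keep <- dt[dt$status %in% c("candidate", "confirmed"), ]
  if (nrow(keep) == 0L) {
    stop("no non-excluded detections: cannot build a presence matrix", call. = FALSE)
  }
  keep$col <- if (level == "family") keep$taxon else keep$order
  grp <- normalize_groups(groups)
  sids <- if (!is.null(grp)) names(grp) else sort(unique(keep$sample_id))
  taxa <- sort(unique(keep$col))
  m <- matrix(FALSE, length(sids), length(taxa), dimnames = list(sids, taxa))
  m[cbind(match(keep$sample_id, sids), match(keep$col, taxa))] <- TRUE
  pm <- dplyr::bind_cols(tibble::tibble(sample_id = sids), tibble::as_tibble(m))
  attr(pm, "level") <- level
  attr(pm, "groups") <- grp
  class(pm) <- c("presence_matrix", class(pm))
  pm
}

normalize_groups <- function(groups) {
  if (is.null(groups)) return(NULL)
  if (is.data.frame(groups)) {
    stopifnot(all(c("sample_id", "species") %in% names(groups)))
    return(stats::setNames(as.character(groups$species), groups$sample_id))
  }
  stopifnot(!is.null(names(groups)))
  stats::setNames(as.character(groups), names(groups))
}

pm_matrix <- function(pm) {
  m <- as.matrix(pm[setdiff(names(pm), "sample_id")])
  rownames(m) <- pm$sample_id
  storage.mode(m) <- "integer"
  m
}

pm_groups <- function(pm, groups = NULL) {
  g <- normalize_groups(groups)
  if (is.null(g)) g <- attr(pm, "groups")
  if (is.null(g)) stop("no sample-to-group mapping available", call. = FALSE)
  unname(g[pm$sample_id])
}

#' Per-taxon presence percentages
#'
#' Percentage of samples in which each taxon was detected, overall or per
#' species group.
#'
#' @param pm A [build_presence_matrix()] result.
#' @param scope `"overall"` or `"per_species"` (requires groups).
#' @param groups Optional group mapping overriding the one stored in `pm`.
#' @param digits Rounding of the percentage; default 0 (integer percent).
#' @return Tibble `taxon`, (`species`,) `n_present`, `n_samples`,
#'   `percent`.
#' @export
presence_percentages <- function(pm, scope = c("overall", "per_species"),
                                 groups = NULL, digits = 0) {
  scope <- match.arg(scope)
  m <- pm_matrix(pm)
  if (scope == "overall") {
    out <- tibble::tibble(
      taxon = colnames(m),
      n_present = unname(colSums(m)),
      n_samples = nrow(m)
    )
  } else {
    g <- pm_groups(pm, groups)
    out <- purrr::map_dfr(sort(unique(g)), function(sp) {
      sub <- m[g == sp, , drop = FALSE]
      tibble::tibble(species = sp, taxon = colnames(sub),
                     n_present = unname(colSums(sub)), n_samples = nrow(sub))
    })
  }
  out$percent <- round(100 * out$n_present / out$n_samples, digits)
  dplyr::arrange(out, dplyr::desc(.data$percent))
}

#' Binary Bray-Curtis (Sorensen) dissimilarity
#'
#' For presence/absence rows i and j with `a` shared taxa and `b`, `c`
#' taxa unique to each, `d = (b + c) / (2a + b + c)`. Two all-absent
#' samples are defined as identical (`d = 0`) with a warning.
#'
#' @param pm A [build_presence_matrix()] result, or any data frame with
#'   `sample_id` plus logical/0-1 taxon columns.
#' @return A [stats::dist] object labelled by sample id.
#' @examples
#' pm <- tibble::tibble(sample_id = c("s1", "s2"),
#'                      t1 = c(TRUE, TRUE), t2 = c(TRUE, FALSE),
#'                      t3 = c(TRUE, TRUE), t4 = c(FALSE, TRUE))
#' binary_bray_curtis(pm)  # (1+1)/(2*2+1+1) = 1/3
#' @export
binary_bray_curtis <- function(pm) {
  m <- pm_matrix(pm)
  if (nrow(m) < 2L) stop("need at least two samples", call. = FALSE)
  tot <- rowSums(m)
  shared <- m %*% t(m)                      # a for every pair
  d <- matrix(0, nrow(m), nrow(m))
  denom <- outer(tot, tot, "+")             # 2a + b + c
  num <- denom - 2 * shared                 # b + c
  empty_pair <- denom == 0
  if (any(empty_pair[lower.tri(empty_pair)])) {
    warning("pairs of all-absent samples: dissimilarity defined as 0", call. = FALSE)
  }
  d[!empty_pair] <- num[!empty_pair] / denom[!empty_pair]
  rownames(d) <- rownames(m)
  stats::as.dist(d)
}

# mean between/within ranks -> Clarke's R with divisor n(n-1)/4
anosim_R_from_ranks <- function(rk, between) {
  n_pairs <- length(rk)
  n <- (1 + sqrt(1 + 8 * n_pairs)) / 2
  (mean(rk[between]) - mean(rk[!between])) / (n * (n - 1) / 4)
}

pair_between <- function(g) {
  n <- length(g)
  gi <- matrix(g, n, n)
  as.vector(stats::as.dist(gi != t(gi))) > 0
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based test of group separation on a dissimilarity matrix:
#' `R = (mean between-group rank - mean within-group rank) / (n(n-1)/4)`,
#' with mid-ranks for ties. `R` is near 0 under no structure and 1 when
#' every between-group dissimilarity exceeds every within-group one. The
#' p-value comes from random permutations of the group labels using the
#' `(count >= observed + 1) / (n_permutations + 1)` estimator, or from
#' exhaustive enumeration of all distinct labellings when
#' `exact = TRUE`.
#'
#' @param d A [stats::dist] object (see [binary_bray_curtis()]).
#' @param groups Group label per sample, in `d`'s sample order, or a
#'   named vector/tibble matched by `d`'s labels.
#' @param n_permutations Number of random label permutations (default
#'   999). `0` skips the test (p is `NA`).
#' @param seed Integer seed making the permutation p reproducible.
#' @param exact Enumerate all distinct labellings instead of sampling
#'   (feasible for small designs only).
#' @return A `prey_anosim` object: list with `R`, `p_value`, `n_permutations`
#'   (or number of enumerated labellings), `seed`, `exact`, `perm_R`
#'   (permutation null values), `groups`, `n`.
#' @export
anosim <- function(d, groups, n_permutations = 999, seed = NULL, exact = FALSE) {
  stopifnot(inherits(d, "dist"))
  n <- attr(d, "Size")
  g <- resolve_group_labels(groups, d)
  tab <- table(g)
  if (length(tab) < 2L) stop("ANOSIM needs at least two groups", call. = FALSE)
  if (any(tab < 2L)) {
    stop("every group needs at least two samples; offending group(s): ",
         paste(names(tab)[tab < 2L], collapse = ", "), call. = FALSE)
  }
  dv <- as.vector(d)
  rk <- rank(dv)  # mid-ranks for ties
  all_tied <- length(unique(dv)) == 1L
  if (all_tied) warning("all dissimilarities tied; R = 0", call. = FALSE)
  obs <- anosim_R_from_ranks(rk, pair_between(g))

  if (exact) {
    labellings <- multiset_permutations(g)
    perm_R <- vapply(labellings, function(gg) anosim_R_from_ranks(rk, pair_between(gg)),
                     numeric(1))
    p <- mean(perm_R >= obs - 1e-12)  # observed labelling is in the enumeration
    np <- length(labellings)
  } else if (n_permutations > 0L) {
    perm_R <- withr::with_seed(
      if (is.null(seed)) stats::runif(1, 1, 2^30) else seed,
      vapply(seq_len(n_permutations), function(i) {
        anosim_R_from_ranks(rk, pair_between(sample(g)))
      }, numeric(1))
    )
    p <- (sum(perm_R >= obs - 1e-12) + 1) / (n_permutations + 1)
    np <- n_permutations
  } else {
    perm_R <- numeric(0)
    p <- NA_real_
    np <- 0L
  }
  structure(
    list(R = obs, p_value = p, n_permutations = np,
         seed = seed, exact = exact, perm_R = perm_R, groups = g, n = n),
    class = "prey_anosim"
  )
}

resolve_group_labels <- function(groups, d) {
  labs <- attr(d, "Labels")
  if (is.data.frame(groups)) groups <- normalize_groups(groups)
  if (!is.null(names(groups)) && !is.null(labs)) {
    if (!all(labs %in% names(groups))) {
      stop("group mapping does not cover all samples in the distance matrix",
           call. = FALSE)
    }
    groups <- groups[labs]
  }
  if (length(groups) != attr(d, "Size")) {
    stop("`groups` length does not match the distance matrix", call. = FALSE)
  }
  as.character(groups)
}

# all distinct permutations of a label multiset (exponential; small n only)
multiset_permutations <- function(g) {
  g <- as.character(g)
  lev <- sort(unique(g))
  counts <- as.integer(table(factor(g, levels = lev)))
  n <- length(g)
  out <- list()
  rec <- function(pos, counts, current) {
    if (pos > n) {
      out[[length(out) + 1L]] <<- current
      return(invisible())
    }
    for (i in seq_along(lev)) {
      if (counts[i] > 0L) {
        counts[i] <- counts[i] - 1L
        current[pos] <- lev[i]
        rec(pos + 1L, counts, current)
        counts[i] <- counts[i] + 1L
      }
    }
  }
  rec(1L, counts, character(n))
  out
}

#' @export
print.prey_anosim <- function(x, ...) {
  cat("ANOSIM (", length(unique(x$groups)), " groups, n = ", x$n, ")\n", sep = "")
  cat(sprintf("  R = %.4f\n", x$R))
  if (is.na(x$p_value)) {
    cat("  p  = NA (no permutations run)\n")
  } else {
    cat(sprintf("  p  = %.4g (%s, %d labellings)\n", x$p_value,
                if (x$exact) "exact enumeration" else "permutation", x$n_permutations))
  }
  invisible(x)
}

#' Pairwise ANOSIM between all group pairs
#'
#' Runs one ANOSIM per unordered group pair on the sub-matrix of that
#' pair's samples; dissimilarities are recomputed on the subset rather
#' than sliced from the global ranking.
#'
#' @param pm A [build_presence_matrix()] result.
#' @param groups Group mapping (defaults to the one stored in `pm`).
#' @param n_permutations,seed As in [anosim()].
#' @param adjust Apply Bonferroni correction across pairs (off by
#'   default, matching common PRIMER-style reporting).
#' @return Tibble: `group_a`, `group_b`, `R`, `p_value`,
#'   (`p_adjusted`,) `n_a`, `n_b`, and an `anosim` list-column of the
#'   underlying `prey_anosim` objects.
#' @export
pairwise_anosim <- function(pm, groups = NULL, n_permutations = 999, seed = NULL,
                            adjust = FALSE) {
  g <- pm_groups(pm, groups)
  lev <- sort(unique(g))
  if (length(lev) < 2L) stop("need at least two groups", call. = FALSE)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  res <- purrr::imap_dfr(pairs, function(pr, k) {
    sel <- g %in% pr
    sub <- pm[sel, ]
    a <- anosim(binary_bray_curtis(sub), g[sel],
                n_permutations = n_permutations,
                seed = if (is.null(seed)) NULL else seed + k)
    tibble::tibble(group_a = pr[1], group_b = pr[2], R = a$R,
                   p_value = a$p_value, n_a = sum(g == pr[1]),
                   n_b = sum(g == pr[2]), anosim = list(a))
  })
  if (adjust) {
    res$p_adjusted <- pmin(1, res$p_value * nrow(res))
  }
  res
}

#' SIMPER: per-taxon contributions to between-group dissimilarity
#'
#' Decomposes the average between-group binary Bray-Curtis dissimilarity
#' into per-taxon contributions. For each between-group sample pair
#' (i, j), taxon k contributes
#' `100 * |x_ik - x_jk| / sum_l (x_il + x_jl)`; its overall contribution
#' is the mean over all between-group pairs, so taxon contributions sum
#' exactly to the average between-group percentage dissimilarity.
#'
#' @param pm A [build_presence_matrix()] result.
#' @param groups Group mapping (defaults to the one stored in `pm`).
#' @param pair Character vector of the two group labels to compare.
#' @return A `prey_simper` tibble sorted by contribution: `taxon`,
#'   `mean_contribution` (percentage points of dissimilarity),
#'   `percent_contribution`, `cumulative_percent`, `freq_a`, `freq_b`
#'   (presence frequencies in each group), `more_frequent_group`.
#'   Attribute `average_dissimilarity` holds the mean between-group
#'   dissimilarity in percent.
#' @export
simper <- function(pm, groups = NULL, pair) {
  g <- pm_groups(pm, groups)
  stopifnot(length(pair) == 2L)
  if (!all(pair %in% g)) stop("pair labels not found in groups", call. = FALSE)
  m <- pm_matrix(pm)
  A <- m[g == pair[1], , drop = FALSE]
  B <- m[g == pair[2], , drop = FALSE]
  contrib <- matrix(0, nrow(A) * nrow(B), ncol(m))
  row <- 0L
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      row <- row + 1L
      denom <- sum(A[i, ] + B[j, ])
      if (denom > 0) contrib[row, ] <- 100 * abs(A[i, ] - B[j, ]) / denom
    }
  }
  mean_contrib <- colMeans(contrib)
  avg_diss <- sum(mean_contrib)
  if (avg_diss <= 0) {
    stop("average between-group dissimilarity is zero; SIMPER is undefined ",
         "for identical groups", call. = FALSE)
  }
  freq_a <- colMeans(A)
  freq_b <- colMeans(B)
  out <- tibble::tibble(
    taxon = colnames(m),
    mean_contribution = mean_contrib,
    percent_contribution = 100 * mean_contrib / avg_diss,
    freq_a = freq_a,
    freq_b = freq_b,
    more_frequent_group = dplyr::case_when(
      freq_a > freq_b ~ pair[1],
      freq_b > freq_a ~ pair[2],
      TRUE ~ "tie"
    )
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$percent_contribution), .data$taxon)
  out$cumulative_percent <- cumsum(out$percent_contribution)
  out <- out[, c("taxon", "mean_contribution", "percent_contribution",
                 "cumulative_percent", "freq_a", "freq_b", "more_frequent_group")]
  attr(out, "average_dissimilarity") <- avg_diss
  attr(out, "pair") <- pair
  class(out) <- c("prey_simper", class(out))
  out
}
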