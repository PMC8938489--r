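# Independent oracles used to cross-check the package's implementations.
# These deliberately use naive, loop-based arithmetic so they share no code
# path with the functions under test.

RANKS6 <- c("phylum", "class", "order", "family", "genus", "species")

# longest common assigned prefix by rank-by-rank scan
oracle_lcp <- function(a, b) {
  out <- rep(NA_character_, 6L)
  for (i in 1:6) {
    ai <- a[i]; bi <- b[i]
    ok <- !is.na(ai) && !is.na(bi) &&
      tolower(trimws(ai)) == tolower(trimws(bi))
    if (!ok) break
    out[i] <- trimws(ai)
  }
  out
}

# random valid lineage (prefix of random depth) over a small name pool so
# that partial agreements are common
random_lineage <- function(depth = sample(0:6, 1)) {
  pool <- list(
    c("Arthropoda", "Chordata"),
    c("Insecta", "Arachnida"),
    c("Diptera", "Hemiptera", "Coleoptera"),
    c("Muscidae", "Calliphoridae", "Lygaeidae"),
    c("GenA", "GenB"),
    c("sp1", "sp2")
  )
  out <- rep(NA_character_, 6L)
  if (depth > 0) for (i in seq_len(depth)) out[i] <- sample(pool[[i]], 1)
  out
}

# naive ANOSIM R: explicit double loop over sample pairs
oracle_anosim_R <- function(d, g) {
  m <- as.matrix(d)
  n <- nrow(m)
  dv <- c(); between <- c()
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      dv <- c(dv, m[i, j])
      between <- c(between, g[i] != g[j])
    }
  }
  rk <- rank(dv)
  (mean(rk[between]) - mean(rk[!between])) / (n * (n - 1) / 4)
}

# enumerate all distinct labellings of the multiset g by filling group
# positions with nested combinations (independent of the package's
# recursive-permutation generator)
oracle_labellings <- function(g) {
  lev <- sort(unique(g))
  counts <- as.integer(table(factor(g, levels = lev)))
  n <- length(g)
  combine <- function(positions, li) {
    if (li > length(lev)) {
      v <- rep(NA_character_, n)
      return(list(v))
    }
    k <- counts[li]
    subs <- if (length(positions) == k) list(positions) else
      utils::combn(positions, k, simplify = FALSE)
    out <- list()
    for (s in subs) {
      for (tail in combine(setdiff(positions, s), li + 1)) {
        v <- tail
        v[s] <- lev[li]
        out[[length(out) + 1L]] <- v
      }
    }
    out
  }
  combine(seq_len(n), 1L)
}

# classical Kruskal-Wallis H by direct rank arithmetic (no ties assumed)
oracle_kruskal_H <- function(values_by_group) {
  x <- unlist(values_by_group)
  N <- length(x)
  rk <- rank(x)
  idx <- rep(seq_along(values_by_group), lengths(values_by_group))
  H <- 0
  for (i in seq_along(values_by_group)) {
    ri <- mean(rk[idx == i])
    H <- H + lengths(values_by_group)[i] * (ri - (N + 1) / 2)^2
  }
  unname(12 / (N * (N + 1)) * H)
}

# small random presence matrix as a tibble
random_presence <- function(n_samples, n_taxa, p = 0.5) {
  m <- matrix(stats::runif(n_samples * n_taxa) < p, n_samples, n_taxa)
  # avoid all-absent taxa columns and all-absent rows
  for (j in seq_len(n_taxa)) if (!any(m[, j])) m[sample(n_samples, 1), j] <- TRUE
  for (i in seq_len(n_samples)) if (!any(m[i, ])) m[i, sample(n_taxa, 1)] <- TRUE
  colnames(m) <- sprintf("tax%02d", seq_len(n_taxa))
  dplyr::bind_cols(tibble::tibble(sample_id = sprintf("s%02d", seq_len(n_samples))),
                   tibble::as_tibble(m))
}

# minimal detection tibble builder for filtering/plausibility tests
make_detections <- function(...) {
  rows <- list(...)
  purrr::map_dfr(rows, function(r) {
    tibble::tibble(
      sample_id = r$sample_id, taxon = r$taxon,
      level = r$level %||% "family",
      order = r$order, phylum = r$phylum %||% "Arthropoda",
      otu_ids = list(r$otu_ids %||% "OTU_X"),
      reads = r$reads %||% 100L,
      status = r$status %||% "candidate",
      exclusion_reason = NA_character_
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
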