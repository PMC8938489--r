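#' Taxonomic ranks used throughout the package
#'
#' The six Linnaean ranks carried by barcode identification tables, from
#' coarsest to finest. Sub-ranks (subfamily, tribe, ...) present in input
#' files are ignored.
#'
#' @format Character vector of length six.
#' @export
TAX_RANKS <- c("phylum", "class", "order", "family", "genus", "species")

# canonical form used for name comparison; display form is preserved
canon_name <- function(x) {
  x <- trimws(x)
  x[!nzchar(x)] <- NA_character_
  tolower(x)
}

#' Enforce the lineage prefix invariant on rank columns
#'
#' A valid lineage is assigned as a contiguous prefix of
#' phylum > class > order > family > genus > species: no rank may be
#' assigned below an unassigned one. Violations are repaired by truncating
#' at the first gap; the number of repaired rows is reported via a warning.
#'
#' @param df Data frame containing the columns in [TAX_RANKS] (character;
#'   `NA` or empty string means unassigned).
#' @param quiet Suppress the repair warning.
#' @return The input as a tibble with rank columns truncated to valid
#'   prefixes and empty strings replaced by `NA`.
#' @export
enforce_lineage_prefix <- function(df, quiet = FALSE) {
  df <- tibble::as_tibble(df)
  stopifnot(all(TAX_RANKS %in% names(df)))
  m <- as.matrix(df[TAX_RANKS])
  m[!is.na(m) & !nzchar(trimws(m))] <- NA_character_
  assigned <- !is.na(m)
  # deepest contiguous prefix per row
  keep_depth <- apply(assigned, 1L, function(a) {
    gap <- which(!a)
    if (length(gap) == 0L) length(a) else gap[1L] - 1L
  })
  repaired <- 0L
  for (i in seq_len(nrow(m))) {
    d <- keep_depth[i]
    if (d < length(TAX_RANKS) && any(assigned[i, (d + 1L):length(TAX_RANKS)])) {
      m[i, (d + 1L):length(TAX_RANKS)] <- NA_character_
      repaired <- repaired + 1L
    }
  }
  if (repaired > 0L && !quiet) {
    warning(repaired, " lineage(s) violated the prefix invariant and were truncated",
            call. = FALSE)
  }
  df[TAX_RANKS] <- as.data.frame(m, stringsAsFactors = FALSE)
  df
}

#' Depth of a lineage
#'
#' @param df Data frame with rank columns (prefix invariant assumed).
#' @return Integer vector: number of assigned ranks per row (0 = fully
#'   unassigned, 6 = assigned to species).
#' @export
lineage_depth <- function(df) {
  m <- as.matrix(df[TAX_RANKS])
  rowSums(!is.na(m) & nzchar(trimws(m)))
}

#' Read a per-OTU BLAST identification table
#'
#' Parses the CSV export of a BLAST identification run against one
#' reference database (BOLD- or GenBank-style). Required columns:
#' `otu_id`, `hit_pct_id`, and the six rank columns in [TAX_RANKS].
#' `process_id`, `bin` (BOLD only) and `hit_length` are carried through
#' when present; extra columns are ignored.
#'
#' @param path Path to the CSV file.
#' @param source_db `"BOLD"` or `"NCBI"`; recorded on every row.
#' @return Tibble with one row per OTU hit: `otu_id`, `source_db`,
#'   `process_id`, `bin`, `hit_pct_id`, `hit_length`, and the rank
#'   columns as valid lineage prefixes.
#' @export
parse_hit_table <- function(path, source_db = c("BOLD", "NCBI")) {
  source_db <- match.arg(source_db)
  if (!file.exists(path)) stop("hit table not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("otu_id", "hit_pct_id", TAX_RANKS)
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stop("hit table ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad_id <- which(is.na(raw$otu_id) | !nzchar(trimws(raw$otu_id)))
  if (length(bad_id) > 0L) {
    stop("rows with empty otu_id in ", path, ": ",
         paste(bad_id, collapse = ", "), call. = FALSE)
  }
  pct <- suppressWarnings(as.numeric(raw$hit_pct_id))
  bad_pct <- which(is.na(pct) | pct < 0 | pct > 100)
  if (length(bad_pct) > 0L) {
    stop("unparseable or out-of-range hit_pct_id in ", path, " at row(s): ",
         paste(bad_pct, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    otu_id = trimws(raw$otu_id),
    source_db = source_db,
    process_id = if ("process_id" %in% names(raw)) raw$process_id else NA_character_,
    bin = if ("bin" %in% names(raw)) raw$bin else NA_character_,
    hit_pct_id = pct,
    hit_length = if ("hit_length" %in% names(raw)) {
      suppressWarnings(as.integer(raw$hit_length))
    } else NA_integer_
  )
  out <- dplyr::bind_cols(out, raw[TAX_RANKS])
  enforce_lineage_prefix(out, quiet = TRUE)
}

#' Consensus of two taxonomic lineages
#'
#' The consensus keeps a rank only if every rank above it agrees and, at
#' the rank itself, both databases assign the same name (compared after
#' trimming and case-folding; original case of the first input is kept
#' for display). In `"strict"` mode a rank unassigned in either input
#' stops the consensus there; in `"lenient"` mode the assigned name is
#' inherited and the scan continues.
#'
#' @param a,b Character vectors of length six (one name or `NA` per rank,
#'   ordered as [TAX_RANKS]), each a valid prefix.
#' @param mode `"strict"` (default) or `"lenient"`.
#' @return Character vector of length six: the consensus lineage.
#' @examples
#' a <- c("Arthropoda", "Insecta", "Diptera", "Muscidae", NA, NA)
#' b <- c("Arthropoda", "Insecta", "Diptera", "Calliphoridae", NA, NA)
#' consensus_lineage(a, b)  # stops at order Diptera
#' @export
consensus_lineage <- function(a, b, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  stopifnot(length(a) == length(TAX_RANKS), length(b) == length(TAX_RANKS))
  out <- rep(NA_character_, length(TAX_RANKS))
  ca <- canon_name(a)
  cb <- canon_name(b)
  for (i in seq_along(TAX_RANKS)) {
    if (!is.na(ca[i]) && !is.na(cb[i])) {
      if (ca[i] == cb[i]) out[i] <- trimws(a[i]) else break
    } else if (mode == "lenient" && xor(is.na(ca[i]), is.na(cb[i]))) {
      out[i] <- if (is.na(ca[i])) trimws(b[i]) else trimws(a[i])
    } else {
      break
    }
  }
  out
}

#' Per-OTU consensus taxonomy across two identification tables
#'
#' Joins a BOLD-style and a GenBank-style hit table by `otu_id` and
#' computes the consensus lineage for every OTU. OTUs present in only one
#' table keep that table's lineage and are flagged `single_db`.
#'
#' @param bold_hits,ncbi_hits Tibbles as returned by [parse_hit_table()].
#' @param mode Consensus mode, see [consensus_lineage()].
#' @return Tibble with one row per OTU: `otu_id`, the consensus rank
#'   columns, `deepest_rank` (`"none"` if fully unassigned), `single_db`,
#'   `bold_pct_id`, `ncbi_pct_id`, `bin`.
#' @export
consensus_table <- function(bold_hits, ncbi_hits, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  for (tab in list(BOLD = bold_hits, NCBI = ncbi_hits)) {
    dup <- unique(tab$otu_id[duplicated(tab$otu_id)])
    if (length(dup) > 0L) {
      stop("duplicate otu_id within one hit table: ",
           paste(dup, collapse = ", "), call. = FALSE)
    }
  }
  ids <- union(bold_hits$otu_id, ncbi_hits$otu_id)
  bi <- match(ids, bold_hits$otu_id)
  ni <- match(ids, ncbi_hits$otu_id)
  bm <- as.matrix(bold_hits[TAX_RANKS])
  nm <- as.matrix(ncbi_hits[TAX_RANKS])
  cons <- matrix(NA_character_, nrow = length(ids), ncol = length(TAX_RANKS),
                 dimnames = list(NULL, TAX_RANKS))
  single <- logical(length(ids))
  for (k in seq_along(ids)) {
    in_b <- !is.na(bi[k]); in_n <- !is.na(ni[k])
    if (in_b && in_n) {
      cons[k, ] <- consensus_lineage(bm[bi[k], ], nm[ni[k], ], mode = mode)
    } else if (in_b) {
      cons[k, ] <- bm[bi[k], ]; single[k] <- TRUE
    } else {
      cons[k, ] <- nm[ni[k], ]; single[k] <- TRUE
    }
  }
  depth <- rowSums(!is.na(cons))
  tibble::tibble(
    otu_id = ids,
    tibble::as_tibble(cons),
    deepest_rank = ifelse(depth == 0L, "none", TAX_RANKS[pmax(depth, 1L)]),
    single_db = single,
    bold_pct_id = bold_hits$hit_pct_id[bi],
    ncbi_pct_id = ncbi_hits$hit_pct_id[ni],
    bin = bold_hits$bin[bi]
  )
}

#' Identification success by taxonomic rank
#'
#' For each rank, the fraction of OTUs whose consensus lineage reaches
#' that rank or deeper. Fractions are non-increasing from phylum to
#' species.
#'
#' @param records Consensus tibble from [consensus_table()].
#' @return Tibble with columns `rank`, `n_reaching`, `fraction`.
#' @export
rank_summary <- function(records) {
  if (nrow(records) == 0L) stop("rank_summary: empty consensus table", call. = FALSE)
  depth <- lineage_depth(records)
  n <- nrow(records)
  tibble::tibble(
    rank = TAX_RANKS,
    n_reaching = vapply(seq_along(TAX_RANKS), function(i) sum(depth >= i), integer(1)),
    fraction = vapply(seq_along(TAX_RANKS), function(i) mean(depth >= i), numeric(1))
  )
}
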