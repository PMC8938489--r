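#' Remove low-abundance read counts from an OTU table
#'
#' Cells below `threshold_fraction` of the read total are set to zero and
#' OTUs left without any reads are dropped. The denominator is the grand
#' total of the whole table by default; `denominator = "per_sample"`
#' instead thresholds each sample column against its own column total.
#' The threshold is computed once from the incoming table, so re-applying
#' the function with the same snapshot changes nothing.
#'
#' @param table Tibble with an `otu_id` column and one non-negative
#'   integer column per sample.
#' @param threshold_fraction Relative-abundance cutoff in `[0, 1)`;
#'   default `1e-4` (0.01\% of total reads).
#' @param denominator `"grand_total"` (default) or `"per_sample"`.
#' @return The cleaned tibble, with attributes `cells_zeroed` (tibble of
#'   removed cells: `otu_id`, `sample_id`, `count`) and `otus_dropped`
#'   (character vector).
#' @examples
#' tab <- tibble::tibble(otu_id = c("a", "b"), s1 = c(999901L, 99L))
#' clean_low_reads(tab)  # 99 reads fall below 0.01 percent of 1e6: "b" dropped
#' @export
clean_low_reads <- function(table, threshold_fraction = 1e-4,
                            denominator = c("grand_total", "per_sample")) {
  denominator <- match.arg(denominator)
  stopifnot(is.numeric(threshold_fraction), threshold_fraction >= 0,
            threshold_fraction < 1)
  if (!"otu_id" %in% names(table)) stop("OTU table must have an `otu_id` column",
                                        call. = FALSE)
  sample_cols <- setdiff(names(table), "otu_id")
  m <- as.matrix(table[sample_cols])
  if (nrow(m) == 0L || length(sample_cols) == 0L || sum(m) == 0) {
    warning("clean_low_reads: empty OTU table, returned unchanged", call. = FALSE)
    return(table)
  }
  if (any(m < 0)) stop("OTU table contains negative counts", call. = FALSE)
  cutoff <- if (denominator == "grand_total") {
    matrix(threshold_fraction * sum(m), nrow(m), ncol(m))
  } else {
    matrix(threshold_fraction * colSums(m), nrow(m), ncol(m), byrow = TRUE)
  }
  kill <- m > 0 & m < cutoff
  zeroed <- tibble::tibble(
    otu_id = table$otu_id[(which(kill) - 1L) %% nrow(m) + 1L],
    sample_id = sample_cols[(which(kill) - 1L) %/% nrow(m) + 1L],
    count = m[kill]
  )
  m[kill] <- 0L
  keep <- rowSums(m) > 0
  out <- dplyr::bind_cols(tibble::tibble(otu_id = table$otu_id),
                          tibble::as_tibble(m))[keep, ]
  attr(out, "cells_zeroed") <- zeroed
  attr(out, "otus_dropped") <- table$otu_id[!keep]
  out
}

#' Pool OTU detections to prey-family level
#'
#' Per sample, every OTU with reads contributes to one detection row keyed
#' by its consensus family; OTUs whose consensus stops at order level form
#' `"Other <Order>"` pseudo-family rows; OTUs whose consensus stops above
#' order are dropped and counted. Reads are summed over contributing OTUs.
#'
#' @param records Consensus tibble from [consensus_table()]; must cover
#'   every OTU in `table`.
#' @param table Cleaned OTU table (see [clean_low_reads()]).
#' @return Detection tibble: `sample_id`, `taxon` (family label or
#'   `"Other <Order>"`), `level` (`"family"`/`"other_order"`), `order`,
#'   `phylum`, `otu_ids` (list-column), `reads`, `status` (all
#'   `"candidate"`), `exclusion_reason` (`NA`). Attributes:
#'   `dropped_above_order` (tibble `otu_id`, `deepest_rank`, `reads`) and
#'   `input_reads` (grand total of the cleaned table).
#' @export
pool_to_family <- function(records, table) {
  sample_cols <- setdiff(names(table), "otu_id")
  missing <- setdiff(table$otu_id, records$otu_id)
  if (length(missing) > 0L) {
    stop("OTUs in table missing from consensus records: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  long <- tidyr::pivot_longer(table, cols = dplyr::all_of(sample_cols),
                              names_to = "sample_id", values_to = "reads")
  long <- dplyr::filter(long, .data$reads > 0)
  long <- dplyr::left_join(long, records[, c("otu_id", TAX_RANKS)], by = "otu_id")

  depth <- lineage_depth(long)
  above_order <- depth < 3L
  dr <- long[above_order, c("otu_id", "reads")]
  dr$deepest_rank <- ifelse(depth[above_order] == 0L, "none",
                            TAX_RANKS[pmax(depth[above_order], 1L)])
  dropped <- dplyr::summarise(
    dplyr::group_by(dr, .data$otu_id, .data$deepest_rank),
    reads = sum(.data$reads), .groups = "drop"
  )
  long <- long[!above_order, ]
  long$level <- ifelse(is.na(long$family), "other_order", "family")
  long$taxon <- ifelse(long$level == "family", long$family,
                       paste("Other", long$order))
  dt <- dplyr::summarise(
    dplyr::group_by(long, .data$sample_id, .data$taxon, .data$level,
                    .data$order, .data$phylum),
    otu_ids = list(sort(unique(.data$otu_id))),
    reads = sum(.data$reads),
    .groups = "drop"
  )
  dt$status <- "candidate"
  dt$exclusion_reason <- NA_character_
  dt <- dplyr::arrange(dt, .data$sample_id, .data$taxon)
  attr(dt, "dropped_above_order") <- dropped
  attr(dt, "input_reads") <- sum(as.matrix(table[sample_cols]))
  dt
}

#' Default contaminant and plant-parasite blocklists
#'
#' Editable lists seeding the exclusion cascade: non-arthropod detections
#' are always excluded; `contaminant_families` holds known non-prey
#' contaminants that are arthropods (marine taxa cannot be recognised from
#' the lineage alone, so they live on this user-editable list);
#' `parasite_families` and `parasite_orders` hold phytophagous taxa
#' assumed to have parasitised the plant tissue rather than been captured
#' (mealybugs, trombidiform and mesostigmatid mites).
#'
#' @return Named list with `contaminant_families`, `contaminant_orders`,
#'   `parasite_families`, `parasite_orders` character vectors.
#' @export
default_blocklists <- function() {
  list(
    contaminant_families = c("Penaeidae"),
    contaminant_orders = c("Decapoda"),
    parasite_families = c("Pseudococcidae"),
    parasite_orders = c("Trombidiformes", "Mesostigmata")
  )
}

#' Apply the exclusion cascade to a detection table
#'
#' Flips the status of detection rows matching (i) a non-Arthropoda
#' phylum, (ii) the contaminant blocklist, or (iii) the plant-parasite
#' blocklist to `"excluded"` with a reason. Rows are never deleted, so the
#' full audit trail is preserved.
#'
#' @param dt Detection tibble from [pool_to_family()].
#' @param blocklists As returned by [default_blocklists()]; edit to taste.
#' @return The detection tibble with updated `status`/`exclusion_reason`.
#' @export
apply_exclusions <- function(dt, blocklists = default_blocklists()) {
  non_arthropod <- !is.na(dt$phylum) & canon_name(dt$phylum) != "arthropoda"
  fam <- ifelse(dt$level == "family", dt$taxon, NA_character_)
  contaminant <- (!is.na(fam) & fam %in% blocklists$contaminant_families) |
    dt$order %in% blocklists$contaminant_orders
  parasite <- (!is.na(fam) & fam %in% blocklists$parasite_families) |
    dt$order %in% blocklists$parasite_orders
  dt$exclusion_reason <- dplyr::case_when(
    non_arthropod ~ "non-arthropod contaminant",
    contaminant ~ "blocklisted contaminant",
    parasite ~ "plant parasite, not prey",
    TRUE ~ dt$exclusion_reason
  )
  dt$status <- ifelse(non_arthropod | contaminant | parasite, "excluded", dt$status)
  dt
}
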