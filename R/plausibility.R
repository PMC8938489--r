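#' Default photo-conspicuity table
#'
#' Families whose members are large enough that a truly captured
#' individual would be clearly visible on a macro photograph of the leaf
#' (wasps, beetles, moths, large flies, orb-weaver spiders, grasshoppers).
#' Families absent from the table are treated as small-bodied and are
#' never excludable by the pictorial control — the conservative default.
#' This is data, not code: edit or replace it for other trap systems.
#'
#' @return Tibble with columns `family`, `large_bodied`.
#' @export
default_conspicuity <- function() {
  fams <- c("Vespidae", "Ichneumonidae",
            "Curculionidae", "Chrysomelidae", "Coccinellidae", "Carabidae",
            "Staphylinidae",
            "Erebidae", "Noctuidae", "Crambidae", "Gelechiidae", "Pyralidae",
            "Tortricidae",
            "Calliphoridae", "Sarcophagidae",
            "Gryllotalpidae", "Acrididae", "Gryllidae", "Tettigoniidae",
            "Araneidae")
  tibble::tibble(family = fams, large_bodied = TRUE)
}

conspicuity_lookup <- function(conspicuity) {
  if (is.null(conspicuity)) return(character(0))
  stopifnot(all(c("family", "large_bodied") %in% names(conspicuity)))
  conspicuity$family[conspicuity$large_bodied]
}

#' Reconcile barcoding detections with in-situ photo annotations
#'
#' The pictorial plausibility control. Each candidate detection is matched
#' against the identifiable photo items of the same sample: a family-rank
#' photo label matches a detection of that family; an order-rank label
#' matches any detection of that order (including `"Other <Order>"`
#' rows). Matched rows become `confirmed`. Unmatched rows are `excluded`
#' only if the family is flagged large-bodied in the conspicuity table —
#' a truly captured large animal would have been visible — otherwise they
#' stay in the analysis as `not_excludable` (small prey degrade into
#' unidentifiable crumbs, so absence from the photos proves nothing).
#' Read counts are never altered; only statuses flip.
#'
#' @param dt Detection tibble (after [apply_exclusions()]).
#' @param photos Photo-annotation tibble (`sample_id`, `item_id`, `rank`,
#'   `taxon`, `size_class`, `identifiable`).
#' @param conspicuity Tibble `family`/`large_bodied`; defaults to
#'   [default_conspicuity()]. Families not listed are never excludable.
#' @param sample_ids Known sample ids; photo rows referencing unknown
#'   samples raise an error. Defaults to the ids present in `dt`.
#' @return List: `detections` (the updated tibble) and `decisions`
#'   (tibble `sample_id`, `taxon`, `verdict`
#'   (`confirmed`/`not_excludable`/`excluded`), `matched_item_ids`
#'   list-column, `note`).
#' @export
reconcile <- function(dt, photos, conspicuity = default_conspicuity(),
                      sample_ids = unique(dt$sample_id)) {
  unknown <- setdiff(unique(photos$sample_id), sample_ids)
  if (length(unknown) > 0L) {
    stop("photo rows reference unknown sample(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  large_fams <- conspicuity_lookup(conspicuity)
  ph <- photos[photos$identifiable & photos$rank %in% c("family", "order"), ]

  decisions <- vector("list", nrow(dt))
  for (r in seq_len(nrow(dt))) {
    if (dt$status[r] == "excluded") next  # already out of the cascade
    p <- ph[ph$sample_id == dt$sample_id[r], ]
    match_fam <- p$rank == "family" & dt$level[r] == "family" &
      p$taxon == dt$taxon[r]
    match_ord <- p$rank == "order" & p$taxon == dt$order[r]
    ids <- p$item_id[match_fam | match_ord]
    large <- dt$level[r] == "family" && dt$taxon[r] %in% large_fams
    if (length(ids) > 0L) {
      verdict <- "confirmed"
      note <- if (any(match_fam)) "matched at family rank" else "matched at order rank"
      dt$status[r] <- "confirmed"
    } else if (large) {
      verdict <- "excluded"
      note <- "large-bodied taxon absent from photos"
      dt$status[r] <- "excluded"
      dt$exclusion_reason[r] <- "pictorial plausibility control"
    } else {
      verdict <- "not_excludable"
      note <- "small-bodied; photos cannot confirm or exclude"
    }
    decisions[[r]] <- tibble::tibble(
      sample_id = dt$sample_id[r], taxon = dt$taxon[r], verdict = verdict,
      matched_item_ids = list(ids), note = note
    )
  }
  decisions <- dplyr::bind_rows(decisions)
  if (nrow(decisions) == 0L) {
    decisions <- tibble::tibble(sample_id = character(), taxon = character(),
                                verdict = character(),
                                matched_item_ids = list(), note = character())
  }
  list(detections = dt, decisions = decisions)
}

#' Identifiable photo items with no barcoding detection
#'
#' The reverse control: identifiable photo items whose taxon, at its own
#' rank, has no candidate or confirmed barcoding detection in the same
#' sample. An empty report is the expected healthy outcome — it means the
#' barcoding data is a superset of what the photographs show.
#'
#' @param dt Detection tibble after [reconcile()].
#' @param photos Photo-annotation tibble.
#' @return Tibble of unexplained photo items (possibly empty).
#' @export
photo_only_report <- function(dt, photos) {
  keep <- dt[dt$status %in% c("candidate", "confirmed"), ]
  ph <- photos[photos$identifiable & photos$rank %in% c("family", "order"), ]
  if (nrow(ph) == 0L) return(ph)
  covered <- logical(nrow(ph))
  for (r in seq_len(nrow(ph))) {
    k <- keep[keep$sample_id == ph$sample_id[r], ]
    covered[r] <- if (ph$rank[r] == "family") {
      ph$taxon[r] %in% k$taxon[k$level == "family"]
    } else {
      ph$taxon[r] %in% k$order
    }
  }
  ph[!covered, ]
}
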