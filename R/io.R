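#' Read an OTU-by-sample read-count table
#'
#' Tab-separated, rows = OTUs, first column `otu_id`, remaining columns
#' one per sample (non-negative integers).
#'
#' @param path Path to the TSV file.
#' @return Tibble `otu_id` + integer sample columns.
#' @export
read_otu_table <- function(path) {
  if (!file.exists(path)) stop("OTU table not found: ", path, call. = FALSE)
  tab <- readr::read_tsv(path, col_types = readr::cols(
    otu_id = readr::col_character(), .default = readr::col_integer()),
    progress = FALSE)
  if (!"otu_id" %in% names(tab)) stop("OTU table must have an `otu_id` column",
                                      call. = FALSE)
  if (anyDuplicated(tab$otu_id)) stop("duplicate otu_id in OTU table", call. = FALSE)
  m <- as.matrix(tab[setdiff(names(tab), "otu_id")])
  if (any(is.na(m)) || any(m < 0)) {
    stop("OTU table counts must be non-negative integers", call. = FALSE)
  }
  tab
}

#' Read a photo-annotation table
#'
#' CSV with columns `sample_id`, `item_id`, `rank`
#' (`family`/`order`/`unidentifiable`), `taxon`, `size_class`
#' (`large`/`small`), `identifiable` (logical).
#'
#' @param path Path to the CSV file.
#' @return Tibble of photo items.
#' @export
read_photo_table <- function(path) {
  if (!file.exists(path)) stop("photo table not found: ", path, call. = FALSE)
  ph <- readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(), item_id = readr::col_character(),
    rank = readr::col_character(), taxon = readr::col_character(),
    size_class = readr::col_character(), identifiable = readr::col_logical()),
    progress = FALSE)
  bad <- !ph$rank %in% c("family", "order", "unidentifiable")
  if (any(bad)) {
    stop("invalid photo rank at row(s): ", paste(which(bad), collapse = ", "),
         call. = FALSE)
  }
  inconsistent <- ph$rank == "unidentifiable" & (!is.na(ph$taxon) | ph$identifiable)
  if (any(inconsistent)) {
    stop("unidentifiable photo items must have empty taxon and identifiable = FALSE; row(s): ",
         paste(which(inconsistent), collapse = ", "), call. = FALSE)
  }
  ph
}

#' Read a sample metadata table
#'
#' CSV with columns `sample_id`, `species`, `site`,
#' `leaf_len_1_cm` ... `leaf_len_5_cm`, `total_prey_count`.
#'
#' @param path Path to the CSV file.
#' @return Tibble of sample metadata.
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop("sample table not found: ", path, call. = FALSE)
  smp <- readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(), species = readr::col_character(),
    site = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
  needed <- c("sample_id", "species", sprintf("leaf_len_%d_cm", 1:5),
              "total_prey_count")
  missing <- setdiff(needed, names(smp))
  if (length(missing) > 0L) {
    stop("sample table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(smp$sample_id)) stop("duplicate sample_id", call. = FALSE)
  smp$total_prey_count <- as.integer(smp$total_prey_count)
  smp
}
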