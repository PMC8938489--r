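#' Configuration for an end-to-end pipeline run
#'
#' Either `input_paths` (a named list with `otu_table`, `hits_bold`,
#' `hits_ncbi`, `photos`, `samples`) or `generator` (a
#' [generator_config()]) must be supplied; exactly one of the two.
#'
#' @param input_paths Named list of the five input file paths, or `NULL`.
#' @param generator A [generator_config()] to synthesise the inputs, or
#'   `NULL`.
#' @param threshold_fraction,denominator Passed to [clean_low_reads()].
#' @param consensus_mode `"strict"` or `"lenient"`, see
#'   [consensus_lineage()].
#' @param blocklists See [apply_exclusions()].
#' @param conspicuity See [reconcile()].
#' @param n_permutations,seed ANOSIM permutation settings; the seed also
#'   covers every other stochastic step and is recorded in the outputs.
#' @param output_dir Directory for the per-stage TSV/JSON outputs, or
#'   `NULL` to skip writing.
#' @return A `prey_run_config` list.
#' @export
pipeline_config <- function(input_paths = NULL,
                            generator = NULL,
                            threshold_fraction = 1e-4,
                            denominator = "grand_total",
                            consensus_mode = "strict",
                            blocklists = default_blocklists(),
                            conspicuity = default_conspicuity(),
                            n_permutations = 999,
                            seed = 1,
                            output_dir = NULL) {
  if (is.null(input_paths) == is.null(generator)) {
    stop("supply exactly one of `input_paths` or `generator`", call. = FALSE)
  }
  if (!is.null(input_paths)) {
    needed <- c("otu_table", "hits_bold", "hits_ncbi", "photos", "samples")
    missing <- setdiff(needed, names(input_paths))
    if (length(missing) > 0L) {
      stop("input_paths missing: ", paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(input_paths = input_paths, generator = generator,
         threshold_fraction = threshold_fraction, denominator = denominator,
         consensus_mode = consensus_mode, blocklists = blocklists,
         conspicuity = conspicuity, n_permutations = n_permutations,
         seed = seed, output_dir = output_dir),
    class = "prey_run_config"
  )
}

#' Run the full prey-spectra pipeline
#'
#' Executes clean, consensus, family pooling, exclusion cascade,
#' pictorial plausibility control, presence-matrix construction, ANOSIM
#' (global and pairwise, family and order level), SIMPER per species
#' pair, and photo-derived prey quantification. When `output_dir` is set,
#' per-stage tables, a decisions audit file and a machine-readable
#' `results.json` are written there.
#'
#' @param config A [pipeline_config()].
#' @return A `prey_report` list: `inputs`, `consensus`, `rank_summary`,
#'   `cleaned_otu_table`, `detections` (full audit trail), `decisions`,
#'   `photo_only`, `presence` (family/order matrices), `anosim`
#'   (global + pairwise at both levels), `simper` (per level and pair),
#'   `quantity`, `summary` (taxon/order counts, presence percentages),
#'   `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "prey_run_config"))
  inputs <- load_pipeline_inputs(config)

  cons <- consensus_table(inputs$hits_bold, inputs$hits_ncbi,
                          mode = config$consensus_mode)
  cleaned <- clean_low_reads(inputs$otu_table,
                             threshold_fraction = config$threshold_fraction,
                             denominator = config$denominator)
  dt <- pool_to_family(cons, cleaned)
  dt <- apply_exclusions(dt, config$blocklists)
  rec <- reconcile(dt, inputs$photos, config$conspicuity,
                   sample_ids = inputs$samples$sample_id)
  dt <- rec$detections
  photo_only <- photo_only_report(dt, inputs$photos)

  groups <- stats::setNames(inputs$samples$species, inputs$samples$sample_id)
  pm_family <- build_presence_matrix(dt, "family", groups = groups)
  pm_order <- build_presence_matrix(dt, "order", groups = groups)

  anosim_level <- function(pm, seed_offset) {
    d <- binary_bray_curtis(pm)
    list(
      global = anosim(d, pm_groups(pm), n_permutations = config$n_permutations,
                      seed = config$seed + seed_offset),
      pairwise = pairwise_anosim(pm, n_permutations = config$n_permutations,
                                 seed = config$seed + seed_offset + 10L)
    )
  }
  anosim_res <- list(family = anosim_level(pm_family, 100L),
                     order = anosim_level(pm_order, 200L))

  species <- sort(unique(inputs$samples$species))
  pairs <- if (length(species) >= 2L) utils::combn(species, 2, simplify = FALSE) else list()
  simper_level <- function(pm) {
    stats::setNames(
      lapply(pairs, function(pr) simper(pm, pair = pr)),
      vapply(pairs, paste, character(1), collapse = " vs ")
    )
  }
  simper_res <- list(family = simper_level(pm_family),
                     order = simper_level(pm_order))

  quant <- prey_quantity(inputs$samples)

  kept <- dt[dt$status != "excluded", ]
  summary <- list(
    n_otus_input = nrow(inputs$otu_table),
    n_otus_cleaned = nrow(cleaned),
    n_otus_dropped_above_order = nrow(attr(dt, "dropped_above_order") %||%
                                        tibble::tibble()),
    n_prey_families = length(unique(kept$taxon[kept$level == "family"])),
    n_prey_orders = length(unique(kept$order)),
    n_photo_excluded_taxa = length(unique(
      dt$taxon[dt$exclusion_reason %in% "pictorial plausibility control"])),
    presence_percent_order = presence_percentages(pm_order, "overall"),
    presence_percent_family = presence_percentages(pm_family, "overall")
  )

  report <- structure(
    list(inputs = inputs, consensus = cons, rank_summary = rank_summary(cons),
         cleaned_otu_table = cleaned, detections = dt,
         decisions = rec$decisions, photo_only = photo_only,
         presence = list(family = pm_family, order = pm_order),
         anosim = anosim_res, simper = simper_res, quantity = quant,
         summary = summary, config = config),
    class = "prey_report"
  )
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_pipeline_inputs <- function(config) {
  if (!is.null(config$generator)) {
    study <- simulate_prey_study(config$generator)
    list(otu_table = study$otu_table, hits_bold = study$hits_bold,
         hits_ncbi = study$hits_ncbi, photos = study$photos,
         samples = study$samples, truth = study$truth,
         otu_truth = study$otu_truth, noise_cells = study$noise_cells)
  } else {
    p <- config$input_paths
    list(otu_table = read_otu_table(p$otu_table),
         hits_bold = parse_hit_table(p$hits_bold, "BOLD"),
         hits_ncbi = parse_hit_table(p$hits_ncbi, "NCBI"),
         photos = read_photo_table(p$photos),
         samples = read_sample_table(p$samples),
         truth = NULL, otu_truth = NULL, noise_cells = NULL)
  }
}

#' Write a pipeline report to disk
#'
#' Per-stage TSVs (`consensus.tsv`, `cleaned_otu_table.tsv`,
#' `detections.tsv` — the full audit trail with exclusion reasons —
#' `plausibility_decisions.tsv`, `photo_only.tsv`, presence matrices,
#' `prey_quantity.tsv`) plus a machine-readable `results.json` with the
#' headline statistics and the seed.
#'
#' @param report A `prey_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) readr::write_tsv(x, file.path(dir, name), na = "")
  w(report$consensus, "consensus.tsv")
  w(report$rank_summary, "rank_summary.tsv")
  w(report$cleaned_otu_table, "cleaned_otu_table.tsv")
  det <- report$detections
  det$otu_ids <- vapply(det$otu_ids, paste, character(1), collapse = ";")
  w(det, "detections.tsv")
  dec <- report$decisions
  dec$matched_item_ids <- vapply(dec$matched_item_ids, paste, character(1),
                                 collapse = ";")
  w(dec, "plausibility_decisions.tsv")
  w(report$photo_only, "photo_only.tsv")
  w(tibble::as_tibble(report$presence$family), "presence_family.tsv")
  w(tibble::as_tibble(report$presence$order), "presence_order.tsv")
  w(report$quantity$per_sample, "prey_quantity.tsv")
  w(report$quantity$per_species, "prey_quantity_species.tsv")

  res <- list(
    seed = report$config$seed,
    n_permutations = report$config$n_permutations,
    anosim = list(
      family = list(R = report$anosim$family$global$R,
                    p = report$anosim$family$global$p_value,
                    pairwise = report$anosim$family$pairwise[
                      c("group_a", "group_b", "R", "p_value")]),
      order = list(R = report$anosim$order$global$R,
                   p = report$anosim$order$global$p_value,
                   pairwise = report$anosim$order$pairwise[
                     c("group_a", "group_b", "R", "p_value")])
    ),
    summary = report$summary[c("n_otus_input", "n_otus_cleaned",
                               "n_otus_dropped_above_order", "n_prey_families",
                               "n_prey_orders", "n_photo_excluded_taxa")],
    kruskal = as.list(report$quantity$kruskal),
    prey_per_cm = stats::setNames(as.list(report$quantity$per_species$mean),
                                  report$quantity$per_species$species)
  )
  jsonlite::write_json(res, file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.prey_report <- function(x, ...) {
  cat("Prey-spectra pipeline report\n")
  cat(sprintf("  OTUs: %d in, %d after cleaning, %d dropped above order\n",
              x$summary$n_otus_input, x$summary$n_otus_cleaned,
              x$summary$n_otus_dropped_above_order))
  cat(sprintf("  Prey taxa kept: %d families in %d orders (%d photo-excluded)\n",
              x$summary$n_prey_families, x$summary$n_prey_orders,
              x$summary$n_photo_excluded_taxa))
  cat(sprintf("  ANOSIM family level: R = %.3f (p = %.3g)\n",
              x$anosim$family$global$R, x$anosim$family$global$p_value))
  cat(sprintf("  ANOSIM order level:  R = %.3f (p = %.3g)\n",
              x$anosim$order$global$R, x$anosim$order$global$p_value))
  cat(sprintf("  Kruskal-Wallis prey/cm: H = %.2f (p = %.3g)\n",
              x$quantity$kruskal$H, x$quantity$kruskal$p_value))
  invisible(x)
}
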