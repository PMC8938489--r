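#' Configuration for the synthetic prey-study generator
#'
#' Bundles every knob of the synthetic data generator. Defaults encode the
#' study design the package targets: three sundew species, ten plants
#' (samples) per species, five leaves per plant, with moderate overlap
#' between the species' prey-family pools and realistic nuisance rates.
#'
#' @param n_species Number of plant species (groups).
#' @param n_samples_per_species Plants sampled per species.
#' @param n_leaves_per_sample Leaves pooled into one sample.
#' @param family_separation In `[0, 1]`: 0 = all species draw prey from one
#'   shared family pool, 1 = fully disjoint family pools within a shared
#'   order inventory.
#' @param contaminant_rate Expected number of contaminant OTU detections
#'   injected per sample (human, bacterial, fungal, marine, plant-parasite
#'   lineages).
#' @param db_disagreement_rate Probability that the two reference-database
#'   identifications of an OTU disagree below some rank.
#' @param rank_dropout_rate Probability that one database's lineage for an
#'   OTU is truncated (gappy reference coverage).
#' @param noise_cell_rate Probability that an empty OTU-table cell receives
#'   a stray sub-threshold read count (index hopping / low-level
#'   cross-contamination).
#' @param small_identifiable_fraction Fraction of small-bodied prey items
#'   that remain identifiable on the macro photographs; the rest appear as
#'   unidentifiable "crumbs". Large-bodied items are always identifiable.
#' @param read_meanlog,read_sdlog Log-normal parameters for per-detection
#'   read counts.
#' @param read_floor Minimum read count for a genuine detection cell;
#'   keeps true detections above the relative-abundance cleaning threshold
#'   at the default table size.
#' @param families_per_order Size of each species' family pool within each
#'   order.
#' @param seed Integer seed; the same config and seed reproduce the fixture
#'   set exactly.
#' @return A `prey_generator_config` list.
#' @export
generator_config <- function(n_species = 3,
                             n_samples_per_species = 10,
                             n_leaves_per_sample = 5,
                             family_separation = 0.6,
                             contaminant_rate = 1.5,
                             db_disagreement_rate = 0.15,
                             rank_dropout_rate = 0.35,
                             noise_cell_rate = 0.02,
                             small_identifiable_fraction = 0.25,
                             read_meanlog = 6.5,
                             read_sdlog = 1,
                             read_floor = 200,
                             families_per_order = 4,
                             seed = 1) {
  cfg <- list(
    n_species = n_species,
    n_samples_per_species = n_samples_per_species,
    n_leaves_per_sample = n_leaves_per_sample,
    family_separation = family_separation,
    contaminant_rate = contaminant_rate,
    db_disagreement_rate = db_disagreement_rate,
    rank_dropout_rate = rank_dropout_rate,
    noise_cell_rate = noise_cell_rate,
    small_identifiable_fraction = small_identifiable_fraction,
    read_meanlog = read_meanlog,
    read_sdlog = read_sdlog,
    read_floor = read_floor,
    families_per_order = families_per_order,
    seed = seed
  )
  class(cfg) <- "prey_generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  chk_count <- function(field, min = 1) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < min || v != round(v)) {
      stop("generator config: `", field, "` must be an integer >= ", min, call. = FALSE)
    }
  }
  chk_prob <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop("generator config: `", field, "` must be a probability in [0, 1]", call. = FALSE)
    }
  }
  chk_nonneg <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      stop("generator config: `", field, "` must be non-negative", call. = FALSE)
    }
  }
  chk_count("n_species"); chk_count("n_samples_per_species")
  chk_count("n_leaves_per_sample"); chk_count("families_per_order")
  chk_prob("family_separation"); chk_prob("db_disagreement_rate")
  chk_prob("rank_dropout_rate"); chk_prob("noise_cell_rate")
  chk_prob("small_identifiable_fraction")
  chk_nonneg("contaminant_rate"); chk_nonneg("read_floor")
  chk_count("seed", min = 0)
  invisible(cfg)
}

# Shared order inventory (12 arthropod orders typical of sundew prey) and
# a catalogue of real family names to seed the pools; synthetic names are
# appended when a pool needs more families than the catalogue offers.
prey_order_catalogue <- function() {
  tibble::tribble(
    ~order,            ~class,       ~families,
    "Diptera",         "Insecta",    list(c("Cecidomyiidae", "Chironomidae", "Muscidae", "Syrphidae",
                                            "Calliphoridae", "Sarcophagidae", "Limoniidae", "Culicidae")),
    "Hemiptera",       "Insecta",    list(c("Cicadellidae", "Lygaeidae", "Aleyrodidae", "Miridae",
                                            "Aphididae", "Delphacidae", "Cixiidae")),
    "Hymenoptera",     "Insecta",    list(c("Formicidae", "Torymidae", "Braconidae", "Vespidae",
                                            "Ichneumonidae", "Pteromalidae")),
    "Lepidoptera",     "Insecta",    list(c("Erebidae", "Noctuidae", "Crambidae", "Gelechiidae",
                                            "Pyralidae", "Tortricidae")),
    "Thysanoptera",    "Insecta",    list(c("Thripidae", "Phlaeothripidae", "Aeolothripidae")),
    "Coleoptera",      "Insecta",    list(c("Curculionidae", "Chrysomelidae", "Coccinellidae",
                                            "Carabidae", "Staphylinidae")),
    "Orthoptera",      "Insecta",    list(c("Gryllotalpidae", "Acrididae", "Gryllidae", "Tettigoniidae")),
    "Blattodea",       "Insecta",    list(c("Ectobiidae", "Blattidae")),
    "Neuroptera",      "Insecta",    list(c("Chrysopidae", "Hemerobiidae")),
    "Psocodea",        "Insecta",    list(c("Psocidae", "Caeciliusidae")),
    "Araneae",         "Arachnida",  list(c("Salticidae", "Thomisidae", "Araneidae", "Oxyopidae")),
    "Entomobryomorpha", "Collembola", list(c("Entomobryidae", "Isotomidae"))
  )
}

# orders whose members are photo-conspicuous; plus a few named large families
LARGE_BODIED_ORDERS <- c("Coleoptera", "Lepidoptera", "Orthoptera")
LARGE_BODIED_FAMILIES <- c("Vespidae", "Ichneumonidae", "Calliphoridae",
                           "Sarcophagidae", "Araneidae")

default_species_table <- function(n_species) {
  base <- tibble::tibble(
    species = c("D. margaritacea", "D. hartmeyerorum", "D. finlaysoniana"),
    site = c("Site 2", "Site 3", "Site 1"),
    code = c("MARG", "HART", "FINL"),
    prey_rate_per_cm = c(2.25, 1.80, 0.81),
    leaf_length_mean_cm = c(7.1, 5.3, 10.4),
    leaf_length_sd_cm = c(1.3, 1.1, 0.6)
  )
  if (n_species <= 3L) return(base[seq_len(n_species), ])
  extra <- tibble::tibble(
    species = sprintf("Species %d", 4:n_species),
    site = sprintf("Site %d", 4:n_species),
    code = sprintf("SP%02d", 4:n_species),
    prey_rate_per_cm = rep(base$prey_rate_per_cm, length.out = n_species - 3L),
    leaf_length_mean_cm = rep(base$leaf_length_mean_cm, length.out = n_species - 3L),
    leaf_length_sd_cm = rep(base$leaf_length_sd_cm, length.out = n_species - 3L)
  )
  dplyr::bind_rows(base, extra)
}

#' Build per-species prey-pool profiles
#'
#' Every species shares the same 12-order inventory; within each order a
#' species' family pool is composed of `round((1 - s) * F)` families shared
#' by all species plus `F - round((1 - s) * F)` private families, where
#' `s = family_separation` and `F = families_per_order`. Sampling weights
#' (occurrence probabilities) are attached to family names, so shared
#' families are equally likely in every species and per-order detection
#' rates stay comparable across species at any separation.
#'
#' @param config A [generator_config()].
#' @return Tibble with one row per species: `species`, `site`,
#'   `prey_rate_per_cm`, `leaf_length_mean_cm`, `leaf_length_sd_cm`, and a
#'   `prey_pool` list-column of tibbles (`family`, `order`, `class`,
#'   `weight`, `large_bodied`).
#' @export
make_profiles <- function(config) {
  validate_generator_config(config)
  withr::with_seed(config$seed, make_profiles_impl(config))
}

make_profiles_impl <- function(config) {
  s <- config$family_separation
  f_per <- config$families_per_order
  n_shared <- round((1 - s) * f_per)
  n_private <- f_per - n_shared
  orders <- prey_order_catalogue()
  sp <- default_species_table(config$n_species)

  # per order: name pool of n_shared + n_species * n_private families,
  # each with a weight drawn once (identical across species). Weights are
  # heavy-tailed (lognormal family weight x lognormal order multiplier):
  # arthropod communities are dominated by a few abundant taxa, and rare
  # orders must exist for order-level presence to vary between samples.
  order_mult <- stats::rlnorm(nrow(orders), 0, 1.5)
  pools <- purrr::pmap(
    list(orders$order, orders$class, orders$families, order_mult),
    function(order, class, families, mult) {
      need <- n_shared + config$n_species * n_private
      nm <- families[[1]]
      if (length(nm) < need) {
        nm <- c(nm, sprintf("%sidae_syn%02d", substr(order, 1, 4), seq_len(need - length(nm))))
      }
      nm <- nm[seq_len(need)]
      tibble::tibble(
        family = nm, order = order, class = class,
        weight = mult * stats::rlnorm(need, 0, 1),
        order_mult = mult,
        large_bodied = order %in% LARGE_BODIED_ORDERS | nm %in% LARGE_BODIED_FAMILIES
      )
    })
  pool_all <- dplyr::bind_rows(pools)

  # private-family weights are rescaled so every species' per-order total
  # weight is identical: order-level composition is a property of the
  # shared site inventory, only the family identities separate species
  sp$prey_pool <- purrr::map(seq_len(config$n_species), function(i) {
    picked <- dplyr::group_modify(
      dplyr::group_by(pool_all, .data$order),
      function(g, key) {
        shared <- g[seq_len(n_shared), , drop = FALSE]
        if (n_private > 0L) {
          from <- n_shared + (i - 1L) * n_private + 1L
          priv <- g[from:(from + n_private - 1L), , drop = FALSE]
          target <- if (n_shared > 0L) {
            sum(shared$weight) * n_private / n_shared
          } else {
            g$order_mult[1] * n_private
          }
          priv$weight <- priv$weight * target / sum(priv$weight)
          dplyr::bind_rows(shared, priv)
        } else {
          shared
        }
      }
    )
    dplyr::ungroup(picked)[, c("family", "order", "class", "weight", "large_bodied")]
  })
  sp$code <- NULL
  sp
}

sample_codes <- function(labels) {
  code <- toupper(substr(gsub("[^A-Za-z]", "", sub("^\\w+\\.?\\s*", "", labels)), 1, 4))
  code[!nzchar(code)] <- toupper(substr(gsub("[^A-Za-z]", "", labels[!nzchar(code)]), 1, 4))
  make.unique(code, sep = "")
}

#' Simulate field samples, prey items and photo annotations
#'
#' For each plant: leaf lengths are drawn from the species' normal
#' distribution truncated at 0.5 cm; the total prey count is Poisson with
#' mean `prey_rate_per_cm * sum(leaf lengths)`; each prey item is assigned
#' a family from the species' pool with probability proportional to the
#' family weights. Every large-bodied item yields an identifiable photo
#' annotation at family rank; small items are identifiable (at family or
#' order rank) with probability `small_identifiable_fraction` and appear
#' as unidentifiable crumbs otherwise.
#'
#' @param profiles Output of [make_profiles()].
#' @param config The same [generator_config()].
#' @return List of tibbles: `samples` (`sample_id`, `species`, `site`,
#'   `leaf_len_1..5_cm`, `total_prey_count`), `photos` (`sample_id`,
#'   `item_id`, `rank`, `taxon`, `size_class`, `identifiable`), and
#'   `truth` — the per-sample true family detections (`sample_id`,
#'   `species`, `family`, `order`, `class`, `large_bodied`, `n_items`).
#' @export
simulate_samples <- function(profiles, config) {
  validate_generator_config(config)
  withr::with_seed(config$seed + 1L, simulate_samples_impl(profiles, config))
}

rnorm_trunc <- function(n, mean, sd, lower = 0.5) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lower)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

simulate_samples_impl <- function(profiles, config) {
  codes <- sample_codes(profiles$species)
  n_leaves <- config$n_leaves_per_sample
  samples <- list(); photos <- list(); truth <- list()

  for (i in seq_len(nrow(profiles))) {
    prof <- profiles[i, ]
    pool <- prof$prey_pool[[1]]
    for (j in seq_len(config$n_samples_per_species)) {
      sid <- sprintf("%s-%02d", codes[i], j)
      leaves <- rnorm_trunc(n_leaves, prof$leaf_length_mean_cm, prof$leaf_length_sd_cm)
      n_prey <- stats::rpois(1, prof$prey_rate_per_cm * sum(leaves))
      smp <- tibble::tibble(sample_id = sid, species = prof$species, site = prof$site)
      for (l in seq_len(n_leaves)) smp[[sprintf("leaf_len_%d_cm", l)]] <- round(leaves[l], 2)
      smp$total_prey_count <- n_prey
      samples[[length(samples) + 1L]] <- smp

      if (n_prey > 0L) {
        idx <- sample.int(nrow(pool), n_prey, replace = TRUE, prob = pool$weight)
        items <- pool[idx, ]
        large <- items$large_bodied
        ident <- large | stats::runif(n_prey) < config$small_identifiable_fraction
        # identifiable small items are sometimes only resolvable to order
        rank <- ifelse(!ident, "unidentifiable",
                       ifelse(large | stats::runif(n_prey) < 0.5, "family", "order"))
        photos[[length(photos) + 1L]] <- tibble::tibble(
          sample_id = sid,
          item_id = sprintf("%s-I%03d", sid, seq_len(n_prey)),
          rank = rank,
          taxon = dplyr::case_when(
            rank == "family" ~ items$family,
            rank == "order" ~ items$order,
            TRUE ~ NA_character_
          ),
          size_class = ifelse(large, "large", "small"),
          identifiable = ident
        )
        truth[[length(truth) + 1L]] <- dplyr::summarise(
          dplyr::group_by(
            tibble::tibble(sample_id = sid, species = prof$species,
                           family = items$family, order = items$order,
                           class = items$class, large_bodied = items$large_bodied),
            .data$sample_id, .data$species, .data$family, .data$order,
            .data$class, .data$large_bodied
          ),
          n_items = dplyr::n(), .groups = "drop"
        )
      }
    }
  }
  list(
    samples = dplyr::bind_rows(samples),
    photos = if (length(photos)) dplyr::bind_rows(photos) else tibble::tibble(
      sample_id = character(), item_id = character(), rank = character(),
      taxon = character(), size_class = character(), identifiable = logical()),
    truth = if (length(truth)) dplyr::bind_rows(truth) else tibble::tibble(
      sample_id = character(), species = character(), family = character(),
      order = character(), class = character(), large_bodied = logical(),
      n_items = integer())
  )
}

# contaminant lineages the exclusion cascade must catch
contaminant_catalogue <- function() {
  tibble::tribble(
    ~kind,            ~phylum,          ~class,                  ~order,           ~family,          ~genus,        ~species,
    "human",          "Chordata",       "Mammalia",              "Primates",       "Hominidae",      "Homo",        "Homo sapiens",
    "endosymbiont",   "Proteobacteria", "Alphaproteobacteria",   "Rickettsiales",  "Anaplasmataceae", "Wolbachia",  "Wolbachia pipientis",
    "fungus",         "Ascomycota",     "Sordariomycetes",       "Hypocreales",    "Nectriaceae",    "Fusarium",    "Fusarium oxysporum",
    "marine",         "Arthropoda",     "Malacostraca",          "Decapoda",       "Penaeidae",      "Penaeus",     "Penaeus monodon",
    "plant_parasite", "Arthropoda",     "Insecta",               "Hemiptera",      "Pseudococcidae", "Planococcus", "Planococcus citri",
    "plant_parasite", "Arthropoda",     "Arachnida",             "Trombidiformes", "Tetranychidae",  "Tetranychus", "Tetranychus urticae",
    "plant_parasite", "Arthropoda",     "Arachnida",             "Mesostigmata",   "Parasitidae",    "Parasitus",   "Parasitus sp."
  )
}

#' Simulate the OTU table and the two identification tables
#'
#' Each true family detection is backed by one or more OTUs with log-normal
#' read counts (floored at `read_floor`); contaminant OTUs drawn from a
#' fixed catalogue (human, *Wolbachia*-like, fungal, marine, plant-parasite
#' lineages) are injected per sample at `contaminant_rate`; stray
#' sub-threshold counts are written into empty cells at `noise_cell_rate`.
#' The BOLD- and GenBank-style hit tables carry the OTU's true lineage
#' except where `rank_dropout_rate` truncates one database's lineage or
#' `db_disagreement_rate` replaces a name below some rank.
#'
#' @param truth True detection table from [simulate_samples()].
#' @param config The same [generator_config()].
#' @param sample_ids All sample ids to emit as OTU-table columns (defaults
#'   to those present in `truth`; pass the full sample table's ids so that
#'   preyless samples keep an all-zero column).
#' @return List: `otu_table` (tibble, `otu_id` + one integer column per
#'   sample), `hits_bold`, `hits_ncbi` (per-OTU identification tibbles),
#'   `otu_truth` (ground-truth OTU-to-taxon map with `is_contaminant`,
#'   `db_dropout`, `db_disagreement` flags), `noise_cells` (`otu_id`,
#'   `sample_id`, `count` of every injected stray cell).
#' @export
simulate_otu_table <- function(truth, config, sample_ids = unique(truth$sample_id)) {
  validate_generator_config(config)
  withr::with_seed(config$seed + 2L, simulate_otu_table_impl(truth, config, sample_ids))
}

simulate_otu_table_impl <- function(truth, config, sample_ids) {
  rlnorm_floor <- function(n) {
    as.integer(pmax(config$read_floor,
                    round(stats::rlnorm(n, config$read_meanlog, config$read_sdlog))))
  }

  # regional OTU pool per detected family: 1-3 OTUs each
  fams <- dplyr::distinct(truth, .data$family, .data$order, .data$class)
  fam_otus <- NULL
  if (nrow(fams) > 0L) {
    k <- 1L + stats::rpois(nrow(fams), 0.8)
    fam_otus <- fams[rep(seq_len(nrow(fams)), k), ]
    fam_otus$phylum <- "Arthropoda"
    within_idx <- unlist(lapply(k, seq_len))
    stem <- gsub("idae.*$", "", fam_otus$family)
    fam_otus$genus <- sprintf("%sus%d", stem, within_idx)
    fam_otus$species <- sprintf("%s sp%d", fam_otus$genus, within_idx)
    fam_otus$is_contaminant <- FALSE
    fam_otus$kind <- "prey"
  }

  # contaminant OTUs: one per catalogue entry actually used
  cat_tab <- contaminant_catalogue()
  cont_hits <- NULL
  if (config$contaminant_rate > 0 && length(sample_ids) > 0L) {
    per_sample <- stats::rpois(length(sample_ids), config$contaminant_rate)
    rows <- list()
    for (si in seq_along(sample_ids)) {
      if (per_sample[si] > 0L) {
        pick <- sample.int(nrow(cat_tab), per_sample[si], replace = TRUE)
        rows[[length(rows) + 1L]] <- tibble::tibble(sample_id = sample_ids[si],
                                                    cat_row = pick)
      }
    }
    if (length(rows)) cont_hits <- dplyr::bind_rows(rows)
  }
  used_cat <- if (is.null(cont_hits)) integer(0) else sort(unique(cont_hits$cat_row))
  cont_otus <- NULL
  if (length(used_cat) > 0L) {
    cont_otus <- cat_tab[used_cat, c("phylum", "class", "order", "family", "genus", "species", "kind")]
    cont_otus$is_contaminant <- TRUE
    cont_otus$cat_row <- used_cat
  }

  all_otus <- dplyr::bind_rows(
    if (!is.null(fam_otus)) fam_otus[, c("phylum", "class", "order", "family",
                                         "genus", "species", "is_contaminant", "kind")],
    if (!is.null(cont_otus)) cont_otus[, c("phylum", "class", "order", "family",
                                           "genus", "species", "is_contaminant", "kind")]
  )
  if (is.null(all_otus) || nrow(all_otus) == 0L) {
    empty <- tibble::tibble(otu_id = character())
    for (sid in sample_ids) empty[[sid]] <- integer()
    return(list(otu_table = empty,
                hits_bold = tibble::tibble(), hits_ncbi = tibble::tibble(),
                otu_truth = tibble::tibble(), noise_cells = tibble::tibble(
                  otu_id = character(), sample_id = character(), count = integer())))
  }
  all_otus$otu_id <- sprintf("OTU_%04d", seq_len(nrow(all_otus)))

  counts <- matrix(0L, nrow = nrow(all_otus), ncol = length(sample_ids),
                   dimnames = list(all_otus$otu_id, sample_ids))

  # genuine detections: each of the family's OTUs fires with prob 0.7, >= 1
  if (nrow(truth) > 0L && !is.null(fam_otus)) {
    fam_index <- split(seq_len(sum(!all_otus$is_contaminant)),
                       fam_otus$family)
    for (r in seq_len(nrow(truth))) {
      otus <- fam_index[[truth$family[r]]]
      fire <- stats::runif(length(otus)) < 0.7
      if (!any(fire)) fire[sample.int(length(otus), 1L)] <- TRUE
      sel <- otus[fire]
      counts[sel, truth$sample_id[r]] <- rlnorm_floor(length(sel))
    }
  }
  # contaminants
  if (!is.null(cont_hits)) {
    cont_id_by_cat <- stats::setNames(
      all_otus$otu_id[all_otus$is_contaminant],
      as.character(cont_otus$cat_row))
    for (r in seq_len(nrow(cont_hits))) {
      oid <- cont_id_by_cat[[as.character(cont_hits$cat_row[r])]]
      counts[oid, cont_hits$sample_id[r]] <- rlnorm_floor(1L)
    }
  }
  # stray sub-threshold cells into empty cells only
  noise_cells <- tibble::tibble(otu_id = character(), sample_id = character(),
                                count = integer())
  if (config$noise_cell_rate > 0) {
    zero <- which(counts == 0L)
    hit <- zero[stats::runif(length(zero)) < config$noise_cell_rate]
    if (length(hit) > 0L) {
      val <- sample.int(3L, length(hit), replace = TRUE)
      counts[hit] <- val
      noise_cells <- tibble::tibble(
        otu_id = rownames(counts)[(hit - 1L) %% nrow(counts) + 1L],
        sample_id = colnames(counts)[(hit - 1L) %/% nrow(counts) + 1L],
        count = val
      )
    }
  }

  # database noise: dropout truncates one db's lineage; disagreement
  # replaces one db's name at a rank (consensus then stops above it)
  n_otu <- nrow(all_otus)
  lin <- as.matrix(all_otus[, TAX_RANKS])
  bold_lin <- lin; ncbi_lin <- lin
  dropout <- stats::runif(n_otu) < config$rank_dropout_rate
  disagree <- stats::runif(n_otu) < config$db_disagreement_rate
  which_db <- stats::runif(n_otu) < 0.5  # TRUE -> BOLD affected
  for (o in seq_len(n_otu)) {
    if (dropout[o]) {
      keep <- sample(3:5, 1L)  # truncate below order/family/genus
      if (which_db[o]) bold_lin[o, (keep + 1L):6L] <- NA_character_
      else ncbi_lin[o, (keep + 1L):6L] <- NA_character_
    }
    if (disagree[o]) {
      at <- sample(4:6, 1L)  # family, genus or species name differs
      alt <- paste0(lin[o, at], "_alt")
      if (which_db[o]) {
        if (!is.na(bold_lin[o, at])) bold_lin[o, at] <- alt
      } else {
        if (!is.na(ncbi_lin[o, at])) ncbi_lin[o, at] <- alt
      }
    }
  }

  mk_hits <- function(lin_m, db) {
    h <- tibble::tibble(
      otu_id = all_otus$otu_id,
      source_db = db,
      process_id = if (db == "BOLD") sprintf("PROC%05d", seq_len(n_otu)) else NA_character_,
      bin = if (db == "BOLD") sprintf("BOLD:AAA%04d", seq_len(n_otu)) else NA_character_,
      hit_pct_id = round(stats::runif(n_otu, 96, 100), 2),
      hit_length = sample(300:650, n_otu, replace = TRUE)
    )
    dplyr::bind_cols(h, tibble::as_tibble(lin_m))
  }
  hits_bold <- enforce_lineage_prefix(mk_hits(bold_lin, "BOLD"), quiet = TRUE)
  hits_ncbi <- enforce_lineage_prefix(mk_hits(ncbi_lin, "NCBI"), quiet = TRUE)

  otu_table <- dplyr::bind_cols(
    tibble::tibble(otu_id = all_otus$otu_id),
    tibble::as_tibble(counts)
  )
  otu_truth <- dplyr::bind_cols(
    all_otus[, c("otu_id", "kind", "is_contaminant")],
    tibble::as_tibble(lin)
  )
  otu_truth$db_dropout <- dropout
  otu_truth$db_disagreement <- disagree

  list(otu_table = otu_table, hits_bold = hits_bold, hits_ncbi = hits_ncbi,
       otu_truth = otu_truth, noise_cells = noise_cells)
}

#' Generate a complete synthetic prey study
#'
#' Runs [make_profiles()], [simulate_samples()] and [simulate_otu_table()]
#' under one config and returns the full fixture set.
#'
#' @param config A [generator_config()].
#' @return List with `config`, `profiles`, `samples`, `photos`, `truth`,
#'   `otu_table`, `hits_bold`, `hits_ncbi`, `otu_truth`, `noise_cells`.
#' @examples
#' study <- simulate_prey_study(generator_config(seed = 42))
#' dim(study$otu_table)
#' @export
simulate_prey_study <- function(config = generator_config()) {
  profiles <- make_profiles(config)
  field <- simulate_samples(profiles, config)
  seq_part <- simulate_otu_table(field$truth, config,
                                 sample_ids = field$samples$sample_id)
  c(list(config = config, profiles = profiles), field, seq_part)
}

#' Write a fixture set as plain-text files
#'
#' Writes `otu_table.tsv` (rows = OTUs, columns = samples),
#' `hits_bold.csv`, `hits_ncbi.csv`, `photos.csv`, `samples.csv`,
#' `truth.csv` and a `manifest.yml` recording the generator config and
#' seed.
#'
#' @param study Output of [simulate_prey_study()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_fixture_set <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(study$otu_table, file.path(dir, "otu_table.tsv"))
  readr::write_csv(study$hits_bold, file.path(dir, "hits_bold.csv"), na = "")
  readr::write_csv(study$hits_ncbi, file.path(dir, "hits_ncbi.csv"), na = "")
  readr::write_csv(study$photos, file.path(dir, "photos.csv"), na = "")
  readr::write_csv(study$samples, file.path(dir, "samples.csv"), na = "")
  readr::write_csv(study$truth, file.path(dir, "truth.csv"), na = "")
  manifest <- unclass(study$config)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yml"))
  invisible(dir)
}
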