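test_that("consensus_lineage matches the longest-common-assigned-prefix oracle", {
  withr::with_seed(101, {
    for (i in 1:300) {
      a <- random_lineage()
      b <- random_lineage()
      expect_identical(consensus_lineage(a, b), oracle_lcp(a, b))
    }
  })
})

test_that("consensus_lineage is commutative, idempotent and depth-monotone", {
  depth_of <- function(x) sum(!is.na(x))
  withr::with_seed(102, {
    for (i in 1:200) {
      a <- random_lineage()
      b <- random_lineage()
      ab <- consensus_lineage(a, b)
      ba <- consensus_lineage(b, a)
      expect_identical(tolower(ab), tolower(ba))
      expect_identical(consensus_lineage(a, a), ifelse(is.na(a), a, trimws(a)))
      expect_lte(depth_of(ab), min(depth_of(a), depth_of(b)))
    }
  })
})

test_that("consensus truncates at the first disagreement or gap", {
  a <- c("Arthropoda", "Insecta", "Diptera", "Muscidae", "Musca", "Musca domestica")
  b <- c("Arthropoda", "Insecta", "Diptera", "Calliphoridae", NA, NA)
  expect_identical(consensus_lineage(a, b),
                   c("Arthropoda", "Insecta", "Diptera", NA, NA, NA))
  # identical full lineages pass through unchanged
  expect_identical(consensus_lineage(a, a), a)
  # case and whitespace are ignored for matching, display case kept
  b2 <- c(" arthropoda ", "INSECTA", "diptera", "muscidae", "musca", "musca domestica")
  expect_identical(consensus_lineage(a, b2), a)
  # gap in one database: strict stops, lenient inherits
  gap <- c("Arthropoda", "Insecta", "Diptera", NA, NA, NA)
  expect_identical(consensus_lineage(a, gap)[4], NA_character_)
  expect_identical(consensus_lineage(a, gap, mode = "lenient")[4:6],
                   c("Muscidae", "Musca", "Musca domestica"))
  # two fully unassigned lineages give a fully unassigned result
  expect_true(all(is.na(consensus_lineage(rep(NA, 6), rep(NA, 6)))))
})

test_that("hit tables round-trip through write and parse", {
  study <- simulate_prey_study(generator_config(seed = 11))
  dir <- withr::local_tempdir()
  write_fixture_set(study, dir)
  for (db in c("bold", "ncbi")) {
    parsed <- parse_hit_table(file.path(dir, sprintf("hits_%s.csv", db)),
                              toupper(db))
    orig <- study[[sprintf("hits_%s", db)]]
    expect_equal(nrow(parsed), nrow(orig))
    expect_identical(parsed$otu_id, orig$otu_id)
    expect_identical(as.matrix(parsed[TAX_RANKS]), as.matrix(orig[TAX_RANKS]))
    expect_equal(parsed$hit_pct_id, orig$hit_pct_id)
  }
})

test_that("parse_hit_table rejects malformed input with row numbers", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "bad.csv")

  readr::write_csv(tibble::tibble(otu_id = "o1", phylum = "Arthropoda"), f)
  expect_error(parse_hit_table(f, "BOLD"), "missing required column")

  tab <- tibble::tibble(otu_id = c("o1", ""), hit_pct_id = c("99", "98"),
                        phylum = "Arthropoda", class = "Insecta",
                        order = "Diptera", family = NA_character_,
                        genus = NA_character_, species = NA_character_)
  readr::write_csv(tab, f, na = "")
  expect_error(parse_hit_table(f, "BOLD"), "empty otu_id.*2")

  tab$otu_id <- c("o1", "o2")
  tab$hit_pct_id <- c("99", "not-a-number")
  readr::write_csv(tab, f, na = "")
  expect_error(parse_hit_table(f, "NCBI"), "hit_pct_id.*2")

  expect_error(parse_hit_table(file.path(dir, "absent.csv"), "BOLD"), "not found")
})

test_that("lineages violating the prefix invariant are truncated on construction", {
  df <- tibble::tibble(phylum = "Arthropoda", class = NA_character_,
                       order = "Diptera", family = "Muscidae",
                       genus = NA_character_, species = NA_character_)
  expect_warning(fixed <- enforce_lineage_prefix(df), "prefix invariant")
  expect_identical(unlist(fixed[1, TAX_RANKS], use.names = FALSE),
                   c("Arthropoda", NA, NA, NA, NA, NA))
})

test_that("consensus_table flags single-database OTUs and rejects duplicates", {
  lin <- function(otu, fam) tibble::tibble(
    otu_id = otu, source_db = "BOLD", process_id = NA, bin = NA,
    hit_pct_id = 99, hit_length = 400L,
    phylum = "Arthropoda", class = "Insecta", order = "Diptera",
    family = fam, genus = NA_character_, species = NA_character_)
  bold <- lin(c("o1", "o2"), c("Muscidae", "Syrphidae"))
  ncbi <- lin(c("o2", "o3"), c("Culicidae", "Muscidae"))

  ct <- consensus_table(bold, ncbi)
  expect_equal(nrow(ct), 3L)
  expect_identical(ct$single_db[match(c("o1", "o3"), ct$otu_id)], c(TRUE, TRUE))
  # o1 keeps the BOLD lineage wholesale
  expect_identical(ct$family[ct$otu_id == "o1"], "Muscidae")
  # o2 disagrees at family -> consensus stops at order
  expect_identical(ct$family[ct$otu_id == "o2"], NA_character_)
  expect_identical(ct$deepest_rank[ct$otu_id == "o2"], "order")

  # disjoint id sets: record count is the sum of table sizes
  ct2 <- consensus_table(lin("a", "Muscidae"), lin("b", "Muscidae"))
  expect_equal(nrow(ct2), 2L)

  expect_error(consensus_table(dplyr::bind_rows(bold, bold[1, ]), ncbi),
               "duplicate otu_id.*o1")
})

test_that("rank_summary counts reach-or-deeper fractions, non-increasing", {
  mk <- function(fams, gens, spps) tibble::tibble(
    otu_id = sprintf("o%d", seq_along(fams)),
    phylum = "Arthropoda", class = "Insecta", order = "Diptera",
    family = fams, genus = gens, species = spps)
  rs <- rank_summary(mk(c("F1", "F2", "F3", "F4"),
                        c(NA, NA, "G3", "G4"),
                        c(NA, NA, NA, "S4")))
  expect_equal(rs$fraction[rs$rank == "family"], 1.0)
  expect_equal(rs$fraction[rs$rank == "genus"], 0.5)
  expect_equal(rs$fraction[rs$rank == "species"], 0.25)
  expect_true(all(diff(rs$fraction) <= 0))

  all_sp <- mk(c("F1", "F2"), c("G1", "G2"), c("S1", "S2"))
  expect_true(all(rank_summary(all_sp)$fraction == 1))

  expect_error(rank_summary(all_sp[0, ]), "empty")

  # property: non-increasing on generated consensus tables
  withr::with_seed(103, {
    study <- simulate_prey_study(generator_config(seed = 5))
    ct <- consensus_table(study$hits_bold, study$hits_ncbi)
    expect_true(all(diff(rank_summary(ct)$fraction) <= 1e-12))
  })
})
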