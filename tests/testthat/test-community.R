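test_that("binary Bray-Curtis reproduces hand-computed values", {
  pm <- tibble::tibble(sample_id = c("s1", "s2"),
                       t1 = c(TRUE, TRUE), t2 = c(TRUE, FALSE),
                       t3 = c(TRUE, TRUE), t4 = c(FALSE, TRUE))
  # a = 2, b = 1, c = 1 -> (1+1)/(4+1+1) = 1/3
  expect_equal(as.vector(binary_bray_curtis(pm)), 1 / 3)

  ident <- tibble::tibble(sample_id = c("a", "b"), t1 = c(TRUE, TRUE))
  expect_equal(as.vector(binary_bray_curtis(ident)), 0)

  disj <- tibble::tibble(sample_id = c("a", "b"),
                         t1 = c(TRUE, FALSE), t2 = c(FALSE, TRUE))
  expect_equal(as.vector(binary_bray_curtis(disj)), 1)

  empty <- tibble::tibble(sample_id = c("a", "b"), t1 = c(FALSE, FALSE))
  expect_warning(d <- binary_bray_curtis(empty), "all-absent")
  expect_equal(as.vector(d), 0)
})

test_that("binary Bray-Curtis matches vegan and is permutation-invariant", {
  skip_if_not_installed("vegan")
  withr::with_seed(31, {
    for (i in 1:10) {
      pm <- random_presence(8, 12)
      d <- binary_bray_curtis(pm)
      m <- as.matrix(pm[-1]) * 1
      expect_equal(as.vector(d), as.vector(vegan::vegdist(m, "bray")),
                   tolerance = 1e-12)
      expect_true(all(as.vector(d) >= 0 & as.vector(d) <= 1))
      # reordering samples permutes the matrix consistently
      perm <- sample(nrow(pm))
      d2 <- as.matrix(binary_bray_curtis(pm[perm, ]))
      expect_equal(d2[pm$sample_id, pm$sample_id], as.matrix(d),
                   tolerance = 1e-12)
    }
  })
})

test_that("ANOSIM R is 1 on perfect separation and matches vegan on random data", {
  # two groups, every between-group distance above every within-group one
  pm <- tibble::tibble(
    sample_id = sprintf("s%d", 1:6),
    t1 = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    t2 = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    t3 = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
    t4 = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE)
  )
  g <- rep(c("A", "B"), each = 3)
  res <- anosim(binary_bray_curtis(pm), g, n_permutations = 99, seed = 1)
  expect_equal(res$R, 1)
  # exact floor for a 3+3 layout is p = 2/20; sampled p sits near it
  expect_lte(res$p_value, 0.2)

  skip_if_not_installed("vegan")
  withr::with_seed(32, {
    for (i in 1:8) {
      pm <- random_presence(10, 10)
      g <- sample(rep(c("A", "B"), each = 5))
      d <- binary_bray_curtis(pm)
      ours <- anosim(d, g, n_permutations = 0)
      veg <- vegan::anosim(as.matrix(pm[-1]) * 1, g, permutations = 0)
      expect_equal(ours$R, unname(veg$statistic), tolerance = 1e-12)
    }
  })
})

test_that("ANOSIM is rank-based: invariant to monotone transforms of distances", {
  withr::with_seed(33, {
    pm <- random_presence(9, 8)
    g <- c("A", "A", "A", "B", "B", "B", "C", "C", "C")
    d <- binary_bray_curtis(pm)
    r1 <- anosim(d, g, n_permutations = 199, seed = 7)
    d2 <- d; d2[] <- d[]^2
    r2 <- anosim(d2, g, n_permutations = 199, seed = 7)
    expect_equal(r1$R, r2$R, tolerance = 1e-12)
    expect_equal(r1$p_value, r2$p_value)
  })
})

test_that("ANOSIM permutation machinery: determinism, null behaviour, errors", {
  withr::with_seed(34, {
    pm <- random_presence(8, 10)
    g <- rep(c("A", "B"), each = 4)
    d <- binary_bray_curtis(pm)
    a1 <- anosim(d, g, n_permutations = 99, seed = 11)
    a2 <- anosim(d, g, n_permutations = 99, seed = 11)
    expect_identical(a1$perm_R, a2$perm_R)
    expect_identical(a1$p_value, a2$p_value)
    # the permutation null is centred near zero
    expect_lt(abs(mean(a1$perm_R)), 0.15)
    expect_true(a1$p_value > 0 && a1$p_value <= 1)

    expect_error(anosim(d, rep("A", 8)), "two groups")
    expect_error(anosim(d, c(rep("A", 7), "B")), "at least two samples")

    tied <- tibble::tibble(sample_id = sprintf("s%d", 1:4),
                           t1 = c(TRUE, FALSE, TRUE, FALSE),
                           t2 = c(FALSE, TRUE, FALSE, TRUE))
    dt <- binary_bray_curtis(tied)  # distances all 0 or 1... make all equal
    dall <- stats::as.dist(matrix(0.5, 4, 4) - diag(0.5, 4))
    attr(dall, "Labels") <- sprintf("s%d", 1:4)
    expect_warning(rz <- anosim(dall, rep(c("A", "B"), 2), n_permutations = 0),
                   "tied")
    expect_equal(rz$R, 0)
  })
})

test_that("exact enumeration agrees with the brute-force oracle at n = 6", {
  withr::with_seed(35, {
    pm <- random_presence(6, 9)
    g <- rep(c("A", "B"), each = 3)
    d <- binary_bray_curtis(pm)
    res <- anosim(d, g, exact = TRUE)
    expect_equal(res$R, oracle_anosim_R(d, g), tolerance = 1e-12)

    labellings <- oracle_labellings(g)
    expect_equal(res$n_permutations, length(labellings))  # choose(6,3) = 20
    oracle_null <- vapply(labellings, function(lab) oracle_anosim_R(d, lab),
                          numeric(1))
    expect_equal(sort(res$perm_R), sort(oracle_null), tolerance = 1e-12)
    p_exact <- mean(oracle_null >= res$R - 1e-12)
    expect_equal(res$p_value, p_exact, tolerance = 1e-12)

    # sampled permutations approach the exact p within binomial error
    samp <- anosim(d, g, n_permutations = 999, seed = 3)
    se <- sqrt(p_exact * (1 - p_exact) / 999)
    expect_lt(abs(samp$p_value - p_exact), 4 * se + 2 / 999)
  })
})

test_that("pairwise ANOSIM recomputes distances per subset", {
  withr::with_seed(36, {
    pm <- random_presence(12, 10)
    g <- stats::setNames(rep(c("A", "B", "C"), each = 4), pm$sample_id)
    res <- pairwise_anosim(pm, groups = g, n_permutations = 49, seed = 5)
    expect_equal(nrow(res), 3)
    expect_setequal(paste(res$group_a, res$group_b),
                    c("A B", "A C", "B C"))
    # each pair equals a fresh ANOSIM on that subset
    sel <- names(g)[g %in% c("A", "B")]
    sub <- pm[pm$sample_id %in% sel, ]
    direct <- anosim(binary_bray_curtis(sub), g[sel], n_permutations = 0)
    expect_equal(res$R[res$group_a == "A" & res$group_b == "B"], direct$R,
                 tolerance = 1e-12)
    # Bonferroni option caps at 1
    adj <- pairwise_anosim(pm, groups = g, n_permutations = 49, seed = 5,
                           adjust = TRUE)
    expect_true(all(adj$p_adjusted <= 1))
    expect_true(all(adj$p_adjusted >= adj$p_value))
  })
})

test_that("SIMPER decomposes the average between-group dissimilarity", {
  # 2x2 toy: A rows (1,0), B rows (0,1) -> each taxon contributes 50%
  pm <- tibble::tibble(sample_id = c("a1", "a2", "b1", "b2"),
                       t1 = c(TRUE, TRUE, FALSE, FALSE),
                       t2 = c(FALSE, FALSE, TRUE, TRUE))
  g <- stats::setNames(c("A", "A", "B", "B"), pm$sample_id)
  sr <- simper(pm, groups = g, pair = c("A", "B"))
  expect_equal(sr$percent_contribution, c(50, 50))
  expect_equal(attr(sr, "average_dissimilarity"), 100)
  expect_identical(sr$more_frequent_group, c("A", "B"))

  # ubiquitous taxon contributes zero
  pm$t3 <- TRUE
  sr2 <- simper(pm, groups = g, pair = c("A", "B"))
  expect_equal(sr2$mean_contribution[sr2$taxon == "t3"], 0)

  # identical groups: undefined
  pm_same <- tibble::tibble(sample_id = c("a1", "a2", "b1", "b2"),
                            t1 = TRUE, t2 = FALSE)
  expect_error(simper(pm_same, groups = g, pair = c("A", "B")),
               "zero dissimilarity|identical groups")
})

test_that("SIMPER sums to 100% and to the mean between-group Bray-Curtis", {
  withr::with_seed(37, {
    for (i in 1:10) {
      pm <- random_presence(9, 12)
      g <- stats::setNames(rep(c("A", "B", "C"), each = 3), pm$sample_id)
      sr <- simper(pm, groups = g, pair = c("A", "C"))
      expect_equal(sum(sr$percent_contribution), 100, tolerance = 1e-9)
      expect_true(all(diff(sr$percent_contribution) <= 1e-12))
      expect_equal(utils::tail(sr$cumulative_percent, 1), 100, tolerance = 1e-9)

      d <- as.matrix(binary_bray_curtis(pm))
      between <- d[g == "A", g == "C"]
      expect_equal(attr(sr, "average_dissimilarity"), mean(between) * 100,
                   tolerance = 1e-9)
    }
  })
})

test_that("SIMPER average contributions match vegan", {
  skip_if_not_installed("vegan")
  withr::with_seed(38, {
    pm <- random_presence(10, 8)
    g <- rep(c("A", "B"), each = 5)
    names(g) <- pm$sample_id
    sr <- simper(pm, groups = g, pair = c("A", "B"))
    veg <- vegan::simper(as.matrix(pm[-1]) * 1, g)
    veg_avg <- veg$A_B$average[match(sr$taxon, rownames(veg$A_B$average) %||%
                                       names(veg$A_B$average))]
    expect_equal(sr$mean_contribution / 100, unname(veg_avg), tolerance = 1e-10)
  })
})

test_that("presence matrices aggregate detections and OR-collapse to orders", {
  dt <- make_detections(
    list(sample_id = "s1", taxon = "Cicadellidae", order = "Hemiptera",
         status = "confirmed"),
    list(sample_id = "s1", taxon = "Curculionidae", order = "Coleoptera",
         status = "excluded"),
    list(sample_id = "s1", taxon = "Muscidae", order = "Diptera"),
    list(sample_id = "s1", taxon = "Other Diptera", order = "Diptera",
         level = "other_order"),
    list(sample_id = "s2", taxon = "Cicadellidae", order = "Hemiptera")
  )
  pm <- build_presence_matrix(dt, "family")
  expect_false("Curculionidae" %in% names(pm))  # excluded, and column all-false
  expect_true(pm$Cicadellidae[pm$sample_id == "s1"])
  expect_true(pm$`Other Diptera`[pm$sample_id == "s1"])

  pmo <- build_presence_matrix(dt, "order")
  # Muscidae + Other Diptera collapse into one Diptera column
  expect_setequal(setdiff(names(pmo), "sample_id"), c("Hemiptera", "Diptera"))
  expect_true(pmo$Diptera[pmo$sample_id == "s1"])
  expect_false(pmo$Diptera[pmo$sample_id == "s2"])

  dt_all_excl <- dt
  dt_all_excl$status <- "excluded"
  expect_error(build_presence_matrix(dt_all_excl, "family"), "no non-excluded")
})

test_that("presence percentages count samples in scope with rounding", {
  dt <- purrr::map_dfr(sprintf("s%02d", 1:30), function(s)
    make_detections(list(sample_id = s, taxon = "Cicadellidae", order = "Hemiptera")))
  dt26 <- dt[1:26, ]
  dt26$taxon <- "Lygaeidae"
  pm <- build_presence_matrix(dplyr::bind_rows(dt, dt26), "family")
  pct <- presence_percentages(pm)
  expect_equal(pct$percent[pct$taxon == "Cicadellidae"], 100)
  # 26 of 30 = 86.67 -> 87 at integer rounding
  expect_equal(pct$percent[pct$taxon == "Lygaeidae"], 87)
  expect_equal(presence_percentages(pm, digits = 2)$percent[2], 86.67)

  g <- stats::setNames(rep(c("X", "Y"), each = 15), sprintf("s%02d", 1:30))
  per <- presence_percentages(pm, "per_species", groups = g)
  expect_equal(nrow(per), 4)
  expect_true(all(per$n_samples == 15))
})
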