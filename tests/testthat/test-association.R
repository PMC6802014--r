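test_that("pearson_chi2 matches the textbook formula", {
  expect_equal(pearson_chi2(matrix(5, 2, 2)), 0)
  expect_equal(pearson_chi2(matrix(c(10, 0, 0, 10), 2, 2)), 20)
  expect_identical(attr(pearson_chi2(matrix(1:3, 1, 3)), "note"), "degenerate")
  set.seed(3)
  for (rep in 1:20) {
    tab <- matrix(rpois(12, 4), 3, 4)
    expect_equal(as.numeric(pearson_chi2(tab)), bf_chi2(tab))
    # agreement with the base-R statistic when defined
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
      ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      expect_equal(as.numeric(pearson_chi2(tab)), unname(ref$statistic))
    }
  }
})

test_that("permutation_test is reproducible, symmetric and sane", {
  set.seed(8)
  a <- sample(c("x", "y"), 40, TRUE)
  b <- sample(c("p", "q", "r"), 40, TRUE)
  r1 <- permutation_test(a, b, n_perm = 499, seed = 11)
  r2 <- permutation_test(a, b, n_perm = 499, seed = 11)
  expect_identical(r1$p_value, r2$p_value)
  # statistic is symmetric in the two margins
  r3 <- permutation_test(b, a, n_perm = 499, seed = 11)
  expect_equal(r1$statistic, r3$statistic)
  # invariant to relabelling categories
  b2 <- c(p = "P1", q = "Q2", r = "R3")[b]
  r4 <- permutation_test(a, b2, n_perm = 499, seed = 11)
  expect_identical(r1$p_value, r4$p_value)
  expect_identical(r1$statistic, r4$statistic)
  # constant vector: degenerate, p = 1
  r5 <- permutation_test(rep("x", 10), sample(c("p", "q"), 10, TRUE))
  expect_identical(r5$note, "degenerate")
  expect_equal(r5$p_value, 1)
  expect_equal(r5$statistic, 0)
  # perfect association on n = 20 hits the add-one floor
  a6 <- rep(c("x", "y"), each = 10)
  r6 <- permutation_test(a6, a6, n_perm = 999, seed = 1)
  expect_equal(r6$statistic, 20)
  expect_equal(r6$p_value, 1 / 1000)
  expect_identical(r6$significance, "***")
})

test_that("Monte-Carlo p agrees with full enumeration on small tables", {
  cases <- list(
    list(a = c("x", "x", "x", "y", "y", "y", "y"),
         b = c("p", "p", "q", "q", "q", "p", "q")),
    list(a = c("x", "x", "y", "y", "x", "y"),
         b = c("p", "q", "p", "q", "p", "q")),
    list(a = c("x", "x", "x", "x", "y", "y", "y", "y"),
         b = c("p", "p", "p", "q", "q", "q", "q", "p")))
  for (cs in cases) {
    ex <- enumeration_test(cs$a, cs$b)
    mc <- permutation_test(cs$a, cs$b, n_perm = 19999, seed = 5)
    se <- sqrt(ex$p_value * (1 - ex$p_value) / 19999)
    expect_equal(mc$statistic, ex$statistic)
    expect_lt(abs(mc$p_value - ex$p_value), 3 * se + 2 / 19999)
  }
})

test_that("encode_infection implements every coding scheme", {
  rec <- data.frame(
    specimen_id = paste0("s", 1:6),
    taxon = "t", region = "r", cox1_haplotype = paste0("H", 1:6),
    wg_genotype = "", status = c("uninfected", "single", "double", "double",
                                 "ambiguous", "double"),
    st1 = c(NA, "wCallB2", "wCallA1", "wCallA1", NA, "wCallB1"),
    st2 = c(NA, NA, "wCallC1", "wCallA6", NA, "wCallC1"),
    uncertain = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  e <- encode_infection(rec, "infection_level")
  expect_identical(e$labels,
                   c("uninfected", "single", "double", "double", NA, "double"))
  e <- encode_infection(rec, "group")
  expect_identical(e$labels, c(NA, "B", "A+C", "A", NA, NA))
  expect_true("uncertain ST assignment" %in% e$excluded$reason)
  e <- encode_infection(rec, "genotype")
  expect_identical(e$labels[2:4],
                   c("wCallB2", "wCallA1+wCallC1", "wCallA1+wCallA6"))
  e <- encode_infection(rec, "genotype_with_uninfected")
  expect_identical(e$labels[1L], "uninfected")
  e <- encode_infection(rec, "level_and_group")
  expect_identical(e$labels[3L], "double:A+C")
  e <- encode_infection(rec, "level_and_genotype")
  expect_identical(e$labels[2L], "single:wCallB2")
})

test_that("run_battery holds its type-I error under a simulated null", {
  set.seed(123)
  n <- 200L
  reps <- 200L
  hits <- 0L
  for (r in seq_len(reps)) {
    a <- sample(c("c1", "c2", "c3"), n, TRUE)
    b <- sample(c("uninfected", "single", "double"), n, TRUE)
    p <- permutation_test(a, b, n_perm = 199, seed = r)$p_value
    if (p <= 0.05) hits <- hits + 1L
  }
  rate <- hits / reps
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.085)
})

test_that("run_battery finds a planted clade-exclusive strain and skips degenerate cells", {
  set.seed(77)
  tab <- data.frame(haplotype = paste0("H", 1:8),
                    clade_L1 = rep(c("c1", "c2", "c3", "c4"), each = 2),
                    clade_L2 = rep(c("top1", "top2"), each = 4),
                    stringsAsFactors = FALSE)
  h <- import_nesting(tab)
  n <- 120L
  hap <- sample(tab$haplotype, n, TRUE)
  status <- rep("single", n)
  st1 <- ifelse(hap %in% tab$haplotype[1:4], "wCallB1", "wCallC2")
  rec <- data.frame(specimen_id = paste0("s", 1:n), taxon = "t", region = "r",
                    cox1_haplotype = hap, wg_genotype = "",
                    status = status, st1 = st1, st2 = NA_character_,
                    uncertain = FALSE, stringsAsFactors = FALSE)
  rep_ <- run_battery(rec, h, schemes = c("infection_level", "genotype"),
                      n_perm = 1999, seed = 42)
  res <- rep_$results
  total_geno <- res[res$clade == "Total" & res$scheme == "genotype", ]
  expect_equal(nrow(total_geno), 1L)
  expect_lte(total_geno$p_value, 0.001)
  expect_identical(total_geno$significance, "***")
  # infection_level is constant -> skipped everywhere as degenerate
  expect_true(all(rep_$skipped$scheme[rep_$skipped$clade == "Total"] ==
                    "infection_level"))
  # within level-2 clades the strain is uniform -> genotype degenerate there
  expect_true(all(c("top1", "top2") %in%
                    rep_$skipped$clade[rep_$skipped$scheme == "genotype"]))
  # determinism of the full report
  rep2 <- run_battery(rec, h, schemes = c("infection_level", "genotype"),
                      n_perm = 1999, seed = 42)
  expect_identical(rep_, rep2)
  # unknown haplotypes are named
  rec$cox1_haplotype[1L] <- "H99"
  expect_error(run_battery(rec, h), "H99")
})

test_that("wg_association mirrors the battery on the nuclear axis", {
  set.seed(5)
  tab <- data.frame(haplotype = paste0("H", 1:6),
                    clade_L1 = rep(c("c1", "c2"), each = 3),
                    stringsAsFactors = FALSE)
  h <- import_nesting(tab)
  n <- 150L
  hap <- sample(tab$haplotype, n, TRUE)
  st1 <- ifelse(hap %in% tab$haplotype[1:3], "wCallB1", "wCallC2")
  wg <- ifelse(st1 == "wCallB1", "W1", "W2")            # planted association
  flip <- sample(n, 10)
  wg[flip] <- sample(c("W1", "W2"), 10, TRUE)
  rec <- data.frame(specimen_id = paste0("s", 1:n), taxon = "t", region = "r",
                    cox1_haplotype = hap, wg_genotype = wg, status = "single",
                    st1 = st1, st2 = NA_character_, uncertain = FALSE,
                    stringsAsFactors = FALSE)
  out <- wg_association(rec, h, schemes = "genotype", all = TRUE,
                        n_perm = 499, seed = 9)
  tot <- out[out$clade == "Total", ]
  expect_lte(tot$p_value, 0.002)
  # under a shuffled Wg the association disappears in most replicates
  hits <- 0L
  for (r in 1:40) {
    rec$wg_genotype <- sample(wg)
    o <- wg_association(rec, h, schemes = "genotype", all = TRUE,
                        n_perm = 199, seed = r)
    if (nrow(o) && any(o$p_value[o$clade == "Total"] <= 0.05)) hits <- hits + 1L
  }
  expect_lte(hits / 40, 0.10 + 0.12)  # nominal 5% plus binomial slack
  # no Wg data: empty result
  rec$wg_genotype <- ""
  expect_equal(nrow(wg_association(rec, h, all = TRUE)), 0L)
})
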