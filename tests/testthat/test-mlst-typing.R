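test_that("trim_to_fragment recovers the fragment from flanked and mutated reads", {
  set.seed(11)
  flank <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  for (loc in c("gatB", "fbpA")) {
    ref_id <- db_allele_ids(fx_db, loc)[1L]
    ref <- db_sequence(fx_db, loc, ref_id)
    raw <- paste0(flank(20), ref, flank(20))
    expect_identical(trim_to_fragment(raw, loc, fx_db), ref)
    expect_identical(trim_to_fragment(ref, loc, fx_db), ref)  # already trimmed
    # two internal substitutions must not shift the window
    mutated <- ref
    substr(mutated, 50, 50) <- setdiff(c("A", "C", "G", "T"),
                                       substr(ref, 50, 50))[1L]
    substr(mutated, 200, 200) <- setdiff(c("A", "C", "G", "T"),
                                         substr(ref, 200, 200))[1L]
    got <- trim_to_fragment(paste0(flank(15), mutated, flank(25)), loc, fx_db)
    expect_identical(got, mutated)
    expect_equal(sum(strsplit(got, "")[[1]] != strsplit(ref, "")[[1]]), 2L)
  }
  junk <- paste(rep("ACGT", 200), collapse = "")
  expect_error(trim_to_fragment(junk, "gatB", fx_db), "untypeable")
})

test_that("call_allele distinguishes known, novel, mixture and unresolved", {
  seq_c <- db_sequence(fx_db, "gatB", "c")
  expect_identical(call_allele("gatB", seq_c, fx_db)$status, "known")
  expect_identical(call_allele("gatB", seq_c, fx_db)$allele_id, "c")
  # clean novel sequence: minted on request with the next free letter id
  novel <- seq_c
  substr(novel, 7, 7) <- setdiff(c("A", "C", "G", "T"), substr(novel, 7, 7))[1L]
  res <- call_allele("gatB", novel, fx_db, mint = TRUE)
  expect_identical(res$status, "novel")
  expect_identical(res$allele_id, "e")  # a-d and r taken
  expect_identical(db_sequence(res$db, "gatB", "e"), novel)
  # union of two alleles decodes to the pair
  mix <- iupac_union(seq_c, db_sequence(fx_db, "gatB", "d"))
  res <- call_allele("gatB", mix, fx_db)
  expect_identical(res$status, "mixture")
  expect_identical(res$pair, c("c", "d"))
  # a three-allele union at a diagnostic site is unresolved
  tri <- strsplit(mix, "")[[1]]
  amb <- which(!tri %in% c("A", "C", "G", "T"))[1L]
  tri[amb] <- "N"
  expect_identical(call_allele("gatB", paste(tri, collapse = ""), fx_db)$status,
                   "unresolved")
})

test_that("mixture calls decode every allele pair at every locus", {
  for (loc in MLST_LOCI) {
    ids <- db_allele_ids(fx_db, loc)
    for (i in seq_len(length(ids) - 1L)) for (j in (i + 1L):length(ids)) {
      mix <- iupac_union(db_sequence(fx_db, loc, ids[i]),
                         db_sequence(fx_db, loc, ids[j]))
      res <- call_allele(loc, mix, fx_db)
      info <- paste(loc, ids[i], ids[j])
      expect_identical(res$status, "mixture", info = info)
      expect_identical(res$pair, sort(c(ids[i], ids[j])), info = info)
    }
  }
})

test_that("assign_group follows the gatB rule and partitions the fixture", {
  expect_identical(assign_group(fx_profile("wCallA1")), "wCallA")
  expect_identical(assign_group(fx_profile("wCallB1")), "wCallB")
  expect_identical(assign_group(fx_profile("wCallC2")), "wCallC")
  expect_error(assign_group(mlst_profile("z", "33", "42", "32", "36")),
               "unmapped gatB")
  groups <- vapply(fx_st$st_id, function(id) assign_group(fx_profile(id)), "")
  expect_identical(unname(groups), fx_st$group)
  expect_identical(sort(unique(fx_st$group)), c("wCallA", "wCallB", "wCallC"))
})

test_that("the fixture inventory matches the published allele and type counts", {
  expect_equal(nrow(fx_st), 15L)
  expect_equal(sum(fx_st$provenance == "observed"), 7L)
  expect_equal(sum(fx_st$provenance == "deduced"), 8L)
  counts <- vapply(MLST_LOCI, function(l) length(unique(fx_st[[l]])), 0L)
  expect_equal(unname(counts), c(4L, 2L, 3L, 3L, 5L))  # gatB..fbpA; 17 alleles
  # every deduced profile is one allele change from another fixture type
  d <- fx_distance_matrix()
  for (id in fx_st$st_id[fx_st$provenance == "deduced"]) {
    expect_equal(min(d[id, setdiff(fx_st$st_id, id)]), 1L, info = id)
  }
})

test_that("profile_distance is a metric and matches the published examples", {
  expect_equal(profile_distance(fx_profile("wCallB1"), fx_profile("wCallB2")), 1L)
  expect_equal(profile_distance(fx_profile("wCallA1"), fx_profile("wCallC2")), 4L)
  expect_equal(profile_distance(fx_profile("wCallA1"), fx_profile("wCallA1")), 0L)
  set.seed(42)
  rand_prof <- function() mlst_profile(
    c(sample(letters[1:4], 1), sample(c("33", "b"), 1), sample(c("42", "b", "c"), 1),
      sample(c("32", "75", "b"), 1), sample(c("36", "b", "c", "d", "e"), 1)))
  for (rep in 1:50) {
    p <- rand_prof(); q <- rand_prof(); r <- rand_prof()
    expect_identical(profile_distance(p, q), profile_distance(q, p))
    expect_identical(profile_distance(p, q) == 0L, identical(p, q))
    expect_true(profile_distance(p, r) <=
                  profile_distance(p, q) + profile_distance(q, r))
  }
})

test_that("detect_chimera finds the single-breakpoint gatB mosaic and nothing else", {
  frag_r <- db_sequence(fx_db, "gatB", "r")
  db_no_r <- fx_db
  db_no_r$alleles$gatB <- db_no_r$alleles$gatB[names(db_no_r$alleles$gatB) != "r"]
  rep <- detect_chimera(frag_r, "gatB", db_no_r)
  expect_true(rep$is_chimeric)
  expect_identical(rep$parent_ids, c("c", "d"))
  w <- rep$breakpoint_window
  expect_true(w[1L] >= 0 && w[2L] <= 369 && w[1L] < w[2L])
  # the window is exactly the stretch between the last c-specific and the
  # first d-specific difference (exhaustive check of every breakpoint)
  f <- strsplit(frag_r, "")[[1]]
  cc <- strsplit(db_sequence(fx_db, "gatB", "c"), "")[[1]]
  dd <- strsplit(db_sequence(fx_db, "gatB", "d"), "")[[1]]
  valid <- vapply(1:368, function(t)
    all(f[1:t] == cc[1:t]) && all(f[(t + 1):369] == dd[(t + 1):369]), TRUE)
  expect_identical(which(valid), seq.int(w[1L], w[2L] - 1L))
  # an unmodified allele is not chimeric
  expect_false(detect_chimera(db_sequence(fx_db, "gatB", "c"), "gatB",
                              db_no_r)$is_chimeric)
  # a two-breakpoint mosaic fails the single-breakpoint model
  two_bp <- c(cc[1:100], dd[101:250], cc[251:369])
  expect_false(all(two_bp == cc) || all(two_bp == dd))
  expect_false(detect_chimera(paste(two_bp, collapse = ""), "gatB",
                              db_no_r)$is_chimeric)
})

test_that("allele databases round-trip through per-locus FASTA", {
  dir <- withr::local_tempdir()
  write_allele_db(fx_db, dir)
  back <- read_allele_db(dir)
  expect_identical(back$alleles, fx_db$alleles)
})

test_that("ST tables round-trip and reject inconsistent groups", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_st_table(fx_st, path)
  expect_identical(read_st_table(path), fx_st)
  bad <- fx_st
  bad$group[bad$st_id == "wCallA1"] <- "wCallB"
  expect_error(validate_st_table(bad), "disagrees")
})
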