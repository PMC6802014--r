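#' Encode resolved infection records under a coding scheme
#'
#' The contingency battery tests infection against the mtDNA clade
#' hierarchy under several codings of the infection variable:
#' * `infection_level`: uninfected / single / double;
#' * `group`: the sorted combination of wCall groups carried, as one label
#'   ("A", "A+C", ...), infected records only;
#' * `level_and_group`: infection level crossed with the group combination,
#'   including an "uninfected" category;
#' * `genotype`: the sorted ST combination ("wCallA1+wCallB1"), infected
#'   records only; `genotype_with_uninfected` adds the uninfected category;
#' * `level_and_genotype` (`_with_uninfected`): level crossed with the ST
#'   combination.
#'
#' Records whose ST assignment is uncertain (flagged by the deconvolution)
#' are kept under level-based schemes at their observed level but excluded
#' from genotype and group schemes; ambiguous records are excluded from
#' all schemes except `infection_level` when their level is known.
#' Exclusions are returned, never silent.
#'
#' @param records resolved records from [classify_cohort()].
#' @param scheme one of the names above.
#' @return list with `labels` (character, NA = excluded), `included`
#'   (logical), `excluded` (data.frame specimen_id, reason).
#' @export
encode_infection <- function(records,
                             scheme = c("infection_level", "group",
                                        "level_and_group", "genotype",
                                        "genotype_with_uninfected",
                                        "level_and_genotype",
                                        "level_and_genotype_with_uninfected")) {
  scheme <- match.arg(scheme)
  n <- nrow(records)
  status <- records$status
  uncertain <- if (!is.null(records$uncertain)) records$uncertain else
    rep(FALSE, n)
  sts <- record_sts(records)
  grp_of <- function(st) {
    g <- sub("^(wCall[A-Z]).*$", "\\1", st)
    sub("^wCall", "", g)
  }
  combo <- vapply(sts, function(s)
    if (length(s)) paste(sort(s), collapse = "+") else NA_character_, "")
  gcombo <- vapply(sts, function(s)
    if (length(s)) paste(sort(unique(grp_of(s))), collapse = "+") else
      NA_character_, "")
  lab <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  with_uninf <- scheme %in% c("infection_level", "level_and_group",
                              "genotype_with_uninfected",
                              "level_and_genotype_with_uninfected")
  uses_genotype <- grepl("genotype", scheme)
  uses_group <- grepl("group", scheme)
  for (i in seq_len(n)) {
    if (status[i] == "uninfected") {
      if (with_uninf) lab[i] <- "uninfected" else reason[i] <- "uninfected record excluded by scheme"
      next
    }
    if (status[i] == "ambiguous") {
      if (scheme == "infection_level") reason[i] <- "ambiguous resolution"
      else reason[i] <- "ambiguous resolution"
      next
    }
    if ((uses_genotype || uses_group) && uncertain[i]) {
      reason[i] <- "uncertain ST assignment"
      next
    }
    lab[i] <- switch(scheme,
      infection_level = status[i],
      group = gcombo[i],
      level_and_group = paste(status[i], gcombo[i], sep = ":"),
      genotype = combo[i],
      genotype_with_uninfected = combo[i],
      level_and_genotype = paste(status[i], combo[i], sep = ":"),
      level_and_genotype_with_uninfected = paste(status[i], combo[i], sep = ":"))
  }
  excluded <- data.frame(
    specimen_id = records$specimen_id[!is.na(reason)],
    reason = reason[!is.na(reason)], stringsAsFactors = FALSE)
  list(labels = lab, included = !is.na(lab), excluded = excluded)
}

#' Pearson chi-square statistic of a contingency table
#'
#' Plain sum of (observed - expected)^2 / expected with expectations from
#' the row/column margins; no continuity correction (the permutation null
#' supplies the reference distribution). Degenerate 1 x k or k x 1 tables
#' return 0 with a note.
#'
#' @param table a count matrix.
#' @return numeric statistic, with attribute `"note"` set to "degenerate"
#'   when the pruned table has fewer than 2 rows or columns.
#' @export
pearson_chi2 <- function(table) {
  table <- as.matrix(table)
  table <- table[rowSums(table) > 0, colSums(table) > 0, drop = FALSE]
  if (nrow(table) < 2L || ncol(table) < 2L) {
    return(structure(0, note = "degenerate"))
  }
  e <- outer(rowSums(table), colSums(table)) / sum(table)
  sum((table - e)^2 / e)
}

# fast chi2 from two integer factor codings (no pruning needed: zero
# rows/columns contribute 0 and margins are unchanged)
.chi2_codes <- function(ia, ib, nr, nc) {
  tab <- matrix(tabulate(ia + nr * (ib - 1L), nbins = nr * nc), nr, nc)
  rs <- rowSums(tab); cs <- colSums(tab)
  e <- outer(rs, cs) / sum(tab)
  ok <- e > 0
  sum((tab[ok] - e[ok])^2 / e[ok])
}

#' Permutation chi-square test of independence
#'
#' Cross-tabulates two categorical vectors and assesses the Pearson
#' statistic against the permutation null obtained by uniformly shuffling
#' one vector. The p-value uses the add-one Monte-Carlo estimator
#' p = (1 + #\{permuted >= observed\}) / (1 + n_perm), which is unbiased
#' and never returns 0.
#'
#' @param labels_a,labels_b equal-length category vectors (NAs dropped
#'   pairwise).
#' @param n_perm number of permutations (default 9999).
#' @param seed integer seed for reproducibility (NULL = current RNG state).
#' @return a `contingency_result`: list with `statistic`, `p_value`,
#'   `n`, `n_perm`, `dims`, `significance` ("" / "*" / "**" / "***" at
#'   .05/.01/.001) and `note`.
#' @export
permutation_test <- function(labels_a, labels_b, n_perm = 9999L, seed = NULL) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors differ in length", call. = FALSE)
  keep <- !is.na(labels_a) & !is.na(labels_b)
  a <- factor(labels_a[keep]); b <- factor(labels_b[keep])
  n <- length(a)
  if (n < 2L || nlevels(a) < 2L || nlevels(b) < 2L) {
    return(structure(list(statistic = 0, p_value = 1, n = n, n_perm = 0L,
                          dims = c(nlevels(a), nlevels(b)),
                          significance = "", note = "degenerate"),
                     class = "contingency_result"))
  }
  ia <- as.integer(a); ib <- as.integer(b)
  nr <- nlevels(a); nc <- nlevels(b)
  obs <- .chi2_codes(ia, ib, nr, nc)
  runner <- function() {
    ge <- 0L
    for (k in seq_len(n_perm)) {
      if (.chi2_codes(ia, ib[sample.int(n)], nr, nc) >= obs - 1e-12)
        ge <- ge + 1L
    }
    ge
  }
  ge <- if (is.null(seed)) runner() else {
    old <- .Random.seed_exists()
    set.seed(seed)
    on.exit(.restore_seed(old), add = TRUE)
    runner()
  }
  p <- (1 + ge) / (1 + n_perm)
  structure(list(statistic = obs, p_value = p, n = n, n_perm = n_perm,
                 dims = c(nr, nc), significance = .sig_tier(p), note = ""),
            class = "contingency_result")
}

.sig_tier <- function(p) {
  if (p <= 0.001) "***" else if (p <= 0.01) "**" else if (p <= 0.05) "*" else ""
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("chi2 = %.4f%s  (n = %d, %dx%d, p = %.4g, %d perms)%s\n",
              x$statistic, x$significance, x$n, x$dims[1L], x$dims[2L],
              x$p_value, x$n_perm,
              if (nzchar(x$note)) paste0(" [", x$note, "]") else ""))
  invisible(x)
}

#' Exact permutation p-value by full enumeration
#'
#' Enumerates all n! orderings of one label vector (feasible for n <= 8)
#' and returns the exact conditional probability of a chi-square at least
#' as large as observed. Serves as the reference for the Monte-Carlo
#' estimator on small tables.
#'
#' @inheritParams permutation_test
#' @return list with `statistic` and `p_value`.
#' @export
enumeration_test <- function(labels_a, labels_b) {
  keep <- !is.na(labels_a) & !is.na(labels_b)
  a <- factor(labels_a[keep]); b <- factor(labels_b[keep])
  n <- length(a)
  if (n > 8L) stop("full enumeration limited to n <= 8", call. = FALSE)
  ia <- as.integer(a); ib <- as.integer(b)
  nr <- nlevels(a); nc <- nlevels(b)
  obs <- .chi2_codes(ia, ib, nr, nc)
  perms <- .all_perms(n)
  ge <- 0L
  for (k in seq_len(nrow(perms))) {
    if (.chi2_codes(ia, ib[perms[k, ]], nr, nc) >= obs - 1e-12) ge <- ge + 1L
  }
  list(statistic = obs, p_value = ge / nrow(perms))
}

.all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .all_perms(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out[r + seq_len(nrow(sub)), 1L] <- i
    out[r + seq_len(nrow(sub)), -1L] <- matrix(rest[sub], nrow(sub))
    r <- r + nrow(sub)
  }
  out
}

#' Run the nested-clade contingency battery
#'
#' For the whole dataset and for every clade at every hierarchy level, the
#' records falling inside the clade are cross-tabulated — subclade
#' membership one level down (haplotype identity below 1-step clades)
#' against each requested infection coding — and assessed by
#' [permutation_test()]. Tables where either variable has a single
#' observed category are skipped as degenerate, with the reason recorded.
#'
#' @param records resolved records from [classify_cohort()] with
#'   `cox1_haplotype` present in the hierarchy.
#' @param hierarchy a `nested_hierarchy` (see [nest_clades()],
#'   [import_nesting()]).
#' @param schemes coding scheme names (see [encode_infection()]).
#' @param n_perm permutations per table (default 9999).
#' @param seed integer; every table's test derives its own substream
#'   deterministically from this seed.
#' @return a `battery_report`: list with `results` (data.frame: clade,
#'   level, scheme, n, statistic, p_value, dims, significance, note),
#'   `skipped` (data.frame with reasons) and `summary` (per-level fraction
#'   of significant tests at .05).
#' @export
run_battery <- function(records, hierarchy,
                        schemes = c("infection_level", "level_and_group",
                                    "group", "genotype_with_uninfected",
                                    "genotype",
                                    "level_and_genotype_with_uninfected",
                                    "level_and_genotype"),
                        n_perm = 9999L, seed = 1L) {
  hap <- records$cox1_haplotype
  nlev <- length(hierarchy$levels)
  memb <- lapply(seq_len(nlev), function(k) clade_at_level(hierarchy, hap, k))
  enc <- lapply(schemes, function(s) encode_infection(records, s))
  names(enc) <- schemes
  res <- list(); skipped <- list()
  tid <- 0L
  run_one <- function(clade_label, level, rows_axis, idx) {
    for (s in schemes) {
      tid <<- tid + 1L
      lab <- enc[[s]]$labels[idx]
      keep <- !is.na(lab)
      a <- rows_axis[keep]; b <- lab[keep]
      if (length(unique(a)) < 2L || length(unique(b)) < 2L) {
        skipped[[length(skipped) + 1L]] <<- data.frame(
          clade = clade_label, level = level, scheme = s,
          reason = "degenerate: a single category on one axis",
          stringsAsFactors = FALSE)
        next
      }
      r <- permutation_test(a, b, n_perm = n_perm, seed = seed + tid)
      res[[length(res) + 1L]] <<- data.frame(
        clade = clade_label, level = level, scheme = s, n = r$n,
        statistic = r$statistic, p_value = r$p_value,
        rows = r$dims[1L], cols = r$dims[2L],
        significance = r$significance, note = r$note,
        stringsAsFactors = FALSE)
    }
  }
  # whole dataset: rows = membership at the highest level
  run_one("Total", nlev + 1L, memb[[nlev]], seq_along(hap))
  # every clade at levels >= 1; rows = membership one level down
  for (k in rev(seq_len(nlev))) {
    for (cl in sort(unique(memb[[k]]))) {
      idx <- which(memb[[k]] == cl)
      rows_axis <- if (k == 1L) hap[idx] else memb[[k - 1L]][idx]
      run_one(cl, k, rows_axis, idx)
    }
  }
  results <- if (length(res)) do.call(rbind, res) else NULL
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(clade = character(), level = integer(), scheme = character(),
               reason = character(), stringsAsFactors = FALSE)
  summary <- NULL
  if (!is.null(results)) {
    summary <- do.call(rbind, lapply(split(results, results$level), function(d)
      data.frame(level = d$level[1L], n_tests = nrow(d),
                 frac_significant = mean(d$p_value <= 0.05))))
    rownames(summary) <- NULL
  }
  structure(list(results = results, skipped = skipped, summary = summary,
                 n_perm = n_perm, seed = seed),
            class = "battery_report")
}

#' @export
print.battery_report <- function(x, ...) {
  cat("<battery_report> ", if (is.null(x$results)) 0L else nrow(x$results),
      " tests, ", nrow(x$skipped), " skipped (n_perm = ", x$n_perm, ")\n",
      sep = "")
  if (!is.null(x$summary)) print(x$summary)
  invisible(x)
}

#' Association of Wolbachia infection with nuclear Wg genotypes
#'
#' Runs the same permutation machinery with the specimen's Wg genotype as
#' the second axis, within each clade. By default only (clade, scheme)
#' pairs whose mtDNA-axis test was significant at .05 are followed up,
#' mirroring the design where nuclear tests probe whether an mtDNA
#' association extends to the nuclear background; `all = TRUE` tests every
#' clade. Records without a Wg genotype are excluded (with a note), so the
#' effective n can be smaller than the mtDNA test's.
#'
#' @param records resolved records with a `wg_genotype` column.
#' @param hierarchy the clade hierarchy.
#' @param schemes infection codings to cross with Wg (default infection
#'   level and genotype).
#' @param mt_report optionally, a `battery_report` from [run_battery()]
#'   used to select significant (clade, scheme) pairs.
#' @param all test all clades regardless of the mtDNA results.
#' @inheritParams run_battery
#' @return data.frame like a battery's `results`, plus `n_missing_wg`.
#' @export
wg_association <- function(records, hierarchy,
                           schemes = c("infection_level", "genotype"),
                           mt_report = NULL, all = is.null(mt_report),
                           n_perm = 9999L, seed = 1L) {
  has_wg <- !is.na(records$wg_genotype) & nzchar(records$wg_genotype)
  if (!any(has_wg)) return(data.frame())
  hap <- records$cox1_haplotype
  nlev <- length(hierarchy$levels)
  memb <- lapply(seq_len(nlev), function(k) clade_at_level(hierarchy, hap, k))
  enc <- lapply(schemes, function(s) encode_infection(records, s))
  names(enc) <- schemes
  clades <- c(list(c("Total", nlev + 1L)),
              unlist(lapply(seq_len(nlev), function(k)
                lapply(sort(unique(memb[[k]])), function(cl) c(cl, k))),
                recursive = FALSE))
  sig_ok <- function(cl) {
    if (all) return(TRUE)
    any(mt_report$results$clade == cl & mt_report$results$p_value <= 0.05)
  }
  out <- list(); tid <- 0L
  for (cld in clades) {
    cl <- cld[1L]; k <- as.integer(cld[2L])
    if (!sig_ok(cl)) next
    idx <- if (cl == "Total") seq_along(hap) else which(memb[[k]] == cl)
    for (s in schemes) {
      tid <- tid + 1L
      lab <- enc[[s]]$labels[idx]
      keep <- !is.na(lab) & has_wg[idx]
      a <- records$wg_genotype[idx][keep]; b <- lab[keep]
      if (length(unique(a)) < 2L || length(unique(b)) < 2L) next
      r <- permutation_test(a, b, n_perm = n_perm, seed = seed + tid)
      out[[length(out) + 1L]] <- data.frame(
        clade = cl, level = k, scheme = paste0("wg_", s), n = r$n,
        statistic = r$statistic, p_value = r$p_value,
        rows = r$dims[1L], cols = r$dims[2L],
        significance = r$significance,
        n_missing_wg = sum(!has_wg[idx]), stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else data.frame()
}
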