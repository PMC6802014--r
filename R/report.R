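#' Round half away from zero, to one decimal by default
#'
#' Display convention for percentages; stored fractions are never altered.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return numeric.
#' @export
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Prevalence and carrier tabulations of a resolved cohort
#'
#' Exact integer counts of infection levels and of carriers of each
#' sequence type (alone or in combination), with percentages on both
#' denominators: all specimens, and infected specimens (single + double +
#' ambiguous). Records whose ST assignment is uncertain count towards
#' their infection level but not towards any named ST's carrier tally;
#' variant (mosaic) types are tallied under their own id, never under
#' their base type.
#'
#' @param records resolved records from [classify_cohort()].
#' @return a `prevalence_summary`: list with scalar counts (`n_total`,
#'   `n_uninfected`, `n_single`, `n_double`, `n_ambiguous`, `n_infected`),
#'   `pct` (display-rounded percentages incl. `double_of_infected`),
#'   `per_st` (data.frame st_id, n_carriers, pct_total, pct_infected),
#'   `per_group`, `per_taxon`, `per_region` breakdowns, and raw fractions
#'   in `frac`.
#' @export
tabulate_prevalence <- function(records) {
  n <- nrow(records)
  status <- records$status
  cnt <- function(s) sum(status == s)
  n_uninf <- cnt("uninfected"); n_single <- cnt("single")
  n_double <- cnt("double"); n_ambig <- cnt("ambiguous")
  n_inf <- n_single + n_double + n_ambig
  certain <- status %in% c("single", "double") &
    !(if (!is.null(records$uncertain)) records$uncertain else FALSE)
  sts <- record_sts(records)
  carrier_tab <- if (any(certain))
    sort(table(unlist(sts[certain])), decreasing = TRUE) else
    table(character())
  pct <- function(num, den) if (den > 0) 100 * num / den else 0
  per_st <- if (length(carrier_tab)) data.frame(
    st_id = names(carrier_tab),
    n_carriers = as.integer(carrier_tab),
    pct_total = round_half_up(pct(as.integer(carrier_tab), n)),
    pct_infected = round_half_up(pct(as.integer(carrier_tab), n_inf)),
    stringsAsFactors = FALSE) else data.frame(
    st_id = character(), n_carriers = integer(), pct_total = numeric(),
    pct_infected = numeric(), stringsAsFactors = FALSE)
  grp_of <- function(s) sub("^(wCall[A-Z]).*$", "\\1", s)
  groups <- lapply(sts, function(s) unique(grp_of(s)))
  grp_tab <- if (any(certain)) table(unlist(groups[certain])) else
    table(character())
  per_group <- data.frame(group = names(grp_tab),
                          n_carriers = as.integer(grp_tab),
                          stringsAsFactors = FALSE)
  bylevel <- function(key) {
    t(vapply(split(status, key), function(s)
      c(n = length(s), uninfected = sum(s == "uninfected"),
        single = sum(s == "single"), double = sum(s == "double"),
        ambiguous = sum(s == "ambiguous")), numeric(5)))
  }
  structure(list(
    n_total = n, n_uninfected = n_uninf, n_single = n_single,
    n_double = n_double, n_ambiguous = n_ambig, n_infected = n_inf,
    frac = list(infected = if (n) n_inf / n else 0,
                double_of_infected = if (n_inf) n_double / n_inf else 0,
                uninfected = if (n) n_uninf / n else 0),
    pct = list(infected = round_half_up(pct(n_inf, n)),
               uninfected = round_half_up(pct(n_uninf, n)),
               double_of_infected = round_half_up(pct(n_double, n_inf)),
               single_of_infected = round_half_up(pct(n_single, n_inf))),
    per_st = per_st, per_group = per_group,
    per_taxon = bylevel(records$taxon),
    per_region = bylevel(records$region)),
    class = "prevalence_summary")
}

#' @export
print.prevalence_summary <- function(x, ...) {
  cat("<prevalence_summary> n =", x$n_total, "\n")
  cat(sprintf("  uninfected %d  single %d  double %d  ambiguous %d\n",
              x$n_uninfected, x$n_single, x$n_double, x$n_ambiguous))
  cat(sprintf("  infected: %.1f%%;  double among infected: %.1f%%\n",
              x$pct$infected, x$pct$double_of_infected))
  if (nrow(x$per_st)) {
    cat("  top sequence types (% of infected):\n")
    top <- utils::head(x$per_st, 5L)
    for (i in seq_len(nrow(top)))
      cat(sprintf("    %-10s %4d  %5.1f%%\n", top$st_id[i],
                  top$n_carriers[i], top$pct_infected[i]))
  }
  invisible(x)
}

#' Infection breakdown of the unisexual taxa
#'
#' Proportions of the named (unisexual) taxa that are uninfected, carry
#' wCallA1 alone, or carry wCallA1 doubly with wCallC1 or wCallB1.
#'
#' @param records resolved records.
#' @param unisexual_taxa character vector of taxon labels.
#' @return data.frame with category, n, proportion and display percent.
#' @export
unisexual_breakdown <- function(records,
                                unisexual_taxa = c("C. suturella", "C. vicina")) {
  unknown <- setdiff(unisexual_taxa, unique(records$taxon))
  if (length(unknown))
    stop("unknown taxon label: ", paste(unknown, collapse = ","), call. = FALSE)
  sel <- records[records$taxon %in% unisexual_taxa, , drop = FALSE]
  n <- nrow(sel)
  sts <- record_sts(sel)
  combo <- vapply(sts, function(s) paste(sort(s), collapse = "+"), "")
  cats <- c(uninfected = sum(sel$status == "uninfected"),
            `wCallA1 alone` = sum(sel$status == "single" & combo == "wCallA1"),
            `wCallA1+wCallC1` = sum(combo == "wCallA1+wCallC1"),
            `wCallA1+wCallB1` = sum(combo == "wCallA1+wCallB1"))
  cats <- c(cats, other = n - sum(cats))
  data.frame(category = names(cats), n = as.integer(cats),
             proportion = if (n) as.numeric(cats) / n else 0,
             pct = round_half_up(if (n) 100 * as.numeric(cats) / n else 0),
             stringsAsFactors = FALSE)
}

#' Write a prevalence summary as TSV files
#'
#' @param summary a `prevalence_summary`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_prevalence <- function(summary, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  counts <- data.frame(
    quantity = c("n_total", "n_uninfected", "n_single", "n_double",
                 "n_ambiguous", "n_infected", "pct_infected",
                 "pct_double_of_infected"),
    value = c(summary$n_total, summary$n_uninfected, summary$n_single,
              summary$n_double, summary$n_ambiguous, summary$n_infected,
              summary$pct$infected, summary$pct$double_of_infected))
  utils::write.table(counts, file.path(dir, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(summary$per_st, file.path(dir, "carriers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
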