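#' The packaged Calligrapha/Wolbachia fixture dataset
#'
#' A self-contained dataset mirroring the published survey of Wolbachia
#' MLST diversity in Calligrapha leaf beetles: the 15 sequence-type
#' profiles (7 observed in single infections, 8 deduced from
#' double-infection mixtures) in their three wCall groups, and a cohort of
#' 506 specimens whose per-locus observations reconstruct every single
#' infection, double-infection mixture, the chimeric-gatB mosaic
#' individuals and the one low-confidence double infection. Allele
#' sequences are synthetic stand-ins (flagged in the FASTA provenance):
#' internally consistent, pairwise distinct, with the gatB mosaic an exact
#' single-breakpoint chimera of the "c" and "d" alleles, but not the
#' deposited sequences.
#'
#' @return `fixture_dir()` returns the extdata path; `fixture_st_table()`
#'   the 15-ST table (16 rows with `include_variant = TRUE`, adding the
#'   mosaic wCallB1r); `fixture_allele_db()` the [allele_db()];
#'   `fixture_cohort()` the 506-row specimen table in the
#'   [read_specimen_table()] dialect.
#' @name calligrapha_tables
NULL

#' @rdname calligrapha_tables
#' @export
fixture_dir <- function() {
  d <- system.file("extdata", "calligrapha_tables", package = "wolmlst")
  if (!nzchar(d)) stop("fixture data not installed", call. = FALSE)
  d
}

#' @rdname calligrapha_tables
#' @param include_variant also return the chimeric wCallB1r mosaic row
#'   (excluded from the canonical 15-type inventory).
#' @export
fixture_st_table <- function(include_variant = FALSE) {
  tab <- read_st_table(file.path(fixture_dir(), "st_profiles.tsv"))
  if (include_variant) {
    row <- data.frame(st_id = "wCallB1r", gatB = "r", coxA = "33",
                      hcpA = "c", ftsZ = "b", fbpA = "b",
                      group = "wCallB", provenance = "deduced",
                      variant = TRUE, stringsAsFactors = FALSE)
    tab <- rbind(tab, row)
  }
  tab
}

#' @rdname calligrapha_tables
#' @export
fixture_allele_db <- function() {
  read_allele_db(fixture_dir(),
                 provenance = "synthetic stand-in alleles, calligrapha_tables fixture")
}

#' @rdname calligrapha_tables
#' @export
fixture_cohort <- function() {
  entries <- utils::read.delim(file.path(fixture_dir(), "cohort_entries.tsv"),
                               colClasses = "character", check.names = FALSE)
  entries$count <- as.integer(entries$count)
  prof <- .st_profiles(fixture_st_table(include_variant = TRUE))
  rows <- list()
  sid <- 0L
  for (r in seq_len(nrow(entries))) {
    e <- entries[r, ]
    obs <- stats::setNames(rep("", 5L), MLST_LOCI)
    if (nzchar(e$st1)) {
      p1 <- prof[e$st1, ]
      if (nzchar(e$st2)) {
        p2 <- prof[e$st2, ]
        obs[] <- ifelse(p1 == p2, p1,
                        paste(pmin(p1, p2), pmax(p1, p2), sep = "/"))
      } else {
        obs[] <- p1
      }
    }
    if (identical(e$flag, "uncertain"))
      obs[["gatB"]] <- paste0(obs[["gatB"]], "?low")
    for (i in seq_len(e$count)) {
      sid <- sid + 1L
      rows[[sid]] <- data.frame(
        specimen_id = sprintf("CAL%04d", sid), taxon = e$taxon,
        region = "", cox1_haplotype = e$haplotype, wg_genotype = "",
        t(obs), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' An empty sequence-type table
#'
#' Starting point for de-novo cohort classification.
#'
#' @return a zero-row ST table with the canonical columns.
#' @export
empty_st_table <- function() {
  data.frame(st_id = character(), gatB = character(), coxA = character(),
             hcpA = character(), ftsZ = character(), fbpA = character(),
             group = character(), provenance = character(),
             variant = logical(), stringsAsFactors = FALSE)
}
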