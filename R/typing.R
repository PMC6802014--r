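#' MLST profiles and sequence-type tables
#'
#' An MLST profile is a named character vector of allele ids, one per locus
#' in the canonical order. A sequence-type (ST) table is a data.frame with
#' columns `st_id`, one column per locus, `group` (wCallA/wCallB/wCallC
#' class), `provenance` (`"observed"` for STs seen in single infections,
#' `"deduced"` for STs implied by double-infection mixtures) and `variant`
#' (TRUE for mosaic variants such as chimeric-allele types, which are
#' excluded from the main ST inventory).
#'
#' @param ... allele ids in locus order, or named by locus.
#' @return `mlst_profile()` returns a named character vector of length 5.
#' @examples
#' mlst_profile(gatB = "a", coxA = "33", hcpA = "42", ftsZ = "32", fbpA = "36")
#' @export
mlst_profile <- function(...) {
  x <- c(...)
  if (is.null(names(x)) || all(names(x) == "")) {
    if (length(x) != 5L) stop("a profile needs exactly five alleles")
    names(x) <- MLST_LOCI
  }
  if (!setequal(names(x), MLST_LOCI)) stop("profile loci must be ", paste(MLST_LOCI, collapse = ","))
  x <- x[MLST_LOCI]
  storage.mode(x) <- "character"
  x
}

.profile_key <- function(profile) paste(profile[MLST_LOCI], collapse = ",")

.st_profiles <- function(st_table) {
  m <- as.matrix(st_table[, MLST_LOCI, drop = FALSE])
  rownames(m) <- st_table$st_id
  m
}

#' Number of loci at which two MLST profiles differ
#'
#' The allele-change distance between two sequence types: a count between 0
#' (identical profiles) and 5. It is the edge weight of the ST parsimony
#' network and the metric behind the "deduced types differ at a single
#' locus" parsimony used by the deconvolution.
#'
#' @param p1,p2 profiles from [mlst_profile()].
#' @return integer in 0..5.
#' @export
profile_distance <- function(p1, p2) {
  p1 <- mlst_profile(p1); p2 <- mlst_profile(p2)
  sum(p1 != p2)
}

#' Assign a sequence type to its wCall group
#'
#' The three strain classes are defined by the gatB allele: "a" or "b" gives
#' wCallA, "c" gives wCallB, "d" gives wCallC. An extension mapping lets
#' users type novel gatB alleles; chimeric gatB alleles inherit no group
#' here and must be mapped explicitly.
#'
#' @param profile an [mlst_profile()].
#' @param extra optional named character vector mapping further gatB allele
#'   ids to group labels.
#' @return one of `"wCallA"`, `"wCallB"`, `"wCallC"` (or an `extra` label).
#' @export
assign_group <- function(profile, extra = NULL) {
  g <- mlst_profile(profile)[["gatB"]]
  map <- c(a = "wCallA", b = "wCallA", c = "wCallB", d = "wCallC", extra)
  if (!g %in% names(map))
    stop("unmapped gatB allele: ", g, call. = FALSE)
  unname(map[[g]])
}

#' Trim a raw sequence to its MLST fragment
#'
#' Slides a fragment-length window over the raw read and returns the window
#' with the highest identity to the best-matching database allele
#' (leftmost window on ties). Raw Sanger reads carry primer-proximal flanks
#' beyond the canonical MLST fragment; this locates the fragment without an
#' external aligner.
#'
#' @param raw_sequence nucleotide string, at least fragment length long.
#' @param locus locus name.
#' @param db an [allele_db()] with at least one allele for the locus.
#' @param min_identity minimum acceptable identity of the best window
#'   (default 0.80); below it the sequence is rejected as untypeable.
#' @return the trimmed fragment (character scalar).
#' @export
trim_to_fragment <- function(raw_sequence, locus, db, min_identity = 0.80) {
  .check_locus(locus)
  raw_sequence <- toupper(raw_sequence)
  L <- .fragment_lengths()[[locus]]
  n <- nchar(raw_sequence)
  if (n < L) stop("raw sequence shorter than the ", L, " bp fragment", call. = FALSE)
  seqs <- db$alleles[[locus]]
  if (!length(seqs)) stop("allele database has no alleles for ", locus, call. = FALSE)
  raw <- strsplit(raw_sequence, "")[[1]]
  amat <- do.call(rbind, strsplit(unname(seqs), ""))
  best_score <- -1L; best_off <- NA_integer_
  for (off in 0:(n - L)) {
    win <- raw[(off + 1):(off + L)]
    sc <- max(rowSums(amat == matrix(win, nrow(amat), L, byrow = TRUE)))
    if (sc > best_score) { best_score <- sc; best_off <- off }
  }
  if (best_score / L < min_identity)
    stop("untypeable sequence: best window identity ",
         round(best_score / L, 3), " < ", min_identity, call. = FALSE)
  substr(raw_sequence, best_off + 1L, best_off + L)
}

#' Call an allele from a trimmed fragment
#'
#' Resolves a fragment (possibly containing IUPAC ambiguity codes from
#' double-peak chromatograms) against the allele database:
#' * exact match to a known allele: a `"known"` call;
#' * clean sequence with no match: a `"novel"` call (optionally minted into
#'   the database);
#' * ambiguity codes that are, at every position, exactly the base union of
#'   two distinct database alleles: a `"mixture"` call naming the pair;
#' * anything else (three-way unions, partial explanations): `"unresolved"`.
#'
#' @param locus locus name.
#' @param fragment fragment-length nucleotide string, IUPAC codes allowed.
#' @param db an [allele_db()].
#' @param mint if TRUE and the call is novel, append the allele to the
#'   database (returned in the `db` field).
#' @return a list with `status` (known/novel/mixture/unresolved),
#'   `allele_id` (known/novel), `pair` (mixture), `note`, and `db`.
#' @export
call_allele <- function(locus, fragment, db, mint = FALSE) {
  .check_locus(locus)
  fragment <- toupper(fragment)
  L <- .fragment_lengths()[[locus]]
  if (nchar(fragment) != L)
    stop("fragment must be ", L, " bp for ", locus, call. = FALSE)
  seqs <- db$alleles[[locus]]
  hit <- names(seqs)[match(fragment, seqs)]
  if (!is.na(hit) && length(hit))
    return(list(status = "known", allele_id = hit, pair = NULL, note = "", db = db))
  chars <- strsplit(fragment, "")[[1]]
  ambig <- !chars %in% c("A", "C", "G", "T")
  if (!any(ambig)) {
    out <- list(status = "novel", allele_id = NA_character_, pair = NULL,
                note = "no exact match, clean sequence", db = db)
    if (mint) {
      db <- db_add_allele(db, locus, fragment)
      out$allele_id <- attr(db, "minted_id")
      out$db <- db
    }
    return(out)
  }
  # mixture: exact position-wise union of one allele pair
  ids <- names(seqs)
  hits <- list()
  if (length(ids) >= 2L) {
    cmb <- utils::combn(ids, 2L)
    for (k in seq_len(ncol(cmb))) {
      a1 <- cmb[1L, k]; a2 <- cmb[2L, k]
      if (iupac_union(seqs[[a1]], seqs[[a2]]) == fragment)
        hits[[length(hits) + 1L]] <- sort(c(a1, a2))
    }
  }
  if (length(hits) == 1L)
    return(list(status = "mixture", allele_id = NA_character_, pair = hits[[1L]],
                note = "", db = db))
  note <- if (length(hits) > 1L) {
    paste("ambiguous mixture; candidate pairs:",
          paste(vapply(hits, paste, "", collapse = "/"), collapse = "; "))
  } else {
    "ambiguity codes not explained by any allele pair"
  }
  list(status = "unresolved", allele_id = NA_character_, pair = NULL,
       note = note, db = db)
}

#' Detect a single-breakpoint chimera between two database alleles
#'
#' Tests whether a fragment is an exact mosaic `prefix(x) + suffix(y)` of
#' two distinct alleles of the locus, with a single breakpoint and zero
#' mismatches. The breakpoint window is the maximal half-open interval of
#' equally valid breakpoints (0-based positions within the fragment); the
#' parent pair is the one minimising the window start (ties broken by
#' lexicographic allele ids).
#'
#' @inheritParams call_allele
#' @return a list with `is_chimeric`, `parent_ids` (ordered prefix-parent,
#'   suffix-parent), `breakpoint_window` (c(start, end), half-open), `locus`.
#' @export
detect_chimera <- function(fragment, locus, db) {
  .check_locus(locus)
  fragment <- toupper(fragment)
  L <- .fragment_lengths()[[locus]]
  if (nchar(fragment) != L)
    stop("fragment must be ", L, " bp for ", locus, call. = FALSE)
  seqs <- db$alleles[[locus]]
  none <- list(is_chimeric = FALSE, parent_ids = NULL,
               breakpoint_window = NULL, locus = locus)
  if (fragment %in% seqs) return(none)  # a plain allele is not a chimera
  f <- strsplit(fragment, "")[[1]]
  ids <- names(seqs)
  best <- NULL
  for (x in ids) for (y in setdiff(ids, x)) {
    ex <- f == strsplit(seqs[[x]], "")[[1]]
    ey <- f == strsplit(seqs[[y]], "")[[1]]
    # t valid iff prefix [1..t] matches x and suffix [t+1..L] matches y,
    # 1 <= t <= L-1 (both parents contribute)
    px <- if (ex[1L]) which(!c(ex, FALSE))[1L] - 1L else 0L  # longest matching prefix vs x
    sy <- L - (if (ey[L]) which(!c(rev(ey), FALSE))[1L] - 1L else 0L)  # first pos of matching suffix vs y, minus 1
    lo <- max(1L, sy); hi <- min(px, L - 1L)
    if (lo <= hi) {
      cand <- list(parent_ids = c(x, y), window = c(lo, hi + 1L))
      if (is.null(best) ||
          cand$window[1L] < best$window[1L] ||
          (cand$window[1L] == best$window[1L] &&
           paste(cand$parent_ids, collapse = ",") <
           paste(best$parent_ids, collapse = ","))) best <- cand
    }
  }
  if (is.null(best)) return(none)
  list(is_chimeric = TRUE, parent_ids = best$parent_ids,
       breakpoint_window = best$window, locus = locus)
}

#' Read / write a sequence-type profile table
#'
#' TSV with header `ST, gatB, coxA, hcpA, ftsZ, fbpA, group, provenance`
#' (an optional `variant` column marks mosaic types). The same dialect is
#' used for ST inventories written by [classify_cohort()].
#'
#' @param path file path.
#' @return a data.frame with columns `st_id`, the five loci, `group`,
#'   `provenance` and `variant`.
#' @export
read_st_table <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  names(tab)[names(tab) == "ST"] <- "st_id"
  need <- c("st_id", MLST_LOCI, "group", "provenance")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("ST table misses columns: ", paste(miss, collapse = ","))
  if (!"variant" %in% names(tab)) tab$variant <- "FALSE"
  tab$variant <- as.logical(tab$variant)
  validate_st_table(tab[, c(need, "variant")])
}

#' @rdname read_st_table
#' @param st_table an ST table data.frame.
#' @export
write_st_table <- function(st_table, path) {
  out <- st_table
  names(out)[names(out) == "st_id"] <- "ST"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_st_table
#' @export
validate_st_table <- function(st_table) {
  if (anyDuplicated(st_table$st_id))
    stop("duplicate st_id in ST table", call. = FALSE)
  keys <- apply(st_table[, MLST_LOCI, drop = FALSE], 1L, paste, collapse = ",")
  if (anyDuplicated(keys))
    stop("duplicate profiles in ST table: ",
         paste(st_table$st_id[duplicated(keys) | duplicated(keys, fromLast = TRUE)],
               collapse = ","), call. = FALSE)
  for (i in seq_len(nrow(st_table))) {
    if (st_table$variant[i]) next  # variant types may carry unmapped (chimeric) alleles
    g <- assign_group(mlst_profile(unlist(st_table[i, MLST_LOCI])))
    if (g != st_table$group[i])
      stop("group of ", st_table$st_id[i], " (", st_table$group[i],
           ") disagrees with its gatB allele (", g, ")", call. = FALSE)
  }
  rownames(st_table) <- NULL
  st_table
}
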