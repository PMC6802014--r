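#' Allele databases
#'
#' An allele database stores, per MLST locus, the known allele sequences
#' trimmed to the canonical fragment length, keyed by allele id. Ids follow
#' the public MLST convention: established alleles carry numeric ids
#' ("33"), provisional alleles carry letter ids ("a", "b", ...). It replaces
#' a remote MLST database lookup with a local, serialisable object.
#'
#' @param alleles named list, one element per locus, each a named character
#'   vector of sequences (names = allele ids).
#' @param provenance free-text note on where the alleles came from.
#' @return An object of class `allele_db`.
#' @seealso [read_allele_db()], [write_allele_db()]
#' @export
allele_db <- function(alleles, provenance = "") {
  frag <- .fragment_lengths()
  bad <- setdiff(names(alleles), MLST_LOCI)
  if (length(bad)) stop("unknown loci in allele set: ", paste(bad, collapse = ","))
  for (loc in names(alleles)) {
    seqs <- alleles[[loc]]
    if (is.null(names(seqs)) || any(names(seqs) == ""))
      stop("alleles for ", loc, " must be named by allele id")
    if (anyDuplicated(names(seqs)))
      stop("duplicate allele ids for locus ", loc)
    if (any(nchar(seqs) != frag[[loc]]))
      stop("allele sequences for ", loc, " must be ", frag[[loc]], " bp")
    if (anyDuplicated(toupper(seqs)))
      stop("allele sequences within locus ", loc, " must be pairwise distinct")
    alleles[[loc]] <- stats::setNames(toupper(seqs), names(seqs))
  }
  structure(list(alleles = alleles, provenance = provenance),
            class = "allele_db")
}

#' @export
print.allele_db <- function(x, ...) {
  cat("<allele_db>", if (nzchar(x$provenance)) paste0(" (", x$provenance, ")"), "\n")
  for (loc in names(x$alleles)) {
    cat("  ", loc, ": ", length(x$alleles[[loc]]), " alleles [",
        paste(names(x$alleles[[loc]]), collapse = ", "), "]\n", sep = "")
  }
  invisible(x)
}

#' Look up one allele sequence
#'
#' @param db an [allele_db()].
#' @param locus locus name.
#' @param allele_id allele identifier.
#' @return the sequence string, or an error if absent.
#' @export
db_sequence <- function(db, locus, allele_id) {
  .check_locus(locus)
  seqs <- db$alleles[[locus]]
  if (is.null(seqs) || !allele_id %in% names(seqs))
    stop("no allele ", allele_id, " for locus ", locus, call. = FALSE)
  unname(seqs[[allele_id]])
}

#' @rdname db_sequence
#' @export
db_allele_ids <- function(db, locus) {
  .check_locus(locus)
  names(db$alleles[[locus]])
}

#' Add a novel allele to a database
#'
#' Provisional ids continue the single-letter a, b, c, ... series within the
#' locus (skipping ids already taken); established numeric ids are never
#' reissued.
#'
#' @inheritParams db_sequence
#' @param sequence fragment-length nucleotide string.
#' @param allele_id optional explicit id; default mints the next free letter.
#' @return the updated database, with the minted id in attribute `"minted_id"`.
#' @export
db_add_allele <- function(db, locus, sequence, allele_id = NULL) {
  .check_locus(locus)
  sequence <- toupper(sequence)
  frag <- .fragment_lengths()[[locus]]
  if (nchar(sequence) != frag)
    stop("sequence must be ", frag, " bp for ", locus, call. = FALSE)
  seqs <- db$alleles[[locus]]
  if (sequence %in% seqs)
    stop("sequence already present for ", locus, call. = FALSE)
  if (is.null(allele_id)) {
    cand <- setdiff(letters, names(seqs))
    if (!length(cand)) stop("provisional letter ids exhausted for ", locus)
    allele_id <- cand[[1L]]
  } else if (allele_id %in% names(seqs)) {
    stop("allele id ", allele_id, " already taken for ", locus, call. = FALSE)
  }
  db$alleles[[locus]] <- c(seqs, stats::setNames(sequence, allele_id))
  attr(db, "minted_id") <- allele_id
  db
}

#' Read / write an allele database as per-locus FASTA
#'
#' One FASTA file per locus, headers `locus_alleleid` (e.g. `gatB_33`).
#'
#' @param dir directory holding `<locus>.fasta` files (read) or to be
#'   populated (write).
#' @param loci which loci to read; default all five.
#' @param provenance note stored on the database.
#' @return `read_allele_db()` returns an [allele_db()]; `write_allele_db()`
#'   returns the directory, invisibly.
#' @export
read_allele_db <- function(dir, loci = MLST_LOCI, provenance = dir) {
  alleles <- list()
  for (loc in loci) {
    path <- file.path(dir, paste0(loc, ".fasta"))
    if (!file.exists(path)) stop("missing allele FASTA: ", path, call. = FALSE)
    ss <- Biostrings::readDNAStringSet(path)
    ids <- sub("\\s.*$", "", names(ss))
    pre <- paste0(loc, "_")
    if (!all(startsWith(ids, pre)))
      stop("headers in ", path, " must look like ", pre, "<allele_id>")
    alleles[[loc]] <- stats::setNames(as.character(ss), sub(pre, "", ids, fixed = TRUE))
  }
  allele_db(alleles, provenance = provenance)
}

#' @rdname read_allele_db
#' @param db an [allele_db()] to write.
#' @export
write_allele_db <- function(db, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (loc in names(db$alleles)) {
    seqs <- db$alleles[[loc]]
    ss <- Biostrings::DNAStringSet(unname(seqs))
    names(ss) <- paste0(loc, "_", names(seqs))
    Biostrings::writeXStringSet(ss, file.path(dir, paste0(loc, ".fasta")), width = 70L)
  }
  invisible(dir)
}
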