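#' The five Wolbachia MLST loci
#'
#' The standard Wolbachia multilocus sequence typing (MLST) scheme types a
#' strain by the allele it carries at five conserved housekeeping genes.
#' Every profile, allele database and observation table in this package is
#' keyed by these loci, in this canonical order. Fragment lengths are the
#' base-pair sizes of the canonical MLST fragments.
#'
#' @return A data.frame with columns `locus` and `fragment_length`, one row
#'   per locus (gatB, coxA, hcpA, ftsZ, fbpA).
#' @examples
#' mlst_loci()
#' @export
mlst_loci <- function() {
  data.frame(
    locus = c("gatB", "coxA", "hcpA", "ftsZ", "fbpA"),
    fragment_length = c(369L, 402L, 444L, 435L, 429L),
    stringsAsFactors = FALSE
  )
}

#' @rdname mlst_loci
#' @format NULL
#' @export
MLST_LOCI <- c("gatB", "coxA", "hcpA", "ftsZ", "fbpA")

# fragment length lookup, names = loci
.fragment_lengths <- function() {
  li <- mlst_loci()
  stats::setNames(li$fragment_length, li$locus)
}

.check_locus <- function(locus) {
  if (length(locus) != 1L || !locus %in% MLST_LOCI) {
    stop("unknown MLST locus: ", paste(locus, collapse = ","), call. = FALSE)
  }
  locus
}

# IUPAC nucleotide code helpers ------------------------------------------

# base-set -> code, keyed by sorted concatenation of A/C/G/T members
.iupac_from_set <- local({
  map <- NULL
  function() {
    if (is.null(map)) {
      codes <- Biostrings::IUPAC_CODE_MAP
      key <- vapply(strsplit(unname(codes), ""), function(b)
        paste(sort(b), collapse = ""), "")
      map <<- stats::setNames(names(codes), key)
    }
    map
  }
})

.iupac_to_set <- function() Biostrings::IUPAC_CODE_MAP

#' Position-wise IUPAC union of two sequences
#'
#' Models the double-peak chromatogram signal of a host carrying two strains:
#' at each position the observed base is the IUPAC code for the union of the
#' two alleles' bases.
#'
#' @param s1,s2 nucleotide strings of equal length (plain A/C/G/T).
#' @return a nucleotide string, possibly with ambiguity codes.
#' @export
iupac_union <- function(s1, s2) {
  if (nchar(s1) != nchar(s2)) stop("sequences differ in length", call. = FALSE)
  a <- strsplit(toupper(s1), "")[[1]]
  b <- strsplit(toupper(s2), "")[[1]]
  same <- a == b
  out <- a
  if (any(!same)) {
    key <- ifelse(a[!same] < b[!same],
                  paste0(a[!same], b[!same]), paste0(b[!same], a[!same]))
    out[!same] <- .iupac_from_set()[key]
  }
  paste(out, collapse = "")
}
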