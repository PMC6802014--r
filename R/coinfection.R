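#' Parse per-locus allele observations
#'
#' Observation strings in a specimen table follow a small dialect:
#' `"33"` or `"a"` (single allele), `"a/b"` (two-allele double-peak
#' mixture), `""` (no amplification), `"?low"` (faint, unrepeatable
#' signal), and a trailing `"?low"` on a call (e.g. `"c/d?low"`) marking a
#' low-confidence read whose downstream resolution is flagged uncertain.
#'
#' @param x character vector of observation strings.
#' @return a list with `sets` (list of character vectors of allele ids,
#'   possibly empty), `low_conf` (logical), `faint` (logical: faint signal
#'   only, no usable call).
#' @keywords internal
parse_observations <- function(x) {
  x <- trimws(x)
  low <- grepl("\\?low$", x)
  core <- sub("\\?low$", "", x)
  faint <- low & core == ""
  sets <- strsplit(core, "/", fixed = TRUE)
  sets <- lapply(sets, function(s) s[nzchar(s)])
  list(sets = sets, low_conf = low & !faint, faint = faint)
}

# candidate pair enumeration for one mixture -----------------------------
# mix: named list (by locus) of character vectors of allele ids (size 1-2)
# st_table: current ST table; returns data.frame of candidate resolutions
.pair_candidates <- function(mix, st_table, max_new_dist = 1L) {
  prof <- .st_profiles(st_table)
  out <- list()
  for (i in seq_len(nrow(prof))) {
    s1 <- prof[i, ]
    ok <- TRUE
    partner <- character(5L)
    names(partner) <- MLST_LOCI
    for (loc in MLST_LOCI) {
      set <- mix[[loc]]
      if (!s1[[loc]] %in% set) { ok <- FALSE; break }
      partner[[loc]] <- if (length(set) == 2L) setdiff(set, s1[[loc]]) else set
    }
    if (!ok) next
    if (identical(unname(partner), unname(s1))) next  # double = two distinct STs
    j <- match(.profile_key(partner), apply(prof, 1L, paste, collapse = ","))
    if (!is.na(j)) {
      pair <- sort(c(rownames(prof)[i], rownames(prof)[j]))
      out[[length(out) + 1L]] <- data.frame(
        s1 = pair[1L], s2 = pair[2L], s2_new = FALSE,
        s2_profile = .profile_key(prof[match(pair[2L], rownames(prof)), ]),
        dist = 0L, stringsAsFactors = FALSE)
    } else {
      d <- min(apply(prof, 1L, function(p) sum(p != partner)))
      if (d <= max_new_dist) {
        out[[length(out) + 1L]] <- data.frame(
          s1 = rownames(prof)[i], s2 = NA_character_, s2_new = TRUE,
          s2_profile = .profile_key(partner), dist = as.integer(d),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(s1 = character(), s2 = character(), s2_new = logical(),
                      s2_profile = character(), dist = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[!duplicated(paste(res$s1, res$s2, res$s2_profile)), , drop = FALSE]
}

# mint a deduced ST for a new profile; returns updated table + new id
.mint_st <- function(st_table, profile, db = NULL, provenance = "deduced") {
  profile <- mlst_profile(profile)
  # mosaic variant: one locus away from a known type via a chimeric allele
  if (!is.null(db) && nrow(st_table)) {
    regular <- st_table[!st_table$variant, , drop = FALSE]
    prof <- .st_profiles(regular)
    for (i in seq_len(nrow(prof))) {
      diffs <- which(prof[i, ] != profile)
      if (length(diffs) == 1L) {
        loc <- MLST_LOCI[diffs]
        aid <- profile[[loc]]
        # mosaic variants carry an allele seen in no regular ST profile
        if (!aid %in% regular[[loc]] &&
            aid %in% db_allele_ids(db, loc) &&
            .allele_is_chimeric(db, loc, aid)) {
          id <- paste0(rownames(prof)[i], "r")
          k <- 1L
          while (id %in% st_table$st_id) { k <- k + 1L; id <- paste0(rownames(prof)[i], "r", k) }
          row <- data.frame(st_id = id, t(profile),
                            group = st_table$group[match(rownames(prof)[i], st_table$st_id)],
                            provenance = provenance, variant = TRUE,
                            stringsAsFactors = FALSE)
          return(list(st_table = rbind(st_table, row), st_id = id))
        }
      }
    }
  }
  group <- assign_group(profile)
  used <- st_table$st_id[st_table$group == group]
  idx <- suppressWarnings(as.integer(sub(paste0("^", group), "", used)))
  idx <- idx[!is.na(idx)]
  i <- 1L
  while (i %in% idx) i <- i + 1L
  id <- paste0(group, i)
  row <- data.frame(st_id = id, t(profile), group = group,
                    provenance = provenance, variant = FALSE,
                    stringsAsFactors = FALSE)
  list(st_table = rbind(st_table, row), st_id = id)
}

.allele_is_chimeric <- function(db, locus, allele_id) {
  seqs <- db$alleles[[locus]]
  if (length(seqs) < 3L || !allele_id %in% names(seqs)) return(FALSE)
  frag <- seqs[[allele_id]]
  db2 <- db
  db2$alleles[[locus]] <- seqs[names(seqs) != allele_id]
  detect_chimera(frag, locus, db2)$is_chimeric
}

#' Resolve a complete single-infection profile
#'
#' An exact profile match returns the matching sequence type; an unseen
#' complete profile mints a new observed ST (flagged novel in the notes).
#'
#' @param profile an [mlst_profile()].
#' @param st_table an ST table ([read_st_table()] dialect).
#' @param db optional [allele_db()], used to recognise chimeric alleles
#'   when minting.
#' @return a list with `status = "single"`, `sts` (one st_id), `uncertain`,
#'   `notes` and the (possibly grown) `st_table`.
#' @export
resolve_single <- function(profile, st_table, db = NULL) {
  profile <- mlst_profile(profile)
  keys <- apply(.st_profiles(st_table), 1L, paste, collapse = ",")
  hit <- match(.profile_key(profile), keys)
  if (!is.na(hit)) {
    return(list(status = "single", sts = st_table$st_id[hit],
                uncertain = FALSE, notes = "", st_table = st_table))
  }
  m <- .mint_st(st_table, profile, db = db, provenance = "observed")
  list(status = "single", sts = m$st_id, uncertain = FALSE,
       notes = "novel ST minted from single infection", st_table = m$st_table)
}

#' Deconvolve a double-infection mixture into two sequence types
#'
#' A doubly infected host shows, at every locus, the set union of its two
#' strains' alleles. Deconvolution enumerates ordered hypotheses (S1, S2)
#' with S1 a known sequence type whose allele lies in the observed set at
#' every locus; S2 is then fully determined (the complementary allele at
#' two-allele loci). Pairs in which both members are known types are
#' preferred; if exactly one such pair exists it is returned. Otherwise
#' candidates whose implied partner is a new profile within `max_new_dist`
#' allele changes of a known type are ranked by (distance of the new
#' profile to the nearest known type, S1 id, partner profile) and the top
#' candidate is returned, minting the partner as a deduced ST. Several
#' both-known pairs, or no candidate at all, give an `"ambiguous"` result.
#'
#' @param mixture named list (by locus) of character vectors of 1 or 2
#'   allele ids; at least one locus must hold 2 alleles.
#' @param st_table an ST table.
#' @param max_new_dist maximum allele-change distance of a newly implied
#'   partner profile from some known type (default 1, the parsimony the
#'   deduced types obey).
#' @param db optional [allele_db()] for chimeric-variant naming.
#' @param uncertain propagate TRUE when any contributing locus call was
#'   low-confidence; the resolved pair is then flagged.
#' @return a list with `status` (`"double"` or `"ambiguous"`), `sts`,
#'   `uncertain`, `notes`, `candidates` (data.frame) and `st_table`.
#' @export
deconvolve <- function(mixture, st_table, max_new_dist = 1L, db = NULL,
                       uncertain = FALSE) {
  if (!setequal(names(mixture), MLST_LOCI))
    stop("mixture must name all five loci", call. = FALSE)
  sizes <- lengths(mixture[MLST_LOCI])
  if (any(sizes == 0L)) stop("malformed mixture: empty allele set", call. = FALSE)
  if (any(sizes > 2L)) stop("malformed mixture: >2 alleles at a locus", call. = FALSE)
  if (!any(sizes == 2L)) stop("not a mixture: no two-allele locus", call. = FALSE)
  cand <- .pair_candidates(mixture[MLST_LOCI], st_table, max_new_dist)
  known <- cand[!cand$s2_new, , drop = FALSE]
  if (nrow(known) == 1L) {
    return(list(status = "double", sts = c(known$s1, known$s2),
                uncertain = uncertain, notes = "", candidates = cand,
                st_table = st_table))
  }
  if (nrow(known) > 1L) {
    return(list(status = "ambiguous", sts = character(),
                uncertain = uncertain,
                notes = paste("multiple consistent known pairs:",
                              paste(known$s1, known$s2, sep = "+", collapse = "; ")),
                candidates = cand, st_table = st_table))
  }
  new <- cand[cand$s2_new, , drop = FALSE]
  if (!nrow(new)) {
    return(list(status = "ambiguous", sts = character(),
                uncertain = uncertain,
                notes = "no consistent resolution within max_new_dist",
                candidates = cand, st_table = st_table))
  }
  new <- new[order(new$dist, new$s1, new$s2_profile), , drop = FALSE]
  top <- new[1L, ]
  m <- .mint_st(st_table, mlst_profile(strsplit(top$s2_profile, ",")[[1]]),
                db = db, provenance = "deduced")
  list(status = "double", sts = sort(c(top$s1, m$st_id)),
       uncertain = uncertain,
       notes = paste0("partner ", m$st_id, " deduced (distance ", top$dist,
                      " from nearest known ST)"),
       candidates = cand, st_table = m$st_table)
}

#' Read / write a specimen table
#'
#' CSV with columns `specimen_id, taxon, region, cox1_haplotype,
#' wg_genotype, gatB, coxA, hcpA, ftsZ, fbpA`; per-locus cells use the
#' observation dialect of [parse_observations()].
#'
#' @param path file path.
#' @return a data.frame.
#' @export
read_specimen_table <- function(path) {
  tab <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("specimen_id", "taxon", "region", "cox1_haplotype", "wg_genotype",
            MLST_LOCI)
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("specimen table misses columns: ", paste(miss, collapse = ","))
  if (anyDuplicated(tab$specimen_id)) stop("duplicate specimen_id")
  tab
}

#' @rdname read_specimen_table
#' @param records a specimen data.frame.
#' @export
write_specimen_table <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Classify a cohort: resolve every specimen's infection state
#'
#' Resolves all specimens against (and growing) a sequence-type table.
#' Single-allele profiles match or mint observed STs. Double-peak mixtures
#' are deconvolved globally: the cohort is reduced to unique mixture
#' signatures and iterated to a fixed point, resolving first every
#' signature with a unique both-known pairing; when no signature resolves
#' that way, one new deduced ST is minted from the best-supported
#' one-novel candidate (ranked by current carrier frequency of the known
#' member, then by the number of specimens showing the signature, then
#' lexicographically) and the sweep restarts. This mirrors how deduced
#' types are accumulated by subtracting known types from the empirical
#' polymorphism, and reuses every type it mints.
#'
#' Specimens with no amplification at any locus are uninfected; faint
#' one-or-two-locus signals (`"?low"`) are uninfected with a weak-signal
#' note. Low-confidence mixture calls resolve normally but are flagged
#' `uncertain` and excluded from per-ST carrier counts downstream.
#'
#' @param records specimen data.frame ([read_specimen_table()] dialect).
#' @param st_table starting ST table (may be empty or observed-only).
#' @param db optional [allele_db()] for chimeric-variant recognition.
#' @param max_new_dist see [deconvolve()].
#' @return a list with `records` (input plus `status`, `st1`, `st2`,
#'   `uncertain`, `notes` columns), `st_table` (final), and `inventory`
#'   (final table plus `n_carriers`, specimens per ST).
#' @export
classify_cohort <- function(records, st_table, db = NULL, max_new_dist = 1L) {
  n <- nrow(records)
  status <- character(n); st1 <- rep(NA_character_, n); st2 <- rep(NA_character_, n)
  uncertain <- logical(n); notes <- character(n)
  obs <- lapply(MLST_LOCI, function(loc) parse_observations(records[[loc]]))
  names(obs) <- MLST_LOCI

  kind <- character(n)
  for (i in seq_len(n)) {
    sz <- vapply(MLST_LOCI, function(loc) length(obs[[loc]]$sets[[i]]), 0L)
    faint <- vapply(MLST_LOCI, function(loc) obs[[loc]]$faint[i], TRUE)
    if (all(sz == 0L)) {
      kind[i] <- "uninfected"
      if (any(faint)) notes[i] <- "weak-signal: faint amplification only"
    } else if (any(sz == 0L)) {
      kind[i] <- "incomplete"
    } else if (all(sz == 1L)) {
      kind[i] <- "single"
    } else {
      kind[i] <- "mixture"
    }
  }
  status[kind == "uninfected"] <- "uninfected"
  status[kind == "incomplete"] <- "ambiguous"
  notes[kind == "incomplete"] <- "incomplete profile: some loci failed to amplify"

  # singles first (they seed the carrier frequencies)
  for (i in which(kind == "single")) {
    prof <- mlst_profile(vapply(MLST_LOCI, function(loc) obs[[loc]]$sets[[i]], ""))
    r <- resolve_single(prof, st_table, db = db)
    st_table <- r$st_table
    status[i] <- "single"; st1[i] <- r$sts
    if (nzchar(r$notes)) notes[i] <- r$notes
  }

  # unique mixture signatures
  mi <- which(kind == "mixture")
  sig_of <- character(0)
  sigs <- list()
  for (i in mi) {
    sets <- lapply(MLST_LOCI, function(loc) sort(obs[[loc]]$sets[[i]]))
    names(sets) <- MLST_LOCI
    lc <- any(vapply(MLST_LOCI, function(loc) obs[[loc]]$low_conf[i], TRUE))
    key <- paste(vapply(sets, paste, "", collapse = "/"), collapse = "|")
    key <- paste0(key, if (lc) "?" else "")
    if (is.null(sigs[[key]]))
      sigs[[key]] <- list(sets = sets, low_conf = lc, members = integer())
    sigs[[key]]$members <- c(sigs[[key]]$members, i)
  }

  carrier_freq <- function() {
    sts <- c(st1[status %in% c("single", "double")],
             st2[status == "double"])
    table(factor(sts[!is.na(sts)], levels = st_table$st_id))
  }

  if (length(sigs)) {
    sol <- .deconvolve_cohort(sigs, st_table, db, max_new_dist,
                              freq0 = carrier_freq())
    st_table <- sol$st_table
    for (key in names(sigs)) {
      sg <- sigs[[key]]
      r <- sol$resolution[[key]]
      status[sg$members] <- r$status
      if (r$status == "double") {
        st1[sg$members] <- r$pair[1L]; st2[sg$members] <- r$pair[2L]
      }
      uncertain[sg$members] <- sg$low_conf && r$status == "double"
      notes[sg$members] <- if (sg$low_conf && r$status == "double")
        paste0(if (nzchar(r$note)) paste0(r$note, "; "),
               "low-confidence locus call: ST pair uncertain") else r$note
    }
  }

  records$status <- status
  records$st1 <- st1
  records$st2 <- st2
  records$uncertain <- uncertain
  records$notes <- notes

  freq <- carrier_freq()
  inventory <- st_table
  inventory$n_carriers <- as.integer(freq[inventory$st_id])
  list(records = records, st_table = st_table, inventory = inventory)
}

# Global deconvolution of all mixture signatures at once.
#
# The published deduction is a parsimony argument: the smallest set of new
# sequence types that, together with the established ones, explains every
# double-peak signature as a union of two types. This solver makes that
# exact: every signature enumerates all ways of splitting its two-allele
# loci into an (unordered) pair of profiles; pairs are admissible when both
# members are established types or candidate deductions (profiles within
# max_new_dist allele changes of the growing table that co-occur with an
# admissible member). A branch-and-bound search over one pair choice per
# signature then (1) explains the most specimens, (2) mints the fewest new
# types and (3) maximises support from observed single-infection carrier
# counts. Each signature is finally resolved to its best-supported
# consistent pair; genuine ties stay ambiguous.
.deconvolve_cohort <- function(sigs, st_table, db, max_new_dist, freq0,
                               node_cap = 2e5) {
  kp <- .st_profiles(st_table)
  known_keys <- apply(kp, 1L, paste, collapse = ",")   # named by st_id
  id_of <- stats::setNames(rownames(kp), unname(known_keys))
  split_key <- function(k) strsplit(k, ",", fixed = TRUE)[[1]]
  dist_key <- function(k1, k2) sum(split_key(k1) != split_key(k2))

  all_pairs_of_sig <- function(sets) {
    loci2 <- which(lengths(sets) == 2L)
    n2 <- length(loci2)
    out <- list()
    base <- vapply(sets, `[`, "", 1L)
    for (bits in seq_len(2^n2) - 1L) {
      if (bitwAnd(bits, 1L) == 1L) next  # fix the first 2-allele locus
      q1 <- q2 <- base
      for (j in seq_len(n2)) {
        take2 <- bitwAnd(bits, bitwShiftL(1L, j - 1L)) > 0L
        loc <- loci2[j]
        q1[loc] <- sets[[loc]][if (take2) 2L else 1L]
        q2[loc] <- sets[[loc]][if (take2) 1L else 2L]
      }
      out[[length(out) + 1L]] <- c(paste(q1, collapse = ","),
                                   paste(q2, collapse = ","))
    }
    out
  }
  raw <- lapply(sigs, function(sg) all_pairs_of_sig(sg$sets))

  # admissible candidate profiles: two layers of "co-occurs with an
  # admissible member and lies within max_new_dist of the table so far"
  U <- character(0)
  for (layer in 1:2) {
    KU0 <- c(unname(known_keys), U)
    newU <- character(0)
    for (pl in raw) for (pr in pl) for (ordr in 1:2) {
      a <- pr[ordr]; b <- pr[3L - ordr]
      if (a %in% KU0 && !b %in% KU0 && !b %in% newU &&
          min(vapply(KU0, dist_key, 0L, k1 = b)) <= max_new_dist) {
        newU <- c(newU, b)
      }
    }
    U <- c(U, newU)
  }
  U <- sort(unique(U))

  nspec <- vapply(sigs, function(sg) length(sg$members), 0L)
  supp0 <- function(key) {
    id <- id_of[key]
    if (is.na(id)) 0L else as.integer(freq0[[id]])
  }
  KU <- c(unname(known_keys), U)
  sig_pairs <- lapply(raw, function(pl) {
    ok <- Filter(function(pr) all(pr %in% KU), pl)
    if (!length(ok)) return(NULL)
    req <- lapply(ok, function(pr) sort(pr[pr %in% U]))
    supp <- vapply(ok, function(pr) supp0(pr[1L]) + supp0(pr[2L]), 0L)
    # drop pairs whose mint requirement is a strict superset of an
    # equally-or-better supported alternative (sound for the search)
    n <- length(ok)
    drop <- rep(FALSE, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j || drop[j]) next
      sub <- all(req[[j]] %in% req[[i]])
      if (sub && supp[j] >= supp[i] &&
          (length(req[[j]]) < length(req[[i]]) || supp[j] > supp[i])) {
        drop[i] <- TRUE; break
      }
    }
    ord <- order(vapply(req[!drop], length, 0L), -supp[!drop])
    list(pairs = ok[!drop][ord], req = req[!drop][ord],
         supp = supp[!drop][ord])
  })

  # branch and bound: one pair per signature, lexicographic objective
  # (specimens covered, -new types minted, support)
  has_pairs <- !vapply(sig_pairs, is.null, TRUE)
  sig_idx <- which(has_pairs)
  sig_idx <- sig_idx[order(vapply(sig_pairs[sig_idx],
                                  function(x) length(x$pairs), 0L),
                           -nspec[sig_idx])]
  cov_total <- sum(nspec[sig_idx])
  maxsupp_tail <- rev(cumsum(rev(vapply(sig_idx, function(s)
    nspec[s] * max(sig_pairs[[s]]$supp), 0))))
  best <- list(M = NULL, nmint = Inf, supp = -Inf)
  nodes <- 0L
  dfs <- function(pos, M, supp) {
    nodes <<- nodes + 1L
    if (nodes > node_cap) return()
    if (pos > length(sig_idx)) {
      if (length(M) < best$nmint ||
          (length(M) == best$nmint && supp > best$supp)) {
        best <<- list(M = M, nmint = length(M), supp = supp)
      }
      return()
    }
    if (length(M) > best$nmint) return()
    if (length(M) == best$nmint &&
        supp + maxsupp_tail[pos] <= best$supp) return()
    s <- sig_idx[pos]
    sp <- sig_pairs[[s]]
    for (k in seq_along(sp$pairs)) {
      dfs(pos + 1L, union(M, sp$req[[k]]), supp + nspec[s] * sp$supp[k])
    }
  }
  dfs(1L, character(0), 0)
  chosen <- best$M

  # mint the chosen profiles: within each group, heavier usage first
  feasible_of <- function(s) {
    sp <- sig_pairs[[s]]
    if (is.null(sp)) return(integer(0))
    which(vapply(sp$req, function(r) all(r %in% chosen), TRUE))
  }
  usage <- stats::setNames(rep(0, length(chosen)), chosen)
  for (s in sig_idx) {
    sp <- sig_pairs[[s]]
    feas <- feasible_of(s)
    if (!length(feas)) next
    top <- feas[order(-sp$supp[feas])][1L]
    for (kk in sp$pairs[[top]])
      if (kk %in% names(usage)) usage[kk] <- usage[kk] + nspec[s]
  }
  for (key in names(usage)[order(-usage, names(usage))]) {
    mm <- .mint_st(st_table, mlst_profile(split_key(key)), db = db,
                   provenance = "deduced")
    st_table <- mm$st_table
    id_of[key] <- mm$st_id
  }

  # resolve each signature, largest first, updating carrier support
  freq <- stats::setNames(rep(0L, nrow(st_table)), st_table$st_id)
  freq[names(freq0)] <- as.integer(freq0)
  resolution <- vector("list", length(sigs))
  names(resolution) <- names(sigs)
  for (s in order(-nspec, names(sigs))) {
    key <- names(sigs)[s]
    sp <- sig_pairs[[s]]
    feas <- feasible_of(s)
    if (!length(feas)) {
      resolution[[key]] <- list(status = "ambiguous", pair = NULL,
                                note = "no consistent resolution within max_new_dist")
      next
    }
    ids <- unique(lapply(sp$pairs[feas], function(pr) sort(unname(id_of[pr]))))
    supp <- vapply(ids, function(pp) sum(freq[pp]), 0)
    top <- which(supp == max(supp))
    if (length(top) > 1L) {
      resolution[[key]] <- list(status = "ambiguous", pair = NULL,
        note = paste("multiple equally supported pairs:",
                     paste(vapply(ids[top], paste, "", collapse = "+"),
                           collapse = "; ")))
      next
    }
    pair <- ids[[top]]
    note <- if (length(ids) > 1L)
      paste("alternative pairings possible:",
            paste(vapply(ids[-top], paste, "", collapse = "+"),
                  collapse = "; ")) else ""
    minted <- pair[pair %in% id_of[chosen]]
    if (length(minted))
      note <- paste0(if (nzchar(note)) paste0(note, "; "),
                     "partner ", paste(minted, collapse = "+"), " deduced")
    resolution[[key]] <- list(status = "double", pair = pair, note = note)
    freq[pair] <- freq[pair] + nspec[s]
  }
  list(st_table = st_table, resolution = resolution)
}

#' Sequence types of one resolved record, as a character vector
#'
#' @param records resolved records from [classify_cohort()].
#' @return list of character vectors (length 0, 1 or 2 per record).
#' @keywords internal
record_sts <- function(records) {
  lapply(seq_len(nrow(records)), function(i) {
    s <- c(records$st1[i], records$st2[i])
    s[!is.na(s)]
  })
}
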