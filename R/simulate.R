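#' Simulation configuration
#'
#' Bundles the study conditions for the synthetic-data generator: a host
#' haplotype genealogy partitioned into geographic lineages, a symbiont
#' backbone inherited vertically with per-branch loss, region-specific
#' horizontal acquisition of the locally resident strain, and mutual
#' exclusion of the two incompatible strain classes (wCallB/wCallC) within
#' one host. Defaults mirror the empirical cohort: 506 specimens over 86
#' cox1 haplotypes in 7 geographic lineages, a widespread wCallA backbone,
#' and B- or C-class residents alternating across regions.
#'
#' @param n_specimens cohort size.
#' @param n_haplotypes tips of the host genealogy.
#' @param n_regions geographic lineages (contiguous clades of the tree).
#' @param vertical_loss_rate per-branch probability that a lineage loses
#'   the inherited backbone strain.
#' @param horizontal_rate_by_region per-host probability of acquiring the
#'   region's resident strain; scalar recycled, or vector of length
#'   `n_regions`.
#' @param ci_exclusion forbid wCallB + wCallC co-occurrence in one host
#'   (cytoplasmic incompatibility); the later (horizontal) acquisition is
#'   rejected.
#' @param strain_inventory ST table; default [fixture_st_table()].
#' @param backbone_st st_id of the vertically inherited strain.
#' @param resident_by_region character vector (length `n_regions`) of
#'   resident st_ids; default alternates wCallB1 / wCallC1.
#' @param dropout per-locus probability that an observation fails ("").
#' @param faint_rate per-specimen probability that a failed specimen shows
#'   a faint one-locus signal ("?low").
#' @param mutation_rate per-site substitution rate used when emitting
#'   synthetic allele sequences.
#' @param seed integer master seed; all generator randomness flows from it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_specimens = 506L, n_haplotypes = 86L,
                       n_regions = 7L, vertical_loss_rate = 0.05,
                       horizontal_rate_by_region = 0.5,
                       ci_exclusion = TRUE,
                       strain_inventory = fixture_st_table(),
                       backbone_st = "wCallA1",
                       resident_by_region = NULL,
                       dropout = 0, faint_rate = 0,
                       mutation_rate = 0.01, seed = 1L) {
  if (length(horizontal_rate_by_region) == 1L)
    horizontal_rate_by_region <- rep(horizontal_rate_by_region, n_regions)
  stopifnot(length(horizontal_rate_by_region) == n_regions,
            all(horizontal_rate_by_region >= 0 & horizontal_rate_by_region <= 1),
            vertical_loss_rate >= 0, vertical_loss_rate <= 1,
            n_haplotypes >= 2L)
  if (is.null(resident_by_region)) {
    bc <- c("wCallB1", "wCallC1")
    resident_by_region <- bc[(seq_len(n_regions) - 1L) %% 2L + 1L]
  }
  if (length(resident_by_region) != n_regions)
    stop("resident_by_region must name one strain per region", call. = FALSE)
  miss <- setdiff(c(backbone_st, resident_by_region),
                  strain_inventory$st_id)
  if (length(miss))
    stop("strains absent from inventory: ", paste(miss, collapse = ","),
         call. = FALSE)
  structure(list(n_specimens = as.integer(n_specimens),
                 n_haplotypes = as.integer(n_haplotypes),
                 n_regions = as.integer(n_regions),
                 vertical_loss_rate = vertical_loss_rate,
                 horizontal_rate_by_region = horizontal_rate_by_region,
                 ci_exclusion = isTRUE(ci_exclusion),
                 strain_inventory = strain_inventory,
                 backbone_st = backbone_st,
                 resident_by_region = resident_by_region,
                 dropout = dropout, faint_rate = faint_rate,
                 mutation_rate = mutation_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate the host haplotype genealogy
#'
#' A neutral coalescent tree over haplotypes (ape::rcoal), partitioned
#' into `n_regions` geographic lineages by repeatedly splitting the
#' largest clade at its root; a nested-clade table is derived from the
#' tree through the package's own network-nesting rules (cophenetic
#' distances discretised to steps, minimum-spanning network, tips-inward
#' nesting).
#'
#' @param config a [sim_config()].
#' @param nesting_levels levels of the derived hierarchy.
#' @return list with `tree` (phylo; tips `H1..Hn`), `region`
#'   (named character: haplotype -> region label `R1..Rk`), `hierarchy`
#'   (a `nested_hierarchy`), `frequencies` (haplotype sampling weights).
#' @export
simulate_genealogy <- function(config, nesting_levels = 3L) {
  set.seed(config$seed)
  n <- config$n_haplotypes
  tree <- ape::rcoal(n, tip.label = paste0("H", seq_len(n)))
  region <- .partition_regions(tree, config$n_regions)
  d <- stats::cophenetic(tree)
  off <- d[upper.tri(d)]
  steps <- ceiling(d / min(off[off > 0]))
  net <- build_network(tree$tip.label, steps[tree$tip.label, tree$tip.label])
  hierarchy <- nest_clades(net, max_level = nesting_levels)
  freq <- stats::setNames(rep(1 / n, n), tree$tip.label)
  list(tree = tree, region = region, hierarchy = hierarchy,
       frequencies = freq)
}

# split the tree into k contiguous clades (tip partitions)
.partition_regions <- function(tree, k) {
  ntip <- length(tree$tip.label)
  tips_below <- function(node) {
    if (node <= ntip) return(node)
    kids <- tree$edge[tree$edge[, 1L] == node, 2L]
    unlist(lapply(kids, tips_below))
  }
  groups <- list(ntip + 1L)  # start from the root
  sizes <- function(g) vapply(g, function(nd) length(tips_below(nd)), 0L)
  while (length(groups) < k) {
    sz <- sizes(groups)
    internal <- vapply(groups, function(nd) nd > ntip, TRUE)
    if (!any(internal)) break
    pick <- which(internal)[which.max(sz[internal])]
    node <- groups[[pick]]
    kids <- tree$edge[tree$edge[, 1L] == node, 2L]
    groups <- c(groups[-pick], as.list(kids))
  }
  out <- character(ntip)
  for (g in seq_along(groups))
    out[tips_below(groups[[g]])] <- paste0("R", g)
  stats::setNames(out, tree$tip.label)[tree$tip.label]
}

#' Simulate infection histories on the genealogy
#'
#' The backbone strain descends from the root by vertical transmission,
#' lost on each branch with probability `vertical_loss_rate` (no
#' re-gain along branches). Sampled hosts then acquire their region's
#' resident strain with the regional horizontal rate; under cytoplasmic-
#' incompatibility exclusion a host never ends up carrying both a
#' wCallB- and a wCallC-class strain (the incoming acquisition is
#' rejected), while wCallA-class strains coexist with either.
#'
#' @param genealogy result of [simulate_genealogy()].
#' @param config a [sim_config()].
#' @return list with `specimens` (data.frame: specimen_id, taxon, region,
#'   cox1_haplotype, wg_genotype, true_st1, true_st2), `node_states`
#'   (backbone presence at internal nodes, ape numbering) and
#'   `tip_backbone` (named logical per haplotype).
#' @export
simulate_infections <- function(genealogy, config) {
  set.seed(config$seed + 1L)
  tree <- genealogy$tree
  ntip <- length(tree$tip.label)
  carries <- rep(NA, ntip + tree$Nnode)
  carries[ntip + 1L] <- TRUE  # root carries the backbone
  ord <- ape::reorder.phylo(tree, "postorder")
  for (e in rev(seq_len(nrow(ord$edge)))) {
    par <- ord$edge[e, 1L]; ch <- ord$edge[e, 2L]
    carries[ch] <- carries[par] &&
      stats::runif(1L) >= config$vertical_loss_rate
  }
  tip_backbone <- stats::setNames(carries[seq_len(ntip)], tree$tip.label)
  inv <- config$strain_inventory
  grp <- stats::setNames(inv$group, inv$st_id)
  hr <- stats::setNames(config$horizontal_rate_by_region,
                        paste0("R", seq_len(config$n_regions)))
  res <- stats::setNames(config$resident_by_region,
                         paste0("R", seq_len(config$n_regions)))
  hap <- sample(tree$tip.label, config$n_specimens, replace = TRUE,
                prob = genealogy$frequencies[tree$tip.label])
  reg <- genealogy$region[hap]
  st1 <- ifelse(tip_backbone[hap], config$backbone_st, NA_character_)
  st2 <- rep(NA_character_, config$n_specimens)
  acquire <- stats::runif(config$n_specimens) < hr[reg]
  for (i in which(acquire)) {
    incoming <- res[[reg[i]]]
    if (!is.na(st1[i])) {
      if (st1[i] == incoming) next
      gi <- grp[[st1[i]]]; gn <- grp[[incoming]]
      if (config$ci_exclusion &&
          ((gi == "wCallB" && gn == "wCallC") ||
           (gi == "wCallC" && gn == "wCallB"))) next
      st2[i] <- incoming
    } else {
      st1[i] <- incoming
    }
  }
  swap <- !is.na(st2) & st2 < st1
  tmp <- st1[swap]; st1[swap] <- st2[swap]; st2[swap] <- tmp
  # nuclear genotype tracks the region with some admixture noise
  wg <- paste0("W", sub("^R", "", reg))
  shuffle <- stats::runif(config$n_specimens) < 0.2
  wg[shuffle] <- paste0("W", sample.int(config$n_regions, sum(shuffle),
                                        replace = TRUE))
  specimens <- data.frame(
    specimen_id = sprintf("S%04d", seq_len(config$n_specimens)),
    taxon = "Calligrapha_sim", region = unname(reg),
    cox1_haplotype = unname(hap), wg_genotype = wg,
    true_st1 = unname(st1), true_st2 = unname(st2),
    stringsAsFactors = FALSE)
  list(specimens = specimens,
       node_states = carries[(ntip + 1L):(ntip + tree$Nnode)],
       tip_backbone = tip_backbone)
}

#' Emit a complete synthetic dataset with ground truth
#'
#' Turns simulated infection truths into the observation dialect consumed
#' by [classify_cohort()]: doubly infected specimens show the
#' position-wise union of their strains' alleles at every locus
#' (`"a/c"`), per-locus dropout blanks observations, and faint-signal
#' noise writes `"?low"`. Optionally writes the specimen CSV, the allele
#' FASTA files and a ground-truth JSON (seed embedded) to a directory.
#'
#' @param infections result of [simulate_infections()].
#' @param genealogy result of [simulate_genealogy()].
#' @param config a [sim_config()].
#' @param db allele database used for the FASTA output; default the
#'   fixture database.
#' @param dir optional output directory.
#' @return list with `records` (specimen table with observation columns),
#'   `truth` (the simulated truths plus config echo) and `paths` (written
#'   files, if `dir` given).
#' @export
emit_dataset <- function(infections, genealogy, config,
                         db = fixture_allele_db(), dir = NULL) {
  set.seed(config$seed + 2L)
  spec <- infections$specimens
  inv <- config$strain_inventory
  prof <- .st_profiles(inv)
  n <- nrow(spec)
  obs <- matrix("", n, 5L, dimnames = list(NULL, MLST_LOCI))
  for (i in seq_len(n)) {
    if (is.na(spec$true_st1[i])) next
    p1 <- prof[spec$true_st1[i], ]
    if (is.na(spec$true_st2[i])) {
      obs[i, ] <- p1
    } else {
      p2 <- prof[spec$true_st2[i], ]
      obs[i, ] <- ifelse(p1 == p2, p1,
                         paste(pmin(p1, p2), pmax(p1, p2), sep = "/"))
    }
  }
  if (config$dropout > 0) {
    drop <- matrix(stats::runif(n * 5L) < config$dropout, n, 5L)
    obs[drop] <- ""
  }
  if (config$faint_rate > 0) {
    blank <- rowSums(obs != "") == 0L
    faint <- blank & stats::runif(n) < config$faint_rate
    obs[faint, 1L] <- "?low"
  }
  records <- cbind(spec[, c("specimen_id", "taxon", "region",
                            "cox1_haplotype", "wg_genotype")],
                   as.data.frame(obs, stringsAsFactors = FALSE))
  truth <- list(config = unclass(config)[setdiff(names(config),
                                                 "strain_inventory")],
                seed = config$seed,
                specimens = spec,
                tip_backbone = infections$tip_backbone,
                node_states = infections$node_states,
                tree = ape::write.tree(genealogy$tree),
                region = as.list(genealogy$region))
  paths <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    csv <- file.path(dir, "specimens.csv")
    write_specimen_table(records, csv)
    write_allele_db(db, file.path(dir, "alleles"))
    nwk <- file.path(dir, "haplotypes.nwk")
    ape::write.tree(genealogy$tree, nwk)
    nst <- file.path(dir, "nesting.tsv")
    write_nesting_table(genealogy$hierarchy, nst)
    js <- file.path(dir, "ground_truth.json")
    jsonlite::write_json(truth, js, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths <- c(specimens = csv, tree = nwk, nesting = nst, truth = js)
  }
  list(records = records, truth = truth, paths = paths)
}

#' One-call synthetic dataset
#'
#' Convenience wrapper chaining [simulate_genealogy()],
#' [simulate_infections()] and [emit_dataset()].
#'
#' @inheritParams emit_dataset
#' @return as [emit_dataset()], plus `genealogy` and `infections`.
#' @export
simulate_dataset <- function(config = sim_config(), db = fixture_allele_db(),
                             dir = NULL) {
  genealogy <- simulate_genealogy(config)
  infections <- simulate_infections(genealogy, config)
  out <- emit_dataset(infections, genealogy, config, db = db, dir = dir)
  out$genealogy <- genealogy
  out$infections <- infections
  out
}
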