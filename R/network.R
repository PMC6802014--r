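#' Build a minimum-spanning (statistical parsimony style) network
#'
#' Edges represent mutational or allele-change steps between items
#' (alleles, sequence types, or haplotypes). The network is the union of
#' all minimum spanning trees — an edge (u, v) of weight w is retained iff
#' u and v are not connected by any path using only edges of weight < w
#' (the cycle/cut characterisation of MST membership) — augmented with all
#' weight-1 edges, so every single-step alternative connection is kept.
#' Edges heavier than `connection_limit` are then dropped, possibly
#' splitting components.
#'
#' @param items character vector of node ids.
#' @param distance symmetric, zero-diagonal matrix of step counts
#'   (dimnames optional; row order follows `items`).
#' @param connection_limit maximum steps per retained edge; `Inf` keeps the
#'   network fully connected whatever the distances.
#' @return an object of class `parsimony_network`: list with `nodes`,
#'   `edges` (data.frame node1, node2, weight) and `connection_limit`.
#' @export
build_network <- function(items, distance, connection_limit = Inf) {
  n <- length(items)
  distance <- as.matrix(distance)
  if (!all(dim(distance) == n)) stop("distance matrix must be ", n, "x", n)
  if (any(abs(distance - t(distance)) > 1e-9)) stop("distance must be symmetric")
  if (any(diag(distance) != 0)) stop("distance must have a zero diagonal")
  off <- distance[upper.tri(distance)]
  if (any(off == 0)) {
    idx <- which(distance == 0 & upper.tri(distance), arr.ind = TRUE)[1L, ]
    stop("distance 0 between distinct items ", items[idx[1L]], " and ",
         items[idx[2L]], ": collapse duplicates first", call. = FALSE)
  }
  edges <- list()
  if (n >= 2L) {
    pairs <- which(upper.tri(distance), arr.ind = TRUE)
    w <- distance[upper.tri(distance)]
    ord <- order(w)
    pairs <- pairs[ord, , drop = FALSE]; w <- w[ord]
    for (k in seq_along(w)) {
      i <- pairs[k, 1L]; j <- pairs[k, 2L]
      # connected by strictly lighter edges?
      sub <- distance < w[k]
      comp <- .components(sub)
      in_msn <- comp[i] != comp[j]
      keep <- (in_msn || w[k] == 1) && w[k] <= connection_limit
      if (keep)
        edges[[length(edges) + 1L]] <- data.frame(
          node1 = items[i], node2 = items[j], weight = w[k],
          stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(node1 = character(), node2 = character(), weight = numeric(),
               stringsAsFactors = FALSE)
  structure(list(nodes = items, edges = edges,
                 connection_limit = connection_limit),
            class = "parsimony_network")
}

# connected components from a logical adjacency matrix
.components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      if (comp[v]) next
      comp[v] <- cur
      stack <- c(stack, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}

#' @export
print.parsimony_network <- function(x, ...) {
  cat("<parsimony_network> ", length(x$nodes), " nodes, ",
      nrow(x$edges), " edges (limit ",
      if (is.finite(x$connection_limit)) x$connection_limit else "none",
      ")\n", sep = "")
  invisible(x)
}

.network_igraph <- function(network) {
  g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                     vertices = data.frame(name = network$nodes))
  g
}

#' Find loops (recombinant candidates) in a parsimony network
#'
#' Cycles in an otherwise tree-like haplotype or ST network point at
#' homoplasy or recombination. Cycles are reported as a fundamental cycle
#' basis (one cycle per non-tree edge of a spanning forest); every node on
#' a basis cycle whose nodes span at least two groups is flagged a
#' recombinant candidate.
#'
#' @param network a [build_network()] result.
#' @param groups named character vector mapping node id to group label.
#' @return list with `cycles` (list of node-id vectors) and
#'   `recombinant_candidates` (character vector).
#' @export
find_loops <- function(network, groups = NULL) {
  g <- .network_igraph(network)
  cycles <- list()
  if (nrow(network$edges)) {
    mst <- igraph::mst(g, weights = igraph::E(g)$weight)
    tree_keys <- apply(igraph::as_edgelist(mst), 1L, function(e)
      paste(sort(e), collapse = "\r"))
    el <- igraph::as_edgelist(g)
    for (k in seq_len(nrow(el))) {
      key <- paste(sort(el[k, ]), collapse = "\r")
      if (key %in% tree_keys) { tree_keys <- tree_keys[-match(key, tree_keys)]; next }
      path <- igraph::shortest_paths(mst, from = el[k, 1L], to = el[k, 2L],
                                     output = "vpath")$vpath[[1L]]
      cycles[[length(cycles) + 1L]] <- names(path)
    }
  }
  cand <- character(0)
  if (length(cycles) && !is.null(groups)) {
    for (cy in cycles) {
      if (length(unique(groups[cy])) >= 2L) cand <- union(cand, cy)
    }
  }
  list(cycles = cycles, recombinant_candidates = sort(cand))
}

#' Nested-clade construction on a parsimony network
#'
#' Builds a multi-level nested-clade hierarchy by the tips-inward rule:
#' at each nesting level, terminal nodes (degree 1 in the current clade
#' graph) are united with their interior neighbour, terminals sharing a
#' neighbour merging into one clade; assigned nodes are removed and the
#' rule is reapplied to the remainder until exhausted. Nodes left isolated
#' form singleton clades. Components without terminals (pure cycles) seed
#' from the node of highest eccentricity (ties: lexicographic id). Higher
#' levels repeat the procedure on the graph of clades.
#'
#' @param network a [build_network()] result (each component connected).
#' @param max_level number of nesting levels to build (>= 1).
#' @return a `nested_hierarchy`: list with `levels` — a list of named
#'   membership vectors (node/clade id -> parent clade label), level 1
#'   grouping the original nodes — and `labels` per level.
#' @export
nest_clades <- function(network, max_level = 2L) {
  if (max_level < 1L) stop("max_level must be >= 1", call. = FALSE)
  nodes <- network$nodes
  edges <- network$edges[, c("node1", "node2"), drop = FALSE]
  levels <- list()
  for (lev in seq_len(max_level)) {
    membership <- .nest_once(nodes, edges, prefix = paste0("L", lev, "-"))
    levels[[lev]] <- membership
    # collapse to clade graph
    new_nodes <- sort(unique(membership))
    if (nrow(edges)) {
      e1 <- membership[edges$node1]; e2 <- membership[edges$node2]
      keep <- e1 != e2
      edges <- unique(data.frame(
        node1 = pmin(e1[keep], e2[keep]),
        node2 = pmax(e1[keep], e2[keep]), stringsAsFactors = FALSE))
    }
    nodes <- new_nodes
  }
  structure(list(levels = levels), class = "nested_hierarchy")
}

# one nesting level: returns named vector node -> clade label
.nest_once <- function(nodes, edges, prefix = "C") {
  n <- length(nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges)) {
    adj[cbind(edges$node1, edges$node2)] <- TRUE
    adj[cbind(edges$node2, edges$node1)] <- TRUE
  }
  clade <- stats::setNames(rep(NA_integer_, n), nodes)
  next_id <- 0L
  remaining <- rep(TRUE, n)
  while (any(remaining)) {
    deg <- rowSums(adj[, remaining, drop = FALSE])[remaining]
    rn <- nodes[remaining]
    if (all(deg == 0L)) {          # isolated leftovers: singleton clades
      for (v in rn) { next_id <- next_id + 1L; clade[v] <- next_id }
      remaining[] <- FALSE
      break
    }
    tips <- rn[deg == 1L]
    if (!length(tips)) {
      # cyclic remainder: seed from max-eccentricity node (lex tie-break)
      sub <- adj[remaining, remaining, drop = FALSE]
      ecc <- .eccentricities(sub)
      seed <- rn[order(-ecc, rn)][1L]
      tips <- seed
    }
    # each tip joins its neighbour; tips sharing a neighbour merge
    assigned <- character(0)
    hubs <- list()
    for (v in sort(tips)) {
      nb <- nodes[adj[v, ] & remaining]
      nb <- setdiff(nb, tips)      # neighbour among interior nodes if any
      if (!length(nb)) nb <- setdiff(nodes[adj[v, ] & remaining], v)
      hub <- if (length(nb)) sort(nb)[1L] else v
      hubs[[hub]] <- c(hubs[[hub]], v)
    }
    for (hub in names(hubs)) {
      next_id <- next_id + 1L
      members <- unique(c(hubs[[hub]], hub))
      clade[members] <- next_id
      assigned <- c(assigned, members)
    }
    remaining[match(assigned, nodes)] <- FALSE
    adj[assigned, ] <- FALSE; adj[, assigned] <- FALSE
  }
  stats::setNames(paste0(prefix, clade), nodes)
}

.eccentricities <- function(adj) {
  n <- nrow(adj)
  d <- ifelse(adj, 1L, 1000000L); diag(d) <- 0L
  for (k in seq_len(n)) d <- pmin(d, outer(d[, k], d[k, ], `+`))
  apply(ifelse(d >= 1000000L, NA, d), 1L, max, na.rm = TRUE)
}

#' Import a nested-clade assignment table
#'
#' Validates an externally built nested-clade design (one row per
#' haplotype, one column per level, e.g. `clade_L1`, `clade_L2`, ...) into
#' a `nested_hierarchy`. Assignments must nest: haplotypes sharing a
#' lower-level clade must share every higher-level clade. Unicode hyphens
#' in clade labels are accepted and preserved.
#'
#' @param table data.frame with a haplotype id column (first column or
#'   named `haplotype`) and one column per level, ordered fine to coarse.
#' @return a `nested_hierarchy` (see [nest_clades()]), plus a `haplotypes`
#'   field.
#' @export
import_nesting <- function(table) {
  hcol <- if ("haplotype" %in% names(table)) "haplotype" else names(table)[1L]
  hap <- as.character(table[[hcol]])
  if (anyDuplicated(hap))
    stop("haplotype assigned twice: ",
         paste(unique(hap[duplicated(hap)]), collapse = ","), call. = FALSE)
  levcols <- setdiff(names(table), hcol)
  if (!length(levcols)) stop("no clade level columns", call. = FALSE)
  levels <- list()
  prev <- stats::setNames(hap, hap)
  for (k in seq_along(levcols)) {
    lab <- stats::setNames(as.character(table[[levcols[k]]]), hap)
    # coarsening: members of one level-(k-1) clade must map to one level-k clade
    up <- tapply(lab, prev, function(x) length(unique(x)))
    if (any(up > 1L)) {
      bad <- names(up)[up > 1L][1L]
      off <- hap[prev == bad]
      stop("non-nested assignment at level ", k, ": clade ", bad,
           " splits across ", paste(unique(lab[off]), collapse = ","),
           " (haplotype ", off[1L], ")", call. = FALSE)
    }
    if (k == 1L) {
      levels[[k]] <- lab
    } else {
      # membership of level-(k-1) clades into level-k clades
      m <- tapply(lab, prev, function(x) x[1L])
      levels[[k]] <- stats::setNames(as.character(m), names(m))
    }
    prev <- lab
  }
  structure(list(levels = levels, haplotypes = hap), class = "nested_hierarchy")
}

#' @export
print.nested_hierarchy <- function(x, ...) {
  cat("<nested_hierarchy> ", length(x$levels), " levels: ",
      paste(vapply(x$levels, function(l) length(unique(l)), 0L), collapse = " / "),
      " clades\n", sep = "")
  invisible(x)
}

#' Clade label of each haplotype at a given level
#'
#' @param hierarchy a `nested_hierarchy`.
#' @param haplotypes character vector of haplotype ids.
#' @param level nesting level (1 = finest clades above the haplotypes).
#' @return character vector of clade labels.
#' @export
clade_at_level <- function(hierarchy, haplotypes, level) {
  if (level < 1L || level > length(hierarchy$levels))
    stop("level out of range", call. = FALSE)
  lab <- hierarchy$levels[[1L]]
  missing <- setdiff(haplotypes, names(lab))
  if (length(missing))
    stop("haplotype absent from hierarchy: ", paste(missing, collapse = ","),
         call. = FALSE)
  cur <- lab[haplotypes]
  k <- 2L
  while (k <= level) {
    cur <- hierarchy$levels[[k]][cur]
    k <- k + 1L
  }
  unname(cur)
}

#' Write / read hierarchy and network interchange files
#'
#' The nesting table is a TSV `haplotype, clade_L1, clade_L2, ...`; the
#' network edge list is a TSV `node1, node2, weight`.
#'
#' @param hierarchy a `nested_hierarchy` whose level 1 names haplotypes.
#' @param path file path.
#' @export
write_nesting_table <- function(hierarchy, path) {
  hap <- names(hierarchy$levels[[1L]])
  tab <- data.frame(haplotype = hap, stringsAsFactors = FALSE)
  for (k in seq_along(hierarchy$levels))
    tab[[paste0("clade_L", k)]] <- clade_at_level(hierarchy, hap, k)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_nesting_table
#' @export
read_nesting_table <- function(path) {
  import_nesting(utils::read.delim(path, colClasses = "character",
                                   check.names = FALSE))
}

#' @rdname write_nesting_table
#' @param network a `parsimony_network`.
#' @export
write_network_edges <- function(network, path) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
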