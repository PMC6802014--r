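# shared fixture objects, loaded once per test run
fx_db <- fixture_allele_db()
fx_st <- fixture_st_table()
fx_st_var <- fixture_st_table(include_variant = TRUE)
fx_obs <- fx_st[fx_st$provenance == "observed", ]
fx_cohort <- fixture_cohort()

fx_profile <- function(st_id, table = fx_st_var) {
  mlst_profile(unlist(table[table$st_id == st_id, MLST_LOCI]))
}

# position-wise union mixture (allele-id level) of two ST profiles
fx_mixture <- function(id1, id2, table = fx_st_var) {
  p1 <- fx_profile(id1, table); p2 <- fx_profile(id2, table)
  sets <- lapply(MLST_LOCI, function(l) sort(unique(c(p1[[l]], p2[[l]]))))
  names(sets) <- MLST_LOCI
  sets
}

fx_distance_matrix <- function(table = fx_st) {
  prof <- as.matrix(table[, MLST_LOCI])
  rownames(prof) <- table$st_id
  n <- nrow(prof)
  d <- matrix(0L, n, n, dimnames = list(table$st_id, table$st_id))
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- sum(prof[i, ] != prof[j, ])
  d
}

# brute-force union-of-all-minimum-spanning-trees via Pruefer enumeration
bf_msn_edges <- function(items, d, connection_limit = Inf) {
  n <- length(items)
  stopifnot(n >= 2L, n <= 7L)
  best_w <- Inf; union_edges <- character(0)
  prufer_tree <- function(code) {
    # decode a Pruefer sequence into an edge list (1-based labels)
    degree <- rep(1L, n)
    for (c in code) degree[c] <- degree[c] + 1L
    edges <- matrix(0L, n - 1L, 2L)
    k <- 0L
    code2 <- code
    for (c in code2) {
      leaf <- min(which(degree == 1L))
      k <- k + 1L
      edges[k, ] <- c(leaf, c)
      degree[leaf] <- degree[leaf] - 1L
      degree[c] <- degree[c] - 1L
    }
    last <- which(degree == 1L)
    edges[n - 1L, ] <- last
    edges
  }
  codes <- if (n == 2L) list(integer(0)) else {
    g <- do.call(expand.grid, rep(list(seq_len(n)), n - 2L))
    lapply(seq_len(nrow(g)), function(i) as.integer(g[i, ]))
  }
  for (code in codes) {
    edges <- prufer_tree(code)
    w <- sum(d[edges])
    key <- sort(apply(edges, 1L, function(e)
      paste(sort(items[e]), collapse = "|")))
    if (w < best_w - 1e-9) { best_w <- w; union_edges <- key }
    else if (abs(w - best_w) < 1e-9) union_edges <- union(union_edges, key)
  }
  # augment with weight-1 edges, apply connection limit
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    if (d[i, j] == 1) union_edges <- union(union_edges,
                                           paste(sort(items[c(i, j)]), collapse = "|"))
  keep <- vapply(union_edges, function(k) {
    ij <- match(strsplit(k, "|", fixed = TRUE)[[1]], items)
    d[ij[1L], ij[2L]] <= connection_limit
  }, TRUE)
  sort(union_edges[keep])
}

net_edge_keys <- function(net) {
  if (!nrow(net$edges)) return(character(0))
  sort(apply(net$edges[, c("node1", "node2")], 1L, function(e)
    paste(sort(e), collapse = "|")))
}

# brute-force marginal posteriors / likelihood by summation over all
# internal-node state assignments
bf_posteriors <- function(tree, rate, root_prior = NULL) {
  phy <- tree$phy
  k <- tree$n_states
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  if (is.null(root_prior)) root_prior <- rep(1 / k, k)
  pmat <- function(t) wolmlst:::.mk_pmat(rate, max(t, 1e-9), k)
  tipsets <- lapply(phy$tip.label, function(tl)
    match(tree$tip_states[[tl]], tree$state_labels))
  internal <- (ntip + 1L):nnode
  grids <- rep(list(seq_len(k)), length(internal))
  assign_grid <- do.call(expand.grid, grids)
  post <- matrix(0, nnode, k)
  total <- 0
  for (r in seq_len(nrow(assign_grid))) {
    istates <- as.integer(assign_grid[r, ])
    names(istates) <- internal
    # sum over tip ambiguity sets
    tipgrids <- do.call(expand.grid, tipsets)
    for (tr in seq_len(nrow(tipgrids))) {
      st <- integer(nnode)
      st[seq_len(ntip)] <- as.integer(tipgrids[tr, ])
      st[internal] <- istates
      pr <- root_prior[st[ntip + 1L]]
      for (e in seq_len(nrow(phy$edge))) {
        pa <- phy$edge[e, 1L]; ch <- phy$edge[e, 2L]
        pr <- pr * pmat(phy$edge.length[e])[st[pa], st[ch]]
      }
      total <- total + pr
      for (v in seq_len(nnode)) post[v, st[v]] <- post[v, st[v]] + pr
    }
  }
  list(posteriors = post / total, loglik = log(total))
}

# exact chi-square statistic straight from the definition
bf_chi2 <- function(tab) {
  tab <- as.matrix(tab)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) return(0)
  n <- sum(tab)
  out <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    e <- sum(tab[i, ]) * sum(tab[, j]) / n
    out <- out + (tab[i, j] - e)^2 / e
  }
  out
}
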