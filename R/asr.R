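#' Trait trees for infection-state reconstruction
#'
#' Couples a rooted tree with per-tip infection states for discrete-trait
#' ancestral reconstruction. A tip may carry an ambiguity set (e.g. a
#' double infection coded as its two strain groups), written `"A|B"` in
#' serialised form. Zero-length branches are clamped to 1e-9 so transition
#' matrices stay well defined.
#'
#' @param phy an [ape::read.tree()] `phylo` object (rooted; branch lengths
#'   required).
#' @param tip_states named list or character vector mapping every tip label
#'   to a state or a character vector of states (ambiguity set); string
#'   values may use the `"A|B"` dialect.
#' @param state_labels optional explicit state inventory; default is the
#'   sorted union of tip states.
#' @return an object of class `trait_tree`.
#' @export
trait_tree <- function(phy, tip_states, state_labels = NULL) {
  if (!inherits(phy, "phylo")) stop("phy must be a phylo object", call. = FALSE)
  if (is.null(phy$edge.length)) stop("branch lengths required", call. = FALSE)
  if (any(phy$edge.length < 0)) stop("negative branch length", call. = FALSE)
  phy$edge.length <- pmax(phy$edge.length, 1e-9)
  if (is.character(tip_states)) tip_states <- as.list(tip_states)
  tip_states <- lapply(tip_states, function(s)
    unique(unlist(strsplit(as.character(s), "|", fixed = TRUE))))
  miss <- setdiff(phy$tip.label, names(tip_states))
  if (length(miss))
    stop("tips without a state: ", paste(miss, collapse = ","), call. = FALSE)
  if (is.null(state_labels))
    state_labels <- sort(unique(unlist(tip_states)))
  bad <- setdiff(unlist(tip_states), state_labels)
  if (length(bad))
    stop("tip states outside the state inventory: ",
         paste(bad, collapse = ","), call. = FALSE)
  structure(list(phy = phy, tip_states = tip_states[phy$tip.label],
                 state_labels = state_labels,
                 n_states = length(state_labels)),
            class = "trait_tree")
}

#' @export
print.trait_tree <- function(x, ...) {
  cat("<trait_tree> ", length(x$phy$tip.label), " tips, ", x$n_states,
      " states: ", paste(x$state_labels, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# transition probability matrix of the symmetric k-state Markov (Mk) model
# with per-pair exchange rate `rate`: closed form, no matrix exponential.
.mk_pmat <- function(rate, t, k) {
  e <- exp(-k * rate * t)
  same <- 1 / k + (k - 1) / k * e
  diff <- 1 / k * (1 - e)
  m <- matrix(diff, k, k)
  diag(m) <- same
  m
}

# tip partial likelihood rows (1 on members of the ambiguity set)
.tip_partials <- function(tree) {
  k <- tree$n_states
  out <- matrix(0, length(tree$phy$tip.label), k,
                dimnames = list(tree$phy$tip.label, tree$state_labels))
  for (tl in tree$phy$tip.label)
    out[tl, tree$tip_states[[tl]]] <- 1
  out
}

# postorder (pruning) pass: per-node partial likelihood matrix
.prune_partials <- function(tree, rate) {
  phy <- tree$phy
  k <- tree$n_states
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  partial <- matrix(0, nnode, k)
  partial[seq_len(ntip), ] <- .tip_partials(tree)
  ord <- ape::reorder.phylo(phy, "postorder")
  # message from child up its branch, cached for the marginal pass
  msg <- matrix(0, nrow(ord$edge), k)
  partial[(ntip + 1):nnode, ] <- 1
  for (e in seq_len(nrow(ord$edge))) {
    par <- ord$edge[e, 1L]; ch <- ord$edge[e, 2L]
    P <- .mk_pmat(rate, ord$edge.length[e], k)
    msg[e, ] <- as.vector(P %*% partial[ch, ])
    partial[par, ] <- partial[par, ] * msg[e, ]
  }
  list(partial = partial, edges = ord, msg = msg, ntip = ntip)
}

#' Log-likelihood of a trait tree under the symmetric Mk model
#'
#' Felsenstein pruning over the tree, with a uniform (equilibrium) root
#' prior by default.
#'
#' @param tree a [trait_tree()].
#' @param rate per-pair instantaneous exchange rate (>= 0).
#' @param root_prior `"uniform"` (the symmetric model's equilibrium) or a
#'   numeric vector over states.
#' @return log-likelihood (scalar).
#' @export
trait_loglik <- function(tree, rate, root_prior = "uniform") {
  pp <- .prune_partials(tree, rate)
  prior <- .root_prior(root_prior, tree)
  root <- pp$ntip + 1L
  l <- sum(prior * pp$partial[root, ])
  if (l <= 0) stop("zero likelihood: contradictory tip constraints", call. = FALSE)
  log(l)
}

.root_prior <- function(root_prior, tree) {
  k <- tree$n_states
  if (identical(root_prior, "uniform") || identical(root_prior, "equilibrium"))
    return(rep(1 / k, k))
  if (length(root_prior) != k) stop("root prior has wrong length", call. = FALSE)
  root_prior / sum(root_prior)
}

#' Maximum-likelihood exchange rate of the symmetric Mk model
#'
#' Bounded one-dimensional optimisation of the pruning likelihood over the
#' per-pair exchange rate. All tips in one state give rate 0 with a
#' warning.
#'
#' @param tree a [trait_tree()].
#' @param upper upper bound of the search interval; default scales as
#'   100 / (total tree length / tips), generous for any identifiable rate.
#' @param tol optimisation tolerance on the rate.
#' @inheritParams trait_loglik
#' @return a `trait_model`: list with `rate`, `n_states`, `loglik`, `kind`.
#' @export
fit_rate <- function(tree, root_prior = "uniform", upper = NULL, tol = 1e-8) {
  states_seen <- unique(unlist(tree$tip_states))
  if (length(states_seen) < 2L ||
      all(vapply(tree$tip_states, function(s) all(states_seen %in% s), TRUE))) {
    warning("tips carry a single (or fully overlapping) state: rate 0")
    return(structure(list(kind = "symmetric", rate = 0,
                          n_states = tree$n_states,
                          loglik = tryCatch(trait_loglik(tree, 1e-12, root_prior),
                                            error = function(e) NA_real_)),
                     class = "trait_model"))
  }
  if (is.null(upper)) {
    mean_path <- sum(tree$phy$edge.length) / length(tree$phy$tip.label)
    upper <- 100 / max(mean_path, 1e-6)
  }
  f <- function(lr) trait_loglik(tree, exp(lr), root_prior)
  opt <- stats::optimize(f, interval = c(log(1e-8), log(upper)),
                         maximum = TRUE, tol = tol)
  structure(list(kind = "symmetric", rate = exp(opt$maximum),
                 n_states = tree$n_states, loglik = opt$objective),
            class = "trait_model")
}

#' @export
print.trait_model <- function(x, ...) {
  cat(sprintf("<trait_model> symmetric Mk, %d states, rate = %.6g (logL = %.4f)\n",
              x$n_states, x$rate, x$loglik))
  invisible(x)
}

#' Marginal ancestral-state posteriors at every node
#'
#' Standard two-pass algorithm: a postorder pruning pass collects partial
#' likelihoods below each node, a preorder pass propagates the
#' likelihood of the rest of the tree; their product, normalised, is the
#' marginal posterior state distribution of each node (tips included —
#' ambiguous tips receive a posterior over their member states).
#'
#' @param tree a [trait_tree()].
#' @param model a `trait_model` from [fit_rate()], or a numeric rate.
#' @inheritParams trait_loglik
#' @return a data.frame with `node` (ape node numbers; tips first),
#'   `label` (tip label or `"node<N>"`), one probability column per state,
#'   and attribute `"loglik"`.
#' @export
marginal_posteriors <- function(tree, model, root_prior = "uniform") {
  rate <- if (inherits(model, "trait_model")) model$rate else as.numeric(model)
  rate <- max(rate, 1e-12)
  k <- tree$n_states
  pp <- .prune_partials(tree, rate)
  phy <- pp$edges
  ntip <- pp$ntip
  nnode <- ntip + phy$Nnode
  prior <- .root_prior(root_prior, tree)
  root <- ntip + 1L
  lik <- sum(prior * pp$partial[root, ])
  if (lik <= 0) stop("zero likelihood: contradictory tip constraints", call. = FALSE)
  outside <- matrix(0, nnode, k)
  outside[root, ] <- prior
  # preorder = reverse postorder edge order
  for (e in rev(seq_len(nrow(phy$edge)))) {
    par <- phy$edge[e, 1L]; ch <- phy$edge[e, 2L]
    P <- .mk_pmat(rate, phy$edge.length[e], k)
    sib <- pp$partial[par, ] / ifelse(pp$msg[e, ] > 0, pp$msg[e, ], 1)
    # guard exact zeros in the cached message: recompute product over siblings
    if (any(pp$msg[e, ] == 0)) {
      sib <- rep(1, k)
      for (e2 in which(phy$edge[, 1L] == par)) {
        if (e2 == e) next
        sib <- sib * pp$msg[e2, ]
      }
    }
    outside[ch, ] <- as.vector(t(P) %*% (outside[par, ] * sib))
  }
  post <- pp$partial * outside
  post <- post / rowSums(post)
  labels <- c(tree$phy$tip.label, paste0("node", (ntip + 1L):nnode))
  out <- data.frame(node = seq_len(nnode), label = labels,
                    stringsAsFactors = FALSE)
  colnames_states <- tree$state_labels
  for (j in seq_len(k)) out[[colnames_states[j]]] <- post[, j]
  attr(out, "loglik") <- log(lik)
  out
}

#' Encode resolved records as trait states for a tree
#'
#' Two codings of the infection trait:
#' * `full_st`: one state per sequence type (each of the inventory's
#'   non-variant STs singly) plus one state per observed double
#'   combination plus `"uninfected"`;
#' * `grouped`: `uninfected`, `A`, `B`, `C`, with a double infection coded
#'   as the ambiguity set of its two groups.
#'
#' Variant STs (mosaics) map to their base type; records with uncertain or
#' ambiguous resolution are coded as fully ambiguous (all states).
#'
#' @param records resolved records from [classify_cohort()].
#' @param st_table the final ST table.
#' @param scheme `"full_st"` or `"grouped"`.
#' @return list with `tip_states` (named list keyed by
#'   `taxon|haplotype|state` tip ids), `states` (inventory), and `tips`
#'   (data.frame mapping tip ids to taxon/haplotype/state).
#' @export
encode_trait_states <- function(records, st_table,
                                scheme = c("full_st", "grouped")) {
  scheme <- match.arg(scheme)
  base_st <- function(s) {
    v <- st_table$variant[match(s, st_table$st_id)]
    ifelse(!is.na(v) & v, sub("r[0-9]*$", "", s), s)
  }
  sts <- lapply(record_sts(records), base_st)
  uncertain <- if (!is.null(records$uncertain)) records$uncertain else
    rep(FALSE, nrow(records))
  grp_of <- function(s) sub("^wCall([A-Z]).*$", "\\1", s)
  if (scheme == "full_st") {
    singles <- sort(st_table$st_id[!st_table$variant])
    combos <- sort(unique(vapply(
      which(records$status == "double" & !uncertain),
      function(i) paste(sort(sts[[i]]), collapse = "+"), "")))
    states <- c("uninfected", singles, combos)
    lab <- function(i) {
      if (records$status[i] == "uninfected") return("uninfected")
      if (records$status[i] == "ambiguous" || uncertain[i]) return(states)
      paste(sort(sts[[i]]), collapse = "+")
    }
  } else {
    states <- c("uninfected", "A", "B", "C")
    lab <- function(i) {
      if (records$status[i] == "uninfected") return("uninfected")
      if (records$status[i] == "ambiguous" || uncertain[i]) return(states)
      sort(unique(grp_of(sts[[i]])))
    }
  }
  state_of <- lapply(seq_len(nrow(records)), lab)
  key <- vapply(seq_len(nrow(records)), function(i)
    paste(records$taxon[i], records$cox1_haplotype[i],
          paste(state_of[[i]], collapse = "|"), sep = "|"), "")
  keep <- !duplicated(key)
  tips <- data.frame(tip_id = key[keep], taxon = records$taxon[keep],
                     haplotype = records$cox1_haplotype[keep],
                     state = vapply(state_of[keep], paste, "", collapse = "|"),
                     stringsAsFactors = FALSE)
  list(tip_states = stats::setNames(state_of[keep], key[keep]),
       states = states, tips = tips)
}

#' Simulate a discrete trait down a tree
#'
#' Forward simulation under the symmetric Mk model, used for planted-
#' history recovery experiments.
#'
#' @param phy a rooted `phylo` with branch lengths.
#' @param rate per-pair exchange rate.
#' @param states state labels.
#' @param root_state starting state (default: uniform draw).
#' @return list with `tip_states` (named character) and `node_states`
#'   (states at internal nodes, ape numbering), `root_state`.
#' @export
simulate_trait <- function(phy, rate, states, root_state = NULL) {
  k <- length(states)
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  st <- integer(nnode)
  root <- ntip + 1L
  st[root] <- if (is.null(root_state)) sample.int(k, 1L) else
    match(root_state, states)
  ord <- ape::reorder.phylo(phy, "postorder")
  for (e in rev(seq_len(nrow(ord$edge)))) {
    par <- ord$edge[e, 1L]; ch <- ord$edge[e, 2L]
    P <- .mk_pmat(rate, ord$edge.length[e], k)
    st[ch] <- sample.int(k, 1L, prob = P[st[par], ])
  }
  list(tip_states = stats::setNames(states[st[seq_len(ntip)]], phy$tip.label),
       node_states = states[st[(ntip + 1L):nnode]],
       root_state = states[st[root]])
}

#' Write per-node posteriors and an annotated tree
#'
#' @param posteriors result of [marginal_posteriors()].
#' @param tree the [trait_tree()] it came from.
#' @param tsv_path path for the per-node posterior TSV.
#' @param nwk_path optional path for a newick with modal-state node labels
#'   (`state=probability`; `=` survives newick label sanitisation).
#' @export
write_posteriors <- function(posteriors, tree, tsv_path, nwk_path = NULL) {
  utils::write.table(posteriors, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(nwk_path)) {
    phy <- tree$phy
    ntip <- length(phy$tip.label)
    prob <- as.matrix(posteriors[, tree$state_labels, drop = FALSE])
    modal <- tree$state_labels[max.col(prob, ties.method = "first")]
    pmax_ <- prob[cbind(seq_len(nrow(prob)), max.col(prob, ties.method = "first"))]
    phy$node.label <- sprintf("%s=%.3f", modal[-seq_len(ntip)],
                              pmax_[-seq_len(ntip)])
    ape::write.tree(phy, nwk_path)
  }
  invisible(tsv_path)
}
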