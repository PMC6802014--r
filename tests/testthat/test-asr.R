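test_that("pruning equals brute-force enumeration on all shapes up to 6 tips", {
  set.seed(31)
  shapes <- c(
    "((a:0.3,b:0.7):0.4,c:1.1);",
    "((a:0.2,b:0.2):0.5,(c:0.4,d:0.9):0.1);",
    "(((a:0.1,b:0.6):0.3,c:0.8):0.2,d:0.5);",
    "((((a:0.4,b:0.2):0.3,c:0.5):0.2,d:0.7):0.1,e:0.9);",
    "(((a:0.2,b:0.3):0.4,(c:0.5,d:0.1):0.2):0.3,e:0.6);",
    "(((a:0.3,b:0.2):0.2,(c:0.4,d:0.3):0.5):0.3,(e:0.2,f:0.7):0.4);",
    "(((((a:0.2,b:0.3):0.1,c:0.4):0.3,d:0.2):0.2,e:0.5):0.1,f:0.8);",
    "((((a:0.1,b:0.2):0.2,(c:0.3,d:0.4):0.1):0.3,e:0.6):0.2,f:0.3);")
  for (nwk in shapes) {
    phy <- ape::read.tree(text = nwk)
    for (k in c(2L, 4L)) {
      states <- paste0("S", seq_len(k))
      tips <- lapply(phy$tip.label, function(x) sample(states, 1L))
      names(tips) <- phy$tip.label
      # one ambiguous tip exercises the ambiguity-set partials
      tips[[1L]] <- sample(states, 2L)
      tree <- trait_tree(phy, tips, state_labels = states)
      rate <- runif(1, 0.05, 1.5)
      got <- marginal_posteriors(tree, rate)
      ref <- bf_posteriors(tree, rate)
      expect_equal(attr(got, "loglik"), ref$loglik, tolerance = 1e-10)
      expect_equal(unname(as.matrix(got[, states])),
                   unname(ref$posteriors), tolerance = 1e-10)
      expect_equal(rowSums(as.matrix(got[, states])),
                   rep(1, nrow(got)), tolerance = 1e-9)
    }
  }
})

test_that("posteriors are invariant to child rotation and obey rate limits", {
  phy <- ape::read.tree(text = "((a:0.2,b:0.4):0.3,(c:0.5,d:0.1):0.2);")
  rot <- ape::read.tree(text = "((c:0.5,d:0.1):0.2,(b:0.4,a:0.2):0.3);")
  tips <- list(a = "X", b = "Y", c = "X", d = "X")
  t1 <- trait_tree(phy, tips, state_labels = c("X", "Y"))
  t2 <- trait_tree(rot, tips, state_labels = c("X", "Y"))
  p1 <- marginal_posteriors(t1, 0.37)
  p2 <- marginal_posteriors(t2, 0.37)
  root1 <- p1[p1$label == "node5", c("X", "Y")]
  root2 <- p2[p2$label == "node5", c("X", "Y")]
  expect_equal(unlist(root1), unlist(root2), tolerance = 1e-12)
  # rate -> infinity: posteriors converge to the (uniform) root prior
  fast <- marginal_posteriors(t1, 500)
  expect_equal(unlist(fast[fast$label == "node5", c("X", "Y")]),
               c(X = 0.5, Y = 0.5), tolerance = 1e-3)
  # rate -> 0 with homogeneous tips: point mass on the shared state
  t3 <- trait_tree(phy, list(a = "X", b = "X", c = "X", d = "X"),
                   state_labels = c("X", "Y"))
  slow <- marginal_posteriors(t3, 1e-9)
  expect_equal(unlist(slow[slow$label == "node5", c("X", "Y")]),
               c(X = 1, Y = 0), tolerance = 1e-6)
})

test_that("fit_rate matches a dense grid search and handles degeneracy", {
  # two concordant cherries in conflict across the root: the likelihood has
  # an interior, well-identified maximum in the rate
  phy <- ape::read.tree(text = "((a:0.4,b:0.6):0.5,(c:0.3,d:0.7):0.4);")
  tree <- trait_tree(phy, list(a = "X", b = "X", c = "Y", d = "Y"),
                     state_labels = c("X", "Y"))
  fit <- fit_rate(tree)
  grid <- exp(seq(log(1e-4), log(50), length.out = 6000))
  ll <- vapply(grid, function(r) trait_loglik(tree, r), 0)
  expect_equal(fit$rate, grid[which.max(ll)], tolerance = 5e-3)
  expect_gte(fit$loglik, max(ll) - 1e-8)
  same <- trait_tree(phy, list(a = "X", b = "X", c = "X", d = "X"),
                     state_labels = c("X", "Y"))
  expect_warning(f0 <- fit_rate(same), "rate 0")
  expect_equal(f0$rate, 0)
})

test_that("marginal reconstruction agrees with an independent ML implementation", {
  set.seed(17)
  phy <- ape::rcoal(12)
  states <- c("A", "B")
  sim <- simulate_trait(phy, rate = 0.6, states = states)
  if (length(unique(sim$tip_states)) < 2L) skip("degenerate draw")
  tree <- trait_tree(phy, as.list(sim$tip_states), state_labels = states)
  fit <- fit_rate(tree)
  post <- marginal_posteriors(tree, fit)
  ref <- ape::ace(factor(sim$tip_states[phy$tip.label], levels = states),
                  phy, type = "discrete",
                  model = "ER")
  ntip <- length(phy$tip.label)
  ours <- as.matrix(post[post$node > ntip, states])
  expect_equal(unname(ours), unname(ref$lik.anc), tolerance = 0.02)
})

test_that("the true root state is recovered at low rates (planted histories)", {
  set.seed(55)
  reps <- 200L
  hit <- 0L; used <- 0L
  states <- c("S1", "S2", "S3")
  for (r in seq_len(reps)) {
    phy <- ape::rcoal(25)
    phy$edge.length <- phy$edge.length / max(ape::node.depth.edgelength(phy))
    sim <- simulate_trait(phy, rate = 0.08, states = states)
    if (length(unique(sim$tip_states)) < 2L) next
    used <- used + 1L
    tree <- trait_tree(phy, as.list(sim$tip_states), state_labels = states)
    post <- marginal_posteriors(tree, fit_rate(tree))
    root <- unlist(post[post$label == "node26", states])
    if (states[which.max(root)] == sim$root_state) hit <- hit + 1L
  }
  expect_gte(hit / used, 0.8)
})

test_that("encode_trait_states yields the published state inventories", {
  res <- classify_cohort(fx_cohort, fx_obs, db = fx_db)
  full <- encode_trait_states(res$records, res$st_table, "full_st")
  expect_length(full$states, 31L)  # 15 types + 15 combinations + uninfected
  expect_true("uninfected" %in% full$states)
  grouped <- encode_trait_states(res$records, res$st_table, "grouped")
  expect_identical(grouped$states, c("uninfected", "A", "B", "C"))
  # a double infection is coded as the ambiguity set of its groups
  dbl <- which(res$records$status == "double" & !res$records$uncertain)[1L]
  key <- paste(res$records$taxon[dbl], res$records$cox1_haplotype[dbl],
               sep = "|")
  tipmatch <- grep(key, names(grouped$tip_states), fixed = TRUE, value = TRUE)
  expect_true(any(vapply(grouped$tip_states[tipmatch], length, 0L) >= 1L))
  # uninfected records map to the uninfected state in both schemes
  unin <- which(res$records$status == "uninfected")[1L]
  ukey <- grep(res$records$cox1_haplotype[unin], names(full$tip_states),
               value = TRUE, fixed = TRUE)
  expect_true(any(vapply(full$tip_states[ukey], identical, TRUE,
                         "uninfected")))
})

test_that("posterior tables and annotated trees serialise", {
  phy <- ape::read.tree(text = "((a:0.2,b:0.4):0.3,c:0.6);")
  tree <- trait_tree(phy, list(a = "X", b = "Y", c = "X"),
                     state_labels = c("X", "Y"))
  post <- marginal_posteriors(tree, 0.5)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  nwk <- withr::local_tempfile(fileext = ".nwk")
  write_posteriors(post, tree, tsv, nwk)
  back <- utils::read.delim(tsv)
  expect_equal(nrow(back), 5L)
  annotated <- ape::read.tree(nwk)
  expect_length(annotated$node.label, 2L)
  expect_match(annotated$node.label[1L], "^[XY]=")
})
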