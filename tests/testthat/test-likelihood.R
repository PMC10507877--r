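test_that("two-taxon likelihood matches the closed-form transition probability", {
  t_total <- log(2) / 2
  tr <- ape::read.tree(text = sprintf("(A:%.10f,B:%.10f);",
                                      t_total / 2, t_total / 2))
  m <- bin_model("BIN")
  # pi = (1/2, 1/2): L = 0.5 * 0.5 * (1 - exp(-2t)) = 0.125
  expect_equal(site_log_likelihood(tr, m, c(A = 0, B = 1)),
               log(0.125), tolerance = 1e-10)
  expect_equal(site_log_likelihood(tr, m, c(A = 0, B = 1)),
               -2.0794, tolerance = 1e-4)
})

test_that("constant sites approach the stationary frequency as branches vanish", {
  tr <- ape::read.tree(text = "((A:1e-9,B:1e-9):1e-9,(C:1e-9,D:1e-9):1e-9);")
  m <- bin_model("BIN", pi = c(0.3, 0.7))
  expect_equal(exp(site_log_likelihood(tr, m, c(A = 1, B = 1, C = 1, D = 1))),
               0.7, tolerance = 1e-6)
  expect_equal(exp(site_log_likelihood(tr, m, c(A = 0, B = 0, C = 0, D = 0))),
               0.3, tolerance = 1e-6)
})

test_that("pruning equals brute-force enumeration for mixed models (<= 5 taxa)", {
  withr::local_seed(61)
  models <- list(
    bin_model("BIN", pi = c(0.4, 0.6)),
    bin_model("BIN+I", pi = c(0.6, 0.4), p_inv = 0.3),
    bin_model("BIN+I+G", pi = c(0.5, 0.5), p_inv = 0.2, alpha = 0.7),
    bin_model("BIN+I+R4", pi = c(0.3, 0.7), p_inv = 0.1,
              rates = c(0.2, 0.8, 1.5, 4), weights = c(0.4, 0.3, 0.2, 0.1))
  )
  for (i in 1:25) {
    n <- sample(3:5, 1)
    phy <- random_rooted_tree(n)
    pattern <- rbinom(n, 1, 0.5)
    m <- models[[sample(length(models), 1)]]
    got <- site_log_likelihood(phy, m, setNames(pattern, phy$tip.label))
    want <- log(brute_site_lik(phy, m, pattern))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("likelihood is invariant to root placement", {
  withr::local_seed(67)
  n <- 6
  phy <- ape::rtree(n, rooted = FALSE, tip.label = paste0("t", 1:n))
  phy$edge.length <- runif(nrow(phy$edge), 0.05, 0.8)
  m <- matrix(rbinom(20 * n, 1, 0.5), 20, n,
              dimnames = list(NULL, phy$tip.label))
  x <- acc_from_matrix(m)
  model <- bin_model("BIN+I", pi = c(0.45, 0.55), p_inv = 0.15)
  base <- tree_log_likelihood(phy, x, model)
  for (og in c("t1", "t3", "t5")) {
    rooted <- root_with_outgroup(phy, og)
    expect_equal(tree_log_likelihood(rooted, x, model), base,
                 tolerance = 1e-10)
  }
})

test_that("branch-length and frequency recovery on simulated data", {
  withr::local_seed(73)
  true_tree <- ape::read.tree(
    text = "((A:0.15,B:0.25):0.2,(C:0.3,D:0.1):0.15,E:0.2);")
  pi <- c(0.4, 0.6)
  n_sites <- 10000
  # independent simulator: draw root state, evolve with closed-form P(t)
  phy <- ape::reorder.phylo(true_tree, "postorder")
  ntip <- 5L
  e <- phy$edge
  sim_states <- matrix(NA_integer_, n_sites, ntip + phy$Nnode)
  root <- e[nrow(e), 1]
  sim_states[, root] <- rbinom(n_sites, 1, pi[2])
  for (i in rev(seq_len(nrow(e)))) {
    p01 <- oracle_pmat(pi, phy$edge.length[i])
    prob_open <- ifelse(sim_states[, e[i, 1]] == 1, p01[2, 2], p01[1, 2])
    sim_states[, e[i, 2]] <- rbinom(n_sites, 1, prob_open)
  }
  m <- sim_states[, 1:ntip]
  colnames(m) <- phy$tip.label
  x <- acc_from_matrix(m)
  fit <- ml_fit(true_tree, x, "BIN", max_iter = 50)
  expect_true(fit$converged)
  expect_lt(abs(fit$model$pi[2] - pi[2]), 0.02)
  total_true <- sum(true_tree$edge.length)
  expect_lt(abs(sum(fit$tree$edge.length) - total_true) / total_true, 0.10)
  # per-branch recovery within 10% (+ small absolute slack for short branches)
  want <- setNames(true_tree$edge.length,
                   paste(true_tree$edge[, 1], true_tree$edge[, 2]))
  got <- setNames(fit$tree$edge.length,
                  paste(fit$tree$edge[, 1], fit$tree$edge[, 2]))
  for (nm in names(want)) {
    expect_lt(abs(got[[nm]] - want[[nm]]), 0.1 * want[[nm]] + 0.02)
  }
  # optimality: fitted lnL is at least the truth's lnL
  true_lnl <- tree_log_likelihood(true_tree, x, bin_model("BIN", pi = pi))
  expect_gte(fit$lnL, true_lnl)
})

test_that("a fully constant matrix drives p_inv to its upper boundary", {
  m <- matrix(rep(c(0L, 1L), each = 4 * 25), 50, 4, byrow = FALSE)
  m <- rbind(matrix(0L, 25, 4), matrix(1L, 25, 4))
  colnames(m) <- c("A", "B", "C", "D")
  fit <- suppressWarnings(
    ml_fit(ape::read.tree(text = "((A,B),(C,D));"), acc_from_matrix(m),
           "BIN+I", max_iter = 30))
  expect_gt(fit$model$p_inv, 0.9)
  expect_lt(mean(fit$tree$edge.length), 1e-4)
})

test_that("AIC bookkeeping is 2k - 2 lnL with the documented k", {
  ks <- vapply(c("BIN", "BIN+I", "BIN+I+G", "BIN+I+R4", "BIN+I+R8",
                 "BIN+I+R12"), accesstree:::model_n_free, integer(1))
  expect_equal(unname(ks), c(1L, 2L, 3L, 8L, 16L, 24L))
  expect_true(all(diff(ks) > 0))
  sim <- simulate_accessibility(n_sites = 150, seed = 91)
  x <- subset_cells(sim$matrix, c("LSK", "B", "Neu", "Ery", "NK"))
  fit <- ml_fit(ape::unroot(nj_tree(pairwise_differences(x))), x, "BIN+I",
                max_iter = 15)
  expect_equal(fit$AIC, 2 * fit$k - 2 * fit$lnL)
  expect_equal(fit$k, 2L + (2L * 5L - 3L))
  expect_lte(fit$lnL, 0)
  g <- glance(fit)
  expect_equal(g$AIC, fit$AIC)
  td <- tidy(fit)
  expect_true(all(c("pi_open", "p_inv") %in% td$term))
})

test_that("model selection returns the AIC table and prefers simple truth", {
  withr::local_seed(97)
  sim <- simulate_accessibility(n_sites = 300, seed = 97)
  x <- subset_cells(sim$matrix, c("LSK", "B", "Neu", "Ery", "NK"))
  tree <- ape::unroot(nj_tree(pairwise_differences(x)))
  sel <- suppressWarnings(
    select_model_aic(tree, x, tags = c("BIN", "BIN+I", "BIN+I+R4"),
                     max_iter = 15))
  expect_equal(nrow(sel$table), 3)
  expect_equal(sel$best$AIC, min(sel$table$AIC))
  expect_equal(tidy(sel)$AIC[1], min(sel$table$AIC))
  # lnL can only improve with model complexity on nested fits
  expect_gte(sel$table$lnL[sel$table$tag == "BIN+I"],
             sel$table$lnL[sel$table$tag == "BIN"] - 1e-6)
})

test_that("ML search finds the dominant-signal topology and improves on NJ", {
  # one homoplasy-free split pattern repeated: AB|CDE
  m <- matrix(rep(c(1, 1, 0, 0, 0), each = 40), 40, 5,
              dimnames = list(NULL, c("A", "B", "C", "D", "E")))
  # add a few constant sites so frequencies are estimable
  m <- rbind(m, matrix(1L, 10, 5, dimnames = list(NULL, colnames(m))))
  x <- acc_from_matrix(m)
  res <- suppressWarnings(ml_search(x, tag = "BIN", max_iter = 5))
  expect_true(paste(sort(c("A", "B")), collapse = "|") %in%
                tree_splits(res$tree) |
              paste(sort(c("C", "D", "E")), collapse = "|") %in%
                tree_splits(res$tree))
  # exhaustive mode equals the best of independently fitting every topology
  sim <- simulate_accessibility(n_sites = 120, seed = 101,
                                class_mix = c(UP = 0.5, DOWN = 0.5))
  x5 <- subset_cells(sim$matrix, c("LSK", "B", "Neu", "Ery", "iMK"))
  ex <- suppressWarnings(ml_search(x5, tag = "BIN", exhaustive = TRUE,
                                   max_iter = 5))
  topos <- enumerate_topologies(c("LSK", "B", "Neu", "Ery", "iMK"),
                                as = "phylo")
  lnls <- vapply(topos, function(tr) {
    suppressWarnings(ml_fit(tr, x5, "BIN", max_iter = 5))$lnL
  }, numeric(1))
  expect_equal(ex$lnL, max(lnls), tolerance = 1e-6)
  # NNI acceptance is monotone: result is never worse than the NJ start
  start <- ape::unroot(nj_tree(pairwise_differences(x5)))
  start_fit <- suppressWarnings(ml_fit(start, x5, "BIN", max_iter = 5))
  res5 <- suppressWarnings(ml_search(x5, tag = "BIN", max_iter = 5))
  expect_gte(res5$lnL, start_fit$lnL - 1e-8)
})

test_that("model constructor enforces its invariants", {
  expect_error(bin_model("BIN", pi = c(0.5, 0.6)),
               class = "accesstree_contract_error")
  expect_error(bin_model("BIN+I", p_inv = 1),
               class = "accesstree_contract_error")
  m <- bin_model("BIN+I+R4", p_inv = 0.2, rates = c(1, 2, 3, 4),
                 weights = c(1, 1, 1, 1))
  expect_equal((1 - m$p_inv) * sum(m$weights * m$rates), 1, tolerance = 1e-12)
  expect_equal(sum(m$weights), 1)
  # negative branch lengths are rejected
  tr <- ape::read.tree(text = "(A:-0.1,B:0.1);")
  expect_error(site_log_likelihood(tr, bin_model("BIN"), c(A = 0, B = 1)),
               class = "accesstree_contract_error")
})
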