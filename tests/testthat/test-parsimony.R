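quartet_tree <- ape::read.tree(text = "((A,B),(C,D));")

test_that("Fitch score matches hand-worked and brute-force cases", {
  x1 <- acc_from_matrix(cbind(A = 1, B = 1, C = 0, D = 0))
  expect_equal(fitch_length(quartet_tree, x1), 1)
  x2 <- acc_from_matrix(cbind(A = 1, B = 0, C = 1, D = 0))
  expect_equal(fitch_length(quartet_tree, x2), 2)
  expect_equal(brute_fitch(quartet_tree, c(1, 0, 1, 0)), 2)
  x3 <- acc_from_matrix(cbind(A = 1, B = 1, C = 1, D = 1))
  expect_equal(fitch_length(quartet_tree, x3), 0)
})

test_that("Fitch agrees with enumeration and phangorn on random instances", {
  withr::local_seed(23)
  for (i in 1:40) {
    n <- sample(4:6, 1)
    phy <- ape::rtree(n, tip.label = paste0("t", 1:n))
    nsite <- sample(1:6, 1)
    m <- matrix(rbinom(nsite * n, 1, 0.5), nsite, n,
                dimnames = list(NULL, phy$tip.label))
    x <- acc_from_matrix(m)
    oracle <- sum(apply(m, 1, function(p) brute_fitch(phy, p)))
    expect_equal(fitch_length(phy, x), oracle)
    pd <- phangorn::phyDat(t(m), type = "USER", levels = c(0, 1))
    expect_equal(fitch_length(phy, x),
                 as.integer(phangorn::fitch(ape::unroot(phy), pd)))
    # invariances: leaf order and global complementation
    perm <- sample(colnames(m))
    expect_equal(fitch_length(phy, acc_from_matrix(m[, perm, drop = FALSE])),
                 oracle)
    expect_equal(fitch_length(phy, acc_from_matrix(1L - m)), oracle)
    # bound: per-site score <= min(#zeros, #ones)
    for (r in seq_len(nsite)) {
      expect_lte(brute_fitch(phy, m[r, ]), min(sum(m[r, ] == 0), sum(m[r, ])))
    }
  }
})

test_that("state sets follow the downpass/uppass rules", {
  x <- acc_from_matrix(cbind(A = 1, B = 1, C = 0, D = 0))
  ss <- fitch_state_sets(quartet_tree, x)
  root <- 5L
  nAB <- ape::getMRCA(quartet_tree, c("A", "B"))
  nCD <- ape::getMRCA(quartet_tree, c("C", "D"))
  expect_equal(ss$down[1, nAB], 2L)  # {1}
  expect_equal(ss$down[1, nCD], 1L)  # {0}
  expect_equal(ss$down[1, root], 3L) # {0,1}
  expect_equal(ss$score, 1)
  # constant pattern: every set is the observed state, score 0
  x0 <- acc_from_matrix(cbind(A = 0, B = 0, C = 0, D = 0))
  ss0 <- fitch_state_sets(quartet_tree, x0)
  expect_true(all(ss0$down == 1L))
  expect_equal(ss0$score, 0)
  # score from the state-set machinery equals fitch_length
  sim <- simulate_accessibility(n_sites = 60, seed = 3)
  leaves <- subset_cells(sim$matrix, constraint_tree()$tip.label)
  ss2 <- fitch_state_sets(constraint_tree(), leaves)
  expect_equal(as.integer(sum(ss2$score)),
               fitch_length(constraint_tree(), leaves))
  expect_error(
    fitch_state_sets(ape::read.tree(text = "(A,B,C);"),
                     acc_from_matrix(cbind(A = 0, B = 0, C = 1))),
    class = "accesstree_contract_error")
})

test_that("ACCTRAN accelerates and DELTRAN delays on the textbook case", {
  phy <- ape::read.tree(text = "(((A,B),C),D);")
  x <- acc_from_matrix(cbind(A = 1, B = 0, C = 1, D = 0))
  ab <- ape::getMRCA(phy, c("A", "B"))
  abc <- ape::getMRCA(phy, c("A", "B", "C"))
  acc <- acctran(phy, x)
  del <- deltran(phy, x)
  expect_equal(acc$calls[[paste0("node", ab)]], 1L)
  expect_equal(acc$calls[[paste0("node", abc)]], 1L)
  expect_equal(del$calls[[paste0("node", ab)]], 0L)
  expect_equal(del$calls[[paste0("node", abc)]], 0L)
  expect_equal(acc$score, 2)
  expect_equal(del$score, 2)
})

test_that("both labelings realise the Fitch score; ACCTRAN/DELTRAN are the
          extremes of change depth within the optimal set", {
  withr::local_seed(37)
  for (i in 1:40) {
    n <- sample(4:6, 1)
    phy <- ape::rtree(n, tip.label = paste0("t", 1:n))
    pattern <- rbinom(n, 1, 0.5)
    if (length(unique(pattern)) == 1) pattern[1] <- 1 - pattern[1]
    x <- acc_from_matrix(matrix(pattern, 1, dimnames = list(NULL, phy$tip.label)))
    acc <- acctran(phy, x, outgroup = "t1")
    del <- deltran(phy, x, outgroup = "t1")
    ntip <- n
    acc_states <- unlist(acc$calls[1, -1])
    del_states <- unlist(del$calls[1, -1])
    min_changes <- brute_fitch(phy, pattern)
    count_changes <- function(states) {
      s <- c(pattern, states)
      sum(s[phy$edge[, 1]] != s[phy$edge[, 2]])
    }
    expect_equal(count_changes(acc_states), min_changes)
    expect_equal(count_changes(del_states), min_changes)
    # compare against every optimal labeling with the same root state
    root_state <- acc_states[1]
    expect_equal(del_states[1], root_state)
    opt <- brute_min_labelings(phy, pattern, root_state = root_state)
    if (nrow(opt) > 0 &&
        min(apply(opt, 1, count_changes)) == min_changes) {
      depths <- apply(opt, 1, function(a) {
        labeling_change_depth(phy, pattern, a)
      })
      expect_equal(labeling_change_depth(phy, pattern, acc_states),
                   min(depths))
      expect_equal(labeling_change_depth(phy, pattern, del_states),
                   max(depths))
    }
  }
})

test_that("homoplasy-free sites are reconstructed perfectly by MP", {
  sim <- simulate_accessibility(
    n_sites = 400, class_mix = c(UP = 0.5, DOWN = 0.5), seed = 71)
  ct <- constraint_tree()
  leaves <- subset_cells(sim$matrix, ct$tip.label)
  for (est in list(acctran(ct, leaves, outgroup = "LSK"),
                   deltran(ct, leaves, outgroup = "LSK"))) {
    pred <- progenitor_states(est)
    for (pg in c("CMP", "GMP", "MEP")) {
      expect_equal(pred[[pg]], sim$truth[[pg]], info = pg)
    }
  }
})

test_that("exhaustive MP finds the optimum and surfaces ties", {
  m <- matrix(rep(c(1, 1, 0, 0), each = 10), 10, 4,
              dimnames = list(NULL, c("A", "B", "C", "D")))
  res <- mp_exhaustive(acc_from_matrix(m))
  expect_equal(res$score, 10)
  expect_length(res$trees, 1)
  expect_equal(rf_distance(res$trees[[1]], quartet_tree), 0)
  expect_equal(res$n_topologies, 3)
  # constant matrix: all three topologies tie at score 0
  m0 <- matrix(0L, 5, 4, dimnames = list(NULL, c("A", "B", "C", "D")))
  res0 <- mp_exhaustive(acc_from_matrix(m0))
  expect_equal(res0$score, 0)
  expect_length(res0$trees, 3)
  expect_error(mp_exhaustive(acc_from_matrix(
    matrix(0L, 1, 11, dimnames = list(NULL, paste0("t", 1:11))))),
    class = "accesstree_capability_error")
})

test_that("exhaustive MP equals an independent scorer over all topologies", {
  withr::local_seed(53)
  for (i in 1:3) {
    m <- matrix(rbinom(6 * 12, 1, 0.5), 12, 6,
                dimnames = list(NULL, paste0("t", 1:6)))
    x <- acc_from_matrix(m)
    res <- mp_exhaustive(x)
    topos <- phangorn::allTrees(6, tip.label = paste0("t", 1:6))
    pd <- phangorn::phyDat(t(m), type = "USER", levels = c(0, 1))
    scores <- vapply(topos, function(tr) phangorn::fitch(tr, pd), numeric(1))
    expect_equal(res$score, as.integer(min(scores)))
    expect_equal(length(res$trees), sum(scores == min(scores)))
  }
})

test_that("NNI hill climbing never worsens the NJ start and matches small optima", {
  sim <- simulate_accessibility(n_sites = 300,
                                class_mix = c(UP = 0.5, DOWN = 0.5), seed = 81)
  x <- subset_cells(sim$matrix, c("LSK", "B", "Neu", "Mon", "Ery", "iMK"))
  start <- ape::unroot(nj_tree(pairwise_differences(x)))
  res <- mp_search(x)
  expect_lte(res$score, fitch_length(start, x))
  # on clean single-change data the climb reaches the exhaustive optimum
  ex <- mp_exhaustive(x)
  expect_equal(res$score, ex$score)
})
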