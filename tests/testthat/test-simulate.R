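test_that("identical seeds give identical output, different seeds differ", {
  a <- simulate_accessibility(n_sites = 80, seed = 5)
  b <- simulate_accessibility(n_sites = 80, seed = 5)
  expect_identical(a$matrix, b$matrix)
  expect_identical(a$truth, b$truth)
  expect_identical(a$events, b$events)
  c <- simulate_accessibility(n_sites = 80, seed = 6)
  expect_false(identical(a$matrix, c$matrix))
})

test_that("degenerate mixes and invalid configurations behave as specified", {
  s <- simulate_accessibility(n_sites = 12,
                              class_mix = c(STABLE_open = 1), seed = 1)
  expect_true(all(acc_values(s$matrix) == 1))
  expect_true(all(s$truth$class == "STABLE_open"))
  expect_error(
    simulate_accessibility(n_sites = 5, class_mix = c(OTHER = 1),
                           other_flip_rate = 0, seed = 1),
    class = "accesstree_config_error")
  expect_error(
    simulate_accessibility(n_sites = 5, class_mix = c(UP = 0.7), seed = 1),
    class = "accesstree_config_error")
  expect_error(
    simulate_accessibility(n_sites = 5, class_mix = c(UP = 2, DOWN = -1),
                           seed = 1),
    class = "accesstree_config_error")
})

test_that("single-event sites change on exactly one branch, OTHER on >= 2", {
  sim <- simulate_accessibility(n_sites = 300, seed = 21)
  ev_per_site <- dplyr::count(sim$events, site_id)
  cls <- setNames(sim$truth$class, sim$truth$site_id)
  for (i in seq_len(nrow(ev_per_site))) {
    sid <- ev_per_site$site_id[i]
    if (cls[[sid]] %in% c("UP", "DOWN")) expect_equal(ev_per_site$n[i], 1)
    if (cls[[sid]] == "OTHER") expect_gte(ev_per_site$n[i], 2)
  }
  # UP sites gain (0 -> 1), DOWN sites lose
  ev <- dplyr::left_join(sim$events, sim$truth[, c("site_id", "class")],
                         by = "site_id")
  expect_true(all(ev$to[ev$class == "UP"] == 1))
  expect_true(all(ev$to[ev$class == "DOWN"] == 0))
})

test_that("realized per-path UP fraction matches branch-enumeration expectation", {
  n <- 10000
  sim <- simulate_accessibility(n_sites = n,
                                class_mix = c(UP = 0.5, DOWN = 0.5),
                                seed = 31)
  # expectation by exhaustively enumerating the branch-sampling scheme on the
  # generating tree, independently of the simulator internals
  tree <- differentiation_tree()
  node_names <- c(tree$tip.label, tree$node.label)
  e <- tree$edge
  desc <- as.list(seq_along(node_names))
  for (i in rev(seq_len(nrow(e)))) {   # tree read in cladewise order
    desc[[e[i, 1]]] <- c(desc[[e[i, 1]]], desc[[e[i, 2]]])
  }
  path <- c("LSK", "CMP", "GMP", "Neu")
  pidx <- match(path, node_names)
  up_branches <- sum(vapply(seq_len(nrow(e)), function(i) {
    states <- as.integer(pidx %in% desc[[e[i, 2]]])
    oracle_classify(states) == "UP"
  }, logical(1)))
  expected <- 0.5 * up_branches / nrow(e)
  cls <- classify_sites(sim$matrix)
  observed <- mean(cls$labels$Neu == "UP")
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(observed - expected), 3 * se)
})

test_that("truth ancestral states are consistent with the recorded events", {
  sim <- simulate_accessibility(n_sites = 150, seed = 41)
  # root state + event log reproduces every internal state
  tree <- differentiation_tree()
  node_names <- c(tree$tip.label, tree$node.label)
  internal <- tree$node.label
  for (i in sample.int(150, 30)) {
    sid <- sim$truth$site_id[i]
    ev <- sim$events[sim$events$site_id == sid, ]
    # replay events down the tree
    states <- setNames(rep(sim$truth$LSK[i], length(node_names)), node_names)
    e <- tree$edge
    for (j in seq_len(nrow(e))) {
      p <- node_names[e[j, 1]]
      ch <- node_names[e[j, 2]]
      hit <- which(ev$parent == p & ev$child == ch)
      states[ch] <- if (length(hit) == 1) ev$to[hit] else states[p]
    }
    got <- unlist(sim$truth[i, internal])
    expect_equal(unname(states[internal]), unname(got))
    # observed leaf states agree too
    expect_equal(unname(states[tree$tip.label]),
                 unname(unlist(sim$matrix[i, tree$tip.label])))
  }
})

test_that("OTHER sites exhibit homoplasy at high flip rates", {
  sim <- simulate_accessibility(
    n_sites = 200, class_mix = c(OTHER = 1), other_flip_rate = 0.3, seed = 51)
  tree <- differentiation_tree()
  node_names <- c(tree$tip.label, tree$node.label)
  e <- tree$edge
  desc <- as.list(seq_along(node_names))
  for (i in rev(seq_len(nrow(e)))) {
    desc[[e[i, 1]]] <- c(desc[[e[i, 1]]], desc[[e[i, 2]]])
  }
  # two events with the same derived state on branches where neither child
  # is an ancestor of the other
  found <- FALSE
  for (sid in unique(sim$events$site_id)) {
    ev <- sim$events[sim$events$site_id == sid, ]
    if (nrow(ev) < 2) next
    for (a in seq_len(nrow(ev) - 1)) for (b in (a + 1):nrow(ev)) {
      if (ev$to[a] != ev$to[b]) next
      ca <- match(ev$child[a], node_names)
      cb <- match(ev$child[b], node_names)
      if (!(cb %in% desc[[ca]]) && !(ca %in% desc[[cb]])) found <- TRUE
    }
    if (found) break
  }
  expect_true(found)
})

test_that("generating_topology turns the stem into a leaf and keeps polytomies", {
  gt <- generating_topology(differentiation_tree())
  expect_true("LSK" %in% gt$tip.label)
  expect_length(gt$tip.label, 9)
  # the lymphoid trifurcation is preserved: one fewer split than a binary tree
  expect_length(tree_splits(gt), 5)
  sub <- generating_topology(differentiation_tree(), taxa = c("LSK", "B", "Neu", "Mon"))
  expect_setequal(sub$tip.label, c("LSK", "B", "Neu", "Mon"))
})

test_that("write_vision_like emits a re-readable bundle", {
  sim <- simulate_accessibility(n_sites = 25, seed = 61)
  dir <- withr::local_tempdir()
  paths <- write_vision_like(sim, dir)
  expect_true(all(file.exists(paths)))
  back <- read_accessibility(paths[["matrix"]], cells = sim$observed)
  expect_equal(as.data.frame(back), as.data.frame(sim$matrix))
  truth <- readr::read_tsv(paths[["truth"]], show_col_types = FALSE)
  expect_equal(nrow(truth), 25)
  tr <- ape::read.tree(paths[["tree"]])
  expect_setequal(tr$tip.label, differentiation_tree()$tip.label)
  expect_equal(rf_distance(tr, differentiation_tree()), 0)
})
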