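# Independent brute-force oracles. These deliberately avoid the package's
# pruning/Fitch code paths: everything is computed by explicit enumeration
# over internal-node state assignments.

# all (parent, child) edges of a phylo as a two-column matrix
edges_of <- function(phy) phy$edge

# enumerate all 0/1 assignments to internal nodes; returns matrix
all_internal_assignments <- function(n_internal) {
  as.matrix(expand.grid(rep(list(0:1), n_internal)))
}

# minimum number of state changes over the tree for one site (any rooting)
brute_fitch <- function(phy, pattern) {
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  assign <- all_internal_assignments(phy$Nnode)
  e <- edges_of(phy)
  best <- Inf
  for (r in seq_len(nrow(assign))) {
    states <- c(pattern, assign[r, ])
    changes <- sum(states[e[, 1]] != states[e[, 2]])
    best <- min(best, changes)
  }
  best
}

# all minimum-change internal labelings, optionally with the root state fixed
brute_min_labelings <- function(phy, pattern, root_state = NULL) {
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  assign <- all_internal_assignments(phy$Nnode)
  e <- edges_of(phy)
  cost <- apply(assign, 1, function(a) {
    states <- c(pattern, a)
    sum(states[e[, 1]] != states[e[, 2]])
  })
  if (!is.null(root_state)) {
    ok <- assign[, root - ntip] == root_state
    keep <- ok & cost == min(cost[ok])
  } else {
    keep <- cost == min(cost)
  }
  assign[keep, , drop = FALSE]
}

# depth (edges from root) of the child endpoint of every edge
edge_depths <- function(phy) {
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  depth <- rep(NA_integer_, ntip + phy$Nnode)
  depth[root] <- 0L
  e <- phy$edge
  repeat {
    done <- TRUE
    for (i in seq_len(nrow(e))) {
      if (is.na(depth[e[i, 2]]) && !is.na(depth[e[i, 1]])) {
        depth[e[i, 2]] <- depth[e[i, 1]] + 1L
        done <- FALSE
      }
    }
    if (done) break
  }
  depth[e[, 2]]
}

# sum over change edges of the depth of the change (small = near root)
labeling_change_depth <- function(phy, pattern, internal_states) {
  states <- c(pattern, internal_states)
  e <- phy$edge
  chg <- states[e[, 1]] != states[e[, 2]]
  sum(edge_depths(phy)[chg])
}

# 2-state transition probability, independent closed form
oracle_pmat <- function(pi, t) {
  beta <- 1 / (2 * pi[1] * pi[2])
  sapply(1:2, function(j) pi[j] + ((1:2 == j) - pi[j]) * exp(-beta * t))
}

# site likelihood by explicit enumeration over internal states and rate mix
brute_site_lik <- function(phy, model, pattern) {
  phy <- ape::reorder.phylo(phy, "postorder")
  ntip <- length(phy$tip.label)
  root <- phy$edge[nrow(phy$edge), 1]
  assign <- all_internal_assignments(phy$Nnode)
  e <- phy$edge
  len <- phy$edge.length
  lik_cat <- function(rate) {
    tot <- 0
    for (r in seq_len(nrow(assign))) {
      states <- c(pattern, assign[r, ]) + 1L
      p <- model$pi[states[root]]
      for (i in seq_len(nrow(e))) {
        P <- oracle_pmat(model$pi, rate * len[i])
        p <- p * P[states[e[i, 1]], states[e[i, 2]]]
      }
      tot <- tot + p
    }
    tot
  }
  var_part <- sum(vapply(seq_along(model$rates), function(k) {
    model$weights[k] * lik_cat(model$rates[k])
  }, numeric(1)))
  const <- if (all(pattern == 0)) model$pi[1] else if (all(pattern == 1)) model$pi[2] else 0
  (1 - model$p_inv) * var_part + model$p_inv * const
}

# marginal posterior P(node = state) by enumeration and conditioning
brute_marginal_open <- function(phy, model, pattern, node) {
  phy <- ape::reorder.phylo(phy, "postorder")
  ntip <- length(phy$tip.label)
  root <- phy$edge[nrow(phy$edge), 1]
  assign <- all_internal_assignments(phy$Nnode)
  e <- phy$edge
  len <- phy$edge.length
  joint_open <- 0
  total <- 0
  for (k in seq_along(model$rates)) {
    for (r in seq_len(nrow(assign))) {
      states <- c(pattern, assign[r, ]) + 1L
      p <- model$pi[states[root]]
      for (i in seq_len(nrow(e))) {
        P <- oracle_pmat(model$pi, model$rates[k] * len[i])
        p <- p * P[states[e[i, 1]], states[e[i, 2]]]
      }
      p <- p * model$weights[k] * (1 - model$p_inv)
      total <- total + p
      if (states[node] == 2L) joint_open <- joint_open + p
    }
  }
  const <- if (all(pattern == 0)) 1L else if (all(pattern == 1)) 2L else 0L
  if (const > 0 && model$p_inv > 0) {
    p <- model$p_inv * model$pi[const]
    total <- total + p
    if (const == 2L) joint_open <- joint_open + p
  }
  joint_open / total
}

# random rooted binary tree with branch lengths, labelled tips t1..tn
random_rooted_tree <- function(n, min_len = 0.05, max_len = 1) {
  phy <- ape::rtree(n, tip.label = paste0("t", seq_len(n)))
  phy$edge.length <- stats::runif(nrow(phy$edge), min_len, max_len)
  phy
}

# accessibility tibble from a plain site x cell 0/1 matrix
acc_from_matrix <- function(m, cells = colnames(m)) {
  colnames(m) <- cells
  tibble::as_tibble(as.data.frame(m)) |>
    dplyr::mutate(chrom = "chr1",
                  start = (dplyr::row_number() - 1L) * 10L,
                  end = (dplyr::row_number() - 1L) * 10L + 5L,
                  site_id = sprintf("s%04d", dplyr::row_number()),
                  .before = 1)
}

# definition-by-enumeration classifier used as the classification oracle
oracle_classify <- function(states) {
  if (all(states == states[1])) return("STABLE")
  n <- length(states)
  is_up <- FALSE
  is_down <- FALSE
  for (k in seq_len(n - 1)) {
    if (identical(states, c(rep(0L, k), rep(1L, n - k)))) is_up <- TRUE
    if (identical(states, c(rep(1L, k), rep(0L, n - k)))) is_down <- TRUE
  }
  if (is_up) return("UP")
  if (is_down) return("DOWN")
  "OTHER"
}
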