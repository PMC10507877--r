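# Above-partials ("outside" likelihoods) for one rate category. A[v, i] is
# the likelihood of everything outside the subtree of v, given state i at v,
# including the stationary frequency at the root.
above_partials <- function(phy, partial, pi, rate) {
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  e <- phy$edge
  len <- phy$edge.length
  root <- e[nrow(e), 1]
  npat <- nrow(partial[[1]])
  above <- vector("list", nnode)
  above[[root]] <- matrix(pi, nrow = npat, ncol = 2, byrow = TRUE)
  children <- split(seq_len(nrow(e)), e[, 1])
  # S[[edge]] = partial of child propagated through its branch (npat x 2,
  # indexed by the parent-side state)
  S <- vector("list", nrow(e))
  for (i in seq_len(nrow(e))) {
    S[[i]] <- partial[[e[i, 2]]] %*% t(pmat_2state(pi, rate * len[i]))
  }
  for (i in rev(seq_len(nrow(e)))) {  # preorder
    u <- e[i, 1]
    v <- e[i, 2]
    sib <- setdiff(children[[as.character(u)]], i)
    acc <- above[[u]]
    for (j in sib) acc <- acc * S[[j]]
    above[[v]] <- acc %*% pmat_2state(pi, rate * len[i])
  }
  above
}

#' Marginal ancestral open probabilities under the ML model
#'
#' For every internal node and site, the marginal posterior probability that
#' the site is open (state 1) given all leaf states, under a fitted
#' two-state model on a fixed rooted topology. Below-likelihoods
#' (Felsenstein pruning) are combined with above-likelihoods and mixed over
#' rate categories, including the invariant class, with their per-site
#' posterior weights.
#'
#' @param fit A `bin_ml_fit` from [ml_fit()] on a rooted binary tree, or a
#'   list with elements `tree` (rooted, with branch lengths) and `model`.
#' @param x Accessibility tibble containing all tip cells (typically the
#'   same one the model was fitted to).
#' @return An `acc_ml_anc` object: `marginals` (tibble `site_id` x
#'   `node<k>` columns of P(open)), `tree`, `model`.
#' @export
ml_marginals <- function(fit, x) {
  tree <- fit$tree
  model <- fit$model
  if (is.null(tree$edge.length)) stop_contract("tree branch lengths must be fitted")
  check_rooted_binary(tree)
  m <- acc_pattern_matrix(x, tree$tip.label)
  cp <- compress_patterns(m)
  phy <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  root <- phy$edge[nrow(phy$edge), 1]
  npat <- nrow(cp$pat)

  joint_open <- matrix(0, npat, nnode)   # (1-p_inv)-weighted variable part
  joint_closed <- matrix(0, npat, nnode)
  for (k in seq_along(model$rates)) {
    part <- pruning_partials(phy, cp$pat, model$pi, model$rates[k])
    ab <- above_partials(phy, part, model$pi, model$rates[k])
    wk <- model$weights[k] * (1 - model$p_inv)
    for (v in (ntip + 1L):nnode) {
      joint_closed[, v] <- joint_closed[, v] + wk * part[[v]][, 1] * ab[[v]][, 1]
      joint_open[, v] <- joint_open[, v] + wk * part[[v]][, 2] * ab[[v]][, 2]
    }
  }
  if (model$p_inv > 0) {
    const0 <- rowSums(cp$pat) == 0
    const1 <- rowSums(cp$pat) == ncol(cp$pat)
    # an invariant-class site is in the root state at every node
    joint_closed[const0, ] <- joint_closed[const0, ] + model$p_inv * model$pi[1]
    joint_open[const1, ] <- joint_open[const1, ] + model$p_inv * model$pi[2]
  }
  site_l <- joint_open[, root] + joint_closed[, root]
  internal <- (ntip + 1L):nnode
  marg <- joint_open[, internal, drop = FALSE] / site_l
  colnames(marg) <- paste0("node", internal)
  out <- dplyr::bind_cols(tibble(site_id = x$site_id),
                          as_tibble(marg[cp$index, , drop = FALSE]))
  structure(list(marginals = out, tree = phy, model = model),
            class = "acc_ml_anc")
}

#' @export
print.acc_ml_anc <- function(x, ...) {
  cat("ML marginal ancestral states (", x$model$tag, "): ",
      nrow(x$marginals), " sites x ", ncol(x$marginals) - 1L,
      " internal nodes\n", sep = "")
  invisible(x)
}

#' Call discrete states from marginal probabilities
#'
#' Calls each internal node/site open (1) or closed (0) by the larger
#' marginal; a site is ambiguous (NA) when the open probability is within
#' `tie_tolerance` of 0.5, or, in threshold mode, when the winning marginal
#' is below `threshold`.
#'
#' @param marg An `acc_ml_anc` object from [ml_marginals()].
#' @param tie_tolerance Half-width of the ambiguity band around 0.5.
#' @param threshold Optional minimum winning marginal (e.g. 0.95) for an
#'   unambiguous call.
#' @return Tibble `site_id` x `node<k>` columns with values 0, 1 or NA
#'   (ambiguous); per-node ambiguity counts are in the `"n_ambiguous"`
#'   attribute.
#' @export
call_states <- function(marg, tie_tolerance = 1e-9, threshold = NULL) {
  stopifnot(inherits(marg, "acc_ml_anc"))
  out <- marg$marginals
  nodes <- setdiff(names(out), "site_id")
  for (nd in nodes) {
    p <- out[[nd]]
    call <- as.integer(p > 0.5)
    amb <- if (is.null(threshold)) {
      abs(p - 0.5) <= tie_tolerance
    } else {
      pmax(p, 1 - p) < threshold
    }
    call[amb] <- NA_integer_
    out[[nd]] <- call
  }
  attr(out, "n_ambiguous") <-
    purrr::map_int(out[nodes], ~ sum(is.na(.x))) |> setNames(nodes)
  out
}

#' Extract per-progenitor state columns from ancestral estimates
#'
#' Maps constraint-tree internal nodes to their progenitor identities (CMP,
#' GMP, MEP) and returns the per-site states/probabilities for those nodes.
#'
#' @param est An `acc_mp_anc` (from [acctran()]/[deltran()]), an
#'   `acc_ml_anc` (from [ml_marginals()]), or a called-state tibble from
#'   [call_states()].
#' @param map Node-progenitor map; default [node_progenitor_map()] of the
#'   estimate's tree.
#' @param tree Tree used to build the default map when `est` is a plain
#'   tibble.
#' @return Tibble with `site_id` and one column per progenitor.
#' @export
progenitor_states <- function(est, map = NULL, tree = NULL) {
  tab <- if (inherits(est, "acc_mp_anc")) {
    tree <- tree %||% est$tree
    est$calls
  } else if (inherits(est, "acc_ml_anc")) {
    tree <- tree %||% est$tree
    est$marginals
  } else {
    if (is.null(map) && is.null(tree)) {
      stop_config("a map or tree is required for plain tibbles")
    }
    est
  }
  map <- map %||% node_progenitor_map(tree)
  out <- tibble(site_id = tab$site_id)
  for (i in seq_len(nrow(map))) {
    col <- paste0("node", map$node[i])
    if (!(col %in% names(tab))) {
      stop_config(paste0("estimate lacks column ", col))
    }
    out[[map$progenitor[i]]] <- tab[[col]]
  }
  out
}
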