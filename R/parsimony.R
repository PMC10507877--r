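# State sets are bit codes: 1 = {0}, 2 = {1}, 3 = {0,1}.

# phangorn::nni returns a compressed multiPhylo (tip labels in an attribute);
# extract with explicit [[ dispatch so each element is a complete phylo
nni_neighbors <- function(tree) {
  nb <- phangorn::nni(tree)
  lapply(seq_along(nb), function(i) nb[[i]])
}

# collapse identical site patterns; returns unique pattern matrix, weights,
# and the site -> pattern index
compress_patterns <- function(m) {
  key <- apply(m, 1, paste, collapse = "")
  u <- !duplicated(key)
  idx <- match(key, key[u])
  list(pat = m[u, , drop = FALSE], w = as.numeric(tabulate(idx, sum(u))),
       index = idx)
}

# vectorised Fitch downpass over a pattern matrix (npat x ntips, columns in
# tip order). Works on rooted or unrooted trees; multifurcations are folded
# pairwise, which is exact for two states.
fitch_down <- function(phy, pat) {
  phy <- ape::reorder.phylo(phy, "postorder")
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  npat <- nrow(pat)
  code <- matrix(0L, npat, nnode)
  code[, seq_len(ntip)] <- pat + 1L
  score <- numeric(npat)
  e <- phy$edge
  for (i in seq_len(nrow(e))) {
    p <- e[i, 1]
    cc <- code[, e[i, 2]]
    pc <- code[, p]
    unset <- pc == 0L
    pc[unset] <- cc[unset]
    if (any(!unset)) {
      ib <- bitwAnd(pc[!unset], cc[!unset])
      un <- bitwOr(pc[!unset], cc[!unset])
      hit <- ib == 0L
      pc[!unset] <- ifelse(hit, un, ib)
      score[!unset] <- score[!unset] + hit
    }
    code[, p] <- pc
  }
  root <- e[nrow(e), 1]
  list(code = code, score = score, root = root, postorder = phy)
}

acc_pattern_matrix <- function(x, taxa) {
  if (length(taxa) == 0) stop_contract("tree has no tip labels")
  missing <- setdiff(taxa, acc_cells(x))
  if (length(missing) > 0) {
    stop_config(paste0("tree tips absent from matrix: ",
                       paste(missing, collapse = ", ")))
  }
  acc_values(x, taxa)
}

#' Fitch parsimony score of a tree
#'
#' Total minimum number of undirected 0/1 state changes the tree requires,
#' summed over sites (open-to-closed and closed-to-open cost the same).
#'
#' @param tree `ape::phylo` whose tips all appear as cell columns.
#' @param x Accessibility tibble.
#' @return Integer parsimony score.
#' @export
#' @examples
#' sim <- simulate_accessibility(n_sites = 100, seed = 1)
#' fitch_length(constraint_tree(), sim$matrix)
fitch_length <- function(tree, x) {
  m <- acc_pattern_matrix(x, tree$tip.label)
  cp <- compress_patterns(m)
  fd <- fitch_down(tree, cp$pat)
  as.integer(round(sum(fd$score * cp$w)))
}

check_rooted_binary <- function(tree) {
  if (!ape::is.rooted(tree)) stop_contract("a rooted tree is required")
  kids <- tabulate(tree$edge[, 1], length(tree$tip.label) + tree$Nnode)
  if (any(kids[kids > 0] != 2)) {
    stop_capability("polytomies are not supported; resolve the tree first")
  }
  invisible(tree)
}

#' Fitch downpass and MPR state sets per node
#'
#' Runs the Fitch downpass (intersection where possible, union with a score
#' increment otherwise) and the uppass refinement yielding the set of states
#' each node takes in at least one most-parsimonious reconstruction (MPR).
#' Sets are bit-coded: 1 = \{0\}, 2 = \{1\}, 3 = \{0,1\}.
#'
#' @param tree Rooted binary `ape::phylo`.
#' @param x Accessibility tibble containing all tip cells.
#' @return List with `down` and `mpr` (integer site-by-node matrices of set
#'   codes), `score` (per-site Fitch score) and `site_id`.
#' @export
fitch_state_sets <- function(tree, x) {
  check_rooted_binary(tree)
  m <- acc_pattern_matrix(x, tree$tip.label)
  cp <- compress_patterns(m)
  fd <- fitch_down(tree, cp$pat)
  mpr <- mpr_sets(fd, root_code = fd$code[, fd$root])
  nodes <- seq_len(ncol(fd$code))
  list(
    down = fd$code[cp$index, , drop = FALSE],
    mpr = mpr[cp$index, , drop = FALSE],
    score = fd$score[cp$index],
    site_id = x$site_id
  )
}

# Swofford & Maddison (1987) uppass: MPR set per node given downpass sets.
# root_code lets the caller fix the root state (outgroup polarisation).
mpr_sets <- function(fd, root_code) {
  phy <- fd$postorder
  ntip <- length(phy$tip.label)
  e <- phy$edge
  children <- split(e[, 2], e[, 1])
  mpr <- fd$code
  mpr[, fd$root] <- root_code
  for (i in rev(seq_len(nrow(e)))) {   # preorder
    v <- e[i, 2]
    if (v <= ntip) next
    u <- e[i, 1]
    D_v <- fd$code[, v]
    M_u <- mpr[, u]
    kids <- children[[as.character(v)]]
    D_l <- fd$code[, kids[1]]
    D_r <- fd$code[, kids[2]]
    res <- D_v
    subset_ok <- bitwAnd(M_u, D_v) == M_u
    inter <- bitwAnd(D_l, D_r) != 0L
    case2 <- !subset_ok & inter
    res[case2] <- bitwOr(D_v[case2],
                         bitwAnd(M_u[case2], bitwOr(D_l[case2], D_r[case2])))
    case3 <- !subset_ok & !inter
    res[case3] <- bitwOr(D_v[case3], M_u[case3])
    mpr[, v] <- res
  }
  mpr
}

resolve_root_code <- function(fd, tree, outgroup) {
  root_code <- fd$code[, fd$root]
  amb <- root_code == 3L
  if (any(amb)) {
    if (is.null(outgroup)) {
      root_kids <- fd$postorder$edge[fd$postorder$edge[, 1] == fd$root, 2]
      og <- root_kids[root_kids <= length(tree$tip.label)]
      if (length(og) == 0) {
        stop_config("root state is ambiguous and no outgroup tip adjoins the root")
      }
      og <- og[1]
    } else {
      og <- match(outgroup, fd$postorder$tip.label)
      if (is.na(og)) stop_config(paste0("unknown outgroup '", outgroup, "'"))
    }
    root_code[amb] <- fd$code[amb, og]
  }
  root_code
}

mp_ancestral_engine <- function(tree, x, method, outgroup) {
  check_rooted_binary(tree)
  m <- acc_pattern_matrix(x, tree$tip.label)
  cp <- compress_patterns(m)
  fd <- fitch_down(tree, cp$pat)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root_code <- resolve_root_code(fd, tree, outgroup)

  final <- matrix(0L, nrow(cp$pat), nnode)
  final[, seq_len(ntip)] <- cp$pat + 1L
  final[, fd$root] <- root_code
  e <- fd$postorder$edge
  if (method == "acctran") {
    # keep the parent state whenever the downpass set allows it; changes are
    # thereby pulled toward the root on union nodes
    for (i in rev(seq_len(nrow(e)))) {
      v <- e[i, 2]
      if (v <= ntip) next
      f_u <- final[, e[i, 1]]
      D_v <- fd$code[, v]
      keep <- bitwAnd(D_v, f_u) != 0L
      final[, v] <- ifelse(keep, f_u, D_v)
    }
  } else {
    mpr <- mpr_sets(fd, root_code)
    for (i in rev(seq_len(nrow(e)))) {
      v <- e[i, 2]
      if (v <= ntip) next
      f_u <- final[, e[i, 1]]
      M_v <- mpr[, v]
      keep <- bitwAnd(M_v, f_u) != 0L
      final[, v] <- ifelse(keep, f_u, M_v)
    }
  }
  internal <- (ntip + 1L):nnode
  calls <- final[cp$index, internal, drop = FALSE] - 1L
  colnames(calls) <- paste0("node", internal)
  out <- tibble(site_id = x$site_id)
  out <- dplyr::bind_cols(out, as_tibble(calls))
  structure(list(calls = out, tree = tree, method = method,
                 score = fd$score[cp$index]),
            class = "acc_mp_anc")
}

#' Most-parsimonious ancestral states (ACCTRAN / DELTRAN)
#'
#' Assigns one minimum-change 0/1 state to every internal node of a rooted
#' binary tree for each site. `acctran()` accelerates transformations
#' (changes are placed as close to the root as the optimal set allows);
#' `deltran()` delays them toward the tips, preferring parallel late changes
#' over early change plus reversal. Both labelings realise exactly the Fitch
#' score of the site. When the Fitch root set is ambiguous it is resolved
#' toward the outgroup-side state (the outgroup observation polarises the
#' change), by default the tip adjoining the root.
#'
#' @param tree Rooted binary `ape::phylo` (e.g. [constraint_tree()]).
#' @param x Accessibility tibble with all tip cells.
#' @param outgroup Optional outgroup tip name used to resolve ambiguous
#'   root sets.
#' @return An `acc_mp_anc` object: `calls` (tibble site_id x `node<k>`
#'   columns of 0/1 states), `score` (per-site Fitch score), `tree`,
#'   `method`.
#' @export
acctran <- function(tree, x, outgroup = NULL) {
  mp_ancestral_engine(tree, x, "acctran", outgroup)
}

#' @rdname acctran
#' @export
deltran <- function(tree, x, outgroup = NULL) {
  mp_ancestral_engine(tree, x, "deltran", outgroup)
}

#' @export
print.acc_mp_anc <- function(x, ...) {
  cat("MP ancestral states (", x$method, "): ",
      nrow(x$calls), " sites x ", ncol(x$calls) - 1L, " internal nodes\n",
      sep = "")
  invisible(x)
}

#' Exhaustive maximum-parsimony search
#'
#' Scores every unrooted binary topology on the cell panel with the Fitch
#' criterion and returns the minimum score with all co-optimal topologies
#' (ties are surfaced, never broken silently).
#'
#' @param x Accessibility tibble.
#' @param cells Taxa to include (default all cell columns).
#' @param cap Maximum taxon count for exhaustive search; above it a
#'   capability error points to [mp_search()].
#' @return List with `score`, `trees` (`multiPhylo` of optima),
#'   `n_topologies` examined.
#' @export
mp_exhaustive <- function(x, cells = acc_cells(x), cap = 10) {
  nwk <- enumerate_topologies(cells, cap = cap, as = "newick")
  topos <- ape::read.tree(text = paste(nwk, collapse = "\n"))
  if (inherits(topos, "phylo")) topos <- c(topos)
  m <- acc_pattern_matrix(x, cells)
  cp <- compress_patterns(m)
  scores <- vapply(topos, function(tr) {
    pat <- cp$pat[, match(tr$tip.label, cells), drop = FALSE]
    sum(fitch_down(tr, pat)$score * cp$w)
  }, numeric(1))
  best <- min(scores)
  keep <- which(scores == best)
  trees <- topos[keep]
  class(trees) <- "multiPhylo"
  list(score = as.integer(round(best)), trees = trees,
       n_topologies = length(topos))
}

#' Heuristic maximum-parsimony search by NNI hill climbing
#'
#' Starts from the neighbor-joining tree on pairwise character differences
#' and accepts nearest-neighbor-interchange moves while the Fitch score
#' decreases.
#'
#' @inheritParams mp_exhaustive
#' @param start Optional starting `phylo` (default the NJ tree).
#' @return List with `score` and `tree`.
#' @export
mp_search <- function(x, cells = acc_cells(x), start = NULL) {
  tree <- start %||% ape::unroot(nj_tree(pairwise_differences(x, cells)))
  m <- acc_pattern_matrix(x, cells)
  cp <- compress_patterns(m)
  score_of <- function(tr) {
    pat <- cp$pat[, match(tr$tip.label, cells), drop = FALSE]
    sum(fitch_down(tr, pat)$score * cp$w)
  }
  best <- score_of(tree)
  repeat {
    nb <- nni_neighbors(tree)
    sc <- vapply(nb, score_of, numeric(1))
    if (min(sc) >= best) break
    best <- min(sc)
    tree <- nb[[which.min(sc)]]
  }
  list(score = as.integer(round(best)), tree = tree)
}
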