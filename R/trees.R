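#' Pairwise character-difference matrix
#'
#' Counts, for every pair of cell types, the number of sites at which their
#' binary accessibility states differ (raw Hamming count, no normalisation
#' or correction).
#'
#' @param x Accessibility tibble.
#' @param cells Cells to include (default all).
#' @return Symmetric numeric matrix with cell names as dimnames.
#' @export
#' @examples
#' sim <- simulate_accessibility(n_sites = 100, seed = 1)
#' pairwise_differences(sim$matrix)[1:3, 1:3]
pairwise_differences <- function(x, cells = acc_cells(x)) {
  if (nrow(x) == 0) stop_input("accessibility table has no sites")
  if (length(cells) < 2) stop_input("need at least two cells")
  m <- acc_values(x, cells)
  d <- as.matrix(stats::dist(t(m), method = "manhattan"))
  dimnames(d) <- list(cells, cells)
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou–Nei neighbor joining (via `ape::nj`) on a symmetric distance
#' matrix; negative estimated branch lengths are clamped to zero, and the
#' number of clamped branches is recorded in the `"clamped"` attribute.
#'
#' @param d Symmetric distance matrix with taxon dimnames (e.g. from
#'   [pairwise_differences()]).
#' @return Unrooted `ape::phylo` with a `"clamped"` attribute.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop_input("neighbor joining needs at least 3 taxa")
  if (is.null(rownames(d))) stop_input("distance matrix must have taxon names")
  phy <- ape::nj(as.dist(d))
  n_clamped <- sum(phy$edge.length < 0)
  if (n_clamped > 0) phy$edge.length[phy$edge.length < 0] <- 0
  attr(phy, "clamped") <- n_clamped
  phy
}

#' Root a tree on an outgroup
#'
#' Places the root at the midpoint of the outgroup's pendant branch, leaving
#' the ingroup topology unchanged. The returned root has degree 2.
#'
#' @param tree `ape::phylo`, rooted or unrooted.
#' @param outgroup A tip label.
#' @return Rooted `ape::phylo`.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  if (!(outgroup %in% tree$tip.label)) {
    stop_config(paste0("outgroup '", outgroup, "' is not a tip"))
  }
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  if (!is.null(rooted$edge.length)) {
    ntip <- length(rooted$tip.label)
    root <- ntip + 1L
    re <- which(rooted$edge[, 1] == root)
    total <- sum(rooted$edge.length[re])
    rooted$edge.length[re] <- total / 2
  }
  rooted
}

#' Canonical non-trivial splits of a tree
#'
#' Each internal branch induces a bipartition of the tips; splits are keyed
#' by the sorted tip set on the side not containing the alphabetically first
#' tip, so keys are comparable across trees with the same leaf set.
#'
#' @param tree `ape::phylo`.
#' @return Character vector of split keys.
#' @export
tree_splits <- function(tree) {
  tree <- ape::unroot(tree)
  tips <- tree$tip.label
  if (length(tips) < 4) return(character(0))
  ref <- sort(tips)[1]
  pp <- ape::prop.part(tree)
  keys <- character(0)
  for (cl in pp) {
    side <- tips[cl]
    other <- setdiff(tips, side)
    if (length(side) < 2 || length(other) < 2) next
    grp <- if (ref %in% side) other else side
    keys <- c(keys, paste(sort(grp), collapse = "|"))
  }
  unique(keys)
}

#' Robinson–Foulds distance between two trees
#'
#' Number of non-trivial splits present in exactly one of the two trees
#' (0 for identical unrooted topologies).
#'
#' @param t1,t2 `ape::phylo` objects over the same leaf set.
#' @return Non-negative integer.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop_input("trees must share the same leaf set")
  }
  s1 <- tree_splits(t1)
  s2 <- tree_splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

# --- exhaustive topology enumeration ----------------------------------------

# all attachments of `lab` within subtree `st`, including the edge above it
insert_sub <- function(st, lab) {
  res <- list(list(st, lab))
  if (is.list(st)) {
    for (i in seq_along(st)) {
      for (v in insert_sub(st[[i]], lab)) {
        t2 <- st
        t2[[i]] <- v
        res[[length(res) + 1L]] <- t2
      }
    }
  }
  res
}

deparse_clade <- function(n) {
  if (is.character(n)) return(n)
  paste0("(", paste(vapply(n, deparse_clade, character(1)), collapse = ","), ")")
}

#' Enumerate all unrooted binary topologies
#'
#' Generates every unrooted binary tree on the given labels exactly once by
#' stepwise leaf addition (each tree on n+1 leaves arises uniquely from
#' inserting the new leaf into one of the 2n-3 branches of a tree on n
#' leaves); the total is the double factorial (2n-5)!!.
#'
#' @param labels Character vector of 3 or more taxon names.
#' @param cap Refuse enumeration above this many taxa (the space grows as
#'   (2n-5)!!); use heuristic search such as [mp_search()] instead.
#' @param as `"newick"` (character vector) or `"phylo"` (`multiPhylo`).
#' @return Newick strings or a `multiPhylo` of all topologies.
#' @export
#' @examples
#' length(enumerate_topologies(LETTERS[1:5])) # 15
enumerate_topologies <- function(labels, cap = 10,
                                 as = c("newick", "phylo")) {
  as <- match.arg(as)
  n <- length(labels)
  if (n < 3) stop_input("at least 3 taxa are required")
  if (anyDuplicated(labels)) stop_input("labels must be unique")
  if (n > cap) {
    stop_capability(paste0(
      "exhaustive enumeration refused for ", n, " taxa (cap ", cap,
      "): (2n-5)!! topologies; use heuristic search (mp_search/ml_search)"))
  }
  trees <- list(list(labels[1], labels[2], labels[3]))
  for (lab in labels[seq_len(n)[-(1:3)]]) {
    trees <- unlist(lapply(trees, function(tr) {
      out <- list()
      for (i in seq_along(tr)) {
        for (v in insert_sub(tr[[i]], lab)) {
          t2 <- tr
          t2[[i]] <- v
          out[[length(out) + 1L]] <- t2
        }
      }
      out
    }), recursive = FALSE)
  }
  nwk <- vapply(trees, function(tr) paste0(deparse_clade(tr), ";"), character(1))
  if (as == "newick") return(nwk)
  ape::read.tree(text = paste(nwk, collapse = "\n"))
}
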