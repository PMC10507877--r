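#' Simulate a binary accessibility matrix along a differentiation tree
#'
#' Generates site-by-cell 0/1 matrices down a known differentiation
#' hierarchy with full ground truth, emulating the structure of a
#' cCRE-style accessibility table. Each site is drawn from one of five
#' generating classes:
#'
#' * `STABLE_open` / `STABLE_closed` — constant 1 / 0 at every node;
#' * `UP` — root closed, exactly one 0->1 gain on a branch chosen
#'   uniformly at random, inherited by the whole clade below, no reversals;
#' * `DOWN` — the mirror image (root open, one 1->0 loss);
#' * `OTHER` — random root state and independent per-branch flips with
#'   probability `other_flip_rate`, rejection-sampled until the realised
#'   pattern is non-monotone (OTHER) on at least one classification path,
#'   so these sites carry genuine homoplasy/multiple hits.
#'
#' Observed columns are the tree tips plus any internal nodes named in
#' `observed_internal` (by default the stem and the myeloid progenitors;
#' lymphoid progenitors stay unobserved, as in the real panel, but their
#' states are recorded in the truth tables).
#'
#' @param n_sites Number of sites to simulate.
#' @param class_mix Named proportions for
#'   `STABLE_open`/`STABLE_closed`/`UP`/`DOWN`/`OTHER`; must sum to 1.
#' @param other_flip_rate Per-branch flip probability for OTHER sites.
#' @param tree Rooted `ape::phylo` with labelled internal nodes.
#' @param observed_internal Internal-node labels reported as observed
#'   cell columns.
#' @param paths Classification paths used for the OTHER rejection rule
#'   (default: the hematopoietic paths restricted to observed cells).
#' @param seed Integer seed; identical seeds give identical output.
#' @return An object of class `acc_sim`: list with `matrix` (accessibility
#'   tibble over observed cells), `truth` (tibble of per-site states at every
#'   internal node plus the generating `class` and a `root_adjacent` flag for
#'   single-event sites), `events` (per-site branch change log with `parent`,
#'   `child`, `from`, `to`), `tree`, and `seed`.
#' @export
#' @examples
#' sim <- simulate_accessibility(n_sites = 50, seed = 1)
#' sim$matrix
#' dplyr::count(sim$truth, class)
simulate_accessibility <- function(n_sites = 2000,
                                   class_mix = c(STABLE_open = 0.07,
                                                 STABLE_closed = 0.43,
                                                 UP = 0.10, DOWN = 0.10,
                                                 OTHER = 0.30),
                                   other_flip_rate = 0.15,
                                   tree = differentiation_tree(),
                                   observed_internal = c("LSK", "CMP",
                                                         "GMP", "MEP"),
                                   paths = NULL,
                                   seed = NULL) {
  classes <- c("STABLE_open", "STABLE_closed", "UP", "DOWN", "OTHER")
  if (is.null(names(class_mix)) || !all(names(class_mix) %in% classes)) {
    stop_config("class_mix must be named with STABLE_open/STABLE_closed/UP/DOWN/OTHER")
  }
  mix <- setNames(numeric(5), classes)
  mix[names(class_mix)] <- class_mix
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-9) {
    stop_config("class_mix proportions must be non-negative and sum to 1")
  }
  if (n_sites < 0) stop_config("n_sites must be >= 0")
  if (other_flip_rate < 0 || other_flip_rate > 1) {
    stop_config("other_flip_rate must be in [0, 1]")
  }

  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  node_names <- c(tree$tip.label, tree$node.label)
  if (is.null(tree$node.label) || any(node_names == "")) {
    stop_config("tree internal nodes must be labelled")
  }
  root <- ntip + 1L
  tree_cw <- ape::reorder.phylo(tree, "cladewise")
  edge <- tree_cw$edge
  nedge <- nrow(edge)

  observed_internal <- intersect(observed_internal, node_names[-seq_len(ntip)])
  observed <- c(node_names[root],
                setdiff(observed_internal, node_names[root]),
                tree$tip.label)
  observed <- intersect(unique(observed), node_names)
  obs_idx <- match(observed, node_names)

  if (is.null(paths)) {
    paths <- purrr::map(differentiation_paths(), ~ intersect(.x, observed))
    paths <- purrr::keep(paths, ~ length(.x) >= 2)
  }
  if (mix[["OTHER"]] > 0) {
    if (other_flip_rate == 0) {
      stop_config("OTHER sites are unsatisfiable with other_flip_rate = 0")
    }
    if (!any(purrr::map_int(paths, length) >= 3)) {
      stop_config("OTHER sites need at least one path with >= 3 observed cells")
    }
  }

  # clade membership below each edge (child subtree), for single-event sites
  desc <- purrr::map(seq_len(nnode), ~.x)
  for (i in rev(seq_len(nedge))) {
    desc[[edge[i, 1]]] <- c(desc[[edge[i, 1]]], desc[[edge[i, 2]]])
  }

  gen <- function() {
    cls <- if (n_sites > 0) {
      sample(classes, n_sites, replace = TRUE, prob = mix)
    } else character(0)
    states <- matrix(0L, nrow = n_sites, ncol = nnode,
                     dimnames = list(NULL, node_names))
    event_edge <- rep(NA_integer_, n_sites)
    other_events <- vector("list", n_sites)

    states[cls == "STABLE_open", ] <- 1L
    for (direction in c("UP", "DOWN")) {
      idx <- which(cls == direction)
      if (length(idx) == 0) next
      ev <- sample.int(nedge, length(idx), replace = TRUE)
      event_edge[idx] <- ev
      base <- if (direction == "UP") 0L else 1L
      states[idx, ] <- base
      for (j in seq_along(idx)) {
        states[idx[j], desc[[edge[ev[j], 2]]]] <- 1L - base
      }
    }

    oth <- which(cls == "OTHER")
    if (length(oth) > 0) {
      path_idx <- purrr::map(paths, ~ match(.x, node_names))
      need <- length(oth)
      got <- 0L
      guard <- 0L
      while (got < need) {
        guard <- guard + 1L
        if (guard > 10000L) {
          stop_config("OTHER rejection sampling failed to converge; raise other_flip_rate")
        }
        k <- max(64L, need - got)
        st <- matrix(0L, nrow = k, ncol = nnode)
        st[, root] <- sample(0:1, k, replace = TRUE)
        flips <- matrix(stats::rbinom(k * nedge, 1L, other_flip_rate),
                        nrow = k, ncol = nedge)
        for (i in seq_len(nedge)) {
          st[, edge[i, 2]] <- bitwXor(st[, edge[i, 1]], flips[, i])
        }
        is_other <- rep(FALSE, k)
        for (pi in path_idx) {
          if (length(pi) < 3) next
          is_other <- is_other |
            classify_path_matrix(st[, pi, drop = FALSE]) == "OTHER"
        }
        keep <- which(is_other)
        if (length(keep) == 0) next
        keep <- keep[seq_len(min(length(keep), need - got))]
        for (j in keep) {
          got <- got + 1L
          site <- oth[got]
          states[site, ] <- st[j, ]
          other_events[[site]] <- which(flips[j, ] == 1L)
        }
      }
    }
    list(cls = cls, states = states, event_edge = event_edge,
         other_events = other_events)
  }
  g <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())

  site_id <- sprintf("site_%05d", seq_len(n_sites))
  x <- new_acc_table(
    chrom = rep("chrS", n_sites),
    start = (seq_len(n_sites) - 1L) * 1000L,
    end = (seq_len(n_sites) - 1L) * 1000L + 500L,
    values = as.data.frame(g$states[, obs_idx, drop = FALSE]) |>
      setNames(observed),
    site_id = site_id
  )

  internal_names <- node_names[-seq_len(ntip)]
  truth <- tibble(site_id = site_id, class = g$cls)
  for (nm in internal_names) {
    truth[[nm]] <- g$states[, match(nm, node_names)]
  }
  root_edges <- which(edge[, 1] == root)
  truth$event_parent <- node_names[edge[g$event_edge, 1]]
  truth$event_child <- node_names[edge[g$event_edge, 2]]
  truth$root_adjacent <- !is.na(g$event_edge) & g$event_edge %in% root_edges

  ev_list <- vector("list", n_sites)
  for (i in seq_len(n_sites)) {
    ee <- if (g$cls[i] %in% c("UP", "DOWN")) g$event_edge[i] else g$other_events[[i]]
    if (length(ee) == 0 || all(is.na(ee))) next
    ev_list[[i]] <- tibble(
      site_id = site_id[i],
      parent = node_names[edge[ee, 1]],
      child = node_names[edge[ee, 2]],
      from = g$states[i, edge[ee, 1]],
      to = g$states[i, edge[ee, 2]]
    )
  }
  events <- dplyr::bind_rows(ev_list)
  if (nrow(events) == 0) {
    events <- tibble(site_id = character(), parent = character(),
                     child = character(), from = integer(), to = integer())
  }

  structure(
    list(matrix = x, truth = truth, events = events, tree = tree,
         observed = observed, paths = paths, seed = seed,
         class_mix = mix, other_flip_rate = other_flip_rate),
    class = "acc_sim"
  )
}

#' @export
print.acc_sim <- function(x, ...) {
  cat("Simulated accessibility matrix:", nrow(x$matrix), "sites x",
      length(x$observed), "observed cells\n")
  print(dplyr::count(x$truth, .data$class, name = "n_sites"))
  invisible(x)
}

#' Observable topology implied by a generating tree
#'
#' Converts a rooted differentiation tree whose root is the stem cell into
#' the unrooted topology over observable taxa: the stem becomes a leaf
#' attached at the root, internal polytomies are preserved, and the tree is
#' optionally restricted to a taxon subset. This is the reference topology
#' for scoring inferred trees (a fully binary estimate necessarily adds one
#' resolving split per polytomy, so the Robinson-Foulds floor is the number
#' of unresolved nodes, not zero).
#'
#' @param tree Rooted `ape::phylo` with a labelled root (e.g.
#'   [differentiation_tree()]), or an `acc_sim` object.
#' @param taxa Optional taxon subset to keep.
#' @return Unrooted `ape::phylo`.
#' @export
generating_topology <- function(tree, taxa = NULL) {
  if (inherits(tree, "acc_sim")) tree <- tree$tree
  stem <- tree$node.label[1]
  nwk <- ape::write.tree(tree)
  out <- ape::read.tree(text = sub("\\)[^);]*;$", paste0(",", stem, ");"), nwk))
  if (!is.null(taxa)) out <- ape::keep.tip(out, intersect(taxa, out$tip.label))
  out
}

#' Write a simulated data set as VISION-like text files
#'
#' Emits `matrix.tsv` (via [write_accessibility()]), `truth.tsv` (per-site
#' generating class and internal-node states), `events.tsv` (branch change
#' log) and `tree.nwk` (the generating tree, Newick).
#'
#' @param sim An `acc_sim` object.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_vision_like <- function(sim, dir) {
  stopifnot(inherits(sim, "acc_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(matrix = file.path(dir, "matrix.tsv"),
             truth = file.path(dir, "truth.tsv"),
             events = file.path(dir, "events.tsv"),
             tree = file.path(dir, "tree.nwk"))
  write_accessibility(sim$matrix, paths[["matrix"]])
  readr::write_tsv(sim$truth, paths[["truth"]], progress = FALSE)
  readr::write_tsv(sim$events, paths[["events"]], progress = FALSE)
  ape::write.tree(sim$tree, file = paths[["tree"]])
  invisible(paths)
}
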