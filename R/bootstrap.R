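infer_tree_method <- function(x, method, cells, tag, exhaustive_cap = 8) {
  switch(method,
    nj = ape::unroot(nj_tree(pairwise_differences(x, cells))),
    mp = if (length(cells) <= exhaustive_cap) {
      mp_exhaustive(x, cells)$trees[[1]]
    } else {
      mp_search(x, cells)$tree
    },
    ml = ml_search(x, tag = tag, cells = cells)$tree,
    stop_config(paste0("unknown method '", method, "'"))
  )
}

#' Bootstrap branch supports
#'
#' Resamples sites with replacement `B` times, re-infers the tree on each
#' replicate with the chosen method, and reports for every internal branch
#' of the point-estimate tree the percentage of replicates containing that
#' split. Deterministic given `seed`; replicate trees are not stored.
#'
#' @param x Accessibility tibble.
#' @param method `"nj"`, `"mp"` or `"ml"`.
#' @param B Number of bootstrap replicates (>= 1).
#' @param seed Integer seed for the resampling stream.
#' @param cells Taxa to include.
#' @param tag Model family for `method = "ml"`.
#' @return An `acc_boot` object: `tree` (point estimate, internal node
#'   labels carrying supports), `supports` (tibble split x support), `B`,
#'   `method`, `seed`.
#' @export
bootstrap_support <- function(x, method = c("nj", "mp", "ml"), B = 100,
                              seed = 1, cells = acc_cells(x),
                              tag = "BIN+I") {
  method <- match.arg(method)
  if (B < 1) stop_contract("B must be >= 1")
  point <- infer_tree_method(x, method, cells, tag)
  splits <- tree_splits(point)
  counts <- setNames(numeric(length(splits)), splits)
  withr::with_seed(seed, {
    for (b in seq_len(B)) {
      xb <- x[sample.int(nrow(x), replace = TRUE), ]
      xb$site_id <- sprintf("bs_%06d", seq_len(nrow(xb)))
      tb <- infer_tree_method(xb, method, cells, tag)
      hit <- intersect(splits, tree_splits(tb))
      counts[hit] <- counts[hit] + 1
    }
  })
  supports <- tibble(split = splits, support = unname(100 * counts / B))
  labelled <- label_splits(point, setNames(supports$support, supports$split))
  structure(list(tree = labelled, supports = supports, B = B,
                 method = method, seed = seed),
            class = "acc_boot")
}

# attach per-split supports as internal node labels of `tree`
label_splits <- function(tree, support_by_split) {
  u <- ape::unroot(tree)
  tips <- u$tip.label
  ref <- sort(tips)[1]
  ntip <- length(tips)
  pp <- ape::prop.part(u)
  labs <- character(u$Nnode)
  for (i in seq_along(pp)) {
    side <- tips[pp[[i]]]
    other <- setdiff(tips, side)
    if (length(side) < 2 || length(other) < 2) next
    grp <- if (ref %in% side) other else side
    key <- paste(sort(grp), collapse = "|")
    if (key %in% names(support_by_split)) {
      labs[i] <- format(round(support_by_split[[key]], 1))
    }
  }
  u$node.label <- labs
  u
}

#' @export
print.acc_boot <- function(x, ...) {
  cat("Bootstrap supports (", x$method, ", B = ", x$B, ", seed = ",
      x$seed, ")\n", sep = "")
  print(x$supports)
  invisible(x)
}
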