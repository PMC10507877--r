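#' Sensitivity and specificity of predicted chromatin states
#'
#' Compares predicted open/closed calls for one internal node with the
#' observed profile of the matched progenitor cell. The positive class is
#' open (1). Ambiguous predictions (NA) and sites flagged by
#' `exclude_stable` (typically STABLE on all lineages) are removed before
#' counting; a site failing both exclusions is removed once and reported in
#' `n_removed_overlap`. Undefined ratios (empty denominator) are NA.
#'
#' @param predicted Integer vector of 0/1/NA calls, one per site.
#' @param observed Integer 0/1 vector of the progenitor's observed states.
#' @param node Label for the compared node (e.g. `"CMP"`).
#' @param exclude_stable Optional logical mask of sites to drop.
#' @return One-row tibble with `node`, `TP`, `FP`, `TN`, `FN`,
#'   `sensitivity`, `specificity`, `n_evaluated`, `n_removed_ambiguous`,
#'   `n_removed_stable`, `n_removed_overlap`.
#' @export
#' @examples
#' sensitivity_specificity(c(1, 1, 0, 0, 0), c(1, 0, 0, 0, 1))
sensitivity_specificity <- function(predicted, observed, node = "node",
                                    exclude_stable = NULL) {
  if (length(predicted) != length(observed)) {
    stop_contract("predicted and observed must have equal length")
  }
  if (!is_binary(observed)) stop_contract("observed must be 0/1")
  ok_pred <- predicted %in% c(0, 1) | is.na(predicted)
  if (!all(ok_pred)) stop_contract("predicted must be 0/1/NA")
  amb <- is.na(predicted)
  stab <- exclude_stable %||% rep(FALSE, length(predicted))
  if (length(stab) != length(predicted)) {
    stop_contract("exclude_stable mask length mismatch")
  }
  keep <- !amb & !stab
  p <- predicted[keep]
  o <- observed[keep]
  tp <- sum(p == 1 & o == 1)
  fp <- sum(p == 1 & o == 0)
  tn <- sum(p == 0 & o == 0)
  fn <- sum(p == 0 & o == 1)
  tibble(
    node = node, TP = tp, FP = fp, TN = tn, FN = fn,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    n_evaluated = sum(keep),
    n_removed_ambiguous = sum(amb),
    n_removed_stable = sum(stab & !amb),
    n_removed_overlap = sum(stab & amb)
  )
}

#' Confusion summaries for all mapped progenitors
#'
#' Convenience wrapper applying [sensitivity_specificity()] to each
#' progenitor column shared between a prediction table and the observed
#' matrix.
#'
#' @param predicted Tibble with `site_id` and one 0/1/NA column per
#'   progenitor (e.g. from [progenitor_states()]).
#' @param x Accessibility tibble holding the observed progenitor columns.
#' @param exclude_stable Optional logical mask over the sites of `x`.
#' @return Tibble with one row per progenitor.
#' @export
evaluate_progenitors <- function(predicted, x, exclude_stable = NULL) {
  nodes <- intersect(setdiff(names(predicted), "site_id"), acc_cells(x))
  if (length(nodes) == 0) stop_config("no shared progenitor columns")
  ord <- match(x$site_id, predicted$site_id)
  if (anyNA(ord)) stop_contract("predicted table must cover all sites of x")
  purrr::map(nodes, function(nd) {
    sensitivity_specificity(predicted[[nd]][ord], x[[nd]], node = nd,
                            exclude_stable = exclude_stable)
  }) |> purrr::list_rbind()
}

#' Quartet delta statistic
#'
#' For four taxa, the three pairwise distance sums d(i,j)+d(k,l) are sorted
#' as m1 >= m2 >= m3 and delta = (m1-m2)/(m1-m3); delta is 0 for additive
#' (perfectly treelike) distances and 1 for maximal conflict. When all
#' three sums are equal delta is defined as 0.
#'
#' @param d Symmetric distance matrix with taxon dimnames.
#' @param quartet Four distinct taxon names.
#' @return One-row tibble `t1..t4`, `m1`, `m2`, `m3`, `delta`.
#' @export
quartet_delta <- function(d, quartet) {
  if (length(quartet) != 4 || anyDuplicated(quartet)) {
    stop_contract("quartet must name four distinct taxa")
  }
  if (!all(quartet %in% rownames(d))) {
    stop_contract("quartet taxa missing from the distance matrix")
  }
  q <- quartet
  s <- c(d[q[1], q[2]] + d[q[3], q[4]],
         d[q[1], q[3]] + d[q[2], q[4]],
         d[q[1], q[4]] + d[q[2], q[3]])
  m <- sort(s, decreasing = TRUE)
  delta <- if (m[1] - m[3] <= 1e-12) 0 else (m[1] - m[2]) / (m[1] - m[3])
  tibble(t1 = q[1], t2 = q[2], t3 = q[3], t4 = q[4],
         m1 = m[1], m2 = m[2], m3 = m[3], delta = delta)
}

#' Delta scores for a taxon group
#'
#' Computes the quartet delta for every 4-subset of the group (C(n,4)
#' quartets). The group mean is the conventional summary, but the full
#' per-quartet distribution is returned so either can be reported.
#'
#' @param d Symmetric distance matrix with taxon dimnames.
#' @param taxa Group of >= 4 taxa (default all).
#' @return Tibble of quartets with a `"mean_delta"` attribute.
#' @export
#' @examples
#' sim <- simulate_accessibility(n_sites = 200, seed = 1)
#' d <- pairwise_differences(sim$matrix)
#' ds <- delta_scores(d, c("LSK", "B", "TCD4", "TCD8", "NK"))
#' attr(ds, "mean_delta")
delta_scores <- function(d, taxa = rownames(d)) {
  if (length(taxa) < 4) stop_input("delta scores need at least 4 taxa")
  combos <- utils::combn(taxa, 4, simplify = FALSE)
  out <- purrr::map(combos, ~ quartet_delta(d, .x)) |> purrr::list_rbind()
  attr(out, "mean_delta") <- mean(out$delta)
  out
}

#' Sites with a lineage-specific branch change
#'
#' Selects sites whose state changes from `parent` to `child` in the stated
#' direction while remaining unchanged on every cell-pair step listed in
#' `unchanged_in` (the paper-style "change on this branch, nowhere else"
#' filter).
#'
#' @param x Accessibility tibble including the relevant progenitor columns.
#' @param parent,child Cell names of the branch endpoints.
#' @param direction `"open_to_closed"` (1 -> 0) or `"closed_to_open"`.
#' @param unchanged_in List of `c(parent, child)` cell pairs that must show
#'   no change.
#' @return Character vector of `site_id`s.
#' @export
branch_change_sites <- function(x, parent, child,
                                direction = c("open_to_closed",
                                              "closed_to_open"),
                                unchanged_in = list()) {
  direction <- match.arg(direction)
  cells <- acc_cells(x)
  need <- c(parent, child, unlist(unchanged_in))
  missing <- setdiff(need, cells)
  if (length(missing) > 0) {
    stop_config(paste0("unknown cell(s): ", paste(missing, collapse = ", ")))
  }
  from <- if (direction == "open_to_closed") 1L else 0L
  sel <- x[[parent]] == from & x[[child]] == 1L - from
  for (step in unchanged_in) {
    sel <- sel & x[[step[1]]] == x[[step[2]]]
  }
  x$site_id[sel]
}
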