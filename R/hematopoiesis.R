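#' The murine hematopoietic cell panel
#'
#' The twelve cell types used throughout the analysis: the stem compartment
#' (LSK, Lin-Sca1+Kit+), the three observed myeloid progenitors (CMP, GMP,
#' MEP) and eight terminally differentiated cell types. Lymphoid progenitors
#' are part of the differentiation hierarchy but have no observed
#' accessibility profile.
#'
#' @return A tibble with columns `name` and `role`
#'   (`stem`/`progenitor`/`terminal`).
#' @export
#' @examples
#' hematopoietic_cells()
hematopoietic_cells <- function() {
  tibble(
    name = c("LSK", "CMP", "GMP", "MEP",
             "Ery", "iMK", "Mon", "Neu", "B", "TCD4", "TCD8", "NK"),
    role = c("stem", rep("progenitor", 3), rep("terminal", 8))
  )
}

#' The known hematopoietic differentiation hierarchy
#'
#' Rooted tree of murine hematopoiesis: LSK gives rise to the myeloid
#' branch (CMP, splitting into GMP with Neu/Mon and MEP with Ery/iMK) and
#' the lymphoid branch (an unobserved lymphoid progenitor, labelled CLP,
#' producing B, NK and the T cells). Internal nodes carry the progenitor
#' names; LSK labels the root.
#'
#' @return A rooted `ape::phylo` object with labelled internal nodes.
#' @export
differentiation_tree <- function() {
  ape::read.tree(text =
    "(((Neu,Mon)GMP,(Ery,iMK)MEP)CMP,(B,(TCD4,TCD8)TNK,NK)CLP)LSK;")
}

#' Differentiation paths from stem to terminal cells
#'
#' The eight stem-to-terminal time courses along which sites are
#' classified. Myeloid paths run through the observed progenitors
#' (e.g. LSK, CMP, GMP, Neu); lymphoid paths are a single step
#' (LSK to B/TCD4/TCD8/NK) because lymphoid progenitor profiles are
#' unavailable.
#'
#' @return Named list of character vectors, each starting at `"LSK"`.
#' @export
differentiation_paths <- function() {
  list(
    Neu  = c("LSK", "CMP", "GMP", "Neu"),
    Mon  = c("LSK", "CMP", "GMP", "Mon"),
    Ery  = c("LSK", "CMP", "MEP", "Ery"),
    iMK  = c("LSK", "CMP", "MEP", "iMK"),
    B    = c("LSK", "B"),
    TCD4 = c("LSK", "TCD4"),
    TCD8 = c("LSK", "TCD8"),
    NK   = c("LSK", "NK")
  )
}

#' Fixed topology for ancestral-state reconstruction
#'
#' The constraint topology used to reconstruct progenitor states: the known
#' myeloid hierarchy plus the consistently inferred lymphoid topology
#' (B,((TCD4,TCD8),NK)), rooted on the LSK outgroup. Leaves are LSK and
#' the eight terminal cells; progenitors appear only as internal nodes.
#'
#' @return A rooted binary `ape::phylo` with 9 tips and a degree-2 root.
#' @export
constraint_tree <- function() {
  ape::read.tree(text =
    "(LSK,((B,((TCD4,TCD8),NK)),((Neu,Mon),(Ery,iMK))));")
}

#' Map constraint-tree internal nodes to progenitor cells
#'
#' Identifies, on a rooted tree over the terminal cells, the internal nodes
#' corresponding to the observed progenitors: the myeloid MRCA is CMP, the
#' MRCA of Neu and Mon is GMP, and the MRCA of Ery and iMK is MEP.
#'
#' @param tree A rooted `ape::phylo` containing the myeloid terminal cells.
#' @return A tibble with columns `progenitor` and `node` (ape node number).
#' @export
node_progenitor_map <- function(tree = constraint_tree()) {
  need <- c("Neu", "Mon", "Ery", "iMK")
  missing <- setdiff(need, tree$tip.label)
  if (length(missing) > 0) {
    stop_config(paste0("tree lacks tips: ", paste(missing, collapse = ", ")))
  }
  tibble(
    progenitor = c("CMP", "GMP", "MEP"),
    node = c(
      ape::getMRCA(tree, c("Neu", "Mon", "Ery", "iMK")),
      ape::getMRCA(tree, c("Neu", "Mon")),
      ape::getMRCA(tree, c("Ery", "iMK"))
    )
  )
}
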