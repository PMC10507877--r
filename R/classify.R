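#' Classify one open/closed time course
#'
#' Classifies a binary accessibility sequence along a single differentiation
#' path: `STABLE` if the state never changes, `UP` if it is monotone
#' non-decreasing with at least one change (closed then open, a single
#' 0->1 transition), `DOWN` for the mirror image, and `OTHER` for any
#' non-monotone course. A two-state path can never be OTHER.
#'
#' @param states Integer/numeric vector of 0/1 states ordered from stem to
#'   terminal cell, length >= 2.
#' @return One of `"STABLE"`, `"UP"`, `"DOWN"`, `"OTHER"`.
#' @export
#' @examples
#' classify_path(c(0, 0, 1, 1)) # UP
#' classify_path(c(1, 0, 1))    # OTHER
classify_path <- function(states) {
  if (length(states) < 2) stop_contract("a path needs at least two states")
  if (!is_binary(states)) stop_contract("states must be 0/1")
  d <- diff(states)
  up <- any(d > 0)
  down <- any(d < 0)
  if (!up && !down) return("STABLE")
  if (up && !down) return("UP")
  if (down && !up) return("DOWN")
  "OTHER"
}

path_class_levels <- c("STABLE", "UP", "DOWN", "OTHER")

# vectorised classification of all sites for one path (matrix of 0/1)
classify_path_matrix <- function(m) {
  if (ncol(m) < 2) stop_contract("a path needs at least two states")
  d <- m[, -1, drop = FALSE] - m[, -ncol(m), drop = FALSE]
  up <- rowSums(d > 0) > 0
  down <- rowSums(d < 0) > 0
  out <- rep("STABLE", nrow(m))
  out[up & !down] <- "UP"
  out[down & !up] <- "DOWN"
  out[up & down] <- "OTHER"
  out
}

#' Classify every site along every differentiation path
#'
#' Applies [classify_path()] to each site for each path and summarises
#' across paths: a site is `OTHER` overall if it is OTHER on any path,
#' `STABLE` if stable on all paths, and otherwise a mixed label recording
#' the set of directions seen (`UP`, `DOWN`, or `UP+DOWN`).
#'
#' @param x Accessibility tibble.
#' @param paths Named list of cell-name vectors (default the eight
#'   hematopoietic lineages restricted to cells present in `x`).
#' @return An object of class `acc_class`: a list with `labels` (tibble
#'   site_id x path label, wide), `tally` (per-path class counts) and
#'   `summary` (per-site cross-path label).
#' @export
classify_sites <- function(x, paths = NULL) {
  cells <- acc_cells(x)
  if (is.null(paths)) {
    paths <- purrr::map(differentiation_paths(), ~ intersect(.x, cells))
    paths <- purrr::keep(paths, ~ length(.x) >= 2)
  }
  if (length(paths) == 0) stop_config("no usable differentiation paths")
  for (p in paths) {
    missing <- setdiff(p, cells)
    if (length(missing) > 0) {
      stop_config(paste0("path cell(s) not in matrix: ",
                         paste(missing, collapse = ", ")))
    }
  }
  if (is.null(names(paths)) || any(names(paths) == "")) {
    names(paths) <- purrr::map_chr(paths, ~ .x[length(.x)])
  }
  mats <- purrr::map(paths, ~ acc_values(x, .x))
  labels <- tibble(site_id = x$site_id)
  for (nm in names(paths)) labels[[nm]] <- classify_path_matrix(mats[[nm]])

  tally <- labels |>
    tidyr::pivot_longer(-"site_id", names_to = "path", values_to = "class") |>
    dplyr::count(.data$path, .data$class, name = "n_sites") |>
    tidyr::complete(path = names(paths), class = path_class_levels,
                    fill = list(n_sites = 0L)) |>
    mutate(class = factor(.data$class, levels = path_class_levels),
           path = factor(.data$path, levels = names(paths))) |>
    arrange(.data$path, .data$class)

  lab_m <- as.matrix(labels[, names(paths), drop = FALSE])
  any_other <- rowSums(lab_m == "OTHER") > 0
  all_stable <- rowSums(lab_m != "STABLE") == 0
  has_up <- rowSums(lab_m == "UP") > 0
  has_down <- rowSums(lab_m == "DOWN") > 0
  summary_label <- dplyr::case_when(
    any_other ~ "OTHER",
    all_stable ~ "STABLE",
    has_up & has_down ~ "UP+DOWN",
    has_up ~ "UP",
    TRUE ~ "DOWN"
  )
  structure(
    list(labels = labels,
         paths = paths,
         tally = tally,
         summary = tibble(site_id = x$site_id, class = summary_label)),
    class = "acc_class"
  )
}

#' @export
print.acc_class <- function(x, ...) {
  cat("Site classification over", length(x$paths), "paths,",
      nrow(x$labels), "sites\n")
  print(dplyr::count(x$summary, .data$class, name = "n_sites"))
  invisible(x)
}

#' Site masks derived from a classification
#'
#' `other_site_mask()` flags sites classified OTHER on at least one path;
#' `stable_everywhere_mask()` flags sites STABLE on all paths. Both return
#' logical vectors aligned with the classified table, directly usable with
#' [filter_sites()]. The two masks are mutually exclusive.
#'
#' @param result An `acc_class` object from [classify_sites()].
#' @return Logical vector, one entry per site.
#' @export
other_site_mask <- function(result) {
  stopifnot(inherits(result, "acc_class"))
  result$summary$class == "OTHER"
}

#' @rdname other_site_mask
#' @export
stable_everywhere_mask <- function(result) {
  stopifnot(inherits(result, "acc_class"))
  result$summary$class == "STABLE"
}
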