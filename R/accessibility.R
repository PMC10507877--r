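#' Accessibility tables
#'
#' An accessibility table is an ordinary tibble with one row per cCRE-style
#' site. The columns `chrom`, `start`, `end` carry the genomic interval
#' (opaque metadata, BED-style 0-based half-open for simulated output),
#' `site_id` is a unique site key, and every remaining column is one cell
#' type holding 0 (closed) or 1 (open). All functions in the package accept
#' such a tibble as their first argument, so analyses chain with the pipe.
#'
#' @name accessibility
NULL

.acc_meta_cols <- c("chrom", "start", "end", "site_id")

#' Cell columns of an accessibility table
#'
#' @param x An accessibility tibble.
#' @return Character vector of cell-type column names, in table order.
#' @export
acc_cells <- function(x) setdiff(names(x), .acc_meta_cols)

#' Extract the binary site-by-cell matrix
#'
#' @param x An accessibility tibble.
#' @param cells Optional subset/order of cell columns.
#' @return Integer matrix (sites x cells) with `site_id` rownames.
#' @export
acc_values <- function(x, cells = acc_cells(x)) {
  missing <- setdiff(cells, names(x))
  if (length(missing) > 0) {
    stop_config(paste0("unknown cell column(s): ", paste(missing, collapse = ", ")))
  }
  m <- as.matrix(x[, cells, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- x$site_id
  m
}

validate_acc <- function(x, cells = acc_cells(x)) {
  if (length(cells) == 0) stop_config("accessibility table has no cell columns")
  for (cc in cells) {
    v <- x[[cc]]
    if (!is_binary(v)) {
      bad <- which(!(v %in% c(0, 1)) | is.na(v))[1]
      stop_parse(paste0("non-binary value in column '", cc, "', row ", bad))
    }
  }
  if (anyDuplicated(x$site_id)) stop_contract("site_id values must be unique")
  invisible(x)
}

new_acc_table <- function(chrom, start, end, values, site_id = NULL) {
  site_id <- site_id %||% paste0(chrom, ":", start, "-", end)
  out <- tibble(chrom = chrom, start = as.integer(start),
                end = as.integer(end), site_id = site_id)
  bind_cols_checked <- as_tibble(values)
  dplyr::bind_cols(out, bind_cols_checked)
}

#' Read a cCRE-style binary accessibility table
#'
#' Reads a tab-separated table with a header row, keeping the requested
#' coordinate columns and an explicit list of cell columns; any other
#' columns (e.g. extra epigenetic-state annotation) are ignored. Cell
#' columns must contain only 0/1 tokens. A `site_id` is synthesised as
#' `chrom:start-end` if the file has no `site_id` column.
#'
#' @param path Path to a TSV file.
#' @param cells Character vector of cell-type column names to keep.
#' @param coords Names of the chromosome/start/end columns in the file.
#' @return An accessibility tibble (see [accessibility]).
#' @export
read_accessibility <- function(path, cells,
                               coords = c("chrom", "start", "end")) {
  if (length(coords) != 3) stop_config("coords must name three columns")
  if (length(cells) == 0) stop_config("at least one cell column is required")
  raw <- tryCatch(
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(.default = readr::col_character())),
    error = function(e) stop_input(paste0("cannot read '", path, "': ", conditionMessage(e)))
  )
  if (nrow(raw) == 0 && ncol(raw) == 0) stop_input(paste0("empty file: ", path))
  missing <- setdiff(c(coords, cells), names(raw))
  if (length(missing) > 0) {
    stop_config(paste0("missing column(s) in '", path, "': ",
                       paste(missing, collapse = ", ")))
  }
  vals <- lapply(cells, function(cc) {
    v <- raw[[cc]]
    ok <- v %in% c("0", "1")
    if (!all(ok)) {
      bad <- which(!ok)[1]
      stop_parse(paste0("non-binary token '", v[bad], "' in column '", cc,
                        "', row ", bad))
    }
    as.integer(v)
  })
  names(vals) <- cells
  new_acc_table(
    chrom = raw[[coords[1]]],
    start = suppressWarnings(as.integer(raw[[coords[2]]])),
    end = suppressWarnings(as.integer(raw[[coords[3]]])),
    values = vals,
    site_id = if ("site_id" %in% names(raw)) raw$site_id else NULL
  )
}

#' Write an accessibility table as TSV
#'
#' Emits a tab-separated file with columns chrom/start/end/site_id followed
#' by one 0/1 column per cell; [read_accessibility()] reads it back
#' bit-identically.
#'
#' @param x Accessibility tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_accessibility <- function(x, path) {
  validate_acc(x)
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Restrict and reorder the cell panel
#'
#' @param x Accessibility tibble.
#' @param cells Cell names to keep, in the desired order.
#' @return The table with cell columns restricted to `cells`; sites unchanged.
#' @export
#' @examples
#' sim <- simulate_accessibility(n_sites = 10, seed = 1)
#' subset_cells(sim$matrix, c("LSK", "B", "Neu"))
subset_cells <- function(x, cells) {
  if (length(cells) == 0) stop_config("cell subset must be non-empty")
  missing <- setdiff(cells, acc_cells(x))
  if (length(missing) > 0) {
    stop_config(paste0("unknown cell(s): ", paste(missing, collapse = ", ")))
  }
  x[, c(intersect(.acc_meta_cols, names(x)), cells)]
}

#' Filter sites by a logical mask
#'
#' @param x Accessibility tibble.
#' @param keep Logical vector, one entry per site (row).
#' @return The rows of `x` with `keep == TRUE`, in order.
#' @export
filter_sites <- function(x, keep) {
  if (!is.logical(keep) || length(keep) != nrow(x) || anyNA(keep)) {
    stop_contract("keep must be a complete logical mask with one entry per site")
  }
  x[keep, ]
}
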