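#' @importFrom rlang abort warn .data %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange bind_rows group_by summarise
#'   across left_join count n pull rename relocate
#' @importFrom purrr map map_dbl map_int map_chr map_lgl imap list_rbind
#' @importFrom stats optimize optim setNames qgamma pgamma
NULL

# centralised error helpers so every module signals the same condition classes
stop_input <- function(msg) abort(msg, class = "accesstree_input_error")
stop_config <- function(msg) abort(msg, class = "accesstree_config_error")
stop_parse <- function(msg) abort(msg, class = "accesstree_parse_error")
stop_contract <- function(msg) abort(msg, class = "accesstree_contract_error")
stop_capability <- function(msg) abort(msg, class = "accesstree_capability_error")

is_binary <- function(x) {
  is.numeric(x) && !anyNA(x) && all(x == 0L | x == 1L)
}

# double factorial (2n-5)!!; number of unrooted binary topologies on n tips
n_unrooted_topologies <- function(n) {
  if (n < 3) stop_input("at least 3 taxa are required")
  if (n == 3) return(1)
  prod(seq(3, 2 * n - 5, by = 2))
}
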