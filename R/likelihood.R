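# Two-state (open/closed) substitution model with stationary frequencies
# pi = (pi0, pi1), exchangeability-symmetric rate matrix
#   Q = beta * [[-pi1, pi1], [pi0, -pi0]],  beta = 1 / (2 pi0 pi1),
# so one unit of branch length is one expected change at rate 1. Closed form
#   P_ij(t) = pi_j + (delta_ij - pi_j) exp(-beta t).
# Among-site rate variation is a mixture: an invariant class (rate 0, weight
# p_inv) plus K categories with rates r_k and weights w_k, rescaled so the
# expected rate over all classes is 1: (1 - p_inv) * sum(w_k r_k) = 1.

model_tags <- c("BIN", "BIN+I", "BIN+I+G", "BIN+I+R4", "BIN+I+R8", "BIN+I+R12")

#' Construct a two-state substitution model
#'
#' @param tag Model family: `"BIN"` (single rate), `"BIN+I"` (adds an
#'   invariant-site class), `"BIN+I+G"` (adds 4-category discrete gamma),
#'   or `"BIN+I+R4"`/`"BIN+I+R8"`/`"BIN+I+R12"` (free rates with n
#'   categories).
#' @param pi Stationary frequencies `c(pi0, pi1)`, summing to 1.
#' @param p_inv Proportion of invariant sites in `[0, 1)`.
#' @param alpha Gamma shape (only for `BIN+I+G`).
#' @param rates,weights Free-rate categories (only for `BIN+I+Rn`); rescaled
#'   internally so the model's expected rate is 1.
#' @return A `bin_model` object.
#' @export
bin_model <- function(tag = "BIN", pi = c(0.5, 0.5), p_inv = 0,
                      alpha = NULL, rates = NULL, weights = NULL) {
  tag <- match.arg(tag, model_tags)
  if (length(pi) != 2 || any(pi <= 0) || abs(sum(pi) - 1) > 1e-9) {
    stop_contract("pi must be two positive frequencies summing to 1")
  }
  if (p_inv < 0 || p_inv >= 1) stop_contract("p_inv must be in [0, 1)")
  if (tag == "BIN" && p_inv != 0) stop_contract("BIN has no invariant class")
  if (tag == "BIN+I+G") {
    alpha <- alpha %||% 1
    if (alpha <= 0) stop_contract("gamma shape must be positive")
    rates <- discrete_gamma_rates(alpha, 4)
    weights <- rep(0.25, 4)
  } else if (grepl("R", tag)) {
    k <- as.integer(sub("BIN\\+I\\+R", "", tag))
    rates <- rates %||% rep(1, k)
    weights <- weights %||% rep(1 / k, k)
    if (length(rates) != k || length(weights) != k) {
      stop_contract(paste0(tag, " needs ", k, " rates and weights"))
    }
    if (any(rates < 0) || any(weights <= 0)) {
      stop_contract("rates must be >= 0 and weights > 0")
    }
  } else {
    rates <- 1
    weights <- 1
  }
  weights <- weights / sum(weights)
  mean_r <- sum(weights * rates)
  if (mean_r <= 0) stop_contract("expected rate must be positive")
  rates <- rates / mean_r / (1 - p_inv)  # (1-p_inv) * sum(w r) = 1
  structure(list(tag = tag, pi = pi, p_inv = p_inv, alpha = alpha,
                 rates = rates, weights = weights),
            class = "bin_model")
}

#' @export
print.bin_model <- function(x, ...) {
  cat("Two-state model ", x$tag, ": pi = (",
      round(x$pi[1], 4), ", ", round(x$pi[2], 4), "), p_inv = ",
      round(x$p_inv, 4), sep = "")
  if (!is.null(x$alpha)) cat(", alpha =", round(x$alpha, 4))
  if (length(x$rates) > 1) {
    cat("\n  rates: ", paste(round(x$rates, 3), collapse = " "),
        "\n  weights:", paste(round(x$weights, 3), collapse = " "))
  }
  cat("\n")
  invisible(x)
}

# mean-rate discretisation of the gamma(alpha, alpha) distribution (equal
# category probabilities; Yang 1994)
discrete_gamma_rates <- function(alpha, k = 4) {
  q <- qgamma(seq(0, 1, length.out = k + 1), shape = alpha, rate = alpha)
  upper <- pgamma(q[-1], shape = alpha + 1, rate = alpha)
  lower <- pgamma(q[-(k + 1)], shape = alpha + 1, rate = alpha)
  k * (upper - lower)
}

model_n_free <- function(tag) {
  # frequencies 1; +I adds 1; +G adds 1; +Rn adds 2n-2
  switch(tag,
         "BIN" = 1L, "BIN+I" = 2L, "BIN+I+G" = 3L,
         "BIN+I+R4" = 2L + 6L, "BIN+I+R8" = 2L + 14L, "BIN+I+R12" = 2L + 22L)
}

pmat_2state <- function(pi, t) {
  e <- exp(-t / (2 * pi[1] * pi[2]))
  matrix(c(pi[1] + pi[2] * e, pi[1] - pi[1] * e,
           pi[2] - pi[2] * e, pi[2] + pi[1] * e),
         nrow = 2)  # [i, j] = P(i -> j)
}

# conditional (pruning) likelihoods for one rate category; returns the list
# of npat x 2 partials per node, in the node numbering of the postorder tree
pruning_partials <- function(phy, pat, pi, rate) {
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  npat <- nrow(pat)
  partial <- vector("list", nnode)
  for (i in seq_len(ntip)) {
    partial[[i]] <- cbind(1 - pat[, i], pat[, i])
  }
  e <- phy$edge
  len <- phy$edge.length
  for (i in seq_len(nrow(e))) {
    p <- e[i, 1]
    ch <- e[i, 2]
    P <- pmat_2state(pi, rate * len[i])
    contrib <- partial[[ch]] %*% t(P)
    partial[[p]] <- if (is.null(partial[[p]])) contrib else partial[[p]] * contrib
  }
  partial
}

# per-pattern site likelihoods under the full mixture
site_likelihoods <- function(phy, pat, model) {
  if (is.null(phy$edge.length)) stop_contract("tree has no branch lengths")
  if (any(phy$edge.length < 0)) stop_contract("negative branch length")
  phy <- ape::reorder.phylo(phy, "postorder")
  root <- phy$edge[nrow(phy$edge), 1]
  lik <- 0
  for (k in seq_along(model$rates)) {
    part <- pruning_partials(phy, pat, model$pi, model$rates[k])
    lik <- lik + model$weights[k] * as.vector(part[[root]] %*% model$pi)
  }
  lik <- (1 - model$p_inv) * lik
  if (model$p_inv > 0) {
    const0 <- rowSums(pat) == 0
    const1 <- rowSums(pat) == ncol(pat)
    lik <- lik + model$p_inv * (const0 * model$pi[1] + const1 * model$pi[2])
  }
  lik
}

#' Log-likelihood of one site pattern
#'
#' Felsenstein pruning under the two-state model: the per-site likelihood is
#' `p_inv * [site constant] * pi(state) + (1 - p_inv) * sum_k w_k L(pattern |
#' r_k-scaled branch lengths)`.
#'
#' @param tree `ape::phylo` with branch lengths (rooted or unrooted).
#' @param model A [bin_model()].
#' @param states Named 0/1 vector over the tree's tips.
#' @return The natural log-likelihood (a single number).
#' @export
#' @examples
#' tr <- ape::read.tree(text = "(A:0.1733,B:0.1733);")
#' site_log_likelihood(tr, bin_model("BIN"), c(A = 0, B = 1))
site_log_likelihood <- function(tree, model, states) {
  if (!all(tree$tip.label %in% names(states))) {
    stop_contract("states must be named with all tip labels")
  }
  s <- states[tree$tip.label]
  if (!is_binary(s)) stop_contract("states must be 0/1")
  log(site_likelihoods(tree, matrix(s, nrow = 1), model))
}

#' Total log-likelihood of an accessibility matrix on a tree
#'
#' @param tree `ape::phylo` with branch lengths.
#' @param x Accessibility tibble containing all tip cells.
#' @param model A [bin_model()].
#' @return Natural log-likelihood summed over sites.
#' @export
tree_log_likelihood <- function(tree, x, model) {
  m <- acc_pattern_matrix(x, tree$tip.label)
  cp <- compress_patterns(m)
  sum(cp$w * log(site_likelihoods(tree, cp$pat, model)))
}

# --- fitting -----------------------------------------------------------------

logit <- function(p) log(p / (1 - p))
inv_logit <- function(z) 1 / (1 + exp(-z))

model_from_par <- function(tag, par) {
  # transforms are clamped so optimisers can roam the unbounded scale safely
  pi1 <- min(max(inv_logit(par[1]), 1e-6), 1 - 1e-6)
  pi <- c(1 - pi1, pi1)
  if (tag == "BIN") return(bin_model(tag, pi))
  p_inv <- min(inv_logit(par[2]), 0.999)
  if (tag == "BIN+I") return(bin_model(tag, pi, p_inv))
  if (tag == "BIN+I+G") {
    return(bin_model(tag, pi, p_inv,
                     alpha = min(max(exp(par[3]), 1e-3), 100)))
  }
  k <- as.integer(sub("BIN\\+I\\+R", "", tag))
  rates <- c(1, pmin(pmax(exp(par[3:(k + 1)]), 1e-6), 1e3))
  wz <- c(0, pmin(pmax(par[(k + 2):(2 * k)], -30), 30))
  weights <- exp(wz - max(wz))
  bin_model(tag, pi, p_inv, rates = rates, weights = weights / sum(weights))
}

par_init <- function(tag, pi1_hat, p_inv_hat = 0.2) {
  pi1_hat <- min(max(pi1_hat, 0.01), 0.99)
  # the constant-site fraction bounds p_inv from above and is the natural start
  p_inv_hat <- min(max(p_inv_hat, 0.02), 0.95)
  base <- logit(pi1_hat)
  if (tag == "BIN") return(base)
  if (tag == "BIN+I") return(c(base, logit(p_inv_hat)))
  if (tag == "BIN+I+G") return(c(base, logit(p_inv_hat), 0))
  k <- as.integer(sub("BIN\\+I\\+R", "", tag))
  # spread initial rates so categories are distinguishable
  c(base, logit(p_inv_hat), log(seq(1.5, 4, length.out = k - 1)),
    rep(0, k - 1))
}

#' Fit branch lengths and model parameters on a fixed topology
#'
#' Maximum-likelihood fit of a two-state model on a fixed tree topology:
#' coordinate ascent alternating bounded line searches on each branch length
#' (bounds `[1e-8, 100]` expected changes per site) with joint optimisation
#' of the model parameters, until the log-likelihood improves by less than
#' `tol` or `max_iter` sweeps are reached. The log-likelihood never
#' decreases across sweeps. For a rooted input the two root branches are
#' tied (only their sum is identifiable under a reversible model), so the
#' free branch-length count is `2 * n_taxa - 3` for every topology, and the
#' AIC (`2k - 2 lnL`) is comparable across models and rootings.
#'
#' @param tree `ape::phylo` topology (rooted binary or unrooted); existing
#'   branch lengths are used as a warm start when present.
#' @param x Accessibility tibble containing all tip cells.
#' @param tag Model family (see [bin_model()]).
#' @param max_iter Maximum coordinate-ascent sweeps.
#' @param tol Convergence tolerance on the log-likelihood.
#' @return A `bin_ml_fit` object: `tree` (fitted branch lengths), `model`,
#'   `lnL`, `k`, `AIC`, `n_sites`, `converged`, `iterations`.
#' @export
ml_fit <- function(tree, x, tag = "BIN+I", max_iter = 100, tol = 1e-6) {
  tag <- match.arg(tag, model_tags)
  m <- acc_pattern_matrix(x, tree$tip.label)
  if (nrow(m) == 0) stop_input("accessibility table has no sites")
  cp <- compress_patterns(m)
  ntip <- length(tree$tip.label)
  rooted <- ape::is.rooted(tree)
  if (rooted) check_rooted_binary(tree)
  phy <- ape::reorder.phylo(tree, "postorder")
  nedge <- nrow(phy$edge)
  if (is.null(phy$edge.length) || any(!is.finite(phy$edge.length)) ||
      all(phy$edge.length <= 0)) {
    phy$edge.length <- rep(0.1, nedge)
  }
  # branch lengths are expected changes per site; warm starts on a raw
  # difference-count scale (e.g. NJ on Hamming counts) are rescaled
  if (max(phy$edge.length) > 3) {
    phy$edge.length <- phy$edge.length / nrow(m)
  }
  phy$edge.length <- pmin(pmax(phy$edge.length, 1e-8), 100)
  root <- phy$edge[nedge, 1]
  root_edges <- which(phy$edge[, 1] == root)
  tie_root <- rooted && length(root_edges) == 2
  if (tie_root) {
    tot <- sum(phy$edge.length[root_edges])
    phy$edge.length[root_edges] <- tot / 2
  }

  lnl_of <- function(ph, model) sum(cp$w * log(site_likelihoods(ph, cp$pat, model)))

  pi1_hat <- sum(cp$w * rowSums(cp$pat)) / (sum(cp$w) * ntip)
  const <- rowSums(cp$pat) %in% c(0L, ncol(cp$pat))
  p_inv_hat <- sum(cp$w[const]) / sum(cp$w) * 0.95
  par <- par_init(tag, pi1_hat, p_inv_hat)
  model <- model_from_par(tag, par)
  lnl <- lnl_of(phy, model)

  free_edges <- if (tie_root) {
    c(setdiff(seq_len(nedge), root_edges), root_edges[1])
  } else {
    seq_len(nedge)
  }
  set_len <- function(ph, i, t) {
    if (tie_root && i %in% root_edges) {
      ph$edge.length[root_edges] <- t / 2
    } else {
      ph$edge.length[i] <- t
    }
    ph
  }

  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    lnl_prev <- lnl
    for (i in free_edges) {
      cur <- if (tie_root && i %in% root_edges) {
        sum(phy$edge.length[root_edges])
      } else {
        phy$edge.length[i]
      }
      opt <- optimize(function(lt) lnl_of(set_len(phy, i, exp(lt)), model),
                      interval = c(log(1e-8), log(100)), maximum = TRUE,
                      tol = 1e-7)
      if (opt$objective > lnl) {
        phy <- set_len(phy, i, exp(opt$maximum))
        lnl <- opt$objective
      }
    }
    if (length(par) == 1) {
      opt <- optimize(function(p) lnl_of(phy, model_from_par(tag, p)),
                      interval = c(-8, 8), maximum = TRUE, tol = 1e-7)
      if (opt$objective > lnl) {
        par <- opt$maximum
        model <- model_from_par(tag, par)
        lnl <- opt$objective
      }
    } else {
      opt <- optim(par, function(p) -lnl_of(phy, model_from_par(tag, p)),
                   method = "Nelder-Mead",
                   control = list(maxit = 200 * length(par)))
      if (-opt$value > lnl) {
        par <- opt$par
        model <- model_from_par(tag, par)
        lnl <- -opt$value
      }
    }
    if (lnl - lnl_prev < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(paste0("ml_fit(", tag, ") did not converge in ", max_iter,
                " sweeps; returning best-so-far fit"))
  }
  k <- model_n_free(tag) + (2L * ntip - 3L)
  structure(
    list(tree = phy, model = model, lnL = lnl, k = k,
         AIC = 2 * k - 2 * lnl, n_sites = nrow(m),
         n_patterns = nrow(cp$pat), converged = converged,
         iterations = iter),
    class = "bin_ml_fit"
  )
}

#' @export
print.bin_ml_fit <- function(x, ...) {
  cat("ML fit ", x$model$tag, ": lnL = ", round(x$lnL, 3),
      ", k = ", x$k, ", AIC = ", round(x$AIC, 3),
      " (", x$n_sites, " sites, ", x$n_patterns, " patterns",
      if (!x$converged) ", NOT converged", ")\n", sep = "")
  invisible(x)
}

#' Fit all six model families and select by AIC
#'
#' Fits `BIN`, `BIN+I`, `BIN+I+G` and the free-rate models `BIN+I+R4/R8/R12`
#' on the same fixed topology and returns the fit with the lowest Akaike
#' Information Criterion together with the full AIC table.
#'
#' @inheritParams ml_fit
#' @param tags Model families to compare.
#' @return A `bin_model_selection` object: `best` (a `bin_ml_fit`), `table`
#'   (tibble of tag, lnL, k, AIC, converged), `fits`.
#' @export
select_model_aic <- function(tree, x, tags = model_tags, max_iter = 100,
                             tol = 1e-6) {
  fits <- purrr::map(tags, ~ ml_fit(tree, x, .x, max_iter = max_iter, tol = tol))
  names(fits) <- tags
  table <- tibble(
    tag = tags,
    lnL = unname(map_dbl(fits, "lnL")),
    k = unname(map_int(fits, "k")),
    AIC = unname(map_dbl(fits, "AIC")),
    converged = unname(map_lgl(fits, "converged"))
  )
  best <- fits[[which.min(table$AIC)]]
  structure(list(best = best, table = table, fits = fits),
            class = "bin_model_selection")
}

#' @export
print.bin_model_selection <- function(x, ...) {
  cat("Model selection by AIC (best:", x$best$model$tag, ")\n")
  print(x$table)
  invisible(x)
}

#' Maximum-likelihood tree search
#'
#' Hill-climbs over tree space with nearest-neighbor interchanges from the
#' neighbor-joining starting tree, refitting branch lengths and model
#' parameters after each candidate move and accepting only improvements; or
#' fits every topology exhaustively for small panels.
#'
#' @param x Accessibility tibble.
#' @param tag Model family used during the search.
#' @param cells Taxa to include.
#' @param exhaustive Fit all `(2n-5)!!` topologies instead of NNI climbing
#'   (allowed up to 8 taxa).
#' @param max_iter Sweeps per candidate fit (kept small during search).
#' @return List with `tree` (fitted), `fit` (`bin_ml_fit` of the winner) and
#'   `lnL`.
#' @export
ml_search <- function(x, tag = "BIN+I", cells = acc_cells(x),
                      exhaustive = FALSE, max_iter = 10) {
  if (length(cells) < 4) stop_input("tree search needs at least 4 taxa")
  if (exhaustive) {
    if (length(cells) > 8) stop_capability("exhaustive ML limited to 8 taxa")
    topos <- enumerate_topologies(cells, as = "phylo")
    fits <- purrr::map(topos, ~ ml_fit(.x, x, tag, max_iter = max_iter))
    best <- fits[[which.max(map_dbl(fits, "lnL"))]]
    return(list(tree = best$tree, fit = best, lnL = best$lnL))
  }
  start <- ape::unroot(nj_tree(pairwise_differences(x, cells)))
  fit <- ml_fit(start, x, tag, max_iter = max_iter)
  repeat {
    nb <- nni_neighbors(fit$tree)
    cand <- purrr::map(nb, ~ suppressWarnings(ml_fit(.x, x, tag, max_iter = max_iter)))
    lnls <- map_dbl(cand, "lnL")
    if (max(lnls) <= fit$lnL + 1e-8) break
    fit <- cand[[which.max(lnls)]]
  }
  list(tree = fit$tree, fit = fit, lnL = fit$lnL)
}
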