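#' Build a run configuration
#'
#' Assembles the configuration for [run_analysis()]: either a path to a
#' cCRE-style TSV (plus its cell columns) or simulation settings, the
#' inference methods to run, model choice, bootstrap effort, filter
#' variants and output directory. All randomness in the run derives from
#' `seed`.
#'
#' @param input Path to an accessibility TSV, or NULL to simulate.
#' @param cells Cell columns of `input` (ignored when simulating).
#' @param sim Named list of arguments for [simulate_accessibility()].
#' @param methods Tree-inference methods, subset of `c("nj","mp","ml")`;
#'   `"mp"`/`"ml"` also switch on the matching ancestral estimators.
#' @param model Model family for ML stages, or `"auto"` for AIC selection.
#' @param bootstrap Bootstrap replicates for the NJ trees (0 = none).
#' @param drop_other,drop_imk Include the minus-OTHER / minus-iMK analysis
#'   variants.
#' @param outgroup Outgroup cell used for rooting and polarisation.
#' @param seed Integer master seed.
#' @param out_dir Output directory, or NULL to keep results in memory only.
#' @return A `run_config` list.
#' @export
run_config <- function(input = NULL, cells = NULL,
                       sim = list(n_sites = 2000),
                       methods = c("nj", "mp"),
                       model = "BIN+I",
                       bootstrap = 0,
                       drop_other = TRUE,
                       drop_imk = TRUE,
                       outgroup = "LSK",
                       seed = 1,
                       out_dir = NULL) {
  methods <- match.arg(methods, c("nj", "mp", "ml"), several.ok = TRUE)
  if (!identical(model, "auto")) model <- match.arg(model, model_tags)
  if (!is.null(input) && is.null(cells)) {
    stop_config("cells must be given when input is a file")
  }
  structure(list(input = input, cells = cells, sim = sim, methods = methods,
                 model = model, bootstrap = bootstrap,
                 drop_other = drop_other, drop_imk = drop_imk,
                 outgroup = outgroup, seed = seed, out_dir = out_dir),
            class = "run_config")
}

#' Run the full accessibility-phylogenetics analysis
#'
#' Orchestrates the whole pipeline from one configuration: load or simulate
#' the binary matrix; classify sites along the differentiation paths; build
#' the analysis variants (all sites / without OTHER sites, full panel /
#' without iMK); infer trees per variant with the requested methods
#' (bootstrap supports on NJ when asked); reconstruct ancestral progenitor
#' states on the outgroup-rooted constraint topology from terminal + stem
#' profiles only; validate the predictions against observed progenitor
#' columns (sensitivity/specificity, with stable-everywhere and ambiguous
#' sites removed); and quantify lymphoid vs myeloid treelikeness with delta
#' scores. When the input is simulated, inferred topologies are also scored
#' against the generating tree (Robinson-Foulds).
#'
#' @param config A [run_config()].
#' @return An `acc_run_report` list with elements `tally`, `trees`,
#'   `confusion`, `delta`, `rf`, `aic`, `skipped`, `manifest`, `seed`,
#'   `version`, `timestamp`.
#' @export
run_analysis <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  skipped <- character(0)
  manifest <- character(0)

  # --- stage 1: data ---------------------------------------------------------
  sim <- NULL
  if (is.null(config$input)) {
    sim_args <- config$sim
    sim_args$seed <- sim_args$seed %||% seed
    sim <- do.call(simulate_accessibility, sim_args)
    x <- sim$matrix
  } else {
    x <- read_accessibility(config$input, config$cells)
  }
  cells <- acc_cells(x)

  # --- stage 2: classification ----------------------------------------------
  cls <- classify_sites(x)

  # --- stage 3: variants -----------------------------------------------------
  variants <- list(all_sites = x)
  if (config$drop_other) {
    variants$no_other <- filter_sites(x, !other_site_mask(cls))
  }
  if (config$drop_imk && "iMK" %in% cells) {
    variants$no_imk <- subset_cells(x, setdiff(cells, "iMK"))
    if (config$drop_other) {
      variants$no_other_no_imk <-
        subset_cells(variants$no_other, setdiff(cells, "iMK"))
    }
  }

  # --- stage 4: tree inference ----------------------------------------------
  trees <- list()
  aic <- NULL
  tag <- if (identical(config$model, "auto")) "BIN+I" else config$model
  for (vn in names(variants)) {
    v <- variants[[vn]]
    for (mth in config$methods) {
      key <- paste(mth, vn, sep = ".")
      if (mth == "nj" && config$bootstrap > 0) {
        bs <- bootstrap_support(v, "nj", B = config$bootstrap, seed = seed)
        trees[[key]] <- bs$tree
      } else {
        trees[[key]] <- infer_tree_method(v, mth, acc_cells(v), tag)
      }
    }
  }

  # --- stage 5: ancestral reconstruction + validation ------------------------
  terminals <- hematopoietic_cells() |>
    filter(.data$role == "terminal") |> pull("name")
  leaves <- intersect(c(config$outgroup, terminals), cells)
  progenitors <- intersect(c("CMP", "GMP", "MEP"), cells)
  confusion <- NULL
  if (length(leaves) >= 4 && config$outgroup %in% leaves) {
    ctree <- ape::keep.tip(constraint_tree(), leaves)
    eval_variants <- list(all_sites = x)
    if (config$drop_other) eval_variants$no_other <- variants$no_other
    confusion <- purrr::imap(eval_variants, function(v, vn) {
      cls_v <- classify_sites(v)
      stable_v <- stable_everywhere_mask(cls_v)
      leaves_v <- subset_cells(v, leaves)
      out <- list()
      if ("mp" %in% config$methods) {
        for (mm in c("acctran", "deltran")) {
          est <- if (mm == "acctran") {
            acctran(ctree, leaves_v, outgroup = config$outgroup)
          } else {
            deltran(ctree, leaves_v, outgroup = config$outgroup)
          }
          if (length(progenitors) > 0) {
            pred <- progenitor_states(est)
            out[[mm]] <- evaluate_progenitors(pred, v, exclude_stable = stable_v)
          }
        }
      }
      if ("ml" %in% config$methods) {
        fit <- if (identical(config$model, "auto")) {
          sel <- select_model_aic(ctree, leaves_v, max_iter = 25)
          aic <<- sel$table
          sel$best
        } else {
          ml_fit(ctree, leaves_v, tag, max_iter = 25)
        }
        marg <- ml_marginals(fit, leaves_v)
        calls <- call_states(marg)
        if (length(progenitors) > 0) {
          pred <- progenitor_states(calls, tree = marg$tree)
          out$ml <- evaluate_progenitors(pred, v, exclude_stable = stable_v)
        }
        out$ml_fit_lnL <- fit$lnL
      }
      out
    })
    if (!("mp" %in% config$methods)) skipped <- c(skipped, "ancestral_mp")
    if (!("ml" %in% config$methods)) skipped <- c(skipped, "ancestral_ml")
  } else {
    skipped <- c(skipped, "ancestral")
  }

  # --- stage 6: treelikeness -------------------------------------------------
  groups <- list(lymphoid = c("LSK", "B", "TCD4", "TCD8", "NK"),
                 myeloid = c("LSK", "Neu", "Mon", "Ery", "iMK"))
  delta <- purrr::imap(variants[intersect(names(variants),
                                          c("all_sites", "no_other"))],
    function(v, vn) {
      purrr::imap(groups, function(g, gn) {
        g <- intersect(g, acc_cells(v))
        if (length(g) < 4) return(NULL)
        ds <- delta_scores(pairwise_differences(v, g), g)
        tibble(variant = vn, group = gn, n_quartets = nrow(ds),
               mean_delta = attr(ds, "mean_delta"))
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()

  # --- stage 7: recovery vs generating tree (simulation only) ----------------
  rf <- NULL
  if (!is.null(sim)) {
    truth9 <- generating_topology(sim, taxa = leaves)
    rf <- purrr::imap(trees, function(tr, key) {
      if (!setequal(tr$tip.label, leaves)) {
        tr <- tryCatch(ape::keep.tip(tr, leaves), error = function(e) NULL)
      }
      if (is.null(tr)) return(NULL)
      tibble(tree = key, rf = rf_distance(tr, truth9))
    }) |> purrr::list_rbind()
  }

  # --- stage 8: outputs ------------------------------------------------------
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- file.path(config$out_dir, "matrix.tsv")
    write_accessibility(x, p)
    manifest <- c(manifest, p)
    p <- file.path(config$out_dir, "site_classes.tsv")
    readr::write_tsv(cls$labels, p, progress = FALSE)
    manifest <- c(manifest, p)
    for (key in names(trees)) {
      p <- file.path(config$out_dir, paste0("tree_", key, ".nwk"))
      ape::write.tree(trees[[key]], file = p)
      manifest <- c(manifest, p)
    }
  }

  report <- structure(
    list(tally = cls$tally, summary = cls$summary, trees = trees,
         confusion = confusion, delta = delta, rf = rf, aic = aic,
         skipped = skipped, manifest = manifest, seed = seed,
         config = config, sim = sim,
         version = as.character(utils::packageVersion("accesstree")),
         timestamp = format(Sys.time(), tz = "UTC")),
    class = "acc_run_report"
  )
  if (!is.null(config$out_dir)) {
    p <- file.path(config$out_dir, "report.json")
    jsonlite::write_json(report_to_json(report), p, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    report$manifest <- c(manifest, p)
  }
  report
}

report_to_json <- function(r) {
  list(
    version = r$version, seed = r$seed, timestamp = r$timestamp,
    tally = r$tally,
    trees = purrr::map(r$trees, ape::write.tree),
    confusion = r$confusion, delta = r$delta, rf = r$rf, aic = r$aic,
    skipped = r$skipped, manifest = r$manifest
  )
}

#' @export
print.acc_run_report <- function(x, ...) {
  cat("accesstree run (seed ", x$seed, ", ", x$timestamp, " UTC)\n", sep = "")
  cat("Trees inferred:", paste(names(x$trees), collapse = ", "), "\n")
  if (!is.null(x$rf)) {
    cat("RF distance to generating topology:\n")
    print(x$rf)
  }
  if (!is.null(x$confusion)) {
    cat("Progenitor prediction (all sites):\n")
    for (nm in setdiff(names(x$confusion$all_sites), "ml_fit_lnL")) {
      cat(" ", nm, ":\n")
      print(x$confusion$all_sites[[nm]])
    }
  }
  cat("Treelikeness (mean delta):\n")
  print(x$delta)
  if (length(x$skipped) > 0) {
    cat("Skipped stages:", paste(x$skipped, collapse = ", "), "\n")
  }
  invisible(x)
}
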