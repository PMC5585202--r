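#' Pipeline run configuration
#'
#' Collects every setting of a full analysis run into one serializable list,
#' echoed verbatim into the report for provenance: re-running from the
#' embedded configuration reproduces the report exactly.
#'
#' @param networks character vector of adjacency-CSV paths, or a named list
#'   of [anatomical_network()] objects.
#' @param tree optional Newick path or [ape::phylo] tree.
#' @param steps walktrap random-walk length (default 3).
#' @param sd_type heterogeneity SD convention, `"population"` or `"sample"`.
#' @param low_degree clustering convention, `"zero"` or `"exclude"`.
#' @param n_perm permutations for Blomberg's K (default 1000).
#' @param seed RNG seed for the permutation tests.
#' @param out_dir output directory; `NULL` suppresses file output.
#' @return a `run_config` list.
#' @export
run_config <- function(networks, tree = NULL, steps = 3,
                       sd_type = "population", low_degree = "zero",
                       n_perm = 1000, seed = 1, out_dir = NULL) {
  structure(list(networks = networks, tree = tree, steps = steps,
                 sd_type = sd_type, low_degree = low_degree,
                 n_perm = n_perm, seed = seed, out_dir = out_dir),
            class = "run_config")
}

#' Run the full anatomical-network analysis pipeline
#'
#' For every input network: validates it, computes the six network parameters
#' and the walktrap module partition (with modularity Q, its jackknife
#' standard error and per-module Wilcoxon tests). If a tree is supplied, each
#' parameter column (plus the module count M) is tested for phylogenetic
#' signal with Pagel's lambda and Blomberg's K and reconstructed onto the
#' tree as a phenogram; a parameter that is constant across taxa carries no
#' signal and is reported with `NA` statistics instead.
#'
#' Any stage failure aborts with a message naming the stage and the
#' offending input. With `out_dir` set, writes `parameters.csv` (one row per
#' taxon: Taxa, N, K, D, C, L, H, M), `modules.json`, and, when a tree is
#' given, `phylosig.csv` and per-trait `phenogram_<trait>.csv`; outputs are
#' deterministic given the configuration (byte-identical across re-runs).
#'
#' @param cfg a [run_config()].
#' @return list with `parameters` (data frame), `partitions` (named list of
#'   `module_partition`), `phylosig` (data frame or `NULL`), `phenograms`
#'   (named list of [ancestral_states()] or `NULL`) and `config`.
#' @export
run_full_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  nets <- stage("read networks", {
    if (is.character(cfg$networks))
      lapply(cfg$networks, read_adjacency_csv)
    else cfg$networks
  })
  names(nets) <- vapply(nets, function(n) n$name, "")

  params <- list(); partitions <- list()
  for (nm in names(nets)) {
    params[[nm]] <- stage(paste("parameters of", nm),
                          network_parameters(nets[[nm]],
                                             low_degree = cfg$low_degree,
                                             sd_type = cfg$sd_type))
    partitions[[nm]] <- stage(paste("modules of", nm),
                              walktrap_modules(nets[[nm]], steps = cfg$steps))
  }
  param_tab <- do.call(rbind, c(params, make.row.names = FALSE))
  param_tab$M <- vapply(partitions, function(p) p$M, integer(1))
  stopifnot(all(abs(param_tab$D -
                      2 * param_tab$K /
                      (param_tab$N * (param_tab$N - 1))) < 1e-12))

  phylosig <- NULL; phenograms <- NULL
  if (!is.null(cfg$tree)) {
    tree <- stage("read tree", {
      if (is.character(cfg$tree)) read_phylogeny(cfg$tree) else
        validate_phylogeny(cfg$tree)
    })
    traits <- c("N", "K", "D", "C", "L", "H", "M")
    rows <- list(); phenograms <- list()
    for (i in seq_along(traits)) {
      tr <- traits[i]
      x <- stats::setNames(as.numeric(param_tab[[tr]]), param_tab$taxon)
      if (stats::sd(x) == 0) {
        # a constant trait carries no signal; report it as untestable
        rows[[tr]] <- data.frame(trait = tr, lambda = NA_real_,
                                 p_lambda = NA_real_, K = NA_real_,
                                 p_K = NA_real_, stringsAsFactors = FALSE)
        next
      }
      rows[[tr]] <- stage(paste("phylogenetic signal of", tr), {
        lam <- fit_pagel_lambda(x, tree)
        kb <- blomberg_k(x, tree, n_perm = cfg$n_perm,
                         seed = cfg$seed + i)
        data.frame(trait = tr, lambda = lam$estimate,
                   p_lambda = lam$p_value, K = kb$estimate,
                   p_K = kb$p_value, stringsAsFactors = FALSE)
      })
      phenograms[[tr]] <- stage(paste("ancestral states of", tr),
                                ancestral_states(x, tree))
    }
    phylosig <- do.call(rbind, c(rows, make.row.names = FALSE))
  }

  result <- list(parameters = param_tab, partitions = partitions,
                 phylosig = phylosig, phenograms = phenograms, config = cfg)
  if (!is.null(cfg$out_dir)) write_report(result, cfg$out_dir)
  result
}

stage <- function(label, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", label, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

write_report <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- format_parameter_table(result$parameters)
  colnames(tab)[1] <- "Taxa"
  utils::write.csv(tab, file.path(out_dir, "parameters.csv"),
                   row.names = FALSE)
  mods <- lapply(names(result$partitions), function(nm) {
    p <- result$partitions[[nm]]
    list(taxon = nm, M = p$M, Q = p$Q, Q_se = p$Q_se,
         modules = lapply(seq_len(p$M), function(m) list(
           id = m,
           nodes = names(p$assignment)[p$assignment == m],
           internal = p$module_stats$internal[m],
           external = p$module_stats$external[m],
           wilcoxon_p = p$module_stats$wilcoxon_p[m])))
  })
  cfg <- result$config
  cfg$networks <- if (is.character(cfg$networks)) cfg$networks else
    names(result$partitions)
  if (!is.character(cfg$tree) && !is.null(cfg$tree))
    cfg$tree <- "<in-memory tree>"
  jsonlite::write_json(list(config = unclass(cfg), results = mods),
                       file.path(out_dir, "modules.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  assign_df <- do.call(rbind, lapply(names(result$partitions), function(nm)
    data.frame(taxon = nm,
               node = names(result$partitions[[nm]]$assignment),
               module = unname(result$partitions[[nm]]$assignment))))
  utils::write.csv(assign_df, file.path(out_dir, "module_assignments.csv"),
                   row.names = FALSE)
  if (!is.null(result$phylosig)) {
    utils::write.csv(result$phylosig, file.path(out_dir, "phylosig.csv"),
                     row.names = FALSE)
    for (tr in names(result$phenograms))
      phenogram_export(result$phenograms[[tr]],
                       file.path(out_dir, paste0("phenogram_", tr, ".csv")))
  }
  invisible(out_dir)
}

#' Group summaries of a parameter table
#'
#' Per-group mean, standard deviation and quartiles of every numeric
#' parameter, plus the quartile band of each taxon's value within the whole
#' sample — values falling in the same interquartile band are conventionally
#' read as similar, in different bands as substantially different, and in
#' non-adjacent bands as very different.
#'
#' @param params data frame with a `taxon` column and numeric parameter
#'   columns (e.g. from [run_full_pipeline()] or
#'   [forelimb_parameter_table()]).
#' @param groups named character vector mapping every taxon to a group label,
#'   or the name of a grouping column already present in `params`.
#' @param quartile_type quantile algorithm (see [stats::quantile()]);
#'   default 7, the inclusive linear-interpolation convention.
#' @return list with `summary` (data frame: group, parameter, n, mean, sd —
#'   `sd` is `NA` for single-taxon groups —, q1, median, q3) and `bands`
#'   (data frame: taxon, parameter, band in
#'   `"below-Q1"`, `"Q1-Q2"`, `"Q2-Q3"`, `"above-Q3"`).
#' @examples
#' tab <- forelimb_parameter_table()
#' s <- summarize_group(tab[c("taxon", "H")], "group" = setNames(tab$group, tab$taxon))
#' subset(s$summary, group == "hominoid")
#' @export
summarize_group <- function(params, groups, quartile_type = 7) {
  if (is.character(groups) && length(groups) == 1 &&
      groups %in% colnames(params)) {
    groups <- stats::setNames(params[[groups]], params$taxon)
    params <- params[setdiff(colnames(params), "group")]
  }
  unmapped <- setdiff(params$taxon, names(groups))
  if (length(unmapped))
    stop("taxon/taxa not mapped to a group: ",
         paste(unmapped, collapse = ", "))
  num_cols <- colnames(params)[vapply(params, is.numeric, TRUE)]
  g <- groups[params$taxon]
  rows <- list()
  for (col in num_cols) for (grp in unique(g)) {
    v <- params[[col]][g == grp]
    qs <- stats::quantile(v, c(0.25, 0.5, 0.75), type = quartile_type)
    rows[[length(rows) + 1L]] <- data.frame(
      group = grp, parameter = col, n = length(v), mean = mean(v),
      sd = if (length(v) > 1) stats::sd(v) else NA_real_,
      q1 = unname(qs[1]), median = unname(qs[2]), q3 = unname(qs[3]),
      stringsAsFactors = FALSE)
  }
  bands <- list()
  for (col in num_cols) {
    qs <- stats::quantile(params[[col]], c(0.25, 0.5, 0.75),
                          type = quartile_type)
    band <- cut(params[[col]], c(-Inf, qs, Inf),
                labels = c("below-Q1", "Q1-Q2", "Q2-Q3", "above-Q3"),
                right = TRUE)
    bands[[col]] <- data.frame(taxon = params$taxon, parameter = col,
                               band = as.character(band),
                               stringsAsFactors = FALSE)
  }
  list(summary = do.call(rbind, c(rows, make.row.names = FALSE)),
       bands = do.call(rbind, c(bands, make.row.names = FALSE)))
}
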