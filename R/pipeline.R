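#' Analysis configuration
#'
#' Collects every tunable of the two-group pipeline: the column schema for
#' reading CSVs, the estimator settings, bootstrap sizes, the case-dropping
#' grid, the permutation count of the network comparison test, the
#' depression cutoff, and the master seed. The configuration round-trips
#' through YAML unchanged ([write_config()] / [read_config()]).
#'
#' @param schema column schema for [read_item_table()] (`NULL` for the
#'   default PHQ1..PHQ9/AA/IA/group names).
#' @param correlation correlation estimator; only `"spearman"` is offered.
#' @param gamma,n_lambda,lambda_min_ratio estimator settings, see
#'   [estimate_network()].
#' @param boot_B nonparametric bootstrap resamples (default 1000).
#' @param curve_B case-dropping resamples per drop fraction (default 1000;
#'   lower, e.g. 200, for quick runs).
#' @param drop_grid case-dropping fractions.
#' @param n_perm permutations for the comparison test (default 1000).
#' @param cutoff depression cutoff on the PHQ-9 total (default 8).
#' @param seed master integer seed; stage seeds are derived from it.
#' @return a validated list of class `analysis_config`.
#' @export
analysis_config <- function(schema = NULL, correlation = "spearman",
                            gamma = 0.5, n_lambda = 100,
                            lambda_min_ratio = 0.01,
                            boot_B = 1000, curve_B = 1000,
                            drop_grid = seq(0.05, 0.75, by = 0.05),
                            n_perm = 1000, cutoff = 8, seed = 1) {
  stopifnot(correlation == "spearman",
            gamma >= 0, gamma <= 2,
            n_lambda >= 2, n_lambda <= 1000,
            lambda_min_ratio > 0, lambda_min_ratio < 1,
            boot_B >= 2, curve_B >= 2,
            all(drop_grid > 0), all(drop_grid < 1),
            n_perm >= 20, cutoff >= 0, cutoff <= 27,
            seed == round(seed), abs(seed) < 2^30)
  structure(list(schema = schema, correlation = correlation, gamma = gamma,
                 n_lambda = n_lambda, lambda_min_ratio = lambda_min_ratio,
                 boot_B = boot_B, curve_B = curve_B,
                 drop_grid = drop_grid, n_perm = n_perm, cutoff = cutoff,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' @rdname analysis_config
#' @param config an `analysis_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname analysis_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(analysis_config, x)
}

derive_seed <- function(seed, k) (seed * 131L + k) %% 2000000011L

#' Run the full two-group symptom-network analysis
#'
#' Executes the whole pipeline in order on a grouped dataset: descriptives,
#' PHQ-9 prevalence and group tests; per-group symptom networks with
#' centrality and predictability; flow decompositions around the suicide
#' item and, when present, the IU dimensions; nonparametric bootstrap edge
#' intervals and difference tests; case-dropping stability curves (strength
#' and expected influence); the permutation comparison test on the
#' symptom-only and, when the IU dimensions are present, the full item set;
#' and covariate-adjusted sensitivity networks. Every output file is listed
#' in a JSON manifest stamped with the configuration hash and seed. A stage
#' failure is recorded in the manifest (status `"failed"`) and the
#' remaining stages still run. Outputs contain no timestamps, so a rerun
#' with identical config and data is byte-identical.
#'
#' @param data an [item_dataset()] with a two-level group label, or a CSV
#'   path to read with the config's schema.
#' @param config an [analysis_config()].
#' @param out_dir output directory (created if needed).
#' @param phq_items the nine symptom columns.
#' @param iu_items the IU dimension columns (used when present in the data).
#' @return the manifest, invisibly.
#' @export
run_full_analysis <- function(data, config = analysis_config(),
                              out_dir,
                              phq_items = paste0("PHQ", 1:9),
                              iu_items = c("AA", "IA")) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(data)) data <- read_item_table(data, config$schema)
  stopifnot(inherits(data, "item_dataset"))
  if (is.null(data$group) || length(levels(data$group)) != 2)
    stop("run_full_analysis needs a dataset with a two-level group label")

  cfg <- net_config(config$gamma, config$n_lambda, config$lambda_min_ratio)
  groups <- split_by_group(data, phq_items = phq_items, iu_items = iu_items)
  glev <- names(groups)
  has_iu <- all(iu_items %in% data$item_labels)
  all_items <- if (has_iu) c(phq_items, iu_items) else phq_items
  seed0 <- config$seed

  manifest <- list(package = "symptomnet",
                   version = as.character(utils::packageVersion("symptomnet")),
                   config = unclass(config),
                   config_hash = config_hash(config),
                   seed = seed0,
                   n = vapply(groups, n_subjects, integer(1)),
                   stages = list(), files = character(0))
  fp <- function(...) file.path(out_dir, paste0(...))
  run_stage <- function(name, expr) {
    res <- tryCatch({force(expr); "ok"},
                    error = function(e) paste0("failed: ",
                                               conditionMessage(e)))
    manifest$stages[[name]] <<- res
    if (res != "ok")
      warning("stage ", name, " ", res, call. = FALSE)
    invisible(NULL)
  }
  add_file <- function(path) {
    manifest$files <<- c(manifest$files, basename(path))
    path
  }

  run_stage("descriptives", {
    desc <- describe_items(data, by_group = TRUE)
    utils::write.csv(desc, add_file(fp("descriptives.csv")),
                     row.names = FALSE)
    prev <- phq_total_and_prevalence(data, cutoff = config$cutoff,
                                     phq_items = phq_items)
    chi <- chi_square_2x2(prev$counts)
    write_json_stable(list(
      cutoff = config$cutoff,
      counts = apply(prev$counts, 1, as.list, simplify = FALSE),
      prevalence = as.list(prev$counts[, 1] / rowSums(prev$counts)),
      chi_square = chi$value, p = chi$p),
      add_file(fp("prevalence.json")))
    tests <- do.call(rbind, lapply(all_items, function(it) {
      tt <- t_from_columns(groups[[1]]$values[, it],
                           groups[[2]]$values[, it])
      cbind(data.frame(item = it, stringsAsFactors = FALSE), tt)
    }))
    utils::write.csv(tests, add_file(fp("group_tests.csv")),
                     row.names = FALSE)
  })

  nets <- list()
  run_stage("networks", {
    for (g in glev) {
      net <- estimate_network(groups[[g]], gamma = cfg$gamma,
                              n_lambda = cfg$n_lambda,
                              lambda_min_ratio = cfg$lambda_min_ratio,
                              items = phq_items)
      nets[[g]] <- net
      write_network_json(net, add_file(fp("network_", g, ".json")))
      utils::write.csv(network_to_edgelist(net),
                       add_file(fp("edges_", g, ".csv")),
                       row.names = FALSE)
      ct <- centrality_table(net, data = select_items(groups[[g]],
                                                      phq_items))
      utils::write.csv(ct, add_file(fp("centrality_", g, ".csv")),
                       row.names = FALSE)
    }
  })

  run_stage("flow", {
    for (g in glev) {
      focal_nets <- list()
      if (has_iu) {
        full <- estimate_network(groups[[g]], gamma = cfg$gamma,
                                 n_lambda = cfg$n_lambda,
                                 lambda_min_ratio = cfg$lambda_min_ratio,
                                 items = all_items)
        focal_nets <- c(focal_nets,
                        list(AA = full, IA = full))
      }
      focal_nets$PHQ9 <- if (!is.null(nets[[g]])) nets[[g]] else
        estimate_network(groups[[g]], gamma = cfg$gamma,
                         n_lambda = cfg$n_lambda,
                         lambda_min_ratio = cfg$lambda_min_ratio,
                         items = phq_items)
      flows <- lapply(names(focal_nets), function(focal)
        flow_to_list(flow_decompose(focal_nets[[focal]], focal)))
      names(flows) <- names(focal_nets)
      write_json_stable(flows, add_file(fp("flow_", g, ".json")))
    }
  })

  run_stage("bootstrap", {
    for (i in seq_along(glev)) {
      g <- glev[i]
      bres <- bootstrap_edge_cis(select_items(groups[[g]], phq_items),
                                 config = cfg, B = config$boot_B,
                                 seed = derive_seed(seed0, 100L + i))
      diffs <- bootstrap_difference_tests(bres)
      write_json_stable(list(
        B = bres$B, skipped = bres$skipped, level = bres$level,
        edges = bres$edges,
        significant_edge_pairs = sum(diffs$edge_differences$significant),
        significant_strength_pairs =
          sum(diffs$strength_differences$significant),
        significant_ei_pairs = sum(diffs$ei_differences$significant)),
        add_file(fp("bootstrap_", g, ".json")))
    }
  })

  run_stage("stability", {
    for (i in seq_along(glev)) {
      g <- glev[i]
      out <- lapply(c(strength = "strength",
                      expected_influence = "expected_influence"),
        function(stat) {
          cs <- case_dropping_curve(
            select_items(groups[[g]], phq_items), config = cfg,
            statistic = stat, drops = config$drop_grid,
            B = config$curve_B,
            seed = derive_seed(seed0, 200L + i))
          list(curve = cs$curve, cs_coefficient = cs$cs_coefficient)
        })
      write_json_stable(out, add_file(fp("stability_", g, ".json")))
    }
  })

  run_stage("comparison", {
    res9 <- nct(select_items(groups[[1]], phq_items),
                select_items(groups[[2]], phq_items),
                config = cfg, n_perm = config$n_perm,
                seed = derive_seed(seed0, 301L))
    write_json_stable(nct_to_list(res9), add_file(fp("nct_symptoms.json")))
    if (has_iu) {
      res11 <- nct(select_items(groups[[1]], all_items),
                   select_items(groups[[2]], all_items),
                   config = cfg, n_perm = config$n_perm,
                   seed = derive_seed(seed0, 302L))
      write_json_stable(nct_to_list(res11), add_file(fp("nct_flow.json")))
    }
  })

  run_stage("covariates", {
    covs <- names(data$covariates)
    if (length(covs)) {
      out <- list()
      for (g in glev) {
        base <- nets[[g]]
        for (cv in covs) {
          adj <- covariate_adjusted_network(
            select_items(groups[[g]], phq_items), cv,
            gamma = cfg$gamma, n_lambda = cfg$n_lambda,
            lambda_min_ratio = cfg$lambda_min_ratio)
          sim <- network_similarity(base, adj)
          out[[paste(g, cv, sep = "_")]] <-
            list(group = g, covariate = cv, r = sim$r, p = sim$p)
        }
      }
      write_json_stable(out, add_file(fp("covariate_sensitivity.json")))
    }
  })

  write_json_stable(manifest, fp("manifest.json"))
  invisible(manifest)
}
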