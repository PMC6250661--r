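#' Run the full pleiotropy analysis pipeline
#'
#' Executes, in order: wildtype reference (pFBA + caps + per-component
#' maxima), per-gene allele sweeps, knockout essentiality, gene
#' classification, type-II (single-reaction) decomposition,
#' currency-metabolite reduction analysis (when a currency list is
#' available), gene-trait network modularity against rewiring nulls, and
#' the knockout-pleiotropy-vs-steps randomization test. All stochastic
#' stages draw fixed seeds derived from `seed`.
#'
#' When `out_dir` is given, results are written as TSV files together with
#' a `run_config.json`; a rerun with an unchanged configuration and intact
#' outputs is skipped, leaving the files byte-identical.
#'
#' @param model a [metabolic_model()].
#' @param exclude biomass-component exclusion list.
#' @param currency currency-metabolite list (default: the model's
#'   `"currency"` attribute, if any).
#' @param fractions capacity-fraction grid.
#' @param n_null rewired null networks for scaled modularity.
#' @param n_rand randomizations for the step test.
#' @param seed master seed.
#' @param genes genes to analyze (default: all).
#' @param out_dir optional output directory for TSV results.
#' @param force recompute even when existing outputs match the config.
#' @return bundle: list with `reference`, `profiles`, `summary` (per-gene
#'   data.frame), `classification`, `type2`, `currency`
#'   (`NULL` without a currency list), `network`, `modularity`,
#'   `step_test`, `config`, `skipped`.
#' @export
run_pipeline <- function(model, exclude = character(0),
                         currency = attr(model, "currency"),
                         fractions = seq(1, 0, by = -0.005),
                         n_null = 10000, n_rand = 1e6, seed = 1,
                         genes = NULL, out_dir = NULL, force = FALSE) {
  if (is.null(genes)) genes <- model$genes
  config <- list(model_id = model$id, n_genes = length(genes),
                 exclude = exclude,
                 n_currency = length(currency),
                 grid_step = if (length(fractions) > 1)
                   fractions[1] - fractions[2] else NA,
                 n_fractions = length(fractions),
                 n_null = n_null, n_rand = n_rand, seed = seed)
  cfg_json <- paste(vapply(names(config), function(k)
    sprintf("\"%s\": %s", k,
            paste(format(config[[k]], digits = 15), collapse = ",")),
    character(1)), collapse = ", ")
  cfg_json <- paste0("{", cfg_json, "}")

  if (!is.null(out_dir) && !force) {
    cfg_path <- file.path(out_dir, "run_config.json")
    expected <- file.path(out_dir,
      c("summary.tsv", "profiles.tsv", "network_edges.tsv"))
    if (file.exists(cfg_path) &&
        identical(readLines(cfg_path, warn = FALSE), cfg_json) &&
        all(file.exists(expected))) {
      message("pipeline outputs up to date in ", out_dir, "; skipping")
      return(invisible(list(skipped = TRUE, out_dir = out_dir,
                            config = config)))
    }
  }

  ref <- build_reference(model, exclude)

  profiles <- lapply(genes, function(g) sweep_gene(ref, g, fractions))
  names(profiles) <- genes

  classification <- classify_genes(ref, genes)
  ess <- vapply(genes, function(g) essentiality_count(ref, g, 0)$count,
                integer(1))
  summary_tab <- data.frame(
    gene = genes,
    ko_pleiotropy = vapply(profiles, `[[`, integer(1), "ko_pleiotropy"),
    essentiality = ess,
    steps = vapply(profiles, `[[`, integer(1), "steps"),
    fitness_contributing = classification$fitness_contributing,
    class = classification$class,
    stringsAsFactors = FALSE)
  rownames(summary_tab) <- NULL

  type2 <- type2_aggregate(ref, genes)

  curr <- NULL
  if (!is.null(currency) && length(currency)) {
    curr <- list(
      pleiotropy = currency_reduction_analysis(model, currency, exclude,
                                               "pleiotropy", genes),
      essentiality = currency_reduction_analysis(model, currency, exclude,
                                                 "essentiality", genes))
  }

  aff0 <- lapply(profiles, function(p) p$affected[[length(p$affected)]])
  net <- NULL; modres <- NULL
  if (any(lengths(aff0) > 0)) {
    net <- gene_trait_network(aff0)
    if (net$m >= 2) {
      modres <- scaled_modularity(net, n_null = n_null,
                                  seed = (seed + 104729L) %% .Machine$integer.max)
    }
  }

  st <- NULL
  if (sum(summary_tab$ko_pleiotropy > 0) >= 3) {
    st <- tryCatch(
      step_randomization_test(summary_tab$ko_pleiotropy,
                              summary_tab$steps, n_rand = n_rand,
                              seed = (seed + 15485863L) %% .Machine$integer.max),
      error = function(e) {
        message("step randomization test skipped: ", conditionMessage(e))
        NULL
      })
  }

  bundle <- list(reference = ref, profiles = profiles,
                 summary = summary_tab, classification = classification,
                 type2 = type2, currency = curr, network = net,
                 modularity = modres, step_test = st,
                 config = config, config_json = cfg_json, skipped = FALSE)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' Write pipeline results as TSV files
#'
#' @param bundle result of [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)

  wr(bundle$summary, "summary.tsv")

  prof <- do.call(rbind, lapply(bundle$profiles, function(p)
    data.frame(gene = p$gene, fraction = p$fractions, count = p$count,
               affected = vapply(p$affected, paste, "", collapse = ";"),
               stringsAsFactors = FALSE)))
  wr(prof, "profiles.tsv")

  if (!is.null(bundle$network)) wr(bundle$network$edges, "network_edges.tsv")
  else wr(data.frame(gene = character(0), trait = character(0)),
          "network_edges.tsv")

  if (!is.null(bundle$modularity)) {
    mr <- bundle$modularity
    wr(data.frame(q = mr$q, z = mr$z, p = mr$p, n_null = mr$n_null),
       "modularity.tsv")
    wr(data.frame(node = names(mr$partition), module = unname(mr$partition)),
       "partition.tsv")
  }
  if (!is.null(bundle$step_test)) {
    st <- bundle$step_test
    wr(data.frame(rho = st$rho, p = st$p, n_rand = st$n_rand,
                  n_genes = st$n_genes), "step_test.tsv")
  }
  if (!is.null(bundle$currency)) {
    wr(bundle$currency$pleiotropy$per_metabolite, "currency_pleiotropy.tsv")
    wr(bundle$currency$essentiality$per_metabolite, "currency_essentiality.tsv")
  }
  if (nrow(bundle$type2$per_gene)) wr(bundle$type2$per_gene, "type2.tsv")
  writeLines(bundle$config_json, file.path(dir, "run_config.json"))
  invisible(dir)
}

#' Summary statistics of a pipeline run
#'
#' Mean and median knockout pleiotropy and essentiality over
#' fitness-contributing genes, step statistics, histograms, and the
#' currency-mediation fractions. Empty fitness-contributing sets yield
#' `NA`, never zero.
#'
#' @param bundle result of [run_pipeline()].
#' @return list with `stats` (data.frame metric/value),
#'   `pleiotropy_histogram`, `steps_histogram`, `currency_reduction`
#'   (per-metabolite fractions, or `NULL`).
#' @export
summarize_bundle <- function(bundle) {
  s <- bundle$summary
  fit <- s[s$fitness_contributing, , drop = FALSE]
  agg <- function(x, f) if (nrow(fit)) f(x) else NA_real_
  stats_tab <- data.frame(
    metric = c("n_genes", "n_fitness_contributing",
               "mean_ko_pleiotropy", "median_ko_pleiotropy",
               "mean_essentiality", "median_essentiality",
               "mean_steps",
               "modularity_q", "scaled_modularity_z", "modularity_p",
               "step_rho", "step_p"),
    value = c(nrow(s), nrow(fit),
              agg(fit$ko_pleiotropy, mean), agg(fit$ko_pleiotropy, stats::median),
              agg(fit$essentiality, mean), agg(fit$essentiality, stats::median),
              agg(fit$steps, mean),
              if (is.null(bundle$modularity)) NA_real_ else bundle$modularity$q,
              if (is.null(bundle$modularity)) NA_real_ else bundle$modularity$z,
              if (is.null(bundle$modularity)) NA_real_ else bundle$modularity$p,
              if (is.null(bundle$step_test)) NA_real_ else bundle$step_test$rho,
              if (is.null(bundle$step_test)) NA_real_ else bundle$step_test$p),
    stringsAsFactors = FALSE)
  list(stats = stats_tab,
       pleiotropy_histogram = table(fit$ko_pleiotropy),
       steps_histogram = table(fit$steps),
       currency_reduction = if (is.null(bundle$currency)) NULL else
         bundle$currency$pleiotropy$per_metabolite)
}
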