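#' Run the full covariance-network analysis
#'
#' Chains every stage on a node-level cohort: ingest (or accept an
#' in-memory table), statistical QC, covariate adjustment, group network
#' construction, graph measures, label-permutation inference with FDR, and
#' the volumetric ANCOVA stage. All result tables are written as TSV under
#' `out_dir`, together with a JSON provenance record (seed, replication
#' count, package version, configuration) sufficient to reproduce the run.
#'
#' @param cohort A `cohort_table`, or a path passed to [read_cohort()].
#' @param out_dir Output directory (created if needed); `NULL` to skip all
#'   file output.
#' @param covariates Adjustment/ANCOVA covariates.
#' @param R Permutation replications (default 1000).
#' @param seed Integer seed for the permutation engine and all graph
#'   randomness.
#' @param q FDR level.
#' @param reference Reference group label (see [permutation_test()]).
#' @param sw_n_rand_obs,sw_n_rand Small-worldness ensemble sizes (observed
#'   / within permutations).
#' @param qc_tolerance Thalamus-consistency tolerance.
#' @param all_nodal Emit all nodal rows in the report, not only
#'   FDR-significant ones.
#' @return List with `qc`, `model`, `adjusted`, `networks`, `measures`,
#'   `permutation`, `tables`, `ancova`.
#' @export
run_pipeline <- function(cohort, out_dir = NULL,
                         covariates = c("age", "sex", "icv"),
                         R = 1000L, seed = 1L, q = 0.05,
                         reference = NULL, sw_n_rand_obs = 100L,
                         sw_n_rand = 20L, qc_tolerance = 0.10,
                         all_nodal = FALSE) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(inherits(cohort, "cohort_table"))
  labs <- sort(unique(as.character(cohort$group)))
  if (length(labs) != 2) stop("stage ingest: exactly two groups required")
  if (is.null(reference)) reference <- if ("HC" %in% labs) "HC" else labs[1]
  other <- setdiff(labs, reference)

  qc <- qc_report(cohort, tolerance = qc_tolerance)
  model <- fit_adjustment(cohort, covariates = covariates)
  adjusted <- residualize(cohort, model)
  nets <- list()
  nets[[reference]] <- build_group_network(adjusted, reference)
  nets[[other]] <- build_group_network(adjusted, other)
  measures <- lapply(nets, graph_measures, sw_n_rand = sw_n_rand_obs,
                     sw_seed = seed, modules_seed = seed)
  perm <- permutation_test(adjusted, R = R, seed = seed,
                           reference = reference, q = q,
                           sw_n_rand_obs = sw_n_rand_obs,
                           sw_n_rand = sw_n_rand)
  tables <- report_tables(perm, all_nodal = all_nodal)
  ancova <- ancova_compare(cohort, covariates = covariates,
                           reference = reference, q = q)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_qc_report(qc, out_dir)
    write_adjustment_model(model, file.path(out_dir, "adjustment_model.tsv"))
    write_cohort(adjusted, file.path(out_dir, "adjusted_cohort.tsv"))
    for (g in names(nets)) {
      tag <- gsub("[^A-Za-z0-9]+", "_", g)
      export_network(nets[[g]],
                     file.path(out_dir, paste0("network_", tag, ".tsv")),
                     file.path(out_dir, paste0("edges_", tag, ".tsv")))
      write_measures(measures[[g]],
                     file.path(out_dir, paste0("measures_global_", tag,
                                               ".tsv")),
                     file.path(out_dir, paste0("measures_nodal_", tag,
                                               ".tsv")))
    }
    report_tables(perm, all_nodal = all_nodal, dir = out_dir)
    write_ancova_table(ancova, file.path(out_dir, "volumetrics.tsv"))
    prov <- paste0(
      '{"package": "thalnet", "version": "',
      as.character(utils::packageVersion("thalnet")),
      '", "seed": ', seed, ', "R": ', R, ', "q": ', q,
      ', "reference": "', reference, '"',
      ', "covariates": [',
      paste0('"', covariates, '"', collapse = ", "), "]",
      ', "sw_n_rand_obs": ', sw_n_rand_obs,
      ', "sw_n_rand": ', sw_n_rand,
      ', "qc_tolerance": ', qc_tolerance,
      ', "n_subjects": ', nrow(cohort), "}")
    writeLines(prov, file.path(out_dir, "provenance.json"))
  }
  invisible(list(qc = qc, model = model, adjusted = adjusted,
                 networks = nets, measures = measures, permutation = perm,
                 tables = tables, ancova = ancova))
}
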