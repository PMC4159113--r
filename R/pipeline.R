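#' Run the full preactivation analysis
#'
#' Orchestrates the fold-change calling chain on a two-genotype x
#' two-treatment experiment: oxidant-induced sets per genotype, the basal
#' differential between genotypes, the common-induced overlap, the
#' preactivated intersection, the uniquely induced remainder, and (when a
#' target list is supplied) enrichment of the preactivated genes for it.
#' All overlap statistics use the measured genes as the universe unless a
#' different one is given.
#'
#' @param mat an `ExpressionMatrix` whose metadata identifies genotype and
#'   treatment per sample.
#' @param genotype_col,treatment_col metadata column names.
#' @param diff_level,dediff_level genotype levels for differentiated /
#'   de-differentiated cells.
#' @param vehicle_level,oxidant_level treatment levels for control / oxidant
#'   arms.
#' @param fc_threshold linear fold-change threshold (default 2).
#' @param targets optional reference `GeneSet` (e.g. direct Nrf2 targets)
#'   for enrichment of the preactivated set.
#' @param universe overlap universe: a `GeneSet` or a count; default = all
#'   measured genes.
#' @param out_dir optional directory; when given, gene sets are written as
#'   GMT, per-gene fold changes as TSV, and a JSON summary (with every
#'   threshold recorded) alongside.
#' @return list of class `PreactivationReport` with elements `sets` (named
#'   `GeneSet` list), `counts`, `overlaps` (`OverlapResult`s for
#'   common-induced, preactivated and, if requested, target enrichment),
#'   `fold_changes` (per-gene data.frame) and `params`.
#' @export
run_preactivation <- function(mat,
                              genotype_col = "genotype",
                              treatment_col = "treatment",
                              diff_level = "differentiated",
                              dediff_level = "dedifferentiated",
                              vehicle_level = "vehicle",
                              oxidant_level = "oxidant",
                              fc_threshold = 2,
                              targets = NULL, universe = NULL,
                              out_dir = NULL) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  md <- mat$metadata
  for (col in c(genotype_col, treatment_col))
    if (!col %in% names(md))
      stop("metadata column '", col, "' not found")
  arm <- function(geno, treat) {
    ids <- rownames(md)[md[[genotype_col]] == geno &
                          md[[treatment_col]] == treat]
    if (!length(ids))
      stop("no samples with ", genotype_col, "='", geno, "' and ",
           treatment_col, "='", treat, "'")
    ids
  }
  diff_veh <- arm(diff_level, vehicle_level)
  diff_ox <- arm(diff_level, oxidant_level)
  dediff_veh <- arm(dediff_level, vehicle_level)
  dediff_ox <- arm(dediff_level, oxidant_level)

  if (is.null(universe))
    universe <- gene_set("measured", genes(mat))

  induced_diff <- up_regulated_set(
    mat, contrast_spec(diff_ox, diff_veh, fc_threshold), "ros_induced_diff")
  induced_dediff <- up_regulated_set(
    mat, contrast_spec(dediff_ox, dediff_veh, fc_threshold),
    "ros_induced_dediff")
  basal <- differential_set(
    mat, contrast_spec(dediff_veh, diff_veh, fc_threshold), "dediff_basal")
  common <- gs_intersect(induced_diff, induced_dediff, "common_induced")
  preact <- preactivated_set(induced_diff, basal$up)
  unique_ind <- uniquely_induced_set(induced_diff, induced_dediff, preact)

  overlaps <- list(
    common_induced = overlap_test(induced_diff, induced_dediff, universe),
    preactivated = overlap_test(induced_diff, basal$up, universe))
  if (!is.null(targets)) {
    stopifnot(inherits(targets, "GeneSet"))
    overlaps$target_enrichment <-
      enrichment_test(preact, targets, universe)
  }

  basal_ctr <- contrast_spec(dediff_veh, diff_veh, fc_threshold)
  fold_changes <- data.frame(
    gene_id = genes(mat),
    lfc_oxidant_diff = unname(log2_fold_change(
      mat, contrast_spec(diff_ox, diff_veh, fc_threshold))),
    lfc_oxidant_dediff = unname(log2_fold_change(
      mat, contrast_spec(dediff_ox, dediff_veh, fc_threshold))),
    lfc_basal_dediff = unname(log2_fold_change(mat, basal_ctr)),
    stringsAsFactors = FALSE)

  sets <- list(ros_induced_diff = induced_diff,
               ros_induced_dediff = induced_dediff,
               dediff_up = basal$up, dediff_down = basal$down,
               differential = basal$differential,
               common_induced = common, preactivated = preact,
               uniquely_induced = unique_ind)
  report <- list(
    sets = sets,
    counts = vapply(sets, function(s) length(s$members), integer(1)),
    overlaps = overlaps,
    fold_changes = fold_changes,
    params = list(fc_threshold = fc_threshold,
                  universe_size = if (inherits(universe, "GeneSet"))
                    length(universe$members) else as.integer(universe),
                  genotype_col = genotype_col, treatment_col = treatment_col,
                  levels = c(diff = diff_level, dediff = dediff_level,
                             vehicle = vehicle_level,
                             oxidant = oxidant_level)))
  class(report) <- "PreactivationReport"
  if (!is.null(out_dir)) write_preactivation_report(report, out_dir)
  report
}

#' @export
print.PreactivationReport <- function(x, ...) {
  cat("Preactivation analysis (fold-change threshold",
      x$params$fc_threshold, ")\n")
  for (nm in names(x$counts))
    cat(sprintf("  %-20s %d genes\n", nm, x$counts[[nm]]))
  for (nm in names(x$overlaps))
    cat(sprintf("  %s: p_upper = %.3g\n", nm, x$overlaps[[nm]]$p_upper))
  invisible(x)
}

write_preactivation_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  nonempty <- Filter(function(s) length(s$members) > 0, report$sets)
  if (length(nonempty))
    write_gmt(nonempty, file.path(out_dir, "gene_sets.gmt"))
  write.table(report$fold_changes,
              file.path(out_dir, "fold_changes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(
    counts = as.list(report$counts),
    overlaps = lapply(report$overlaps, unclass),
    params = report$params)
  jsonlite::write_json(summary, file.path(out_dir, "preactivation.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Run the full cohort signature analysis
#'
#' Scores every cohort sample against a signature, stratifies into
#' high/low/mid groups, and summarises the clinical contrasts between the
#' extreme strata: Kaplan-Meier curves and a Mantel-Cox test for survival,
#' responder fractions for therapy response, and (when a second signature is
#' given) the signature-signature Spearman correlation with its Monte Carlo
#' gene-resampling p-value.
#'
#' @param cohort an `ExpressionMatrix` of patient samples (log2 scale).
#' @param signature the scoring `GeneSet`.
#' @param survival optional `SurvivalRecords` (or data.frame with
#'   `sample_id`, `time`, `event`); strata are attached by sample id.
#' @param response optional `ResponseRecords` (or data.frame with
#'   `sample_id`, `category`).
#' @param signature_b optional second `GeneSet` for the correlation test.
#' @param fraction stratum fraction (default 0.15).
#' @param reps Monte Carlo draws for the correlation null (default 1000).
#' @param seed integer seed; required when `signature_b` is given.
#' @param out_dir optional directory for TSV/JSON outputs.
#' @return list of class `CohortReport` with `scores` (stratified
#'   `ScoreTable`), `km` (per-stratum curves), `logrank`, `response_fractions`,
#'   `correlation` and `params`.
#' @export
run_cohort_analysis <- function(cohort, signature, survival = NULL,
                                response = NULL, signature_b = NULL,
                                fraction = 0.15, reps = 1000, seed = NULL,
                                out_dir = NULL) {
  stopifnot(inherits(cohort, "ExpressionMatrix"),
            inherits(signature, "GeneSet"))
  scores <- stratify(score_cohort(cohort, signature), fraction)
  strat_of <- setNames(scores$stratum, scores$sample_id)

  km <- NULL; lr <- NULL
  if (!is.null(survival)) {
    survival <- as_survival_records(survival)
    missing_s <- setdiff(survival$sample_id, scores$sample_id)
    if (length(missing_s))
      stop("survival records for unknown sample(s): ",
           paste(missing_s, collapse = ", "))
    survival$stratum <- unname(strat_of[survival$sample_id])
    hi <- survival[survival$stratum == "high", , drop = FALSE]
    lo <- survival[survival$stratum == "low", , drop = FALSE]
    km <- list(high = km_curve(hi), low = km_curve(lo))
    lr <- logrank_test(hi, lo)
  }

  rf <- NULL
  if (!is.null(response)) {
    if (!inherits(response, "ResponseRecords"))
      response <- response_records(response$sample_id, response$category)
    response$stratum <- unname(strat_of[response$sample_id])
    extreme <- response[response$stratum %in% c("high", "low"), ,
                        drop = FALSE]
    rf <- response_fraction(extreme)
  }

  corr <- NULL
  if (!is.null(signature_b)) {
    stopifnot(inherits(signature_b, "GeneSet"))
    if (is.null(seed))
      stop("`seed` is required for the Monte Carlo correlation test")
    scores_b <- score_cohort(cohort, signature_b)
    corr <- mc_correlation_pvalue(cohort, signature, scores_b,
                                  reps = reps, seed = seed)
  }

  report <- list(scores = scores, km = km, logrank = lr,
                 response_fractions = rf, correlation = corr,
                 params = list(fraction = fraction, reps = reps,
                               seed = seed,
                               coverage = attr(scores, "coverage"),
                               signature = signature$name))
  class(report) <- "CohortReport"
  if (!is.null(out_dir)) write_cohort_report(report, out_dir)
  report
}

#' @export
print.CohortReport <- function(x, ...) {
  n <- table(x$scores$stratum)
  cat(sprintf("Cohort analysis: %d samples (%s), coverage %.2f\n",
              nrow(x$scores),
              paste(names(n), n, sep = "=", collapse = ", "),
              x$params$coverage))
  if (!is.null(x$logrank))
    cat(sprintf("  log-rank high vs low: chisq = %.3f, p = %.3g\n",
                x$logrank$statistic, x$logrank$p_value))
  if (!is.null(x$response_fractions))
    cat("  responder fractions:",
        paste(names(x$response_fractions),
              sprintf("%.2f", x$response_fractions),
              sep = "=", collapse = ", "), "\n")
  if (!is.null(x$correlation))
    cat(sprintf("  signature correlation rho = %.3f, MC p = %.3g\n",
                x$correlation$rho_obs, x$correlation$p_value))
  invisible(x)
}

write_cohort_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.table(report$scores, file.path(out_dir, "scores.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$km))
    for (nm in names(report$km))
      write.table(report$km[[nm]],
                  file.path(out_dir, paste0("km_", nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(
    strata = as.list(table(report$scores$stratum)),
    logrank = report$logrank,
    response_fractions = as.list(report$response_fractions),
    correlation = report$correlation,
    params = report$params)
  jsonlite::write_json(summary, file.path(out_dir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
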