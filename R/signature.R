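#' Derive a pathway signature from a treatment contrast
#'
#' Ranks genes by log2 fold change (treated minus control) and takes the
#' `top_n` most down- (or up-) regulated as the signature — e.g. the top 500
#' genes down-regulated by PERK inhibition in de-differentiated cells. Ties
#' in fold change are broken by gene id (byte order) so the result is
#' deterministic.
#'
#' @param mat an `ExpressionMatrix` (log2 scale).
#' @param treated,control sample-id vectors for the two arms.
#' @param direction `"down"` (default: most negative fold changes first) or
#'   `"up"`.
#' @param top_n signature size; must not exceed the number of genes.
#' @param name name for the returned set.
#' @return A `GeneSet` of `top_n` genes.
#' @export
derive_signature <- function(mat, treated, control,
                             direction = c("down", "up"), top_n = 500,
                             name = "signature") {
  direction <- match.arg(direction)
  if (!is.numeric(top_n) || length(top_n) != 1 || top_n < 1 ||
      top_n != floor(top_n))
    stop("`top_n` must be a positive integer")
  if (top_n > nrow(mat$values))
    stop("`top_n` (", top_n, ") exceeds the number of genes (",
         nrow(mat$values), ")")
  ctr <- contrast_spec(treated, control, fc_threshold = 2)
  lfc <- log2_fold_change(mat, ctr)
  key <- if (direction == "down") lfc else -lfc
  ord <- order(key, names(lfc), method = "radix")
  gene_set(name, names(lfc)[ord[seq_len(top_n)]],
           description = sprintf("top %d %s-regulated genes", top_n, direction))
}

#' Score cohort samples against a signature
#'
#' The per-sample signature score is the sum of log2 expression over the
#' signature genes present in the cohort matrix. Signature genes missing
#' from the cohort are dropped; the retained fraction is reported as
#' `coverage` and a warning is raised below 0.8.
#'
#' @param cohort an `ExpressionMatrix` of the patient cohort (log2 scale).
#' @param signature a `GeneSet`.
#' @return A `ScoreTable`: data.frame with columns `sample_id`, `score` and
#'   `stratum` (all `"mid"` until [stratify()] is applied), plus attributes
#'   `coverage` and `signature`.
#' @export
score_cohort <- function(cohort, signature) {
  stopifnot(inherits(cohort, "ExpressionMatrix"),
            inherits(signature, "GeneSet"))
  common <- intersect(signature$members, genes(cohort))
  coverage <- length(common) / length(signature$members)
  if (!length(common))
    stop("no signature gene is present in the cohort matrix (zero coverage)")
  if (coverage < 0.8)
    warning(sprintf("signature coverage %.2f < 0.8: %d of %d genes present",
                    coverage, length(common), length(signature$members)))
  scores <- colSums(cohort$values[common, , drop = FALSE])
  out <- data.frame(sample_id = samples(cohort), score = unname(scores),
                    stratum = "mid", stringsAsFactors = FALSE)
  structure(out, coverage = coverage, signature = signature$name,
            class = c("ScoreTable", "data.frame"))
}

#' Stratify a cohort into high / low / mid signature strata
#'
#' Labels the `floor(fraction * n)` highest-scoring samples `"high"`, the
#' same number of lowest-scoring samples `"low"`, and the remainder `"mid"`
#' (the 15 percent rule of the source analyses is `fraction = 0.15`). A
#' single ascending sort on (score, sample id) resolves ties
#' deterministically and keeps the two strata disjoint even when all scores
#' are equal.
#'
#' @param scores a `ScoreTable` from [score_cohort()].
#' @param fraction stratum fraction in (0, 0.5].
#' @return The `ScoreTable` with its `stratum` column filled.
#' @export
stratify <- function(scores, fraction = 0.15) {
  stopifnot(inherits(scores, "ScoreTable"))
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 0.5)
    stop("`fraction` must lie in (0, 0.5]")
  n <- nrow(scores)
  if (n < ceiling(1 / fraction))
    stop("too few samples (", n, ") for fraction ", fraction,
         ": need at least ", ceiling(1 / fraction))
  m <- floor(fraction * n)
  ord <- order(scores$score, scores$sample_id, method = "radix")
  stratum <- rep("mid", n)
  stratum[ord[seq_len(m)]] <- "low"
  stratum[ord[seq.int(n - m + 1L, n)]] <- "high"
  scores$stratum <- stratum
  scores
}

#' Spearman rank correlation with midranks
#'
#' Pearson correlation of average-ranked values (midranks for ties), the
#' standard tie-aware Spearman rho.
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return correlation in \[-1, 1\].
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  if (diff(range(x)) == 0 || diff(range(y)) == 0)
    stop("Spearman correlation is undefined for a constant vector")
  stats::cor(rank(x, ties.method = "average"),
             rank(y, ties.method = "average"))
}

#' Monte Carlo p-value for a signature-signature correlation
#'
#' Observed statistic: Spearman rho between the cohort's scores under
#' `signature_a` and a second score vector `scores_b`. Null: `reps` random
#' gene sets of the same effective size (the number of signature genes
#' present in the cohort), drawn uniformly without replacement from the
#' cohort's measured genes, each scored and correlated with `scores_b`. The
#' two-sided empirical p-value uses the add-one rule
#' `(1 + #\{|rho_null| >= |rho_obs|\}) / (reps + 1)`, so it is never 0.
#'
#' @param cohort an `ExpressionMatrix`.
#' @param signature_a a `GeneSet` with at least one gene in the cohort.
#' @param scores_b a `ScoreTable` or a numeric vector named by sample id,
#'   covering every cohort sample.
#' @param reps number of Monte Carlo draws, at least 100.
#' @param seed integer seed; required, so results are reproducible.
#' @return list with `rho_obs`, `p_value`, `reps` and `set_size` (the
#'   effective signature size used for the null).
#' @export
mc_correlation_pvalue <- function(cohort, signature_a, scores_b,
                                  reps = 1000, seed) {
  stopifnot(inherits(cohort, "ExpressionMatrix"))
  if (!is.numeric(reps) || length(reps) != 1 || reps < 100)
    stop("`reps` must be a single number >= 100")
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1)
    stop("an integer `seed` is required for the Monte Carlo null")
  if (inherits(scores_b, "ScoreTable"))
    scores_b <- setNames(scores_b$score, scores_b$sample_id)
  if (is.null(names(scores_b)))
    stop("`scores_b` must be named by sample id")
  missing_s <- setdiff(samples(cohort), names(scores_b))
  if (length(missing_s))
    stop("`scores_b` is missing cohort sample(s): ",
         paste(missing_s, collapse = ", "))
  scores_b <- scores_b[samples(cohort)]

  sa <- score_cohort(cohort, signature_a)
  rho_obs <- spearman_rho(sa$score, scores_b)
  size <- length(intersect(signature_a$members, genes(cohort)))

  ng <- nrow(cohort$values)
  rb <- rank(scores_b, ties.method = "average")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))
  rho_null <- vapply(seq_len(reps), function(r) {
    idx <- sample.int(ng, size)
    s <- colSums(cohort$values[idx, , drop = FALSE])
    if (diff(range(s)) == 0) return(0)
    stats::cor(rank(s, ties.method = "average"), rb)
  }, numeric(1))
  p <- (1 + sum(abs(rho_null) >= abs(rho_obs))) / (reps + 1)
  list(rho_obs = rho_obs, p_value = p, reps = as.integer(reps),
       set_size = size)
}
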