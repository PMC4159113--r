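#' Parameters for the simulated cell-line experiment
#'
#' Defines a two-genotype (differentiated / de-differentiated) by treatment
#' (vehicle / oxidant, plus an optional inhibitor arm for the
#' de-differentiated genotype) expression design with planted gene sets
#' whose default sizes mirror the analysed study design: 181 and 170
#' oxidant-induced genes in the two genotypes, 44 commonly induced, 54
#' preactivated (of which 16 are also induced in the de-differentiated
#' cells, leaving 38 uniquely induced), and 847 genes up- plus 847 down-
#' regulated between the genotypes at baseline (a 1,694-gene differential
#' union).
#'
#' @param n_genes number of genes (default 10000).
#' @param replicates replicate arrays per arm (default 3).
#' @param baseline_mean,baseline_sd log2 baseline distribution of gene means
#'   (defaults 7, 1.5).
#' @param noise_sd per-measurement Gaussian noise SD in log2 units
#'   (default 0.3; set 0 for exact recovery).
#' @param ros_induced_diff,ros_induced_dediff sizes of the oxidant-induced
#'   sets in the differentiated / de-differentiated genotype (181 / 170).
#' @param common_induced genes induced in both genotypes (44).
#' @param preactivated induced-in-differentiated genes that are basally up
#'   in the de-differentiated genotype (54).
#' @param preactivated_induced_dediff preactivated genes that are also
#'   oxidant-induced in the de-differentiated genotype (16; the remaining 38
#'   are "uniquely induced").
#' @param dediff_up_total,dediff_down_total genes basally up / down in the
#'   de-differentiated genotype (847 each).
#' @param inhibitor_down genes down-regulated by the inhibitor in the
#'   de-differentiated genotype (500); 0 disables the inhibitor arm.
#' @param delta planted effect size in log2 units (default 1.5; must exceed
#'   1 for recovery at a 2-fold threshold).
#' @param seed integer seed.
#' @return validated parameter list of class `CellLineSimParams`.
#' @export
cellline_sim_params <- function(n_genes = 10000, replicates = 3,
                                baseline_mean = 7, baseline_sd = 1.5,
                                noise_sd = 0.3,
                                ros_induced_diff = 181,
                                ros_induced_dediff = 170,
                                common_induced = 44,
                                preactivated = 54,
                                preactivated_induced_dediff = 16,
                                dediff_up_total = 847,
                                dediff_down_total = 847,
                                inhibitor_down = 500,
                                delta = 1.5, seed = 1L) {
  p <- as.list(environment())
  counts <- p[c("n_genes", "replicates", "ros_induced_diff",
                "ros_induced_dediff", "common_induced", "preactivated",
                "preactivated_induced_dediff", "dediff_up_total",
                "dediff_down_total", "inhibitor_down")]
  if (any(!vapply(counts, function(v)
    is.numeric(v) && length(v) == 1 && v >= 0 && v == floor(v), logical(1))))
    stop("all set sizes and counts must be nonnegative integers")
  if (p$replicates < 1) stop("need at least one replicate per arm")
  if (p$common_induced > min(p$ros_induced_diff, p$ros_induced_dediff))
    stop("common_induced exceeds an induced-set size")
  if (p$preactivated > p$ros_induced_diff ||
      p$preactivated > p$dediff_up_total)
    stop("preactivated must fit inside ros_induced_diff and dediff_up_total")
  if (p$preactivated_induced_dediff > min(p$preactivated, p$common_induced))
    stop("preactivated_induced_dediff exceeds preactivated or common_induced")
  if (p$delta <= 0) stop("`delta` must be positive")
  if (p$noise_sd < 0 || p$baseline_sd < 0) stop("SDs must be nonnegative")
  # distinct gene blocks needed (see simulate_cellline_experiment layout)
  used <- p$ros_induced_diff + (p$ros_induced_dediff - p$common_induced) +
    (p$dediff_up_total - p$preactivated) + p$dediff_down_total +
    p$inhibitor_down
  if (used > p$n_genes)
    stop("planted sets need ", used, " genes but n_genes = ", p$n_genes)
  structure(p, class = "CellLineSimParams")
}

#' Simulate the cell-line expression experiment with planted truth
#'
#' Gaussian log2 expression: per-gene baselines, additive planted effects of
#' size `delta` in the designated arms, and iid noise. Arms are
#' genotype x treatment with `replicates` columns each:
#' `differentiated_vehicle`, `differentiated_oxidant`,
#' `dedifferentiated_vehicle`, `dedifferentiated_oxidant`, and (when
#' `inhibitor_down > 0`) `dedifferentiated_inhibitor`.
#'
#' The planted layout realises every overlap constraint of the design:
#' the common-induced genes are induced in both genotypes, the preactivated
#' genes are the intersection of the differentiated-cell induced set with
#' the basal de-differentiated up-set, and exactly
#' `preactivated_induced_dediff` of them are also induced in the
#' de-differentiated genotype.
#'
#' @param params a [cellline_sim_params()] object.
#' @return list with `expression` (an `ExpressionMatrix` whose metadata has
#'   `genotype` and `treatment` columns) and `truth`, a named list of
#'   `GeneSet` objects: `ros_induced_diff`, `ros_induced_dediff`,
#'   `common_induced`, `preactivated`, `uniquely_induced`, `dediff_up`,
#'   `dediff_down`, `differential`, `inhibitor_down`.
#' @export
simulate_cellline_experiment <- function(params = cellline_sim_params()) {
  stopifnot(inherits(params, "CellLineSimParams"))
  p <- params
  set.seed(as.integer(p$seed))
  ids <- sprintf("g%05d", seq_len(p$n_genes))

  # sequential index blocks; letters follow the overlap algebra:
  #   A = induced in differentiated, B = induced in de-differentiated,
  #   D = basally up in de-differentiated
  n_ABD <- p$preactivated_induced_dediff          # A & B & D
  n_AB  <- p$common_induced - n_ABD               # A & B, not D
  n_AD  <- p$preactivated - n_ABD                 # A & D, not B
  n_A   <- p$ros_induced_diff - p$common_induced - n_AD  # A only
  n_B   <- p$ros_induced_dediff - p$common_induced       # B only
  n_D   <- p$dediff_up_total - p$preactivated            # D only
  if (n_A < 0)
    stop("preactivated genes outside the common-induced overlap (",
         n_AD, ") exceed the induced-only pool")
  sizes <- c(n_ABD, n_AB, n_AD, n_A, n_B, n_D,
             p$dediff_down_total, p$inhibitor_down)
  stops <- cumsum(sizes)
  starts <- c(1, head(stops, -1) + 1)
  block <- function(i) if (sizes[i] == 0) integer(0) else starts[i]:stops[i]

  idx_A <- c(block(1), block(2), block(3), block(4))
  idx_B <- c(block(1), block(2), block(5))
  idx_D <- c(block(1), block(3), block(6))
  idx_down <- block(7)
  idx_inh <- block(8)

  arms <- data.frame(
    genotype = c("differentiated", "differentiated",
                 "dedifferentiated", "dedifferentiated"),
    treatment = c("vehicle", "oxidant", "vehicle", "oxidant"),
    stringsAsFactors = FALSE)
  if (p$inhibitor_down > 0)
    arms <- rbind(arms, data.frame(genotype = "dedifferentiated",
                                   treatment = "inhibitor"))

  mu <- rnorm(p$n_genes, p$baseline_mean, p$baseline_sd)
  cols <- list(); meta <- list()
  for (a in seq_len(nrow(arms))) {
    g <- arms$genotype[a]; tr <- arms$treatment[a]
    m <- mu
    if (g == "dedifferentiated") {
      m[idx_D] <- m[idx_D] + p$delta
      m[idx_down] <- m[idx_down] - p$delta
    }
    if (tr == "oxidant") {
      if (g == "differentiated") m[idx_A] <- m[idx_A] + p$delta
      else m[idx_B] <- m[idx_B] + p$delta
    }
    if (tr == "inhibitor") m[idx_inh] <- m[idx_inh] - p$delta
    for (r in seq_len(p$replicates)) {
      nm <- sprintf("%s_%s_%d", g, tr, r)
      cols[[nm]] <- m + rnorm(p$n_genes, 0, p$noise_sd)
      meta[[nm]] <- data.frame(sample_id = nm, genotype = g, treatment = tr,
                               stringsAsFactors = FALSE)
    }
  }
  vals <- do.call(cbind, cols)
  rownames(vals) <- ids
  md <- do.call(rbind, meta)
  expr <- expression_matrix(vals, md)

  truth <- list(
    ros_induced_diff = gene_set("ros_induced_diff", gs_sorted(ids[idx_A])),
    ros_induced_dediff = gene_set("ros_induced_dediff", gs_sorted(ids[idx_B])),
    common_induced = gene_set("common_induced",
                              gs_sorted(ids[intersect(idx_A, idx_B)])),
    preactivated = gene_set("preactivated",
                            gs_sorted(ids[intersect(idx_A, idx_D)])),
    uniquely_induced = gene_set("uniquely_induced",
                                gs_sorted(ids[setdiff(intersect(idx_A, idx_D),
                                                      idx_B)])),
    dediff_up = gene_set("dediff_up", gs_sorted(ids[idx_D])),
    dediff_down = gene_set("dediff_down", gs_sorted(ids[idx_down])),
    differential = gene_set("differential",
                            gs_sorted(ids[c(idx_D, idx_down)])),
    inhibitor_down = gene_set("inhibitor_down", gs_sorted(ids[idx_inh])))
  list(expression = expr, truth = truth)
}

#' Parameters for the simulated patient cohort
#'
#' A latent per-patient pathway activity drives three observables at once:
#' expression of the signature genes (loading `beta`), the survival hazard
#' (log hazard ratio `log_hr` per activity SD on an exponential baseline),
#' and the probability of therapy response (logistic in minus the activity).
#'
#' @param n_samples cohort size (default 200).
#' @param n_genes measured genes (default 5000).
#' @param signature_size planted signature genes (default 500).
#' @param beta expression loading of the activity on signature genes, log2
#'   units per activity SD (default 0.8).
#' @param noise_sd residual expression SD (default 0.5).
#' @param baseline_mean,baseline_sd per-gene baseline distribution (7, 1.5).
#' @param lambda0 baseline exponential hazard per unit time (default 0.05).
#' @param log_hr log hazard ratio per activity SD (default `log(2.5)`).
#' @param censor_time administrative censoring horizon (default 60).
#' @param alpha,kappa intercept and activity slope of the responder model
#'   `P(responder) = plogis(alpha - kappa * a)` (defaults 1, 1.5): high
#'   activity lowers the response probability.
#' @param seed integer seed.
#' @return validated parameter list of class `CohortSimParams`.
#' @export
cohort_sim_params <- function(n_samples = 200, n_genes = 5000,
                              signature_size = 500, beta = 0.8,
                              noise_sd = 0.5, baseline_mean = 7,
                              baseline_sd = 1.5, lambda0 = 0.05,
                              log_hr = log(2.5), censor_time = 60,
                              alpha = 1, kappa = 1.5, seed = 1L) {
  p <- as.list(environment())
  if (p$signature_size > p$n_genes)
    stop("signature_size exceeds n_genes")
  if (p$n_samples < 2) stop("need at least two samples")
  if (p$lambda0 <= 0 || p$censor_time <= 0)
    stop("hazard and censoring horizon must be positive")
  if (p$noise_sd < 0 || p$baseline_sd < 0) stop("SDs must be nonnegative")
  structure(p, class = "CohortSimParams")
}

#' Simulate a patient cohort driven by a latent pathway activity
#'
#' Expression: `x[g, i] = mu_g + beta * a_i + noise` for signature genes,
#' `mu_g + noise` otherwise, with activities `a_i ~ N(0, 1)`. Survival:
#' exponential event times with rate `lambda0 * exp(log_hr * a_i)`,
#' administratively censored at `censor_time`. Response: Bernoulli
#' responders with probability `plogis(alpha - kappa * a_i)`; responders
#' split evenly between complete and partial response.
#'
#' @param params a [cohort_sim_params()] object.
#' @return list with `expression` (`ExpressionMatrix`), `survival`
#'   (`SurvivalRecords`, stratum unset), `response` (`ResponseRecords`,
#'   stratum unset), `activity` (named numeric vector of the latent truth)
#'   and `signature` (the planted `GeneSet`).
#' @export
simulate_cohort <- function(params = cohort_sim_params()) {
  stopifnot(inherits(params, "CohortSimParams"))
  p <- params
  set.seed(as.integer(p$seed))
  gids <- sprintf("G%05d", seq_len(p$n_genes))
  sids <- sprintf("patient_%03d", seq_len(p$n_samples))
  a <- rnorm(p$n_samples)
  mu <- rnorm(p$n_genes, p$baseline_mean, p$baseline_sd)
  sig_idx <- seq_len(p$signature_size)
  vals <- matrix(rnorm(p$n_genes * p$n_samples, 0, p$noise_sd),
                 p$n_genes, p$n_samples) + mu
  vals[sig_idx, ] <- vals[sig_idx, ] + p$beta * rep(a, each = p$signature_size)
  dimnames(vals) <- list(gids, sids)
  md <- data.frame(sample_id = sids, activity = a, stringsAsFactors = FALSE)

  t_event <- rexp(p$n_samples, rate = p$lambda0 * exp(p$log_hr * a))
  observed <- t_event <= p$censor_time
  surv <- survival_records(sids, pmin(t_event, p$censor_time), observed)

  p_resp <- plogis(p$alpha - p$kappa * a)
  responder <- runif(p$n_samples) < p_resp
  complete <- rbinom(p$n_samples, 1, 0.5) == 1
  category <- ifelse(responder, ifelse(complete, "complete", "partial"),
                     "stable_progressive")
  resp <- response_records(sids, category)

  list(expression = expression_matrix(vals, md),
       survival = surv,
       response = resp,
       activity = setNames(a, sids),
       signature = gene_set("planted_signature", gids[sig_idx]))
}
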