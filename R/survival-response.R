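#' Assemble survival records
#'
#' @param sample_id character vector of unique sample ids.
#' @param time nonnegative follow-up times (study units).
#' @param event logical (or 0/1): `TRUE` = event observed, `FALSE` =
#'   censored.
#' @param stratum stratum labels (e.g. `"high"` / `"low"`); may be `NA`
#'   until a stratification is attached.
#' @return data.frame of class `SurvivalRecords`.
#' @export
survival_records <- function(sample_id, time, event, stratum = NA_character_) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop("duplicate sample ids")
  time <- as.numeric(time)
  if (anyNA(time) || any(time < 0)) stop("times must be nonnegative")
  if (is.numeric(event)) event <- event != 0
  if (!is.logical(event) || anyNA(event))
    stop("`event` must be logical (TRUE = event, FALSE = censored)")
  structure(data.frame(sample_id = sample_id, time = time, event = event,
                       stratum = as.character(stratum),
                       stringsAsFactors = FALSE),
            class = c("SurvivalRecords", "data.frame"))
}

as_survival_records <- function(x) {
  if (inherits(x, "SurvivalRecords")) return(x)
  stopifnot(is.data.frame(x),
            all(c("sample_id", "time", "event") %in% names(x)))
  survival_records(x$sample_id, x$time, x$event,
                   if ("stratum" %in% names(x)) x$stratum else NA_character_)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator: at each distinct event time with `d` events and
#' `r` at risk, the survival probability is multiplied by `(1 - d/r)`;
#' censored observations leave the estimate unchanged and only shrink the
#' risk set. Events at a time coincide with censorings there are counted
#' first (the standard convention). Estimation is delegated to
#' [survival::survfit()].
#'
#' @param records a `SurvivalRecords` data.frame (or one coercible to it).
#' @return data.frame with columns `time`, `n_risk`, `n_event`, `n_censor`
#'   and `survival`, starting from the row (0, n, 0, 0, 1).
#' @export
km_curve <- function(records) {
  records <- as_survival_records(records)
  if (!nrow(records)) stop("need at least one record")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records,
                           conf.type = "none")
  data.frame(
    time = c(0, fit$time),
    n_risk = c(nrow(records), fit$n.risk),
    n_event = c(0, fit$n.event),
    n_censor = c(0, fit$n.censor),
    survival = c(1, fit$surv))
}

#' Mantel-Cox (log-rank) test between two survival groups
#'
#' Standard log-rank: over the pooled distinct event times, the observed
#' minus expected event counts for one group are accumulated with their
#' hypergeometric variances; the statistic `(sum(O-E))^2 / sum(V)` is
#' referred to a chi-square distribution with 1 degree of freedom (no
#' continuity correction). Computation is delegated to
#' [survival::survdiff()].
#'
#' @param group_a,group_b non-empty `SurvivalRecords` (or coercible
#'   data.frames); at least one event must occur overall.
#' @return list with `statistic` (chi-square), `p_value`, and per-group
#'   `observed` / `expected` event counts (group order: a, b).
#' @export
logrank_test <- function(group_a, group_b) {
  group_a <- as_survival_records(group_a)
  group_b <- as_survival_records(group_b)
  if (!nrow(group_a) || !nrow(group_b))
    stop("both groups must be non-empty")
  pooled <- data.frame(
    time = c(group_a$time, group_b$time),
    event = c(group_a$event, group_b$event),
    group = rep(c("a", "b"), c(nrow(group_a), nrow(group_b))))
  if (!any(pooled$event))
    stop("log-rank test needs at least one observed event")
  fit <- survival::survdiff(survival::Surv(time, event) ~ group,
                            data = pooled, rho = 0)
  list(statistic = unname(fit$chisq),
       p_value = stats::pchisq(unname(fit$chisq), df = 1,
                               lower.tail = FALSE),
       observed = unname(fit$obs),
       expected = unname(fit$exp))
}

response_categories <- c("complete", "partial", "stable_progressive")

#' Assemble therapy-response records
#'
#' @param sample_id character vector of unique sample ids.
#' @param category response category, one of `"complete"`, `"partial"`,
#'   `"stable_progressive"`.
#' @param stratum stratum labels.
#' @return data.frame of class `ResponseRecords`.
#' @export
response_records <- function(sample_id, category, stratum = NA_character_) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop("duplicate sample ids")
  category <- as.character(category)
  bad <- setdiff(unique(category), response_categories)
  if (length(bad))
    stop("unknown response categor(ies): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(response_categories, collapse = ", "), ")")
  structure(data.frame(sample_id = sample_id, category = category,
                       stratum = as.character(stratum),
                       stringsAsFactors = FALSE),
            class = c("ResponseRecords", "data.frame"))
}

#' Responder fraction per stratum
#'
#' A responder shows complete or partial response; the fraction is
#' responders over stratum size.
#'
#' @param records a `ResponseRecords` data.frame (or coercible: columns
#'   `sample_id`, `category`, `stratum`); every stratum present must be
#'   non-empty and no stratum label may be missing.
#' @return named numeric vector, stratum -> responder fraction.
#' @export
response_fraction <- function(records) {
  if (!inherits(records, "ResponseRecords"))
    records <- response_records(records$sample_id, records$category,
                                records$stratum)
  if (!nrow(records)) stop("no response records")
  if (anyNA(records$stratum))
    stop("every response record needs a stratum label")
  resp <- records$category %in% c("complete", "partial")
  frac <- tapply(resp, records$stratum, mean)
  out <- as.numeric(frac)
  names(out) <- names(frac)
  out
}
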