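#' Configure the exhaustive model search
#'
#' @param n_assets total number of model variables, including the forced
#'   rural/urban setting variable (default 5, i.e. "five questions").
#' @param k_min,k_max inclusive range of cluster counts evaluated.
#' @param mode `"threshold"` selects the smallest k in the range whose best
#'   candidate reaches `asw_threshold` average silhouette width, then the
#'   asset combination with the highest ASW at that k (falling back to
#'   `"max_asw"` with a warning when no k qualifies); `"max_asw"` selects
#'   the global ASW argmax over all (subset, k) candidates.
#' @param asw_threshold ASW level defining a "strong" clustering
#'   (default 0.70, the Kaufman–Rousseeuw convention).
#' @param min_prevalence two-level ownership variables whose survey-weighted
#'   positive prevalence is below this fraction are excluded from the
#'   candidate pool (default 0.10); multi-level variables always qualify.
#' @param forced_variables variables included in every candidate subset;
#'   `NULL` (default) means the survey's setting variable.
#' @param seed integer; recorded for provenance (the search itself is
#'   deterministic).
#' @return an object of class `ec_config`.
#' @export
ec_config <- function(n_assets = 5L, k_min = 5L, k_max = 20L,
                      mode = c("threshold", "max_asw"), asw_threshold = 0.70,
                      min_prevalence = 0.10, forced_variables = NULL,
                      seed = NULL) {
  mode <- match.arg(mode)
  n_assets <- as.integer(n_assets); k_min <- as.integer(k_min)
  k_max <- as.integer(k_max)
  stopifnot(n_assets >= 2L, k_min >= 2L, k_max >= k_min,
            asw_threshold > 0, asw_threshold <= 1,
            min_prevalence >= 0, min_prevalence < 1)
  structure(list(n_assets = n_assets, k_min = k_min, k_max = k_max,
                 mode = mode, asw_threshold = asw_threshold,
                 min_prevalence = min_prevalence,
                 forced_variables = forced_variables,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "ec_config")
}

#' Variables eligible for the candidate pool
#'
#' Applies the prevalence filter: a two-level ownership variable qualifies
#' iff the survey-weighted proportion of its positive level (the second
#' declared level; declare levels as `c("no", "yes")`) is at least
#' `min_prevalence` among households observed on it.  Multi-level variables
#' and forced variables always qualify.
#'
#' @param table an `ec_households` table.
#' @param min_prevalence fraction in `[0, 1)`.
#' @param forced_variables always-eligible variables; default the setting
#'   variable.
#' @return character vector of eligible variable names, forced variables
#'   first, others in declaration order.
#' @export
eligible_variables <- function(table, min_prevalence = 0.10,
                               forced_variables = NULL) {
  cfg <- attr(table, "ec_config")
  vars <- config_variables(cfg)
  if (is.null(forced_variables)) forced_variables <- cfg$setting
  absent <- setdiff(forced_variables, names(vars))
  if (length(absent))
    stop("forced variable(s) absent from table: ",
         paste(absent, collapse = ", "), call. = FALSE)
  keep <- vapply(names(vars), function(v) {
    if (v %in% forced_variables) return(TRUE)
    lv <- vars[[v]]
    if (length(lv) != 2L) return(TRUE)
    x <- table[[v]]
    obs <- !is.na(x)
    if (!any(obs)) return(FALSE)
    p <- sum(table$weight[obs & x == lv[2L]]) / sum(table$weight[obs])
    p >= min_prevalence
  }, logical(1L))
  elig <- names(vars)[keep]
  c(forced_variables, setdiff(elig, forced_variables))
}

#' Enumerate (asset subset, k) candidates
#'
#' Every subset of `n_assets` eligible variables that contains all forced
#' variables, crossed with every k in the configured range, in deterministic
#' lexicographic order.
#'
#' @param eligible character vector from [eligible_variables()] (forced
#'   variables first).
#' @param config an [ec_config()].
#' @return list with `subsets` (list of character vectors) and `k_values`.
#' @export
enumerate_candidates <- function(eligible, config) {
  forced <- config$forced_variables %||% character(0)
  if (length(setdiff(forced, eligible)))
    stop("forced variable(s) not among the eligible variables", call. = FALSE)
  free <- setdiff(eligible, forced)
  m <- config$n_assets - length(forced)
  if (m < 0L) stop("more forced variables than n_assets", call. = FALSE)
  if (m > length(free))
    stop(sprintf("n_assets = %d exceeds the %d eligible variables",
                 config$n_assets, length(free) + length(forced)),
         call. = FALSE)
  combos <- if (m == 0L) matrix(character(0), nrow = 0L, ncol = 1L)
            else utils::combn(free, m)
  subsets <- lapply(seq_len(ncol(combos)), function(j)
    c(forced, combos[, j]))
  list(subsets = subsets, k_values = seq(config$k_min, config$k_max))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Score one candidate model
#'
#' Pipeline: aggregate the complete-case table into distinct profiles over
#' the subset, compute the Gower matrix, run weighted PAM at the requested
#' k, and compute the weighted ASW.  A candidate with fewer distinct
#' profiles than k is recorded as infeasible rather than raising an error.
#'
#' @param table complete-case `ec_households` table.
#' @param subset character vector of model variables.
#' @param k number of clusters.
#' @return one-row data.frame: assets (joined by "+"), k, asw, n_profiles,
#'   total_cost, feasible.
#' @export
score_candidate <- function(table, subset, k) {
  prof <- aggregate_profiles(table, subset)
  score_profiles(prof, k)$score
}

score_profiles <- function(prof, k, d = NULL) {
  assets <- paste(prof$variables, collapse = "+")
  if (prof$n_profiles < max(k, 2L)) {
    return(list(score = data.frame(assets = assets, k = k, asw = NA_real_,
                                   n_profiles = prof$n_profiles,
                                   total_cost = NA_real_, feasible = FALSE,
                                   stringsAsFactors = FALSE)))
  }
  if (is.null(d)) d <- gower_matrix(prof)
  fit <- weighted_pam(d, prof$weight, k)
  sil <- if (k >= 2L) weighted_asw(d, prof$weight, fit$labels)$asw
         else NA_real_
  list(score = data.frame(assets = assets, k = k, asw = sil,
                          n_profiles = prof$n_profiles,
                          total_cost = fit$total_cost, feasible = TRUE,
                          stringsAsFactors = FALSE),
       fit = fit, d = d)
}

#' Select the final model from a candidate score table
#'
#' Threshold mode implements the "smallest strong k" rule: among the k whose
#' best candidate ASW reaches the threshold, take the smallest, then the
#' asset combination with the highest ASW at that k.  If no k qualifies the
#' rule falls back to the global ASW maximum with a warning.  Ties on ASW
#' resolve to the lexicographically first asset subset, then the smaller k.
#'
#' @param scores data.frame of candidate scores (from the search loop).
#' @param config an [ec_config()].
#' @return list with `assets`, `k`, `asw`, `rule_used`, `warnings`.
#' @export
select_model <- function(scores, config) {
  feas <- scores[scores$feasible & !is.na(scores$asw), , drop = FALSE]
  if (nrow(feas) == 0L) stop("no feasible candidate model", call. = FALSE)
  warnings <- character(0)
  pick_best <- function(rows) {
    top <- rows[rows$asw >= max(rows$asw) - 0, , drop = FALSE]
    top <- top[order(top$assets, top$k), , drop = FALSE]
    top[1L, , drop = FALSE]
  }
  rule <- config$mode
  if (config$mode == "threshold") {
    best_per_k <- tapply(feas$asw, feas$k, max)
    ok <- as.integer(names(best_per_k))[best_per_k >= config$asw_threshold]
    if (length(ok)) {
      k_star <- min(ok)
      chosen <- pick_best(feas[feas$k == k_star, , drop = FALSE])
    } else {
      msg <- sprintf(paste0("no k in %d..%d reaches ASW threshold %.2f; ",
                            "falling back to the max-ASW model"),
                     config$k_min, config$k_max, config$asw_threshold)
      warning(msg, call. = FALSE)
      warnings <- c(warnings, msg)
      rule <- "max_asw_fallback"
      chosen <- pick_best(feas)
    }
  } else {
    chosen <- pick_best(feas)
  }
  list(assets = strsplit(chosen$assets, "+", fixed = TRUE)[[1L]],
       k = chosen$k, asw = chosen$asw, rule_used = rule, warnings = warnings)
}

#' Exhaustive search for the best few-asset economic clustering model
#'
#' The main fitting routine: filters variables by weighted prevalence,
#' filters households to complete cases on the eligible variables,
#' enumerates every subset of `n_assets` variables containing the forced
#' setting variable crossed with every cluster count in the range, scores
#' each candidate by weighted-PAM + weighted-ASW on the Gower matrix of its
#' asset-answer profiles, and applies the configured selection rule.
#'
#' @param table an `ec_households` table.
#' @param config an [ec_config()].
#' @param verbose print progress every `report_every` subsets.
#' @param report_every integer.
#' @return an object of class `ec_search`: list with `scores` (all
#'   candidates), `model` (the selected [ec_model]), `eligible`,
#'   `filter_report`, `warnings`.
#' @export
ec_search <- function(table, config = ec_config(), verbose = FALSE,
                      report_every = 25L) {
  stopifnot(inherits(table, "ec_households"), inherits(config, "ec_config"))
  cfg <- attr(table, "ec_config")
  if (is.null(config$forced_variables))
    config$forced_variables <- cfg$setting
  elig <- eligible_variables(table, config$min_prevalence,
                             config$forced_variables)
  cc <- complete_case_filter(table, elig)
  cand <- enumerate_candidates(elig, config)
  scores <- vector("list", length(cand$subsets))
  for (i in seq_along(cand$subsets)) {
    subset <- cand$subsets[[i]]
    prof <- aggregate_profiles(cc, subset)
    d <- if (prof$n_profiles >= 2L) gower_matrix(prof) else NULL
    rows <- lapply(cand$k_values, function(k)
      score_profiles(prof, k, d)$score)
    scores[[i]] <- do.call(rbind, rows)
    if (verbose && i %% report_every == 0L)
      message(sprintf("scored %d / %d subsets", i, length(cand$subsets)))
  }
  scores <- do.call(rbind, scores)
  sel <- withCallingHandlers(
    select_model(scores, config),
    warning = function(w) invokeRestart("muffleWarning"))
  if (length(sel$warnings)) for (msg in sel$warnings) warning(msg, call. = FALSE)
  model <- fit_model(cc, sel$assets, sel$k, config,
                     rule_used = sel$rule_used)
  structure(list(scores = scores, model = model, eligible = elig,
                 filter_report = attr(cc, "ec_filter_report"),
                 warnings = sel$warnings),
            class = "ec_search")
}

#' @export
print.ec_search <- function(x, ...) {
  cat(sprintf("Model search over %d candidates (%d feasible)\n",
              nrow(x$scores), sum(x$scores$feasible)))
  print(x$model)
  invisible(x)
}

#' Fit a clustering model for a fixed asset subset and k
#'
#' @param table complete-case `ec_households` table.
#' @param assets character vector of model variables.
#' @param k number of clusters.
#' @param config the [ec_config()] used (stored for provenance).
#' @param rule_used selection-rule tag stored in the model.
#' @return an object of class `ec_model`: asset names, k, medoid profiles,
#'   per-profile and per-household cluster assignment, ASW, level sets,
#'   config and a reference-data fingerprint.
#' @export
fit_model <- function(table, assets, k, config = NULL,
                      rule_used = "fixed") {
  cc <- complete_case_filter(table, assets)
  prof <- aggregate_profiles(cc, assets)
  d <- gower_matrix(prof)
  fit <- weighted_pam(d, prof$weight, k)
  sil <- weighted_asw(d, prof$weight, fit$labels)
  assignment <- rep(fit$labels, lengths(prof$members))
  names(assignment) <- unlist(prof$members, use.names = FALSE)
  assignment <- assignment[order(names(assignment))]
  scfg <- attr(table, "ec_config")
  levels_used <- config_variables(scfg)[assets]
  structure(list(
    asset_names = assets, k = as.integer(k),
    medoids = prof$profiles[fit$medoid_indices, , drop = FALSE],
    medoid_indices = fit$medoid_indices,
    profiles = prof$profiles, profile_weight = prof$weight,
    profile_assignment = fit$labels,
    assignment = assignment, asw = sil$asw,
    asset_levels = levels_used,
    setting = scfg$setting,
    config = config, rule_used = rule_used,
    fingerprint = table_fingerprint(table),
    n_households = nrow(cc)),
    class = "ec_model")
}

#' @export
print.ec_model <- function(x, ...) {
  cat(sprintf("Economic clustering model: k = %d clusters, ASW = %.4f\n",
              x$k, x$asw))
  cat("  variables:", paste(x$asset_names, collapse = ", "), "\n")
  cat(sprintf("  fitted on %d households (%d distinct profiles)\n",
              x$n_households, nrow(x$profiles)))
  invisible(x)
}

## Rolling 31-bit polynomial hash of the sorted household ids, plus the row
## count: enough to detect reference-table mismatch at assignment time.
table_fingerprint <- function(table) {
  s <- paste(sort(table$household_id), collapse = ";")
  bytes <- utf8ToInt(s)
  h <- 0
  mod <- 2147483647
  for (b in bytes) h <- (h * 31 + b) %% mod
  list(n = nrow(table), hash = sprintf("%.0f", h))
}
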