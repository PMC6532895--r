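EC_MODEL_SCHEMA <- "econclust-model/1"

#' Write a fitted model to versioned JSON
#'
#' The file stores everything needed to re-apply the model to new
#' participants: the chosen variables and their declared level sets, the
#' medoid profiles, the distinct asset-answer profiles of the reference data
#' with their weights and cluster labels, the per-household assignment, the
#' ASW, the search configuration and a fingerprint of the reference table
#' (row count + hash of sorted household ids).  Round-tripping through
#' [read_model()] is lossless.
#'
#' @param model an `ec_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "ec_model"))
  payload <- list(
    schema = EC_MODEL_SCHEMA,
    asset_names = model$asset_names,
    asset_levels = model$asset_levels,
    setting = model$setting,
    k = model$k,
    medoid_indices = model$medoid_indices,
    profiles = lapply(model$asset_names, function(v)
      as.character(model$profiles[[v]])),
    profile_weight = model$profile_weight,
    profile_assignment = model$profile_assignment,
    assignment_ids = names(model$assignment),
    assignment_cluster = unname(model$assignment),
    asw = model$asw,
    rule_used = model$rule_used,
    config = unclass(model$config),
    fingerprint = model$fingerprint,
    n_households = model$n_households)
  names(payload$profiles) <- model$asset_names
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a model written by [write_model()]
#'
#' @param path JSON file path.
#' @return an `ec_model`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e)
                        stop("cannot parse model file: ", conditionMessage(e),
                             call. = FALSE))
  if (!identical(payload$schema, EC_MODEL_SCHEMA))
    stop("model schema mismatch: expected '", EC_MODEL_SCHEMA,
         "', found '", payload$schema %||% "<none>", "'", call. = FALSE)
  levels_used <- lapply(payload$asset_levels, as.character)
  profiles <- as.data.frame(
    lapply(payload$asset_names, function(v)
      factor(payload$profiles[[v]], levels = levels_used[[v]])),
    col.names = payload$asset_names)
  assignment <- as.integer(payload$assignment_cluster)
  names(assignment) <- payload$assignment_ids
  config <- payload$config
  if (!is.null(config) && length(config)) {
    config$forced_variables <- if (is.null(config$forced_variables)) NULL
                               else as.character(config$forced_variables)
    class(config) <- "ec_config"
  } else config <- NULL
  structure(list(
    asset_names = as.character(payload$asset_names),
    k = as.integer(payload$k),
    medoids = profiles[as.integer(payload$medoid_indices), , drop = FALSE],
    medoid_indices = as.integer(payload$medoid_indices),
    profiles = profiles,
    profile_weight = as.numeric(payload$profile_weight),
    profile_assignment = as.integer(payload$profile_assignment),
    assignment = assignment,
    asw = as.numeric(payload$asw),
    asset_levels = levels_used,
    setting = payload$setting,
    config = config,
    rule_used = payload$rule_used,
    fingerprint = list(n = as.integer(payload$fingerprint$n),
                       hash = payload$fingerprint$hash),
    n_households = as.integer(payload$n_households)),
    class = "ec_model")
}
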