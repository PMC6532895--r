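#' Assign new participants to an existing model's clusters
#'
#' Implements the medoid-matching rule with a two-stage tie-break.
#' Stage 1: a participant's answers are compared with each cluster medoid's
#' profile; agreements are counted over the participant's *non-missing*
#' answers, and a unique best-matching medoid assigns its cluster.
#' Stage 2 (tie): the participant is compared, with the same agreement
#' count, against every reference household the model was fitted on; if all
#' maximally-similar reference households belong to one cluster the
#' participant joins it, otherwise the participant is explicitly
#' `UNASSIGNED`.  A participant with no observed answers is `UNASSIGNED`.
#' No random tie-breaking occurs anywhere.
#'
#' @param participants data.frame with a `participant_id` column and one
#'   column per model variable (character; `NA` or `""` = missing).
#' @param model an `ec_model` (fitted by [ec_search()]/[fit_model()] or
#'   loaded with [read_model()]).
#' @param reference optional `ec_households` table to check against the
#'   model's stored fingerprint; the tie-break itself uses the reference
#'   profiles stored inside the model, so assignments do not depend on
#'   passing `reference`.
#' @return data.frame of class `ec_assignments`: `participant_id`,
#'   `cluster` (integer, `NA` when unassigned), `match_count` (agreements
#'   with the winning medoid; `NA` when unassigned), `method` (one of
#'   `"medoid_match"`, `"reference_tiebreak"`, `"unassigned"`).
#' @export
assign_participants <- function(participants, model, reference = NULL) {
  stopifnot(inherits(model, "ec_model"), is.data.frame(participants))
  if (is.null(participants$participant_id))
    stop("participants need a 'participant_id' column", call. = FALSE)
  extra <- setdiff(setdiff(names(participants), "participant_id"),
                   model$asset_names)
  if (length(extra))
    stop("participant column(s) not in the model: ",
         paste(extra, collapse = ", "), call. = FALSE)
  missing_vars <- setdiff(model$asset_names, names(participants))
  if (length(missing_vars))
    stop("participants lack model variable(s): ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  if (!is.null(reference)) {
    fp <- table_fingerprint(reference)
    if (!identical(fp$hash, model$fingerprint$hash) ||
        !identical(fp$n, model$fingerprint$n))
      warning("reference table does not match the model's data fingerprint",
              call. = FALSE)
  }

  np <- nrow(participants)
  vars <- model$asset_names
  ## participant answers as integer level codes (NA = missing / unobserved)
  P <- matrix(NA_integer_, np, length(vars), dimnames = list(NULL, vars))
  for (v in vars) {
    val <- as.character(participants[[v]])
    val[!is.na(val) & !nzchar(val)] <- NA_character_
    bad <- !is.na(val) & !(val %in% model$asset_levels[[v]])
    if (any(bad))
      stop("variable '", v, "': undeclared level(s) ",
           paste(unique(val[bad]), collapse = ", "), call. = FALSE)
    P[, v] <- match(val, model$asset_levels[[v]])
  }
  M <- vapply(vars, function(v) as.integer(model$medoids[[v]]),
              integer(model$k))                       # k x m
  if (model$k == 1L) M <- matrix(M, nrow = 1L)
  R <- vapply(vars, function(v) as.integer(model$profiles[[v]]),
              integer(nrow(model$profiles)))          # profiles x m

  out <- data.frame(participant_id = as.character(participants$participant_id),
                    cluster = NA_integer_, match_count = NA_integer_,
                    method = "unassigned", stringsAsFactors = FALSE)
  for (i in seq_len(np)) {
    obs <- which(!is.na(P[i, ]))
    if (length(obs) == 0L) next
    agree_med <- rowSums(M[, obs, drop = FALSE] ==
                           matrix(P[i, obs], model$k, length(obs),
                                  byrow = TRUE))
    best <- max(agree_med)
    winners <- which(agree_med == best)
    if (length(winners) == 1L) {
      out$cluster[i] <- winners
      out$match_count[i] <- as.integer(best)
      out$method[i] <- "medoid_match"
      next
    }
    ## stage 2: compare against all reference profiles (each stands for its
    ## member households, which share its answers exactly)
    agree_ref <- rowSums(R[, obs, drop = FALSE] ==
                           matrix(P[i, obs], nrow(R), length(obs),
                                  byrow = TRUE))
    top <- which(agree_ref == max(agree_ref))
    cl <- unique(model$profile_assignment[top])
    if (length(cl) == 1L) {
      out$cluster[i] <- cl
      out$match_count[i] <- as.integer(best)
      out$method[i] <- "reference_tiebreak"
    }
  }
  class(out) <- c("ec_assignments", "data.frame")
  out
}

#' @export
print.ec_assignments <- function(x, ...) {
  n_un <- sum(x$method == "unassigned")
  cat(sprintf("Assignments: %d participants, %d unassigned\n", nrow(x), n_un))
  print(table(method = x$method))
  invisible(x)
}

#' Compare cluster shares between newly assigned data and the reference
#'
#' The population share of each cluster in the reference survey is
#' weight-based (survey weights make it nationally representative); the new
#' data's shares are unweighted counts of assigned participants.  Comparing
#' the two reveals over- or under-representation of economic groups in the
#' new data (e.g. a disease registry).  Unassigned participants are reported
#' separately, never silently dropped.
#'
#' @param results an `ec_assignments` data.frame.
#' @param model the `ec_model` the assignments came from.
#' @return data.frame of class `ec_distribution` with columns `cluster`,
#'   `n_new`, `share_new`, `share_reference`; attribute `unassigned` holds
#'   the count of unassigned participants.
#' @export
assignment_distribution <- function(results, model) {
  stopifnot(inherits(results, "ec_assignments"), inherits(model, "ec_model"))
  assigned <- results[!is.na(results$cluster), , drop = FALSE]
  ref_w <- tapply(model$profile_weight, model$profile_assignment, sum)
  ref_share <- as.numeric(ref_w) / sum(model$profile_weight)
  cl <- sort(unique(as.integer(names(ref_w))))
  n_new <- vapply(cl, function(c) sum(assigned$cluster == c), integer(1L))
  out <- data.frame(cluster = cl, n_new = n_new,
                    share_new = if (nrow(assigned)) n_new / nrow(assigned)
                                else NA_real_,
                    share_reference = ref_share)
  attr(out, "unassigned") <- sum(is.na(results$cluster))
  class(out) <- c("ec_distribution", "data.frame")
  out
}
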