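#' Aggregate households into distinct asset-answer profiles
#'
#' Households answering a set of categorical questions identically are
#' interchangeable for clustering purposes, so they are collapsed into a
#' single *profile* whose weight is the sum of the member household weights.
#' The exhaustive model search clusters profiles, not households, which keeps
#' every candidate instance small (bounded by the product of level counts)
#' while being provably identical to clustering at household level.
#'
#' @param table an `ec_households` table, complete on `variables`
#'   (see [complete_case_filter()]).
#' @param variables character vector of model variable names.
#' @return an object of class `ec_profiles`: a list with `profiles`
#'   (data.frame of factor columns, one row per distinct profile, in
#'   lexicographic order of declared levels), `weight`, `members`
#'   (list of household-id vectors), `n_profiles` and `variables`.
#' @export
aggregate_profiles <- function(table, variables) {
  stopifnot(inherits(table, "ec_households"), length(variables) >= 1L)
  if (nrow(table) == 0L) stop("empty household table", call. = FALSE)
  cols <- table[variables]
  if (any(vapply(cols, anyNA, logical(1L))))
    stop("table has missing values on model variables; ",
         "apply complete_case_filter() first", call. = FALSE)
  codes <- lapply(cols, as.integer)
  key <- do.call(paste, c(codes, sep = "\r"))
  first <- which(!duplicated(key))
  ord <- first[do.call(order, lapply(codes, function(z) z[first]))]
  profiles <- as.data.frame(cols[ord, , drop = FALSE])
  rownames(profiles) <- NULL
  okey <- key[ord]
  wsum <- rowsum(table$weight, key)        # sorted by key string
  members <- split(table$household_id, key)
  structure(list(profiles = profiles,
                 weight = as.numeric(wsum[okey, 1L]),
                 members = unname(members[okey]),
                 n_profiles = length(ord),
                 variables = variables),
            class = "ec_profiles")
}

#' @export
print.ec_profiles <- function(x, ...) {
  cat(sprintf("%d asset-answer profiles over {%s}; total weight %.4g\n",
              x$n_profiles, paste(x$variables, collapse = ", "),
              sum(x$weight)))
  invisible(x)
}

#' Gower dissimilarity matrix over asset-answer profiles
#'
#' With all-categorical variables the Gower coefficient reduces to simple
#' matching: the dissimilarity between two profiles is the proportion of the
#' model variables on which they differ, so every entry lies on the grid
#' \{0, 1/m, ..., 1\} for m variables.  No per-variable weights and no
#' ordinal scoring of levels are applied; all variables, including binary
#' ownership and the rural/urban setting, are treated as nominal.
#'
#' @param profiles an `ec_profiles` object (at least 2 profiles).
#' @return a dense symmetric numeric matrix with zero diagonal.
#' @export
gower_matrix <- function(profiles) {
  stopifnot(inherits(profiles, "ec_profiles"))
  n <- profiles$n_profiles
  if (n < 2L) stop("need at least 2 profiles", call. = FALSE)
  m <- length(profiles$variables)
  d <- matrix(0, n, n)
  for (v in profiles$variables) {
    z <- as.integer(profiles$profiles[[v]])
    d <- d + (outer(z, z, `!=`) * 1)
  }
  d / m
}
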