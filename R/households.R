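#' Declare the layout of a household survey table
#'
#' A survey config names the identifier, weight and rural/urban setting
#' columns of a household CSV file and declares the finite level set of every
#' categorical asset column.  Levels are case-sensitive and are never recoded:
#' numeric survey codes (e.g. DHS recode values) must be mapped to labels by
#' the user before or inside the config.  The order in which levels are
#' declared matters in two places: profiles are sorted lexicographically by
#' declared level order, and for two-level ownership variables the *second*
#' declared level is taken as the "owned"/positive level by the prevalence
#' filter (so declare `c("no", "yes")`).
#'
#' @param id name of the unique household identifier column.
#' @param weight name of the positive survey-weight column (inverse
#'   probability of household selection).
#' @param setting name of the rural/urban setting column.  This variable is
#'   part of every clustering model by default (see
#'   [ec_config()]`$forced_variables`).
#' @param assets named list; one entry per asset column, each a character
#'   vector of allowed levels.
#' @param setting_levels the two allowed levels of the setting column.
#' @param stratum,psu optional names of design stratum and primary sampling
#'   unit columns, used for design-based (Taylor-linearized) standard errors.
#' @return an object of class `ec_survey_config`.
#' @export
#' @examples
#' cfg <- ec_survey_config(
#'   id = "hhid", weight = "wt", setting = "setting",
#'   assets = list(phone = c("no", "yes"),
#'                 fuel  = c("wood", "charcoal", "LPG")))
ec_survey_config <- function(id = "household_id", weight = "weight",
                             setting = "setting", assets,
                             setting_levels = c("rural", "urban"),
                             stratum = NULL, psu = NULL) {
  if (missing(assets) || !is.list(assets) || is.null(names(assets)) ||
      any(!nzchar(names(assets))))
    stop("`assets` must be a named list of level sets", call. = FALSE)
  for (a in names(assets)) {
    lv <- assets[[a]]
    if (!is.character(lv) || length(lv) < 2L || anyDuplicated(lv))
      stop("asset '", a, "': levels must be >= 2 distinct strings",
           call. = FALSE)
  }
  if (length(setting_levels) != 2L || anyDuplicated(setting_levels))
    stop("`setting_levels` must be exactly two distinct levels", call. = FALSE)
  if (setting %in% names(assets))
    stop("the setting column must not also be declared in `assets`",
         call. = FALSE)
  structure(list(id = id, weight = weight, setting = setting,
                 assets = assets, setting_levels = as.character(setting_levels),
                 stratum = stratum, psu = psu),
            class = "ec_survey_config")
}

## All categorical model variables (setting first, then assets in declared
## order), as a named list of level sets.
config_variables <- function(config) {
  c(stats::setNames(list(config$setting_levels), config$setting),
    config$assets)
}

#' Read and validate a household table
#'
#' Reads a CSV file (RFC-4180, header row, UTF-8) and validates it against a
#' survey config: unique ids, positive finite weights, every non-missing
#' asset value within its declared level set.  Validation failures are
#' reported with the offending data row numbers; nothing is silently coerced.
#' Empty strings and `NA` are treated as explicit missing markers.
#'
#' @param path CSV file path, or a `data.frame` already in memory.
#' @param config an [ec_survey_config()].
#' @return a `data.frame` of class `ec_households` with columns
#'   `household_id` (character), `weight` (numeric), optional `stratum` and
#'   `psu`, the setting column and one factor column per declared asset.
#'   The config travels with the table as attribute `ec_config`.
#' @export
read_household_table <- function(path, config) {
  stopifnot(inherits(config, "ec_survey_config"))
  raw <- if (is.data.frame(path)) path else {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  }
  as_household_table(raw, config)
}

#' Validate an in-memory household data frame
#'
#' @param df a raw `data.frame`.
#' @param config an [ec_survey_config()].
#' @return see [read_household_table()].
#' @export
as_household_table <- function(df, config) {
  need <- c(config$id, config$weight, config$setting, names(config$assets),
            config$stratum, config$psu)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)

  id <- as.character(df[[config$id]])
  if (anyNA(id) || any(!nzchar(id)))
    stop("missing household id on row(s) ",
         row_list(which(is.na(id) | !nzchar(id))), call. = FALSE)
  if (anyDuplicated(id))
    stop("duplicate household id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)

  w <- suppressWarnings(as.numeric(df[[config$weight]]))
  bad_w <- which(is.na(w) | !is.finite(w) | w <= 0)
  if (length(bad_w))
    stop("non-positive, missing or non-finite weight on row(s) ",
         row_list(bad_w), call. = FALSE)

  out <- data.frame(household_id = id, weight = w, stringsAsFactors = FALSE)
  if (!is.null(config$stratum)) out$stratum <- as.character(df[[config$stratum]])
  if (!is.null(config$psu))     out$psu     <- as.character(df[[config$psu]])

  vars <- config_variables(config)
  for (v in names(vars)) {
    src <- if (v == config$setting) config$setting else v
    val <- as.character(df[[src]])
    val[!is.na(val) & !nzchar(val)] <- NA_character_
    bad <- !is.na(val) & !(val %in% vars[[v]])
    if (any(bad))
      stop("column '", v, "': value(s) outside declared levels {",
           paste(vars[[v]], collapse = ", "), "}: ",
           paste(unique(val[bad]), collapse = ", "),
           " on row(s) ", row_list(which(bad)), call. = FALSE)
    out[[v]] <- factor(val, levels = vars[[v]])
  }
  if (all(is.na(out[[config$setting]])))
    stop("setting column '", config$setting, "' is entirely missing",
         call. = FALSE)

  attr(out, "ec_config") <- config
  class(out) <- c("ec_households", "data.frame")
  out
}

row_list <- function(i, max = 10L) {
  shown <- utils::head(i, max)
  paste0(paste(shown, collapse = ", "),
         if (length(i) > max) sprintf(" (and %d more)", length(i) - max))
}

#' @export
print.ec_households <- function(x, ...) {
  cfg <- attr(x, "ec_config")
  cat(sprintf("Household table: %d households, %d asset variables (+ %s)\n",
              nrow(x), length(cfg$assets), cfg$setting))
  rep <- attr(x, "ec_filter_report")
  if (!is.null(rep))
    cat(sprintf("  complete-case filtered: %d retained, %d dropped\n",
                rep$retained, rep$dropped))
  NextMethod()
}

#' Keep households complete on a set of model variables
#'
#' Complete-case filter used before clustering: households missing any of
#' `variables` are dropped.  The retained/dropped counts are attached as
#' attribute `ec_filter_report`.  The operation is idempotent.
#'
#' @param table an `ec_households` table.
#' @param variables character vector of variable names (assets and/or the
#'   setting variable).
#' @return the filtered `ec_households` table.
#' @export
complete_case_filter <- function(table, variables) {
  stopifnot(inherits(table, "ec_households"))
  cfg <- attr(table, "ec_config")
  unknown <- setdiff(variables, names(config_variables(cfg)))
  if (length(unknown))
    stop("unknown variable(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  keep <- !Reduce(`|`, lapply(table[variables], is.na))
  if (!any(keep))
    stop("no household is complete on the requested variables; ",
         "cannot cluster zero households", call. = FALSE)
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "ec_config") <- cfg
  attr(out, "ec_filter_report") <-
    list(n_input = nrow(table), retained = sum(keep),
         dropped = sum(!keep))
  class(out) <- class(table)
  out
}

#' Read a child anthropometry table
#'
#' @param path CSV path or data.frame with a household id, a positive child
#'   weight and a height-for-age Z-score (HAZ) column.
#' @param id,weight,haz column names.
#' @return data.frame with columns `household_id`, `weight`, `haz`.
#' @export
read_child_table <- function(path, id = "household_id", weight = "weight",
                             haz = "haz") {
  df <- read_plain(path)
  out <- check_member_table(df, id, weight)
  out$haz <- check_finite_num(df[[haz]], haz)
  out
}

#' Read a women's outcome table
#'
#' One row per woman: literacy score on the 0 (cannot read at all) to 2
#' (reads whole sentences) scale, counts of deceased sons and daughters and
#' total children ever born.  `sons_died + daughters_died` may not exceed
#' `children_ever_born`.
#'
#' @param path CSV path or data.frame.
#' @param id,weight,literacy,sons_died,daughters_died,children_ever_born
#'   column names.
#' @return data.frame with standardized column names.
#' @export
read_woman_table <- function(path, id = "household_id", weight = "weight",
                             literacy = "literacy", sons_died = "sons_died",
                             daughters_died = "daughters_died",
                             children_ever_born = "children_ever_born") {
  df <- read_plain(path)
  out <- check_member_table(df, id, weight)
  out$literacy <- check_count(df[[literacy]], literacy)
  if (any(out$literacy > 2L))
    stop("literacy must be in {0, 1, 2}; offending row(s) ",
         row_list(which(out$literacy > 2L)), call. = FALSE)
  out$sons_died <- check_count(df[[sons_died]], sons_died)
  out$daughters_died <- check_count(df[[daughters_died]], daughters_died)
  out$children_ever_born <- check_count(df[[children_ever_born]],
                                        children_ever_born)
  over <- out$sons_died + out$daughters_died > out$children_ever_born
  if (any(over))
    stop("deceased children exceed children ever born on row(s) ",
         row_list(which(over)), call. = FALSE)
  out
}

read_plain <- function(path) {
  if (is.data.frame(path)) return(path)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

check_member_table <- function(df, id, weight) {
  for (col in c(id, weight))
    if (is.null(df[[col]]))
      stop("missing column: ", col, call. = FALSE)
  w <- suppressWarnings(as.numeric(df[[weight]]))
  bad <- which(is.na(w) | !is.finite(w) | w <= 0)
  if (length(bad))
    stop("non-positive or missing weight on row(s) ", row_list(bad),
         call. = FALSE)
  data.frame(household_id = as.character(df[[id]]), weight = w,
             stringsAsFactors = FALSE)
}

check_finite_num <- function(x, name) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) | !is.finite(v))
  if (length(bad))
    stop("column '", name, "': missing or non-finite value on row(s) ",
         row_list(bad), call. = FALSE)
  v
}

check_count <- function(x, name) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) | !is.finite(v) | v < 0 | v != round(v))
  if (length(bad))
    stop("column '", name, "': non-negative integer required on row(s) ",
         row_list(bad), call. = FALSE)
  as.integer(v)
}
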