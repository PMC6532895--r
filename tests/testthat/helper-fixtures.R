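# Small in-code fixtures shared by the unit tests.

tiny_config <- function() {
  ec_survey_config(
    id = "hhid", weight = "wt", setting = "setting",
    assets = list(phone = c("no", "yes"),
                  land = c("no", "yes"),
                  fuel = c("wood", "charcoal", "LPG")))
}

tiny_table <- function() {
  df <- data.frame(
    hhid = c("a", "b", "c", "d", "e"),
    wt = c(1.2, 0.8, 2.0, 1.0, 0.5),
    setting = c("rural", "rural", "urban", "urban", "rural"),
    phone = c("no", "no", "yes", "yes", "no"),
    land = c("yes", "yes", "no", "no", "yes"),
    fuel = c("wood", "wood", "LPG", "charcoal", NA),
    stringsAsFactors = FALSE)
  as_household_table(df, tiny_config())
}

# A random dissimilarity-matrix instance satisfying the metric axioms is not
# required by PAM; plain symmetric matrices with zero diagonal suffice.
random_dissim <- function(n) {
  d <- matrix(stats::runif(n * n), n, n)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d
}

# Random all-categorical profile instance: levels per variable drawn from
# {2, 3}; returns an ec_profiles via the public API.
random_profile_table <- function(n_households, n_vars, seed) {
  set.seed(seed)
  levels_of <- lapply(seq_len(n_vars), function(i)
    if (i %% 2L == 0L) c("no", "yes") else c("lo", "mid", "hi"))
  names(levels_of) <- paste0("v", seq_len(n_vars))
  df <- data.frame(hhid = sprintf("h%03d", seq_len(n_households)),
                   wt = stats::runif(n_households, 0.2, 3),
                   setting = sample(c("rural", "urban"), n_households, TRUE),
                   stringsAsFactors = FALSE)
  for (v in names(levels_of))
    df[[v]] <- sample(levels_of[[v]], n_households, TRUE)
  cfg <- ec_survey_config(id = "hhid", weight = "wt", setting = "setting",
                          assets = levels_of)
  as_household_table(df, cfg)
}
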