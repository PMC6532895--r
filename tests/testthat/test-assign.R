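# A hand-built model with transparent geometry: two variables' worth of
# medoids chosen so agreement counts are easy to enumerate.
toy_model <- function() {
  df <- data.frame(
    hhid = sprintf("h%d", 1:8),
    wt = rep(1, 8),
    setting = c("rural", "rural", "rural", "rural",
                "urban", "urban", "urban", "urban"),
    phone = c("no", "no", "no", "no", "yes", "yes", "yes", "yes"),
    fuel = c("wood", "wood", "charcoal", "charcoal",
             "LPG", "LPG", "wood", "wood"),
    stringsAsFactors = FALSE)
  cfg <- ec_survey_config(id = "hhid", weight = "wt", setting = "setting",
                          assets = list(phone = c("no", "yes"),
                                        fuel = c("wood", "charcoal", "LPG")))
  tab <- as_household_table(df, cfg)
  list(table = tab,
       model = fit_model(tab, c("setting", "phone", "fuel"), 4))
}

test_that("exact medoid match assigns with full agreement count", {
  tm <- toy_model()
  med <- tm$model$medoids
  for (ci in seq_len(tm$model$k)) {
    p <- data.frame(participant_id = "p",
                    setting = as.character(med$setting[ci]),
                    phone = as.character(med$phone[ci]),
                    fuel = as.character(med$fuel[ci]))
    res <- assign_participants(p, tm$model)
    expect_equal(res$cluster, ci)
    expect_equal(res$match_count, 3L)
    expect_equal(res$method, "medoid_match")
  }
})

test_that("ties go to the cluster of the unanimous most-similar reference households", {
  # reference: clusters {rural,no,wood}, {rural,no,charcoal},
  #            {urban,yes,LPG}, {urban,yes,wood}
  tm <- toy_model()
  # (rural, yes, LPG): agreement 1 with every medoid except... compute:
  # m1 rural/no/wood -> 1; m2 rural/no/charcoal -> 1; m3 urban/yes/LPG -> 2;
  # m4 urban/yes/wood -> 1  => unique winner m3
  res <- assign_participants(
    data.frame(participant_id = "p", setting = "rural", phone = "yes",
               fuel = "LPG"), tm$model)
  expect_equal(res$method, "medoid_match")

  # (rural, yes, wood): m1 2, m2 1, m3 1, m4 2 -> tie between m1 and m4.
  # Reference households with maximal agreement: profile (rural,no,wood)
  # agrees 2, (urban,yes,wood) agrees 2 -> clusters differ -> UNASSIGNED.
  res2 <- assign_participants(
    data.frame(participant_id = "p", setting = "rural", phone = "yes",
               fuel = "wood"), tm$model)
  expect_equal(res2$method, "unassigned")
  expect_true(is.na(res2$cluster))
})

test_that("reference tie-break assigns when the most similar households are unanimous", {
  # Three profiles: two heavy ones become the k = 2 medoids, a light third
  # profile sits inside cluster 1 and resolves the tie.
  df <- data.frame(
    hhid = sprintf("h%02d", 1:21),
    wt = 1,
    setting = c(rep("rural", 10), rep("urban", 10), "rural"),
    phone = c(rep("no", 10), rep("yes", 10), "yes"),
    fuel = c(rep("wood", 10), rep("LPG", 10), "wood"),
    stringsAsFactors = FALSE)
  cfg <- ec_survey_config(id = "hhid", weight = "wt", setting = "setting",
                          assets = list(phone = c("no", "yes"),
                                        fuel = c("wood", "charcoal", "LPG")))
  tab <- as_household_table(df, cfg)
  model <- fit_model(tab, c("setting", "phone", "fuel"), 2)
  # medoids must be the two weight-10 profiles (any other pair costs more)
  expect_setequal(
    paste(model$medoids$setting, model$medoids$phone, model$medoids$fuel),
    c("rural no wood", "urban yes LPG"))
  # participant (rural, yes, charcoal): agreement 1 with each medoid (tie);
  # reference profile (rural, yes, wood) agrees on 2 answers -> unique
  # maximally-similar households, all in h21's cluster
  res <- assign_participants(
    data.frame(participant_id = "p", setting = "rural", phone = "yes",
               fuel = "charcoal"), model)
  expect_equal(res$method, "reference_tiebreak")
  expect_equal(res$cluster, unname(model$assignment["h21"]))
  expect_equal(res$match_count, 1L)
})

test_that("all-missing answers and unknown levels are handled explicitly", {
  tm <- toy_model()
  res <- assign_participants(
    data.frame(participant_id = "p", setting = NA_character_,
               phone = NA_character_, fuel = ""), tm$model)
  expect_equal(res$method, "unassigned")

  expect_error(assign_participants(
    data.frame(participant_id = "p", setting = "rural", phone = "maybe",
               fuel = "wood"), tm$model), "undeclared")
  expect_error(assign_participants(
    data.frame(participant_id = "p", setting = "rural", phone = "no",
               fuel = "wood", extra_var = "x"), tm$model), "not in the model")
  expect_error(assign_participants(
    data.frame(participant_id = "p", setting = "rural"), tm$model),
    "lack model variable")
})

test_that("feedback assignment reproduces model clusters for unique-nearest profiles", {
  sim <- simulate_survey(ec_sim_spec(n_households = 400, seed = 12))
  vars <- c("setting", "phone", "electricity", "fuel", "water")
  model <- fit_model(sim$households, vars, 4)
  hh <- as.data.frame(sim$households)
  participants <- data.frame(participant_id = hh$household_id,
                             stringsAsFactors = FALSE)
  for (v in vars) participants[[v]] <- as.character(hh[[v]])
  res <- assign_participants(participants, model,
                             reference = sim$households)
  # identify profiles whose best-agreeing medoid is unique
  agree <- sapply(seq_len(model$k), function(ci)
    rowSums(vapply(vars, function(v)
      as.character(model$profiles[[v]]) ==
        as.character(model$medoids[[v]][ci]), logical(nrow(model$profiles)))))
  unique_best <- apply(agree, 1, function(r) sum(r == max(r)) == 1)
  prof_key <- do.call(paste, c(lapply(vars, function(v)
    as.character(model$profiles[[v]])), sep = "/"))
  part_key <- do.call(paste, c(lapply(vars, function(v)
    participants[[v]]), sep = "/"))
  is_unique <- unique_best[match(part_key, prof_key)]
  matches <- res$cluster == unname(model$assignment[res$participant_id])
  expect_true(all(matches[is_unique]))
  expect_true(all(res$method != "unassigned"))

  # deterministic and order-independent
  perm <- sample(nrow(participants))
  res2 <- assign_participants(participants[perm, ], model)
  expect_equal(res2$cluster, res$cluster[perm])

  # mismatched reference fingerprint warns
  expect_warning(assign_participants(participants[1, ], model,
                                     reference = sim$households[1:10, ]),
                 "fingerprint")
})

test_that("assignment shares compare new data against the weighted reference", {
  sim <- simulate_survey(ec_sim_spec(n_households = 400, seed = 15))
  vars <- c("setting", "phone", "electricity", "fuel", "water")
  model <- fit_model(sim$households, vars, 4)
  hh <- as.data.frame(sim$households)
  participants <- data.frame(participant_id = hh$household_id)
  for (v in vars) participants[[v]] <- as.character(hh[[v]])
  res <- assign_participants(participants, model)
  dist <- assignment_distribution(res, model)
  expect_equal(sum(dist$share_new), 1, tolerance = 1e-12)
  expect_equal(sum(dist$share_reference), 1, tolerance = 1e-12)
  ref_w <- tapply(model$profile_weight, model$profile_assignment, sum)
  expect_equal(dist$share_reference, as.numeric(ref_w / sum(ref_w)),
               tolerance = 1e-12)

  # a registry drawn from one planted group concentrates in one cluster
  g4 <- names(sim$labels)[sim$labels == 4]
  res4 <- res[res$participant_id %in% g4, ]
  class(res4) <- class(res)
  d4 <- assignment_distribution(res4, model)
  expect_gte(max(d4$share_new), 0.9)
})
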