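#' Specify a synthetic household survey with planted economic groups
#'
#' The generator emulates the structure the clustering method assumes in a
#' DHS-style survey: a population partitioned into latent economic groups,
#' each with a characteristic asset-answer signature over a handful of
#' informative variables (binary ownership plus multi-level fuel and water
#' questions), plus uninformative "noise" assets, positive survey weights,
#' and group-graded health/social outcomes (child height-for-age Z-scores,
#' women's literacy on the 0-2 scale, deceased-children counts).
#'
#' Defaults describe a four-group population with a realistic wealth
#' gradient: shares 0.35/0.30/0.20/0.15 from poorest to wealthiest, the two
#' poorer groups rural, mild signature corruption (2% per variable),
#' five informative and five noise assets, and monotone outcome effects
#' (rising HAZ and literacy, falling child mortality).
#'
#' @param n_households number of households.
#' @param groups list, one element per group, each a list with `share`,
#'   `setting` ("rural"/"urban"), `signature` (named character vector over
#'   the informative assets), `corruption` (per-variable probability that
#'   the signature answer is replaced by a uniformly random *other* level),
#'   `haz_mean`, `literacy_probs` (length 3, levels 0/1/2), `death_prob`
#'   (per-child probability of death).
#' @param informative_levels named list of level sets for the informative
#'   assets (binary levels must be declared no-first).
#' @param n_noise_assets number of independent binary assets unrelated to
#'   group (ownership probability 0.5 each).
#' @param weight_sigma log-normal sigma of the survey weights (mean fixed
#'   at 1); 0 gives constant weights.
#' @param haz_sd within-group HAZ standard deviation.
#' @param children_lambda Poisson mean of measured children per household.
#' @param ceb_lambda Poisson mean of children ever born per woman.
#' @param n_psu number of primary sampling units per stratum (exchangeable;
#'   no clustering effect is simulated).
#' @param seed integer seed; every draw flows from it.
#' @return an object of class `ec_sim_spec`.
#' @export
ec_sim_spec <- function(n_households = 5000L,
                        groups = default_sim_groups(),
                        informative_levels = default_informative_levels(),
                        n_noise_assets = 5L,
                        weight_sigma = 0.4,
                        haz_sd = 1.0,
                        children_lambda = 2,
                        ceb_lambda = 3,
                        n_psu = 25L,
                        seed = 20260101L) {
  shares <- vapply(groups, `[[`, numeric(1L), "share")
  if (abs(sum(shares) - 1) > 1e-8)
    stop("group shares must sum to 1", call. = FALSE)
  for (g in groups) {
    stopifnot(g$setting %in% c("rural", "urban"),
              g$corruption >= 0, g$corruption < 1,
              length(g$literacy_probs) == 3L,
              abs(sum(g$literacy_probs) - 1) < 1e-8,
              g$death_prob >= 0, g$death_prob <= 1)
    bad <- setdiff(names(g$signature), names(informative_levels))
    if (length(bad))
      stop("signature names unknown: ", paste(bad, collapse = ", "),
           call. = FALSE)
    for (v in names(g$signature))
      if (!g$signature[[v]] %in% informative_levels[[v]])
        stop("signature value for '", v, "' outside its level set",
             call. = FALSE)
  }
  structure(list(n_households = as.integer(n_households), groups = groups,
                 informative_levels = informative_levels,
                 n_noise_assets = as.integer(n_noise_assets),
                 weight_sigma = weight_sigma, haz_sd = haz_sd,
                 children_lambda = children_lambda, ceb_lambda = ceb_lambda,
                 n_psu = as.integer(n_psu), seed = as.integer(seed)),
            class = "ec_sim_spec")
}

#' @rdname ec_sim_spec
#' @param corruption corruption rate applied to every default group.
#' @export
default_sim_groups <- function(corruption = 0.02) {
  sig <- function(phone, electricity, computer, fuel, water)
    c(phone = phone, electricity = electricity, computer = computer,
      fuel = fuel, water = water)
  list(
    list(share = 0.35, setting = "rural",
         signature = sig("no", "no", "no", "wood", "surface"),
         corruption = corruption, haz_mean = -1.8,
         literacy_probs = c(0.70, 0.20, 0.10), death_prob = 0.12),
    list(share = 0.30, setting = "rural",
         signature = sig("yes", "no", "no", "wood", "well"),
         corruption = corruption, haz_mean = -1.2,
         literacy_probs = c(0.50, 0.30, 0.20), death_prob = 0.09),
    list(share = 0.20, setting = "urban",
         signature = sig("yes", "yes", "no", "charcoal", "well"),
         corruption = corruption, haz_mean = -0.6,
         literacy_probs = c(0.25, 0.30, 0.45), death_prob = 0.06),
    list(share = 0.15, setting = "urban",
         signature = sig("yes", "yes", "yes", "LPG", "piped"),
         corruption = corruption, haz_mean = 0.1,
         literacy_probs = c(0.05, 0.20, 0.75), death_prob = 0.03))
}

#' @rdname ec_sim_spec
#' @export
default_informative_levels <- function() {
  list(phone = c("no", "yes"),
       electricity = c("no", "yes"),
       computer = c("no", "yes"),
       fuel = c("wood", "charcoal", "LPG"),
       water = c("surface", "well", "piped"))
}

## run `expr` under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic household survey
#'
#' Draws a survey from an [ec_sim_spec()]: each household draws a group by
#' share, answers the informative assets per its group signature with
#' independent per-variable corruption, answers noise assets at random, and
#' receives a log-normal survey weight.  One woman per household provides
#' literacy, children-ever-born and deceased-children counts; a Poisson
#' number of measured children provide HAZ values.  Fully reproducible from
#' the spec's seed.
#'
#' @param spec an `ec_sim_spec`.
#' @return list of class `ec_sim` with `households` (an `ec_households`
#'   table with the survey config attached), `children`, `women`, `labels`
#'   (named integer vector: planted group per household) and `spec`.
#' @export
simulate_survey <- function(spec) {
  stopifnot(inherits(spec, "ec_sim_spec"))
  with_seed(spec$seed, {
    n <- spec$n_households
    G <- length(spec$groups)
    shares <- vapply(spec$groups, `[[`, numeric(1L), "share")
    grp <- sample.int(G, n, replace = TRUE, prob = shares)
    id <- sprintf("hh%05d", seq_len(n))
    w <- if (spec$weight_sigma > 0)
      stats::rlnorm(n, meanlog = -spec$weight_sigma^2 / 2,
                    sdlog = spec$weight_sigma)
    else rep(1, n)

    setting <- vapply(spec$groups, `[[`, character(1L), "setting")[grp]
    df <- data.frame(household_id = id, weight = w, setting = setting,
                     stringsAsFactors = FALSE)
    df$stratum <- setting
    df$psu <- paste0(setting, "_psu",
                     sample.int(spec$n_psu, n, replace = TRUE))

    for (v in names(spec$informative_levels)) {
      lv <- spec$informative_levels[[v]]
      val <- vapply(spec$groups, function(g) g$signature[[v]], character(1L))[grp]
      corr <- vapply(spec$groups, `[[`, numeric(1L), "corruption")[grp]
      flip <- stats::runif(n) < corr
      if (any(flip)) {
        val[flip] <- vapply(val[flip], function(cur)
          sample(setdiff(lv, cur), 1L), character(1L))
      }
      df[[v]] <- val
    }
    noise_names <- character(0)
    if (spec$n_noise_assets > 0L) {
      noise_names <- sprintf("noise%02d", seq_len(spec$n_noise_assets))
      for (v in noise_names)
        df[[v]] <- c("no", "yes")[1L + stats::rbinom(n, 1L, 0.5)]
    }

    assets <- c(spec$informative_levels,
                stats::setNames(rep(list(c("no", "yes")), length(noise_names)),
                                noise_names))
    cfg <- ec_survey_config(id = "household_id", weight = "weight",
                            setting = "setting", assets = assets,
                            stratum = "stratum", psu = "psu")
    households <- as_household_table(df, cfg)

    ## women: one per household
    ceb <- stats::rpois(n, spec$ceb_lambda)
    death_p <- vapply(spec$groups, `[[`, numeric(1L), "death_prob")[grp]
    deaths <- stats::rbinom(n, ceb, death_p)
    sons <- stats::rbinom(n, deaths, 0.5)
    lit <- integer(n)
    for (g in seq_len(G)) {
      idx <- which(grp == g)
      lit[idx] <- sample(0:2, length(idx), replace = TRUE,
                         prob = spec$groups[[g]]$literacy_probs)
    }
    women <- data.frame(household_id = id, weight = w, literacy = lit,
                        sons_died = sons, daughters_died = deaths - sons,
                        children_ever_born = ceb, stringsAsFactors = FALSE)

    ## children with measured HAZ
    nch <- stats::rpois(n, spec$children_lambda)
    ch_hh <- rep(id, nch)
    ch_grp <- rep(grp, nch)
    haz_mu <- vapply(spec$groups, `[[`, numeric(1L), "haz_mean")[ch_grp]
    children <- data.frame(
      household_id = ch_hh, weight = rep(w, nch),
      haz = stats::rnorm(length(ch_hh), haz_mu, spec$haz_sd),
      stringsAsFactors = FALSE)

    labels <- stats::setNames(grp, id)
    structure(list(households = households, children = children,
                   women = women, labels = labels, spec = spec),
              class = "ec_sim")
  })
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement under the permutation model; 1 for identical
#' partitions (up to relabeling), about 0 for independent ones.  Symmetric
#' in its arguments.
#'
#' @param x,y partition labels of the same cases (vectors of equal length).
#' @return a number in `[-1, 1]`.
#' @export
ec_ari <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) > 0)
  tab <- table(x, y)
  comb2 <- function(v) sum(v * (v - 1) / 2)
  n <- length(x)
  sum_ij <- comb2(as.vector(tab))
  sum_i <- comb2(rowSums(tab))
  sum_j <- comb2(colSums(tab))
  expected <- sum_i * sum_j / (n * (n - 1) / 2)
  maximum <- (sum_i + sum_j) / 2
  if (maximum == expected) return(1)
  (sum_ij - expected) / (maximum - expected)
}

#' Recovery metrics of a fitted model against planted groups
#'
#' @param labels named integer vector of planted group labels (names =
#'   household ids), e.g. `ec_sim$labels`.
#' @param model an `ec_model`.
#' @return list with `ari` and the planted-vs-recovered `confusion` table.
#' @export
recovery_metrics <- function(labels, model) {
  stopifnot(inherits(model, "ec_model"))
  common <- intersect(names(labels), names(model$assignment))
  if (length(common) == 0L)
    stop("planted labels and model assignment share no household ids",
         call. = FALSE)
  planted <- labels[common]
  recovered <- model$assignment[common]
  list(ari = ec_ari(planted, recovered),
       confusion = table(planted = planted, recovered = recovered))
}
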