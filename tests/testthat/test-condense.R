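# Build an ec_outcome_summary directly (the class is a plain data.frame);
# used to test condensation/ranking in isolation from estimation.
make_summary <- function(cluster, setting, haz, lit, mort) {
  out <- data.frame(cluster = as.character(cluster), setting = setting,
                    n_households = 10L,
                    haz_mean = haz, haz_se = 0.1, haz_n = 50L,
                    literacy_mean = lit, literacy_se = 0.05, literacy_n = 40L,
                    mortality_mean = mort, mortality_se = 0.01,
                    mortality_n = 40L, stringsAsFactors = FALSE)
  class(out) <- c("ec_outcome_summary", "data.frame")
  out
}

test_that("identical outcome means merge first, at height zero", {
  sm <- make_summary(1:4, rep("rural", 4),
                     haz = c(-1.5, -1.5, -0.2, 0.4),
                     lit = c(0.3, 0.3, 1.1, 1.8),
                     mort = c(0.12, 0.12, 0.05, 0.02))
  cond <- condense_clusters(sm, target_groups = c(2, 3))
  tr <- cond$trees[["rural"]]
  expect_equal(min(tr$height), 0)
  # clusters 1 and 2 (identical rows) end up in the same group
  map <- cond$mapping
  expect_equal(map$group[map$cluster == "1"], map$group[map$cluster == "2"])
})

test_that("outcome means are standardized per stratum before clustering", {
  sm <- make_summary(1:5, rep("urban", 5),
                     haz = c(-2, -1, 0, 1, 2),
                     lit = c(0.1, 0.5, 1.0, 1.5, 1.9),
                     mort = c(0.20, 0.15, 0.10, 0.05, 0.01))
  cond <- condense_clusters(sm, target_groups = c(2, 4))
  X <- cond$scaled[["urban"]]
  expect_equal(unname(colMeans(X)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(X, 2, sd)), rep(1, 3), tolerance = 1e-12)
})

test_that("merge heights and topology match a naive agglomerative oracle", {
  set.seed(14)
  for (rep in 1:5) {
    n <- 8
    X <- matrix(rnorm(n * 3), n, 3)
    hc <- stats::hclust(stats::dist(X), method = "complete")
    ref <- naive_agglom(X, "complete")
    expect_equal(sort(hc$height), sort(ref$heights), tolerance = 1e-10)
    # partitions agree after every merge
    for (k in (n - 1):2) {
      ours <- stats::cutree(hc, k = k)
      theirs <- ref$partitions[[n - k]]
      expect_equal(ec_ari(ours, theirs), 1)
    }
  }
})

test_that("condensation is invariant to cluster relabeling", {
  sm <- make_summary(1:6, rep(c("rural", "urban"), each = 3),
                     haz = c(-1.9, -1.6, -1.0, -0.5, 0.2, 0.6),
                     lit = c(0.2, 0.4, 0.8, 1.0, 1.5, 1.9),
                     mort = c(0.14, 0.11, 0.08, 0.06, 0.03, 0.01))
  cond1 <- condense_clusters(sm, target_groups = c(3, 4))
  sm2 <- sm
  relabel <- c("1" = "x1", "2" = "x2", "3" = "x3",
               "4" = "y1", "5" = "y2", "6" = "y3")
  sm2$cluster <- unname(relabel[sm2$cluster])
  cond2 <- condense_clusters(sm2, target_groups = c(3, 4))
  m1 <- cond1$mapping; m2 <- cond2$mapping
  m2$cluster <- names(relabel)[match(m2$cluster, relabel)]
  m2 <- m2[match(m1$cluster, m2$cluster), ]
  expect_equal(ec_ari(m1$group, m2$group), 1)
})

test_that("total group count lands in the target interval", {
  sm <- make_summary(1:10, rep(c("rural", "urban"), each = 5),
                     haz = c(-2, -1.8, -1.1, -1.0, -0.9, -0.4, 0, 0.3, 0.8, 1),
                     lit = c(0.1, 0.2, 0.5, 0.55, 0.6, 1.0, 1.2, 1.4, 1.7, 1.9),
                     mort = c(0.2, 0.18, 0.12, 0.11, 0.10,
                              0.06, 0.05, 0.04, 0.02, 0.01))
  cond <- condense_clusters(sm, target_groups = c(5, 7))
  tot <- length(unique(cond$mapping$group))
  expect_gte(tot, 5); expect_lte(tot, 7)
  # every original cluster appears exactly once
  expect_setequal(cond$mapping$cluster, as.character(1:10))
  expect_false(anyDuplicated(cond$mapping$cluster) > 0)
})

test_that("keep_separate prevents specified clusters from merging", {
  sm <- make_summary(1:6, rep("rural", 6),
                     haz = c(-2, -1.95, -1.0, -0.9, 0.5, 0.55),
                     lit = c(0.1, 0.12, 0.8, 0.85, 1.8, 1.85),
                     mort = c(0.2, 0.19, 0.1, 0.09, 0.02, 0.018))
  cond <- condense_clusters(sm, target_groups = c(2, 3))
  map0 <- cond$mapping
  expect_equal(map0$group[map0$cluster == "5"],
               map0$group[map0$cluster == "6"])
  cond2 <- condense_clusters(sm, target_groups = c(2, 3),
                             keep_separate = list(c("5", "6")))
  map <- cond2$mapping
  expect_false(map$group[map$cluster == "5"] ==
                 map$group[map$cluster == "6"])
})

test_that("single-cluster strata pass through and degenerate scaling warns", {
  sm <- make_summary(1:3, c("rural", "urban", "urban"),
                     haz = c(-1, 0, 1), lit = c(0.5, 1, 1.5),
                     mort = c(0.1, 0.1, 0.1))
  expect_warning(cond <- condense_clusters(sm, target_groups = c(2, 3)),
                 "zero variance")
  expect_equal(nrow(cond$mapping), 3L)
  expect_equal(sum(cond$mapping$setting == "rural"), 1L)
})

test_that("ranking follows literacy with co-monotonicity checks", {
  sm <- make_summary(c("g1", "g2", "g3"), rep("rural", 3),
                     haz = c(-1.8, -1.0, -0.2),
                     lit = c(0.3, 0.9, 1.6),
                     mort = c(0.15, 0.08, 0.02))
  r <- rank_groups(sm)
  expect_equal(r$group[order(r$rank)], c("g1", "g2", "g3"))
  expect_null(attr(r, "conflicts"))

  # HAZ disagrees with literacy between g2 and g3
  sm2 <- make_summary(c("g1", "g2", "g3"), rep("rural", 3),
                      haz = c(-1.8, -0.2, -1.0),
                      lit = c(0.3, 0.9, 1.6),
                      mort = c(0.15, 0.08, 0.02))
  r2 <- rank_groups(sm2)
  expect_equal(r2$group[order(r2$rank)], c("g1", "g2", "g3"))
  cf <- attr(r2, "conflicts")
  expect_false(is.null(cf))
  expect_equal(cf$indicator, "haz")

  # strata are ranked independently
  sm3 <- make_summary(c("r1", "r2", "u1", "u2"),
                      c("rural", "rural", "urban", "urban"),
                      haz = c(-1.8, -1.0, -0.5, 0.3),
                      lit = c(0.3, 0.9, 1.1, 1.7),
                      mort = c(0.15, 0.08, 0.05, 0.01))
  r3 <- rank_groups(sm3)
  expect_equal(r3$rank[r3$group == "r1"], 1L)
  expect_equal(r3$rank[r3$group == "u1"], 1L)
})

test_that("newick export produces one parseable tree per stratum", {
  sm <- make_summary(1:6, rep(c("rural", "urban"), each = 3),
                     haz = c(-1.9, -1.6, -1.0, -0.5, 0.2, 0.6),
                     lit = c(0.2, 0.4, 0.8, 1.0, 1.5, 1.9),
                     mort = c(0.14, 0.11, 0.08, 0.06, 0.03, 0.01))
  cond <- condense_clusters(sm, target_groups = c(3, 4))
  nwk <- ec_newick(cond)
  expect_setequal(names(nwk), c("rural", "urban"))
  for (s in names(nwk)) {
    tr <- ape::read.tree(text = nwk[[s]])
    expect_equal(sort(tr$tip.label),
                 sort(as.character(sm$cluster[sm$setting == s])))
  }
})
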