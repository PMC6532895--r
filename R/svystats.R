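## Design-based estimation of weighted means and their covariance.
##
## The estimator is the Hajek (ratio) mean  m = sum(w y) / sum(w)  with
## Taylor-linearized variance under the with-replacement PSU approximation:
## the linearized score z_i = w_i (y_i - m) / W is summed within PSUs, and
## within each stratum the PSU totals are treated as an iid sample
## (variance multiplier n_h / (n_h - 1)).  With unit weights, one stratum
## and one observation per PSU this reduces exactly to the classical
## var(y)/n of the sample mean.  When no stratum/psu columns are supplied,
## every observation is its own PSU in a single stratum.

svy_mean <- function(y, w, stratum = NULL, psu = NULL) {
  est <- svy_group_means(rep(1L, length(y)), y, w, stratum, psu)
  list(mean = est$mean[1L], se = sqrt(est$vcov[1L, 1L]), n = length(y))
}

## Variance of one weighted mean from linearized scores z_i = w(y - m)/W,
## summed to PSU totals within strata.
svy_var_of_mean <- function(z, stratum, psu) {
  n <- length(z)
  if (is.null(stratum)) stratum <- rep("s1", n)
  if (is.null(psu)) psu <- as.character(seq_len(n))
  sf <- factor(stratum)
  v <- 0
  df_design <- 0L
  for (h in levels(sf)) {
    idx <- which(sf == h)
    tot <- as.vector(tapply(z[idx], factor(psu[idx]), sum))
    nh <- length(tot)
    if (nh == 1L) next               # single-PSU stratum contributes nothing
    v <- v + nh / (nh - 1) * sum((tot - mean(tot))^2)
    df_design <- df_design + (nh - 1L)
  }
  list(var = v, df = max(df_design, 1L))
}

## Per-group weighted means and SEs.  Each group is estimated on its own
## subsample (its own PSUs and strata) and groups are treated as
## independent, so the covariance is diagonal; with unit weights and no
## design columns each group SE is exactly the classical sd/sqrt(n).
svy_group_means <- function(groups, y, w, stratum = NULL, psu = NULL) {
  keep <- !is.na(y) & !is.na(groups)
  y <- y[keep]; w <- w[keep]; groups <- groups[keep]
  if (!is.null(stratum)) stratum <- stratum[keep]
  if (!is.null(psu)) psu <- psu[keep]
  if (length(y) == 0L) stop("no observations", call. = FALSE)
  gf <- factor(groups)
  G <- nlevels(gf)
  mg <- vg <- Wg <- numeric(G)
  ng <- integer(G)
  df_design <- 0L
  for (g in seq_len(G)) {
    idx <- which(as.integer(gf) == g)
    Wg[g] <- sum(w[idx])
    mg[g] <- sum(w[idx] * y[idx]) / Wg[g]
    ng[g] <- length(idx)
    z <- w[idx] * (y[idx] - mg[g]) / Wg[g]
    vv <- svy_var_of_mean(z, if (is.null(stratum)) NULL else stratum[idx],
                          if (is.null(psu)) NULL else psu[idx])
    vg[g] <- vv$var
    df_design <- df_design + vv$df
  }
  list(mean = mg, vcov = diag(vg, nrow = G), levels = levels(gf), W = Wg,
       n = ng, df = max(df_design, 1L))
}

#' Design-based validation statistics for a grouping
#'
#' Given individual-level outcomes, survey weights and a grouping of the
#' individuals (e.g. the economic cluster of their household), computes:
#' per-group weighted means with design-based standard errors; a one-way
#' weighted ANOVA as a design-based Wald test that all group means are
#' equal; eta squared (weighted between-group sum of squares over weighted
#' total sum of squares, the proportion of outcome variance accounted for
#' by the grouping); and unequal-variance two-sample t tests between each
#' adjacently ranked pair of groups, with significance tiers at
#' 0.05 / 0.01 / 0.005.
#'
#' If `stratum`/`psu` are supplied, standard errors use Taylor
#' linearization under the with-replacement PSU approximation; otherwise
#' each observation is treated as its own PSU (weights act as precision
#' weights), which reduces to classical formulas at equal weights.
#'
#' @param groups group label per observation.
#' @param y numeric outcome per observation (`NA` dropped).
#' @param w positive weights.
#' @param stratum,psu optional design columns.
#' @param ranking optional vector of group labels in ordinal rank order;
#'   adjacent-pair t tests follow this order (default: sorted label order).
#' @return an object of class `ec_validation`: list with `groups`
#'   (data.frame label, mean, se, n), `anova` (F statistic, df1, df2,
#'   p value), `eta_squared`, `adjacent` (data.frame of pairwise tests).
#' @export
validation_stats <- function(groups, y, w, stratum = NULL, psu = NULL,
                             ranking = NULL) {
  est <- svy_group_means(groups, y, w, stratum, psu)
  G <- length(est$mean)
  if (G < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(est$n < 2L))
    warning("group(s) with fewer than 2 observations: ",
            paste(est$levels[est$n < 2L], collapse = ", "), call. = FALSE)

  ## Wald test of equal means on G-1 contrasts vs the first group
  C <- cbind(-1, diag(G - 1L))
  delta <- as.vector(C %*% est$mean)
  Vc <- C %*% est$vcov %*% t(C)
  wald <- tryCatch(
    drop(t(delta) %*% solve(Vc, delta)),
    error = function(e) NA_real_)
  df2 <- max(est$df - (G - 1L) + 1L, 1L)
  Fstat <- wald / (G - 1L)
  pval <- stats::pf(Fstat, G - 1L, df2, lower.tail = FALSE)

  ## weighted sums of squares
  keep <- !is.na(y) & !is.na(groups)
  yy <- y[keep]; ww <- w[keep]; gg <- factor(groups[keep])
  grand <- sum(ww * yy) / sum(ww)
  mg <- est$mean[match(levels(gg), est$levels)]
  bss <- sum(est$W * (mg - grand)^2)
  tss <- sum(ww * (yy - grand)^2)
  eta2 <- if (tss > 0) bss / tss else 0

  grp_df <- data.frame(group = est$levels, mean = est$mean,
                       se = sqrt(pmax(diag(est$vcov), 0)), n = est$n,
                       stringsAsFactors = FALSE)

  if (is.null(ranking)) ranking <- est$levels
  ranking <- as.character(ranking)
  unknown <- setdiff(ranking, est$levels)
  if (length(unknown))
    stop("ranking contains unknown group(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  adj <- NULL
  if (length(ranking) >= 2L) {
    rows <- lapply(seq_len(length(ranking) - 1L), function(i) {
      a <- match(ranking[i], est$levels)
      b <- match(ranking[i + 1L], est$levels)
      se_a2 <- est$vcov[a, a]; se_b2 <- est$vcov[b, b]
      se_d <- sqrt(se_a2 + se_b2)
      tt <- if (se_d > 0) (est$mean[b] - est$mean[a]) / se_d else NA_real_
      dfw <- if (se_a2 + se_b2 > 0)
        (se_a2 + se_b2)^2 /
          (se_a2^2 / max(est$n[a] - 1L, 1L) +
           se_b2^2 / max(est$n[b] - 1L, 1L))
      else NA_real_
      p <- if (is.na(tt)) NA_real_
           else 2 * stats::pt(abs(tt), dfw, lower.tail = FALSE)
      data.frame(group_low = ranking[i], group_high = ranking[i + 1L],
                 diff = est$mean[b] - est$mean[a], t = tt, df = dfw, p = p,
                 tier = sig_tier(p), stringsAsFactors = FALSE)
    })
    adj <- do.call(rbind, rows)
  }
  structure(list(groups = grp_df,
                 anova = list(statistic = Fstat, df1 = G - 1L, df2 = df2,
                              p = pval),
                 eta_squared = eta2, adjacent = adj),
            class = "ec_validation")
}

sig_tier <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 0.005, "p<0.005",
                ifelse(p < 0.01, "p<0.01",
                       ifelse(p < 0.05, "p<0.05", "ns"))))
}

#' @export
print.ec_validation <- function(x, ...) {
  cat(sprintf("Weighted one-way ANOVA: F(%d, %d) = %.3f, p = %.3g\n",
              x$anova$df1, x$anova$df2, x$anova$statistic, x$anova$p))
  cat(sprintf("Eta squared: %.4f\n", x$eta_squared))
  print(x$groups, row.names = FALSE)
  if (!is.null(x$adjacent)) {
    cat("Adjacent-group t tests:\n")
    print(x$adjacent, row.names = FALSE)
  }
  invisible(x)
}
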