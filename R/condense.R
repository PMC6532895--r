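#' Per-cluster weighted outcome summaries
#'
#' For each cluster (or any household grouping) computes the survey-weighted
#' mean and standard error of: child height-for-age Z-score (child-level
#' weights), women's literacy score (0-2), and the proportion of a woman's
#' children who are deceased, defined per woman as
#' `(sons_died + daughters_died) / children_ever_born` with childless women
#' excluded.  Each cluster is also tagged with its weighted-majority
#' rural/urban setting.
#'
#' @param labels named vector: cluster/group label per household id (e.g.
#'   `model$assignment`).
#' @param households the `ec_households` table (supplies the setting and,
#'   when present, stratum/psu design columns inherited by members).
#' @param children data.frame from [read_child_table()].
#' @param women data.frame from [read_woman_table()].
#' @return data.frame of class `ec_outcome_summary`: one row per cluster
#'   with `cluster`, `setting`, `n_households`, and `<outcome>_mean`,
#'   `<outcome>_se`, `<outcome>_n` for `haz`, `literacy`, `mortality`.
#' @export
outcome_summary <- function(labels, households, children, women) {
  stopifnot(inherits(households, "ec_households"))
  hh_lab <- labels[match(households$household_id, names(labels))]
  design <- list(stratum = households$stratum, psu = households$psu)

  link <- function(tab) {
    i <- match(tab$household_id, households$household_id)
    list(cluster = hh_lab[i],
         stratum = if (is.null(design$stratum)) NULL else design$stratum[i],
         psu = if (is.null(design$psu)) NULL else design$psu[i])
  }

  clusters <- sort(unique(stats::na.omit(unname(hh_lab))))
  out <- data.frame(cluster = clusters, stringsAsFactors = FALSE)

  ## weighted-majority setting per cluster
  scol <- households[[attr(households, "ec_config")$setting]]
  out$setting <- vapply(clusters, function(cl) {
    idx <- which(hh_lab == cl & !is.na(scol))
    if (!length(idx)) return(NA_character_)
    tw <- tapply(households$weight[idx], scol[idx], sum)
    names(tw)[which.max(tw)]
  }, character(1L))
  out$n_households <- vapply(clusters, function(cl)
    sum(hh_lab == cl, na.rm = TRUE), integer(1L))

  add_outcome <- function(out, name, tab, y) {
    ln <- link(tab)
    mean_v <- se_v <- rep(NA_real_, length(clusters))
    n_v <- integer(length(clusters))
    for (j in seq_along(clusters)) {
      idx <- which(ln$cluster == clusters[j] & !is.na(y))
      n_v[j] <- length(idx)
      if (length(idx) == 0L) {
        warning(sprintf("cluster %s: no observations for outcome '%s'",
                        clusters[j], name), call. = FALSE)
        next
      }
      est <- svy_mean(y[idx], tab$weight[idx],
                      stratum = if (is.null(ln$stratum)) NULL
                                else ln$stratum[idx],
                      psu = if (is.null(ln$psu)) NULL else ln$psu[idx])
      mean_v[j] <- est$mean; se_v[j] <- est$se
    }
    out[[paste0(name, "_mean")]] <- mean_v
    out[[paste0(name, "_se")]] <- se_v
    out[[paste0(name, "_n")]] <- n_v
    out
  }

  out <- add_outcome(out, "haz", children, children$haz)
  out <- add_outcome(out, "literacy", women, as.numeric(women$literacy))
  mort <- deceased_proportion(women)
  out <- add_outcome(out, "mortality", women, mort)
  class(out) <- c("ec_outcome_summary", "data.frame")
  out
}

#' Proportion of a woman's children who are deceased
#'
#' `(sons_died + daughters_died) / children_ever_born`; `NA` for women with
#' no children ever born (they are excluded from the mortality outcome).
#'
#' @param women data.frame from [read_woman_table()].
#' @return numeric vector in `[0, 1]` with `NA` for childless women.
#' @export
deceased_proportion <- function(women) {
  ifelse(women$children_ever_born > 0,
         (women$sons_died + women$daughters_died) / women$children_ever_born,
         NA_real_)
}

#' Condense clusters into broader economic groups
#'
#' Within each setting stratum (rural / urban, taken from the summary), the
#' three per-cluster outcome means are standardized across that stratum's
#' clusters (mean 0, sd 1 per outcome, so no outcome dominates by scale),
#' a Euclidean dissimilarity matrix is computed on the scaled 3-vectors and
#' agglomerative hierarchical clustering is run.  The dendrograms are then
#' cut at a common height chosen so that the total number of groups across
#' strata falls inside `target_groups` with as few groups as possible.
#' Clusters listed together in `keep_separate` are never merged: groups
#' violating the constraint are split further.
#'
#' @param summary an `ec_outcome_summary` with all three outcome means
#'   defined for every cluster.
#' @param target_groups inclusive interval (length-2) for the total number
#'   of condensed groups (default `c(5, 10)`).
#' @param linkage hierarchical linkage: `"complete"` (default),
#'   `"average"` or `"ward.D2"`.
#' @param keep_separate list of vectors of cluster labels that must remain
#'   in distinct groups (subject-matter overrides).
#' @return an object of class `ec_condensed`: list with `mapping`
#'   (data.frame cluster, setting, group), `trees` (one `hclust` per
#'   stratum), `heights`, `scaled` matrices, `linkage`.
#' @export
condense_clusters <- function(summary, target_groups = c(5, 10),
                              linkage = c("complete", "average", "ward.D2"),
                              keep_separate = list()) {
  stopifnot(inherits(summary, "ec_outcome_summary"),
            length(target_groups) == 2L,
            target_groups[1L] >= 1, target_groups[2L] >= target_groups[1L])
  linkage <- match.arg(linkage)
  ocols <- c("haz_mean", "literacy_mean", "mortality_mean")
  if (any(is.na(as.matrix(summary[ocols]))))
    stop("all three outcome means must be defined for every cluster",
         call. = FALSE)

  strata <- split(summary, summary$setting)
  trees <- list(); scaled <- list()
  for (s in names(strata)) {
    sm <- strata[[s]]
    if (nrow(sm) < 2L) { trees[[s]] <- NULL; scaled[[s]] <- NULL; next }
    X <- as.matrix(sm[ocols])
    rownames(X) <- as.character(sm$cluster)
    sds <- apply(X, 2L, stats::sd)
    if (any(sds == 0)) {
      warning("stratum '", s, "': outcome(s) with zero variance across ",
              "clusters dropped from scaling: ",
              paste(ocols[sds == 0], collapse = ", "), call. = FALSE)
      X <- X[, sds > 0, drop = FALSE]
      if (ncol(X) == 0L)
        stop("stratum '", s, "': no outcome varies across clusters",
             call. = FALSE)
    }
    Xs <- scale(X)
    trees[[s]] <- stats::hclust(stats::dist(Xs, method = "euclidean"),
                                method = linkage)
    scaled[[s]] <- Xs
  }
  single <- names(strata)[vapply(strata, nrow, integer(1L)) < 2L]

  ## cut all dendrograms at a common height; prefer the fewest groups whose
  ## total falls inside target_groups
  cut_at <- function(h) {
    gl <- list()
    for (s in names(strata)) {
      sm <- strata[[s]]
      gl[[s]] <- if (is.null(trees[[s]])) {
        stats::setNames(rep(1L, nrow(sm)), as.character(sm$cluster))
      } else stats::cutree(trees[[s]], h = h)
    }
    gl
  }
  n_groups <- function(gl) sum(vapply(gl, function(g) length(unique(g)),
                                      integer(1L)))
  heights <- sort(unique(c(0, unlist(lapply(trees, `[[`, "height")))),
                  decreasing = TRUE)
  chosen <- NULL
  for (h in c(heights[1L] + 1, heights)) {
    gl <- cut_at(h)
    tot <- n_groups(gl)
    if (tot >= target_groups[1L] && tot <= target_groups[2L]) {
      chosen <- gl; chosen_h <- h; break
    }
    if (tot > target_groups[2L]) break
  }
  if (is.null(chosen)) {
    ## no common height lands in the interval; take the finest cut not
    ## exceeding the upper bound
    for (h in heights) {
      gl <- cut_at(h); tot <- n_groups(gl)
      if (tot <= target_groups[2L]) { chosen <- gl; chosen_h <- h }
      else break
    }
    if (is.null(chosen)) { chosen <- cut_at(heights[1L] + 1)
                           chosen_h <- heights[1L] + 1 }
    warning("no common dendrogram height yields a total in [",
            target_groups[1L], ", ", target_groups[2L],
            "]; using the closest cut below the upper bound", call. = FALSE)
  }

  ## enforce keep_separate by refining the offending stratum's cut
  if (length(keep_separate)) {
    violated <- function(gl) {
      for (set in keep_separate) {
        for (s in names(gl)) {
          g <- gl[[s]]
          inset <- intersect(as.character(set), names(g))
          if (length(inset) >= 2L && anyDuplicated(g[inset]))
            return(s)
        }
      }
      NULL
    }
    repeat {
      s <- violated(chosen)
      if (is.null(s)) break
      kcur <- length(unique(chosen[[s]]))
      if (is.null(trees[[s]]) || kcur >= length(chosen[[s]]))
        stop("keep_separate constraint cannot be satisfied in stratum '",
             s, "'", call. = FALSE)
      chosen[[s]] <- stats::cutree(trees[[s]], k = kcur + 1L)
    }
  }

  mapping <- do.call(rbind, lapply(names(chosen), function(s) {
    g <- chosen[[s]]
    data.frame(cluster = names(g), setting = s,
               group = paste0(s, "-", unname(g)), stringsAsFactors = FALSE)
  }))
  rownames(mapping) <- NULL
  structure(list(mapping = mapping, trees = trees, scaled = scaled,
                 cut_height = chosen_h, linkage = linkage,
                 target_groups = target_groups,
                 single_strata = single),
            class = "ec_condensed")
}

#' @export
print.ec_condensed <- function(x, ...) {
  tab <- table(x$mapping$setting,
               sub("^.*-", "", x$mapping$group))
  cat(sprintf("Condensed model: %d groups from %d clusters (%s linkage, cut height %.3f)\n",
              length(unique(x$mapping$group)), nrow(x$mapping),
              x$linkage, x$cut_height))
  print(x$mapping, row.names = FALSE)
  invisible(x)
}

#' Export per-stratum dendrograms as Newick strings
#'
#' @param condensed an `ec_condensed`.
#' @return named character vector of Newick trees (one per stratum with at
#'   least 2 clusters).
#' @export
ec_newick <- function(condensed) {
  stopifnot(inherits(condensed, "ec_condensed"))
  trees <- condensed$trees[!vapply(condensed$trees, is.null, logical(1L))]
  vapply(trees, function(tr) ape::write.tree(ape::as.phylo(tr)),
         character(1L))
}

#' Ordinally rank condensed groups by outcome levels
#'
#' Within each setting stratum, groups are ranked by mean women's literacy
#' (ascending, rank 1 = poorest).  For every adjacent pair the ranking
#' checks whether mean child HAZ (ascending) and the deceased-children
#' proportion (descending) order the pair the same way; disagreements are
#' recorded in the `conflicts` attribute rather than silently resolved.
#' Exact literacy ties break by HAZ, then by mortality, and are flagged.
#'
#' @param group_summary an `ec_outcome_summary` computed over condensed
#'   group labels (see [outcome_summary()]).
#' @return data.frame of class `ec_ranking`: `group`, `setting`, `rank`
#'   (within stratum, 1 = poorest); attribute `conflicts` is a data.frame
#'   of indicator disagreements.
#' @export
rank_groups <- function(group_summary) {
  stopifnot(inherits(group_summary, "ec_outcome_summary"))
  conflicts <- list()
  parts <- lapply(split(group_summary, group_summary$setting), function(sm) {
    ord <- order(sm$literacy_mean, sm$haz_mean, -sm$mortality_mean)
    sm <- sm[ord, , drop = FALSE]
    n <- nrow(sm)
    if (n >= 2L) {
      for (i in seq_len(n - 1L)) {
        lit_tie <- sm$literacy_mean[i] == sm$literacy_mean[i + 1L]
        haz_ok <- sm$haz_mean[i] <= sm$haz_mean[i + 1L]
        mort_ok <- sm$mortality_mean[i] >= sm$mortality_mean[i + 1L]
        if (lit_tie || !haz_ok || !mort_ok)
          conflicts[[length(conflicts) + 1L]] <<- data.frame(
            setting = sm$setting[1L],
            group_low = sm$cluster[i], group_high = sm$cluster[i + 1L],
            indicator = if (lit_tie) "literacy_tie"
                        else if (!haz_ok && !mort_ok) "haz+mortality"
                        else if (!haz_ok) "haz" else "mortality",
            stringsAsFactors = FALSE)
      }
    }
    data.frame(group = sm$cluster, setting = sm$setting, rank = seq_len(n),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  attr(out, "conflicts") <- if (length(conflicts))
    do.call(rbind, conflicts) else NULL
  class(out) <- c("ec_ranking", "data.frame")
  out
}

#' @export
print.ec_ranking <- function(x, ...) {
  cat("Ordinal wealth ranking (1 = poorest, per stratum):\n")
  print(as.data.frame(x), row.names = FALSE)
  cf <- attr(x, "conflicts")
  if (!is.null(cf)) {
    cat("Indicator conflicts:\n")
    print(cf, row.names = FALSE)
  } else cat("No indicator conflicts.\n")
  invisible(x)
}

#' Map original cluster labels to condensed group labels
#'
#' @param labels named vector of original cluster labels per household.
#' @param condensed an `ec_condensed`.
#' @return named character vector of condensed group labels.
#' @export
condensed_labels <- function(labels, condensed) {
  stopifnot(inherits(condensed, "ec_condensed"))
  m <- condensed$mapping
  stats::setNames(m$group[match(as.character(labels), m$cluster)],
                  names(labels))
}
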