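## Group-level statistics: monthly climate aggregation, Welch two-group
## contrasts (climate variables, photosynthesis parameters) and a generic
## hypergeometric over-representation test.

#' Per-accession monthly mean and SD of climate variables
#'
#' @param climate data.frame with columns `accession`, `variable` and
#'   `month_01 ... month_NN` (exactly `months` of them).
#' @param months expected number of monthly columns (default 12).
#' @return data.frame `accession`, `variable`, `mean`, `sd` (sample SD,
#'   denominator n-1, across the months of the year).
#' @export
monthly_summary <- function(climate, months = 12) {
  mcols <- grep("^month_\\d+$", names(climate), value = TRUE)
  gk_assert(length(mcols) == months,
            sprintf("expected %d monthly columns, found %d", months,
                    length(mcols)))
  m <- as.matrix(climate[, mcols])
  gk_assert(!anyNA(m), "missing monthly values are not allowed")
  data.frame(accession = climate$accession, variable = climate$variable,
             mean = rowMeans(m), sd = apply(m, 1, sd),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Welch two-group contrast of one per-accession quantity
#'
#' Welch (unequal-variance) two-sided t-test of group A versus group B.
#' Accessions without a value are dropped (with a message).  If both groups
#' have zero variance: equal means give `t = 0, p = 1`; unequal means are
#' perfectly separated and the variance is floored at 1e-12 (degenerate,
#' flagged in the result).
#'
#' @param values named numeric vector, accession -> value.
#' @param groups an accession [grouping()].
#' @param group_a,group_b cluster ids to contrast.
#' @return One-row data.frame: `mean_a`, `mean_b`, `t_stat`, `df`,
#'   `p_value`, `n_a`, `n_b`, `degenerate`.
#' @export
group_ttest <- function(values, groups, group_a, group_b) {
  gk_assert(!is.null(names(values)), "values must be named by accession")
  pick <- function(gid) {
    ids <- intersect(group_members(groups, gid), names(values))
    v <- values[ids]
    v[!is.na(v)]
  }
  va <- pick(group_a); vb <- pick(group_b)
  dropped <- sum(groups$labels %in% c(group_a, group_b)) -
    length(va) - length(vb)
  if (dropped > 0)
    message(sprintf("group_ttest: %d accession(s) without a value dropped",
                    dropped))
  gk_assert(length(va) >= 2 && length(vb) >= 2,
            "both groups need >= 2 accessions with values")
  degenerate <- var(va) == 0 && var(vb) == 0
  if (degenerate) {
    if (mean(va) == mean(vb)) {
      t_stat <- 0; df <- length(va) + length(vb) - 2; p <- 1
    } else {
      se <- sqrt(1e-12 / length(va) + 1e-12 / length(vb))
      t_stat <- (mean(va) - mean(vb)) / se
      df <- length(va) + length(vb) - 2
      p <- 2 * pt(-abs(t_stat), df)
    }
  } else {
    tt <- stats::t.test(va, vb, var.equal = FALSE)
    t_stat <- unname(tt$statistic); df <- unname(tt$parameter); p <- tt$p.value
  }
  data.frame(mean_a = mean(va), mean_b = mean(vb), t_stat = t_stat, df = df,
             p_value = p, n_a = length(va), n_b = length(vb),
             degenerate = degenerate, row.names = NULL)
}

#' Ranked two-group contrasts of climate summaries
#'
#' Applies [group_ttest()] to every (variable, statistic) combination of a
#' [monthly_summary()] table and ranks the results by ascending p-value.
#'
#' @param summary output of [monthly_summary()].
#' @param groups,group_a,group_b as in [group_ttest()].
#' @return data.frame with columns `variable`, `statistic` (`mean` or `sd`),
#'   the [group_ttest()] columns, `q_value` (BH across rows) and `rank`.
#' @export
climate_group_tests <- function(summary, groups, group_a, group_b) {
  rows <- list()
  for (v in unique(summary$variable)) {
    sub <- summary[summary$variable == v, ]
    for (stat in c("mean", "sd")) {
      vals <- setNames(sub[[stat]], sub$accession)
      rows[[paste(v, stat)]] <- cbind(
        data.frame(variable = v, statistic = stat, stringsAsFactors = FALSE),
        group_ttest(vals, groups, group_a, group_b))
    }
  }
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  out <- out[order(out$p_value), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Group-by-condition contrasts of photosynthesis parameters
#'
#' For each parameter and each accession group, Welch-tests the two light
#' conditions against each other (unpaired), mirroring within-group
#' condition contrasts of PAM-fluorometry parameters; additionally tests
#' group A against group B within each condition.
#'
#' @param photo data.frame with columns `accession`, `condition`,
#'   `parameter`, `value`.
#' @param groups an accession [grouping()].
#' @param group_a,group_b cluster ids.
#' @return data.frame: `parameter`, `contrast`, `group` or `condition`
#'   context, and the [group_ttest()] columns.
#' @export
photosynthesis_tests <- function(photo, groups, group_a, group_b) {
  conds <- sort(unique(photo$condition))
  gk_assert(length(conds) == 2, "need exactly two conditions")
  rows <- list()
  for (par in unique(photo$parameter)) {
    sub <- photo[photo$parameter == par, ]
    ## condition contrast within each group
    for (g in c(group_a, group_b)) {
      members <- group_members(groups, g)
      s <- sub[sub$accession %in% members, ]
      va <- setNames(s$value[s$condition == conds[1]],
                     s$accession[s$condition == conds[1]])
      vb <- setNames(s$value[s$condition == conds[2]],
                     s$accession[s$condition == conds[2]])
      cond_groups <- grouping(setNames(
        rep(1:2, c(length(va), length(vb))),
        c(paste0(names(va), ".1"), paste0(names(vb), ".2"))), 2)
      vals <- setNames(c(va, vb), names(cond_groups$labels))
      rows[[paste(par, "cond", g)]] <- cbind(
        data.frame(parameter = par,
                   contrast = paste0(conds[1], "_vs_", conds[2]),
                   within = paste0("group", g), stringsAsFactors = FALSE),
        group_ttest(vals, cond_groups, 1, 2))
    }
    ## group contrast within each condition
    for (cn in conds) {
      s <- sub[sub$condition == cn, ]
      vals <- setNames(s$value, s$accession)
      rows[[paste(par, "group", cn)]] <- cbind(
        data.frame(parameter = par,
                   contrast = paste0("group", group_a, "_vs_group", group_b),
                   within = cn, stringsAsFactors = FALSE),
        group_ttest(vals, groups, group_a, group_b))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Hypergeometric over-representation of labels in a selection
#'
#' One-sided (upper tail) hypergeometric test per label of a category map,
#' with BH adjustment across labels.  A generic replacement for web-based
#' enrichment services: categories may be GO terms, countries of origin,
#' admixture groups, or any other item labels.
#'
#' @param selected character vector of selected items (non-empty, subset of
#'   `universe`).
#' @param universe character vector of all items.
#' @param categories named character vector, item -> label (items without a
#'   label are ignored for that label's counts but stay in the universe).
#' @return data.frame per label: `label`, `count_sel`, `count_univ`,
#'   `n_sel`, `n_univ`, `p_hypergeom`, `q_bh`, sorted by ascending p.
#' @export
overrepresentation <- function(selected, universe, categories) {
  gk_assert(length(selected) > 0, "selected set is empty")
  bad <- setdiff(selected, universe)
  if (length(bad) > 0)
    gk_stop(paste("selected items outside the universe:",
                  paste(bad, collapse = ", ")), "glknet_invalid")
  labs <- sort(unique(categories[names(categories) %in% universe]))
  n_univ <- length(universe)
  n_sel <- length(selected)
  rows <- lapply(labs, function(L) {
    members <- names(categories)[categories == L]
    K <- length(intersect(members, universe))
    k <- length(intersect(members, selected))
    p <- phyper(k - 1, K, n_univ - K, n_sel, lower.tail = FALSE)
    data.frame(label = L, count_sel = k, count_univ = K,
               n_sel = n_sel, n_univ = n_univ, p_hypergeom = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_bh <- bh_adjust(out$p_hypergeom)
  out <- out[order(out$p_hypergeom, out$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}
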