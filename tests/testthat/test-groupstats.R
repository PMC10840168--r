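# Climate aggregation, Welch group contrasts, photosynthesis
# group-by-condition tests and hypergeometric over-representation.

test_that("monthly summary computes mean and sample SD", {
  clim <- data.frame(accession = c("a1", "a2", "a3"), variable = "srad")
  vals <- rbind(rep(5, 12), 1:12, rnorm(12))
  colnames(vals) <- sprintf("month_%02d", 1:12)
  clim <- cbind(clim, vals)
  s <- monthly_summary(clim)
  expect_equal(s$sd[1], 0)
  expect_equal(s$mean[2], 6.5)
  expect_equal(s$sd[2], sqrt(13))       # sum((x - 6.5)^2) = 143; 143/11 = 13
  expect_equal(s$mean[3], mean(vals[3, ]))
  expect_error(monthly_summary(clim[, -3]), "monthly columns")
})

test_that("monthly SD is translation-invariant and scales linearly", {
  set.seed(14)
  base <- data.frame(accession = "a1", variable = "v")
  v <- rnorm(12, 100, 20)
  mk <- function(x) {
    d <- cbind(base, as.data.frame(t(x)))
    names(d)[-(1:2)] <- sprintf("month_%02d", 1:12)
    monthly_summary(d)
  }
  expect_equal(mk(v + 50)$sd, mk(v)$sd, tolerance = 1e-12)
  expect_equal(mk(3 * v)$sd, 3 * mk(v)$sd, tolerance = 1e-12)
})

test_that("group t-test matches a from-scratch Welch computation", {
  set.seed(15)
  for (i in 1:5) {
    na <- sample(3:10, 1); nb <- sample(3:10, 1)
    va <- rnorm(na); vb <- rnorm(nb, 0.5)
    vals <- setNames(c(va, vb), sprintf("a%02d", seq_len(na + nb)))
    g <- grouping(setNames(rep(1:2, c(na, nb)), names(vals)))
    res <- group_ttest(vals, g, 1, 2)
    se2 <- var(va) / na + var(vb) / nb
    t_exp <- (mean(va) - mean(vb)) / sqrt(se2)
    df_exp <- se2^2 / (var(va)^2 / (na^2 * (na - 1)) +
                         var(vb)^2 / (nb^2 * (nb - 1)))
    expect_equal(res$t_stat, t_exp, tolerance = 1e-12)
    expect_equal(res$df, df_exp, tolerance = 1e-12)
    expect_equal(res$p_value, 2 * pt(-abs(t_exp), df_exp), tolerance = 1e-12)
  }
})

test_that("degenerate group contrasts are handled", {
  g <- grouping(setNames(rep(1:2, each = 4), sprintf("a%d", 1:8)))
  same <- setNames(rep(c(1, 2, 3, 2), 2), sprintf("a%d", 1:8))
  ## identical distributions
  res <- group_ttest(same, g, 1, 2)
  expect_equal(res$t_stat, 0)
  expect_equal(res$p_value, 1)
  ## zero variance in both groups, equal means
  flat <- setNames(rep(5, 8), sprintf("a%d", 1:8))
  resf <- group_ttest(flat, g, 1, 2)
  expect_equal(resf$p_value, 1)
  expect_true(resf$degenerate)
  ## zero variance, separated means: p below any threshold
  sep <- setNames(rep(c(0, 10), each = 4), sprintf("a%d", 1:8))
  ress <- group_ttest(sep, g, 1, 2)
  expect_lt(ress$p_value, 1e-10)
  expect_true(ress$degenerate)
  ## accessions without values are dropped with a message
  partial <- setNames(c(1, 2, 3, NA, 4, 5, 6, NA), sprintf("a%d", 1:8))
  expect_message(group_ttest(partial, g, 1, 2), "dropped")
})

test_that("solar-radiation monthly SD ranks first among climate variables", {
  b <- generate_dataset(small_config(seed = 16))
  s <- monthly_summary(b$climate)
  gr <- grouping(b$truth$accession_groups)
  tests <- climate_group_tests(s, gr, 1, 2)
  expect_equal(tests$variable[1], "srad")
  expect_equal(tests$statistic[1], "sd")
  expect_lt(tests$p_value[1], 1e-7)
  expect_equal(tests$rank, seq_len(nrow(tests)))
  expect_true(!is.unsorted(tests$p_value))
})

test_that("planted NPQ interaction appears in the right group only", {
  b <- generate_dataset(small_config(seed = 18))
  gr <- grouping(b$truth$accession_groups)
  tests <- photosynthesis_tests(b$photosynthesis, gr, 1, 2)
  npq <- tests[tests$parameter == "NPQ_Lss" &
                 tests$contrast == "coastal_vs_inland", ]
  p_g1 <- npq$p_value[npq$within == "group1"]
  p_g2 <- npq$p_value[npq$within == "group2"]
  expect_lt(p_g2, 1e-4)       # group 2 shifts under high light
  expect_gt(p_g1, 0.01)       # group 1 does not
  qy <- tests[tests$parameter == "QY_max" &
                tests$contrast == "coastal_vs_inland", ]
  expect_lt(qy$p_value[qy$within == "group1"],
            qy$p_value[qy$within == "group2"])
})

test_that("over-representation matches the exact hypergeometric", {
  universe <- sprintf("i%02d", 1:10)
  cats <- setNames(rep(c("L", "M"), each = 5), universe)
  res <- overrepresentation(universe[1:5], universe, cats)
  expect_equal(res$p_hypergeom[res$label == "L"], 1 / choose(10, 5),
               tolerance = 1e-12)
  ## selecting the whole universe is never enriched
  res_all <- overrepresentation(universe, universe, cats)
  expect_true(all(res_all$p_hypergeom == 1))
  expect_error(overrepresentation(character(), universe, cats), "empty")
  expect_error(overrepresentation(c("i01", "zz"), universe, cats),
               "outside the universe")
})
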