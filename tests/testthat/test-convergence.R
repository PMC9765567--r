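# Pairwise-distance transform, Mann-Whitney machinery, BH, and the screens.

test_that("pairwise distances enumerate unordered pairs", {
  expect_length(pairwise_distances(setNames(rnorm(6), letters[1:6])), 15)
  expect_equal(unname(pairwise_distances(c(a = 2, b = 2, c = 2))), c(0, 0, 0))
  expect_setequal(unname(pairwise_distances(c(x = 0, y = 1, z = 3))), c(1, 3, 2))
  expect_error(pairwise_distances(c(1, NA)), ">= 2")
})

test_that("U counts pairs with x < y, ties half", {
  expect_equal(mwu_u(1:3, 4:6), 9)
  expect_equal(mwu_u(rep(2, 4), rep(2, 4)), 8)  # n^2 / 2 under total ties
  set.seed(5)
  xs <- sample(1:4, 5, replace = TRUE)
  ys <- sample(1:4, 5, replace = TRUE)
  brute <- sum(outer(xs, ys, function(a, b) (a < b) + 0.5 * (a == b)))
  expect_equal(mwu_u(xs, ys), brute)
})

test_that("normal approximation reproduces the anchored p-value", {
  # the divergence anchor: U = 19 at n = (15, 15), lower tail, continuity on
  expect_equal(signif(mwu_normal_p(19, 15, 15, "less", continuity = TRUE), 2),
               5.7e-5)
  # the central value sits at one half up to the continuity shift
  p_mid <- mwu_normal_p(15 * 15 / 2, 15, 15, "less")
  expect_lt(abs(p_mid - 0.5), 0.01)
  # small-sample sanity against full enumeration: n1 = n2 = 3, U = 0
  expect_lt(abs(mwu_normal_p(0, 3, 3, "less") - 0.05), 0.02)
})

test_that("lower and upper tails are reflections of each other", {
  for (U in c(0, 7, 30, 112.5, 200)) {
    expect_equal(mwu_normal_p(U, 15, 15, "less"),
                 mwu_normal_p(15 * 15 - U, 15, 15, "greater"))
  }
})

test_that("BH adjustment equals the literal step-up procedure", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(9)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, bh_stepup_oracle(p))
    expect_true(all(sort(q) >= sort(p)))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("convergence classifier labels the obvious extremes", {
  strains <- paste0("S", 1:6)
  mk <- function(id, wt, ep) {
    rbind(data.frame(phenotype_id = id, unit = "1/h", strain = strains,
                     stage = "WT", value = wt, stdev = NA_real_),
          data.frame(phenotype_id = id, unit = "1/h", strain = strains,
                     stage = "EP", value = ep, stdev = NA_real_))
  }
  spread <- c(0, 3, 7, 12, 20, 31)
  tab <- rbind(mk("conv", spread, rep(5, 6)),       # EP distances all zero
               mk("same", spread, spread),          # identical stages
               mk("div", rep(5, 6), spread))
  res <- classify_convergence(tab, fdr = 0.05)
  expect_equal(res$label[res$phenotype_id == "conv"], "convergent")
  expect_equal(res$label[res$phenotype_id == "same"], "neither")
  expect_equal(res$label[res$phenotype_id == "div"], "divergent")

  # invariance to per-phenotype affine rescaling (ranks are unchanged)
  tab2 <- tab
  tab2$value <- tab2$value * 3.7 - 11
  res2 <- classify_convergence(tab2, fdr = 0.05)
  expect_equal(res2$U, res$U)
  expect_equal(res2$label, res$label)

  # a phenotype missing a stage is skipped with a warning
  tab3 <- rbind(tab, data.frame(phenotype_id = "halfdata", unit = "1/h",
                                strain = strains, stage = "WT",
                                value = rnorm(6), stdev = NA_real_))
  expect_warning(res3 <- classify_convergence(tab3), "halfdata")
  expect_false("halfdata" %in% res3$phenotype_id)
})

test_that("growth-correlation screen matches the closed-form Pearson r", {
  g <- c(0.6, 0.7, 0.85, 0.95, 1.05)
  vals <- rbind(
    affine = 3 + 2 * g,                 # exact positive correlate
    hand = c(2.0, 1.0, 4.0, 3.0, 5.0),
    flat = rep(1, 5)
  )
  scr <- growth_correlation_screen(vals, g)
  expect_equal(scr$r[scr$target == "affine"], 1)
  expect_lt(scr$q[scr$target == "affine"], 1e-6)
  v <- vals["hand", ]
  r_closed <- sum((v - mean(v)) * (g - mean(g))) /
    sqrt(sum((v - mean(v))^2) * sum((g - mean(g))^2))
  expect_equal(scr$r[scr$target == "hand"], r_closed)
  expect_equal(scr$p[scr$target == "flat"], 1)
  expect_false(scr$significant[scr$target == "flat"])
  expect_error(growth_correlation_screen(vals[, 1:2], g[1:2]), ">= 3")
})

test_that("strain ANOVA equals the hand-computed mean-square ratio", {
  vals <- c(1.1, 0.9, 1.0, 3.2, 2.8, 3.0, 5.1, 4.9, 5.0)
  grp <- rep(c("a", "b", "c"), each = 3)
  res <- anova_f_strain(vals, grp)
  gm <- mean(vals)
  means <- tapply(vals, grp, mean)
  ss_b <- sum(3 * (means - gm)^2)
  ss_w <- sum((vals - means[grp])^2)
  F_hand <- (ss_b / 2) / (ss_w / 6)
  expect_equal(res$F, F_hand, tolerance = 1e-12)
  expect_lt(res$p, 1e-6)

  expect_warning(res0 <- anova_f_strain(c(1, 1, 2, 2), c("a", "a", "b", "b")),
                 "zero within-group")
  expect_equal(res0$F, Inf)
  expect_equal(res0$p, 0)
  expect_error(anova_f_strain(1:4, c("a", "a", "a", "b")), ">= 2 observations")
})

test_that("strain ANOVA p-values are calibrated under label permutation", {
  set.seed(21)
  p <- replicate(300, {
    vals <- rnorm(18)
    anova_f_strain(vals, rep(paste0("s", 1:6), each = 3))$p
  })
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
  expect_lt(abs(mean(p <= 0.05) - 0.05), 0.03)
})
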