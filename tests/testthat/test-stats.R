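null_table <- function(n_rep = 3) {
  tidyr::expand_grid(water = c("CK", "T1", "T2", "T3"),
                     potassium = c("K0", "K1"),
                     stage = c("II", "III"),
                     rep = seq_len(n_rep))
}

test_that("ANOVA F statistics match the explicit projection oracle", {
  set.seed(21)
  for (i in 1:5) {
    tab <- null_table()
    tab$y <- rnorm(nrow(tab), mean = 10, sd = 2) +
      2 * (tab$water == "T2") + 1.5 * (tab$potassium == "K1") * (tab$stage == "III")
    fit <- factorial_anova(tab, "y", c("water", "potassium", "stage"))
    got <- tidy(fit)
    oracle <- projection_anova(tab, "y", c("water", "potassium", "stage"))
    got_terms <- got[got$term != "Residuals", ]
    expect_equal(nrow(got_terms), nrow(oracle))
    # aov labels interactions with ':' in the same factor order
    expect_setequal(got_terms$term, oracle$term)
    m <- match(oracle$term, got_terms$term)
    expect_equal(got_terms$statistic[m], oracle$statistic, tolerance = 1e-8)
    expect_equal(got_terms$sumsq[m], oracle$sumsq, tolerance = 1e-8)
    # decomposition is exhaustive
    expect_equal(sum(got$sumsq), sum((tab$y - mean(tab$y))^2), tolerance = 1e-8)
  }
})

test_that("degenerate and malformed designs are rejected informatively", {
  tab <- null_table()
  tab$y <- rnorm(nrow(tab))
  unbal <- tab[-1, ]
  expect_error(factorial_anova(unbal, "y", c("water", "potassium", "stage")),
               "Unbalanced")
  empty <- tab[!(tab$water == "T1" & tab$potassium == "K1"), ]
  expect_error(factorial_anova(empty, "y", c("water", "potassium", "stage")),
               "Empty design cell")
  single <- null_table(n_rep = 1)
  single$y <- rnorm(nrow(single))
  expect_error(factorial_anova(single, "y", c("water", "potassium", "stage")),
               "at least 2")
})

test_that("constant responses yield zero sums of squares for every term", {
  tab <- null_table()
  tab$y <- 5
  fit <- factorial_anova(tab, "y", c("water", "potassium", "stage"))
  td <- tidy(fit)
  expect_equal(td$sumsq, rep(0, nrow(td)))
  expect_equal(td$statistic[td$term != "Residuals"],
               rep(0, nrow(td) - 1))
})

test_that("an injected single-factor effect is detected and only that factor", {
  set.seed(31)
  pvals <- replicate(40, {
    tab <- null_table()
    tab$y <- rnorm(nrow(tab)) + 3 * (tab$water == "T1")
    td <- tidy(factorial_anova(tab, "y", c("water", "potassium", "stage")))
    c(w = td$p.value[td$term == "water"],
      p = td$p.value[td$term == "potassium"])
  })
  expect_true(all(pvals["w", ] < 0.01))
  # the untouched factor stays null: p spread over (0, 1), not concentrated
  expect_gt(mean(pvals["p", ] > 0.05), 0.8)
})

test_that("type-I error of the water main effect under the null is calibrated", {
  set.seed(123)
  rejections <- replicate(500, {
    tab <- null_table()
    tab$y <- rnorm(nrow(tab))
    td <- tidy(factorial_anova(tab, "y", c("water", "potassium", "stage")))
    td$p.value[td$term == "water"] < 0.05
  })
  expect_gte(mean(rejections), 0.03)
  expect_lte(mean(rejections), 0.08)
})

test_that("glance summarises the fit", {
  tab <- null_table()
  set.seed(5)
  tab$y <- rnorm(nrow(tab))
  g <- glance(factorial_anova(tab, "y", c("water", "potassium", "stage")))
  expect_equal(g$nobs, 48)
  expect_equal(g$df.residual, 48 - 16)
  expect_true(g$r.squared >= 0 && g$r.squared <= 1)
})

test_that("LSD letters: equal means share a letter, separated means do not", {
  all_eq <- lsd_letters(c(A = 5, B = 5, C = 5), n = 4,
                        ms_error = 1, df_error = 9)
  expect_equal(all_eq$letters, rep("a", 3))
  split <- lsd_letters(c(lo = 1, hi = 10), n = 4,
                       ms_error = 0.01, df_error = 6)
  expect_equal(split$letters[split$level == "hi"], "a")
  expect_equal(split$letters[split$level == "lo"], "b")
})

test_that("LSD letter display is consistent with every pairwise comparison", {
  set.seed(77)
  for (i in 1:20) {
    k <- sample(3:6, 1)
    means <- stats::setNames(runif(k, 0, 10), LETTERS[1:k])
    n <- sample(3:8, 1)
    mse <- runif(1, 0.5, 8)
    dfe <- k * (n - 1)
    grp <- lsd_letters(means, n, mse, dfe)
    lsd <- stats::qt(0.975, dfe) * sqrt(2 * mse / n)
    share <- function(a, b) {
      la <- strsplit(grp$letters[grp$level == a], "")[[1]]
      lb <- strsplit(grp$letters[grp$level == b], "")[[1]]
      length(intersect(la, lb)) > 0
    }
    for (a in names(means)) for (b in names(means)) {
      if (a < b) {
        signif_diff <- abs(means[a] - means[b]) > lsd
        expect_identical(!share(a, b), unname(signif_diff),
                         label = sprintf("pair %s-%s (iter %d)", a, b, i))
      }
    }
  }
})

test_that("letters follow descending means with 'a' on the largest", {
  grp <- lsd_letters(c(CK = 97.9, T1 = 76.7, T2 = 71.2, T3 = 74.9),
                     n = 36, ms_error = 263, df_error = 280)
  expect_equal(grp$level[1], "CK")
  expect_match(grp$letters[1], "a")
  expect_true(all(diff(grp$mean) <= 0))
})

test_that("Kruskal-Wallis matches the hand-computed rank statistic", {
  # two groups of 3 with no overlap: ranks 1-3 vs 4-6
  d <- tibble::tibble(y = c(1, 2, 3, 10, 11, 12), g = rep(c("a", "b"), each = 3))
  got <- kruskal_wallis(d, "y", "g")
  # H = 12/(N(N+1)) * sum(R_i^2/n_i) - 3(N+1), R = (6, 15)
  h_hand <- 12 / (6 * 7) * (36 / 3 + 225 / 3) - 3 * 7
  expect_equal(got$statistic, h_hand, tolerance = 1e-12)
  expect_equal(got$df, 1)

  same <- tibble::tibble(y = rep(2, 9), g = rep(c("a", "b", "c"), each = 3))
  expect_equal(kruskal_wallis(same, "y", "g")$statistic, 0)
})

test_that("Kruskal-Wallis chi-square p agrees with a permutation oracle", {
  set.seed(13)
  d <- tibble::tibble(y = rnorm(25, mean = rep(c(0, 0.5, 1, 0, 0.2), each = 5)),
                      g = rep(letters[1:5], each = 5))
  got <- kruskal_wallis(d, "y", "g")
  h_obs <- got$statistic
  perm <- replicate(4000, {
    d2 <- d
    d2$y <- sample(d2$y)
    kruskal_wallis(d2, "y", "g")$statistic
  })
  p_perm <- mean(perm >= h_obs - 1e-12)
  se <- sqrt(p_perm * (1 - p_perm) / 4000)
  expect_lt(abs(p_perm - got$p.value), 4 * se + 0.01)
})
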