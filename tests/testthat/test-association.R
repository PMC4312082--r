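test_that("plaque calling uses strict exceedance of 0.3 mm", {
  expect_true(call_plaque(0.31))
  expect_false(call_plaque(0.30))
  expect_true(call_plaque(2.20))
  expect_true(call_plaque(0.30, strict = FALSE))
  expect_error(call_plaque(c(0.4, -0.1)), "positive")
})

test_that("prevalence percentages reproduce their counts", {
  prev <- prevalence_from_counts(c(124, 50, 60, 87), c(126, 200, 190, 163))
  expect_equal(round(prev$pct_plaque, 1), c(49.6, 20.0, 24.0, 34.8))
  expect_equal(round(attr(prev, "overall_pct"), 1), 32.1)
  expect_equal(round(prev$pct_of_all_plaques[1], 1), 38.6)
  # percentages always reproduce counts
  expect_equal(round(prev$pct_plaque * prev$n / 100), prev$n_plaque)
  all_true <- prevalence_table(plaque = rep(TRUE, 40),
                               quartile = rep(1:4, each = 10))
  expect_equal(all_true$pct_plaque, rep(100, 4))
  expect_error(prevalence_table(plaque = TRUE, quartile = 5), "1..4")
})

test_that("chi-square matches the hand-computed Pearson statistic", {
  m <- rbind(c(10, 20), c(20, 10))
  ct <- chi_square(m)
  # brute-force sum over cells of (O - E)^2 / E
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  expect_equal(ct$statistic, sum((m - E)^2 / E))
  expect_equal(ct$df, 1)

  flat <- prevalence_from_counts(rep(50, 4), rep(50, 4))
  cf <- chi_square(flat)
  expect_equal(cf$statistic, 0)
  expect_equal(cf$p.value, 1)

  expect_error(chi_square(rbind(c(0, 0), c(1, 2))), "marginal|groups")
})

test_that("chi-square is permutation-consistent on a null dataset", {
  set.seed(77)
  n <- 1000
  plaque <- runif(n) < 0.3
  quartile <- rep(1:4, each = 250)
  rej <- 0L
  for (r in 1:500) {
    p <- chi_square(prevalence_table(plaque = sample(plaque),
                                     quartile = quartile))$p.value
    if (p < 0.05) rej <- rej + 1L
  }
  expect_gte(rej / 500, 0.03)
  expect_lte(rej / 500, 0.07)
})

test_that("identical groups share one Duncan letter and F is tiny", {
  set.seed(4)
  base <- rnorm(30)
  d <- data.frame(value = rep(base, 4) + rnorm(120, 0, 1e-9),
                  group = rep(1:4, each = 30))
  ad <- anova_duncan(d)
  expect_lt(ad$anova$statistic, 1e-10)
  expect_equal(unique(ad$groups$letters), "a")
})

test_that("two-group Duncan agrees with the pooled t-test decision", {
  set.seed(8)
  for (delta in c(0, 0.3, 0.8, 1.5)) {
    x <- c(rnorm(25), rnorm(25, delta))
    g <- rep(1:2, each = 25)
    ad <- anova_duncan(data.frame(value = x, group = g), alpha = 0.05)
    tt <- t.test(x ~ g, var.equal = TRUE)
    duncan_separates <- ad$groups$letters[1] != ad$groups$letters[2]
    expect_equal(duncan_separates, tt$p.value < 0.05)
  }
})

test_that("Duncan reproduces an independently hand-computed 5-group example", {
  # balanced one-way layout: 5 groups of 5, within-group deviations
  # (-2,-1,0,1,2) so MSE = 2.5 with 20 error df; group means 10, 11, 14,
  # 14.8, 20.  Critical ranges R_p = q(1-(0.95)^(p-1); p, 20) * sqrt(2.5/5):
  dev <- c(-2, -1, 0, 1, 2)
  means <- c(A = 10, B = 11, C = 14, D = 14.8, E = 20)
  d <- data.frame(value = rep(means, each = 5) + rep(dev, 5),
                  group = rep(names(means), each = 5))
  se <- sqrt(2.5 / 5)
  Rp <- sapply(2:5, function(p) qtukey(1 - 0.95^(p - 1), p, 20,
                                       lower.tail = FALSE) * se)
  # independent stepwise check on the ordered means (A B C D E):
  expect_gt(20 - 10, Rp[4])      # E vs A significant
  expect_gt(14.8 - 10, Rp[3]); expect_gt(20 - 11, Rp[3])
  expect_gt(14 - 10, Rp[2]); expect_gt(14.8 - 11, Rp[2]); expect_gt(20 - 14, Rp[2])
  expect_lt(11 - 10, Rp[1])      # A,B homogeneous
  expect_gt(14 - 11, Rp[1])
  expect_lt(14.8 - 14, Rp[1])    # C,D homogeneous
  expect_gt(20 - 14.8, Rp[1])
  # hence homogeneous subsets {A,B}, {C,D}, {E}:
  ad <- anova_duncan(d)
  expect_equal(ad$groups$letters[match(c("A", "B", "C", "D", "E"),
                                       ad$groups$group)],
               c("a", "a", "b", "b", "c"))
})

test_that("Duncan letters are transitive-consistent", {
  set.seed(15)
  for (r in 1:10) {
    k <- sample(3:6, 1)
    d <- data.frame(value = rnorm(20 * k, rep(runif(k, 0, 2), each = 20)),
                    group = rep(seq_len(k), each = 20))
    ad <- anova_duncan(d)
    g <- ad$groups[order(ad$groups$mean), ]
    # every letter marks a contiguous run of mean-ordered groups, so any
    # group between two letter-sharers shares that letter too
    all_letters <- unique(unlist(strsplit(g$letters, "")))
    for (L in all_letters) {
      pos <- which(grepl(L, g$letters, fixed = TRUE))
      expect_equal(pos, seq(min(pos), max(pos)))
    }
  }
})

test_that("GEE with singleton clusters matches ordinary logistic regression", {
  set.seed(9)
  n <- 400
  d <- data.frame(quartile = sample(1:4, n, TRUE), vessel = seq_len(n))
  d$plaque <- runif(n) < plogis(-1 + 0.5 * (d$quartile == 1))
  g <- fit_clustered_binary(d)
  ref <- glm(plaque ~ factor(quartile), binomial, data = d)
  expect_lt(max(abs(g$coefficients - coef(ref))), 1e-6)
})

test_that("GEE working correlation is near zero for independent clusters", {
  set.seed(21)
  n <- 10000
  d <- data.frame(quartile = sample(1:4, n, TRUE),
                  vessel = rep(seq_len(500), each = 20))
  d$plaque <- runif(n) < 0.35
  g <- fit_clustered_binary(d)
  expect_lt(abs(g$alpha), 0.05)
})

test_that("sandwich SEs exceed naive SEs under positive cluster correlation", {
  set.seed(31)
  n <- 10000
  cl <- rep(seq_len(200), each = 50)
  b <- rnorm(200, 0, 1.05)            # latent ICC ~ 0.25
  d <- data.frame(quartile = sample(1:4, n, TRUE), vessel = cl)
  d$plaque <- runif(n) < plogis(-0.6 + b[cl])
  g <- fit_clustered_binary(d)
  expect_gt(g$alpha, 0.05)
  expect_gt(g$robust_se[["(Intercept)"]], g$naive_se[["(Intercept)"]])
})

test_that("degenerate GEE outcomes error rather than silently fit", {
  d <- data.frame(quartile = rep(1:4, 10), vessel = rep(1:4, 10),
                  plaque = TRUE)
  expect_error(fit_clustered_binary(d), "constant|separation")
  expect_error(fit_clustered_binary(data.frame(quartile = 1:4, vessel = 1,
                                               plaque = c(TRUE, FALSE, TRUE, FALSE))),
               "clusters")
})

test_that("tidy and glance methods return well-formed tibbles", {
  set.seed(9)
  n <- 300
  d <- data.frame(quartile = sample(1:4, n, TRUE),
                  vessel = rep(1:30, each = 10))
  d$plaque <- runif(n) < 0.4
  g <- fit_clustered_binary(d)
  td <- tidy(g)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("term", "estimate", "std.error", "naive.std.error",
                     "statistic", "p.value"))
  expect_equal(glance(g)$n, n)
  ad <- anova_duncan(data.frame(value = rnorm(60), group = rep(1:3, 20)))
  expect_true(all(c("group", "mean", "letters") %in% names(tidy(ad))))
  expect_true("mse" %in% names(glance(ad)))
})

test_that("composition ANOVA separates the fibrofatty signal, not the null", {
  cm <- composition_model()
  pts <- tibble::tibble(quartile = rep(1:4, each = 250))
  cc <- simulate_composition(pts, cm, seed = 12, p_not_analyzable = 0)
  ca <- composition_anova(cc)
  expect_equal(ca$tissue, c("fibrous", "fibrofatty", "necrotic", "calcified"))
  expect_lt(ca$p.value[ca$tissue == "fibrofatty"], 0.05)
  expect_error(composition_anova(cc[cc$quartile == 1, ]), "2 quartiles")
})

test_that("composition ANOVA holds its nominal size under the null", {
  cm_null <- composition_model(means = matrix(rep(c(0.55, 0.25, 0.12, 0.08),
                                                  each = 4), 4, 4))
  set.seed(19)
  rej <- matrix(0L, 1000, 4)
  pts <- tibble::tibble(quartile = rep(1:4, each = 250))
  for (r in 1:1000) {
    cc <- simulate_composition(pts, cm_null, seed = NULL, p_not_analyzable = 0)
    ca <- composition_anova(cc)
    rej[r, ] <- as.integer(ca$p.value < 0.05)
  }
  rate <- colMeans(rej)
  expect_true(all(rate >= 0.035 & rate <= 0.065))
})
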