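test_that("thickness model fits the requested truncated moments", {
  tm <- thickness_model()
  for (q in 1:4) {
    m1 <- coroshear:::tlnorm_moment(1, tm$mu[q], tm$sig[q], tm$min[q], tm$max[q])
    m2 <- coroshear:::tlnorm_moment(2, tm$mu[q], tm$sig[q], tm$min[q], tm$max[q])
    expect_equal(m1, tm$mean[q], tolerance = 1e-5)
    expect_equal(sqrt(m2 - m1^2), tm$sd[q], tolerance = 1e-4)
  }
  expect_error(thickness_model(min = c(0.5, 0.01, 0.06, 0.06)), "min < mean")
})

test_that("thickness draws recover the quartile-1 mean within 2 SE at n = 1e4", {
  tm <- thickness_model()
  pts <- tibble::tibble(quartile = rep(1L, 10000))
  th <- simulate_thickness(pts, tm, seed = 42)$thickness_mm
  se <- sd(th) / sqrt(length(th))
  expect_lt(abs(mean(th) - 0.43), 2 * se)
  expect_true(all(th >= tm$min[1] & th <= tm$max[1]))
})

test_that("all four quartile means are recovered within 3 SE at n = 1e4", {
  tm <- thickness_model()
  pts <- tibble::tibble(quartile = rep(1:4, each = 10000))
  th <- simulate_thickness(pts, tm, seed = 7)$thickness_mm
  for (q in 1:4) {
    x <- th[pts$quartile == q]
    expect_lt(abs(mean(x) - tm$mean[q]), 3 * sd(x) / sqrt(length(x)))
  }
})

test_that("vanishing SD collapses draws to the mean", {
  tm <- thickness_model(sd = rep(1e-10, 4))
  th <- simulate_thickness(tibble::tibble(quartile = rep(1:4, 50)), tm,
                           seed = 1)$thickness_mm
  expect_equal(th, tm$mean[rep(1:4, 50)], tolerance = 1e-6)
})

test_that("point sampling respects quartiles, counts, and seeds", {
  set.seed(2)
  qmap <- tibble::tibble(face = 1:2000,
                         quartile = rep(1:4, each = 500),
                         area_mm2 = runif(2000, 0.5, 2))
  pts <- sample_points(qmap, n_per_quartile = 25, seed = 10)
  expect_equal(nrow(pts), 100)
  expect_equal(as.vector(table(pts$quartile)), rep(25L, 4))
  pts2 <- sample_points(qmap, n_per_quartile = 25, seed = 10)
  expect_identical(pts$face, pts2$face)
  pts3 <- sample_points(qmap, n_per_quartile = 25, seed = 11)
  expect_false(identical(pts$face, pts3$face))
  expect_error(sample_points(qmap[1:30, ], n_per_quartile = 25), "fewer")
})

test_that("composition draws close to 1 and put fibrofatty excess in quartile 1", {
  cm <- composition_model()
  pts <- tibble::tibble(quartile = rep(1:4, each = 5000))
  cc <- simulate_composition(pts, cm, seed = 3, p_not_analyzable = 0)
  sums <- cc$fibrous + cc$fibrofatty + cc$necrotic + cc$calcified
  expect_true(all(abs(sums - 1) < 1e-12))
  ffm <- tapply(cc$fibrofatty, cc$quartile, mean)
  expect_true(all(ffm[1] > ffm[2:4]))
})

test_that("large concentration collapses composition to the mean vector", {
  cm <- composition_model(concentration = 1e7)
  cc <- simulate_composition(tibble::tibble(quartile = rep(2L, 500)), cm,
                             seed = 5, p_not_analyzable = 0)
  for (k in 1:4)
    expect_lt(max(abs(cc[[colnames(cm$means)[k]]] - cm$means[2, k])), 0.005)
})

test_that("not-analyzable fraction hits the configured rate on thin plaques", {
  pts <- tibble::tibble(quartile = rep(1:4, each = 250),
                        thickness_mm = runif(1000, 0.31, 2))
  cc <- simulate_composition(pts, composition_model(), seed = 6,
                             p_not_analyzable = 0.19)
  expect_equal(sum(!cc$analyzable), round(0.19 * 1000))
  # the flagged records are the thinnest ones
  expect_lt(max(pts$thickness_mm[!cc$analyzable]),
            min(pts$thickness_mm[cc$analyzable]))
  expect_true(all(is.na(cc$fibrous[!cc$analyzable])))
})

test_that("pullback registration interpolates and extrapolates at nominal speed", {
  reg <- register_pullback(data.frame(time_s = c(0, 40), arclength_mm = c(0, 20)))
  expect_equal(reg$to_arclength(10), 5)
  reg2 <- register_pullback(data.frame(time_s = c(0, 10, 40),
                                       arclength_mm = c(0, 6, 20)))
  expect_equal(reg2$to_arclength(5), 3)   # first segment at 0.6 mm/s
  expect_equal(reg2$to_arclength(20), 6 + 10 * 14 / 30)
  # extrapolation beyond the anchored range at the nominal 0.5 mm/s
  expect_equal(reg2$to_arclength(42), 20 + 2 * 0.5)
  expect_equal(reg2$to_time(-0.25), -0.5)
  expect_error(register_pullback(data.frame(time_s = c(0, 10),
                                            arclength_mm = c(5, 3))),
               "increasing")
})

test_that("registration inverts exactly on the anchored range", {
  lm <- data.frame(time_s = c(0, 8, 21, 40), arclength_mm = c(0, 5, 11, 20))
  reg <- register_pullback(lm)
  t <- seq(0, 40, by = 0.25)
  expect_lt(max(abs(reg$to_time(reg$to_arclength(t)) - t)), 1e-12)
  s <- seq(0, 20, by = 0.1)
  expect_lt(max(abs(reg$to_arclength(reg$to_time(s)) - s)), 1e-12)
})

test_that("the pullback study table has the reference design shape", {
  tab <- simulate_pullback(seed = 1)
  expect_equal(nrow(tab), 10 * 100)
  expect_equal(as.vector(table(tab$quartile)), rep(250L, 4))
  expect_equal(tab$time_s, tab$position_mm / 0.5)
  expect_true(all(tab$thickness_mm > 0))
  # composition only on plaque cross-sections; NA elsewhere
  expect_true(all(is.na(tab$fibrous[!tab$plaque])))
  expect_true(all(!is.na(tab$fibrous[tab$plaque & tab$analyzable])))
  # determinism
  expect_identical(tab, simulate_pullback(seed = 1))
})
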