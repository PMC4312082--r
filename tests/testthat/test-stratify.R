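make_wss_tbl <- function(tau, area) tibble::tibble(tau = tau, area_mm2 = area)

test_that("equal-area faces stratify one per quartile", {
  q <- stratify_by_area_quartiles(make_wss_tbl(c(1, 2, 3, 4), rep(1, 4)))
  expect_equal(q$quartile, 1:4)
  cuts <- attr(q, "cuts")
  expect_true(all(cuts >= c(1, 2, 3) & cuts <= c(2, 3, 4)))
})

test_that("100 equal faces give exactly 25 per quartile", {
  set.seed(11)
  tau <- sample(seq(0.1, 10, length.out = 100))
  q <- stratify_by_area_quartiles(make_wss_tbl(tau, rep(0.5, 100)))
  expect_equal(as.vector(table(q$quartile)), rep(25L, 4))
})

test_that("unequal areas match the sequential oracle and the area bound", {
  set.seed(42)
  for (rep in 1:25) {
    n <- 10
    tau <- runif(n, 0, 5)
    area <- runif(n, 0.2, 3)
    q <- stratify_by_area_quartiles(make_wss_tbl(tau, area))
    expect_equal(q$quartile, oracle_quartile_labels(tau, area))
    qa <- attr(q, "quartile_area")
    expect_true(all(abs(qa - sum(area) / 4) <= max(area) + 1e-12))
    # enumeration: our deviation is within one max-face-area of the best
    # achievable monotone partition
    ord <- order(tau, seq_len(n))
    a_sorted <- area[ord]
    best <- Inf
    for (cuts in enumerate_partitions(n)) {
      lab <- rep(1:4, diff(c(0, cuts, n)))
      dev <- max(abs(tapply(a_sorted, factor(lab, levels = 1:4), sum,
                            default = 0) - sum(area) / 4))
      best <- min(best, dev)
    }
    expect_lte(max(abs(qa - sum(area) / 4)), best + max(area) + 1e-12)
  }
})

test_that("stratification partitions all faces and orders tau across quartiles", {
  set.seed(7)
  n <- 500
  tau <- rexp(n)
  area <- runif(n, 0.1, 1)
  q <- stratify_by_area_quartiles(make_wss_tbl(tau, area))
  expect_equal(sort(unique(q$quartile)), 1:4)
  expect_equal(length(q$quartile), n)
  for (k in 1:3)
    expect_lte(max(q$tau[q$quartile == k]), min(q$tau[q$quartile == k + 1]))
  expect_equal(sum(attr(q, "quartile_area")), sum(area), tolerance = 1e-9)
})

test_that("stratification is invariant to face storage order", {
  set.seed(13)
  n <- 200
  tau <- rnorm(n, 2, 0.5)  # continuous: no ties
  area <- runif(n, 0.2, 2)
  q1 <- stratify_by_area_quartiles(make_wss_tbl(tau, area))
  perm <- sample(n)
  q2 <- stratify_by_area_quartiles(make_wss_tbl(tau[perm], area[perm]))
  expect_equal(q2$quartile, q1$quartile[perm])
  expect_equal(attr(q2, "quartile_area"), attr(q1, "quartile_area"))
  expect_equal(summarize_quartiles(q1)$mean, summarize_quartiles(q2)$mean)
})

test_that("stratification rejects degenerate inputs", {
  expect_error(stratify_by_area_quartiles(make_wss_tbl(numeric(0), numeric(0))),
               "Empty")
  expect_error(stratify_by_area_quartiles(make_wss_tbl(c(1, NaN), c(1, 1))),
               "Non-finite")
  expect_error(stratify_by_area_quartiles(make_wss_tbl(c(1, 2), c(1, -1))),
               "positive")
})

test_that("quartile summaries reproduce constant and ordered inputs", {
  qc <- stratify_by_area_quartiles(make_wss_tbl(rep(2.5, 40), runif(40, 0.5, 1)))
  sc <- summarize_quartiles(qc)
  expect_equal(sc$mean, rep(2.5, 4))
  expect_equal(sc$sd, rep(0, 4))
  expect_true(all(sc$min <= sc$mean & sc$mean <= sc$max))

  q4 <- stratify_by_area_quartiles(make_wss_tbl(c(1, 2, 3, 4), rep(1, 4)))
  s4 <- summarize_quartiles(q4)
  expect_equal(s4$mean, c(1, 2, 3, 4))
  expect_equal(s4$weighted_mean, c(1, 2, 3, 4))

  set.seed(5)
  qr <- stratify_by_area_quartiles(make_wss_tbl(runif(1000), rep(1, 1000)))
  sr <- summarize_quartiles(qr)
  expect_true(all(diff(sr$mean) > 0))
})

test_that("quartile surface extraction partitions the wall area", {
  case <- poiseuille_case(1)
  wall <- case$mesh$wall
  qmap <- stratify_by_area_quartiles(case$wss)
  subs <- extract_quartile_surfaces(wall, qmap)
  areas <- vapply(subs, function(m) sum(m$area), numeric(1))
  expect_equal(sum(areas), sum(wall$area), tolerance = 1e-9)
  expect_equal(sum(vapply(subs, function(m) length(m$area), numeric(1))),
               length(wall$area))
  # face-disjoint: each wall face appears exactly once across submeshes
  all_faces <- unname(sort(unlist(lapply(subs, function(m) m$volume_face))))
  expect_equal(all_faces, sort(wall$volume_face))
})

test_that("10-face submesh membership equals brute-force label grouping", {
  set.seed(23)
  tau <- runif(10, 0, 3)
  area <- runif(10, 0.3, 2)
  q <- stratify_by_area_quartiles(make_wss_tbl(tau, area))
  oracle <- oracle_quartile_labels(tau, area)
  expect_identical(split(seq_len(10), factor(q$quartile, levels = 1:4)),
                   split(seq_len(10), factor(oracle, levels = 1:4)))
})

test_that("degenerate single-quartile map yields one full and three empty submeshes", {
  case <- poiseuille_case(1)
  wall <- case$mesh$wall
  qmap <- stratify_by_area_quartiles(case$wss)
  qmap$quartile <- 1L
  expect_warning(subs <- extract_quartile_surfaces(wall, qmap), "Empty")
  expect_equal(length(subs$Q1$area), length(wall$area))
  expect_equal(length(subs$Q2$area), 0L)
})
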