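test_that("WHO classification follows the trigger-level boundaries", {
  expect_equal(as.character(classify_who(0.04)), "acceptable")
  expect_equal(as.character(classify_who(0.12)), "serious")
  expect_equal(as.character(classify_who(c(0, 0.049999, 0.05, 0.0999, 0.10,
                                           0.1499, 0.15, 0.20, 0.2000001, 1))),
               c("acceptable", "acceptable", "alert", "alert", "serious",
                 "serious", "critical", "critical", "very_critical",
                 "very_critical"))
  # monotone step function on [0, 1]
  p <- seq(0, 1, by = 0.001)
  cls <- classify_who(p)
  expect_true(all(diff(as.integer(cls)) >= 0))
  expect_error(classify_who(1.2), "\\[0, 1\\]")
  expect_error(classify_who(-0.1), "\\[0, 1\\]")
})

test_that("wasted-children counts conserve the pixel products by zone", {
  region <- make_study_region(60, 60, 10)
  xs <- region_pixel_xs(region); ys <- region_pixel_ys(region)
  prev_vals <- withr::with_seed(20, matrix(runif(36, 0.01, 0.4), 6, 6))
  pop_vals <- withr::with_seed(21, matrix(rpois(36, 400), 6, 6))
  prev <- pixel_grid(xs, ys, prev_vals)
  pop <- pixel_grid(xs, ys, pop_vals)
  rt <- wasted_children_counts(prev, pop, region, year = 2007,
                               season = "Jilaal")
  expect_s3_class(rt, "wm_risk_table")
  expect_equal(sum(rt$wasted), sum(prev_vals * pop_vals), tolerance = 1e-10)
  # zone totals equal zone-wise pixel sums
  z <- zone_of(region, rep(xs, 6), rep(ys, each = 6))
  for (zn in unique(z)) {
    expect_equal(sum(rt$wasted[rt$zone == zn]),
                 sum((as.vector(prev_vals) * as.vector(pop_vals))[z == zn]),
                 tolerance = 1e-10)
  }
})

test_that("uniform prevalence and degenerate populations behave exactly", {
  region <- make_study_region(30, 30, 10)
  xs <- region_pixel_xs(region); ys <- region_pixel_ys(region)
  one_zone_pop <- matrix(0, 3, 3); one_zone_pop[1, ] <- c(400, 300, 300)
  prev <- pixel_grid(xs, ys, matrix(0.2, 3, 3))
  pop <- pixel_grid(xs, ys, one_zone_pop)
  rt <- wasted_children_counts(prev, pop, region, year = 2008, season = "Gu")
  expect_equal(sum(rt$wasted), 200)
  expect_true(all(as.character(rt$who_class) == "critical"))
  expect_equal(rt$zone[rt$wasted > 0], "north_west")

  # zero population -> zero counts whatever the prevalence
  rt0 <- wasted_children_counts(pixel_grid(xs, ys, matrix(0.9, 3, 3)),
                                pixel_grid(xs, ys, matrix(0, 3, 3)),
                                region, year = 2008, season = "Gu")
  expect_equal(sum(rt0$wasted), 0)

  # misaligned geometry is an error
  pop_bad <- pixel_grid(xs / 2, ys, matrix(1, 3, 3))
  expect_error(wasted_children_counts(prev, pop_bad, region),
               "not geometrically aligned")
})

test_that("the formatted table masks small cells as <50", {
  rt <- structure(data.frame(zone = "z", year = 2007, season = "Gu",
                             who_class = c("alert", "serious"),
                             wasted = c(49.4, 50.2)),
                  class = c("wm_risk_table", "data.frame"))
  f <- format_risk_table(rt)
  expect_equal(f$wasted, c("<50", "50"))
})

test_that("the survey description table reproduces the packaged fixture", {
  t1 <- summarize_table1(table1_fixture())
  tot <- t1[t1$region == "Total", ]
  expect_equal(tot$n_clusters, 1066)
  expect_equal(tot$n_examined, 73778)
  expect_equal(tot$n_wasted, 15735)
  expect_equal(tot$percent, 21.33)
  expect_equal(t1$percent[t1$region == "Gedo"], 37.45)
  expect_equal(t1$percent[t1$region == "Bakool"], 37.63)
  # totals equal column sums of the table's own rows (self-consistency)
  body <- t1[t1$region != "Total", ]
  expect_equal(colSums(body[c("n_clusters", "n_examined", "n_wasted")]),
               unlist(tot[c("n_clusters", "n_examined", "n_wasted")]))
})

test_that("summarize_table1 validates input and flags empty regions", {
  expect_error(summarize_table1(data.frame()), "nonempty")
  expect_error(summarize_table1(data.frame(region = "a", n_examined = 1)),
               "missing column")
  one <- summarize_table1(data.frame(region = "a", n_examined = 2,
                                     n_wasted = 1))
  expect_equal(one$percent[one$region == "a"], 50.00)
  expect_warning(
    z <- summarize_table1(data.frame(region = c("a", "b"),
                                     n_examined = c(10, 0),
                                     n_wasted = c(2, 0))),
    "zero children examined")
  expect_true(is.na(z$percent[z$region == "b"]))
})

test_that("dry-wet difference averages the seasonal surfaces per regime", {
  xs <- c(5, 15); ys <- c(5, 15)
  mk <- function(v, seas) list(year = 2007, season = seas,
                               mean = pixel_grid(xs, ys, matrix(v, 2, 2)))
  pv <- structure(list(surfaces = list(a = mk(0.30, "Jilaal"),
                                       b = mk(0.20, "Hagaa"),
                                       c = mk(0.15, "Gu"),
                                       d = mk(0.05, "Deyr")),
                       n_masked = 0, n_predicted = 4),
                  class = "wm_prevalence")
  dw <- dry_wet_difference(pv)
  expect_true(all(abs(dw$values - (0.25 - 0.10)) < 1e-12))
})
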