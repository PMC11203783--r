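test_that("intercept-only GLM matches the closed form on random counts", {
  withr::with_seed(11, {
    for (i in 1:15) {
      a <- sample(1:250, 1)
      b <- sample(1:250, 1)
      fit <- fit_two_choice(choices_from_counts(a, b), trait = "hue")
      td <- tidy(fit)
      cf <- intercept_closed_form(a, b)
      expect_equal(td$estimate[1], cf$estimate, tolerance = 1e-6)
      expect_equal(td$std.error[1], cf$std_error, tolerance = 1e-6)
      expect_equal(td$statistic[1], cf$z_value, tolerance = 1e-6)
    }
  })
})

test_that("reconstructed colour-hue counts reproduce the printed coefficients", {
  fit <- fit_two_choice(choices_from_counts(39, 13,
                                            variants = c("blue", "yellow")),
                        trait = "hue")
  expect_identical(fit$success, "yellow")
  td <- tidy(fit)
  expect_equal(round(td$estimate[1], 3), 1.099)
  expect_equal(round(td$std.error[1], 3), 0.320)
  expect_equal(round(td$statistic[1], 3), 3.430)

  fit2 <- fit_two_choice(choices_from_counts(148, 58,
                                             variants = c("blue", "yellow")),
                         trait = "hue")
  td2 <- tidy(fit2)
  expect_equal(round(td2$estimate[1], 3), 0.937)
  expect_equal(round(td2$statistic[1], 3), 6.047)
})

test_that("balanced choices give a zero intercept with p = 1", {
  td <- tidy(fit_two_choice(choices_from_counts(20, 20), trait = "hue"))
  expect_equal(td$estimate[1], 0, tolerance = 1e-9)
  expect_equal(td$p.value[1], 1, tolerance = 1e-9)
})

test_that("relabelling the variants flips the sign but not the evidence", {
  base <- choices_from_counts(30, 10, variants = c("aa", "bb"))
  flip <- dplyr::mutate(base, variant_chosen =
                          ifelse(variant_chosen == "aa", "zz", "aa"))
  t1 <- tidy(fit_two_choice(base, trait = "hue"))
  t2 <- tidy(fit_two_choice(flip, trait = "hue"))
  expect_equal(t1$estimate[1], -t2$estimate[1], tolerance = 1e-6)
  expect_equal(abs(t1$statistic[1]), abs(t2$statistic[1]), tolerance = 1e-6)
  expect_equal(t1$p.value[1], t2$p.value[1], tolerance = 1e-6)
})

test_that("complete separation is flagged instead of crashing", {
  fit <- fit_two_choice(choices_from_counts(25, 0), trait = "hue")
  expect_true(fit$separation)
  td <- tidy(fit)
  expect_identical(td$estimate[1], Inf)
  expect_true(is.na(td$p.value[1]))

  # with the never-chosen variant named explicitly the sign is negative
  fit0 <- fit_two_choice(choices_from_counts(0, 25), trait = "hue",
                         success = "second")
  expect_identical(tidy(fit0)$estimate[1], -Inf)
})

test_that("global fits accept species and covariate factors", {
  ch <- dplyr::bind_rows(
    choices_from_counts(30, 20, species = "sp one"),
    choices_from_counts(10, 25, species = "sp two")
  )
  ch$block <- rep_len(c("yellow", "blue"), nrow(ch))
  fit <- fit_two_choice(ch, trait = "hue", covariate = "block")
  td <- tidy(fit)
  expect_true(any(grepl("species", td$term)))
  expect_true(any(grepl("block", td$term)))
  expect_equal(fit$n_obs, 85L)
})

test_that("closed-form intercept handles the worked examples", {
  expect_equal(unlist(intercept_closed_form(1, 1)[, c("estimate", "std_error")]),
               c(estimate = 0, std_error = sqrt(2)), tolerance = 1e-5)
  cf <- intercept_closed_form(11, 16)
  expect_equal(round(cf$estimate, 4), -0.3747)
  expect_equal(round(cf$std_error, 4), 0.3917)
  cf2 <- intercept_closed_form(9, 24)
  expect_equal(round(cf2$estimate, 4), -0.9808)
  expect_equal(round(cf2$std_error, 4), 0.3909)
  expect_error(intercept_closed_form(0, 5), ">= 1")
})

test_that("count recovery inverts the closed form and flags ambiguity", {
  expect_equal(unlist(recover_counts(1.099, 0.320)[, c("a", "b")]),
               c(a = 39, b = 13))
  expect_equal(unlist(recover_counts(0.937, 0.155)[, c("a", "b")]),
               c(a = 148, b = 58))
  expect_equal(unlist(recover_counts(0, 1.41421)[, c("a", "b")]),
               c(a = 1, b = 1))
  expect_error(recover_counts(25, 0.001), "No integer pair")

  # round trip on random pairs
  withr::with_seed(23, {
    for (i in 1:10) {
      a <- sample(1:150, 1); b <- sample(1:150, 1)
      cf <- intercept_closed_form(a, b)
      rec <- recover_counts(cf$estimate, cf$std_error, max_total = 300)
      if (rec$unique) expect_equal(c(rec$a, rec$b), c(a, b))
    }
  })
})

test_that("consumption rates convert weighings to mg per hour", {
  rec <- tibble::tibble(
    flower_id = c("F1", "F2", "F3"), depth = c("flat", "deep", "flat"),
    weight_mg_t0 = c(1000, 1000, 1000),
    weight_mg_t40 = c(900, 1000, 950),
    weight_mg_t2h = c(880, 1000, 850)
  )
  r40 <- consumption_rates(rec, "40min")
  expect_equal(r40$rate_mg_h, c(150, 0, 75))
  r2h <- consumption_rates(rec, "2h")
  expect_equal(r2h$rate_mg_h, c(60, 0, 75))

  gain <- dplyr::mutate(rec, weight_mg_t40 = c(1005, 1000, 950))
  expect_warning(out <- consumption_rates(gain, "40min"), "clipped")
  expect_equal(out$rate_mg_h[1], 0)

  expect_error(consumption_rates(dplyr::select(rec, -weight_mg_t2h), "2h"),
               "needs columns")
})

test_that("Mann-Whitney exact p matches the enumeration oracle", {
  expect_equal(mann_whitney(c(1, 2), c(3, 4))$U, 0)
  expect_equal(mann_whitney(c(1, 2), c(3, 4))$p_value, 1 / 3, tolerance = 1e-9)
  expect_equal(mann_whitney(c(5, 1, 3), c(5, 1, 3))$p_value, 1)

  withr::with_seed(31, {
    for (i in 1:12) {
      nx <- sample(2:4, 1); ny <- sample(2:4, 1)
      x <- sample(1:5, nx, replace = TRUE) # ties likely
      y <- sample(1:5, ny, replace = TRUE)
      got <- mann_whitney(x, y, mode = "exact")
      ora <- oracle_mann_whitney(x, y)
      expect_equal(got$U, ora$U)
      expect_equal(got$p_value, ora$p, tolerance = 1e-12)
    }
  })
})

test_that("Mann-Whitney agrees with wilcox.test where both are exact", {
  withr::with_seed(37, {
    for (i in 1:8) {
      x <- rnorm(4); y <- rnorm(4) # continuous, no ties
      got <- mann_whitney(x, y, mode = "exact")
      ref <- wilcox.test(x, y, exact = TRUE)
      expect_equal(got$U, unname(ref$statistic))
      expect_equal(got$p_value, ref$p.value, tolerance = 1e-9)
    }
  })
})

test_that("U statistics of the two samples partition the comparisons", {
  withr::with_seed(41, {
    for (i in 1:10) {
      x <- sample(1:20, 6, replace = TRUE)
      y <- sample(1:20, 8, replace = TRUE)
      ux <- mann_whitney(x, y, mode = "normal")$U
      uy <- mann_whitney(y, x, mode = "normal")$U
      expect_equal(ux + uy, length(x) * length(y))
    }
  })
})

test_that("preference table reports preferred variants at strict alpha", {
  ch <- dplyr::bind_rows(
    choices_from_counts(39, 13, variants = c("blue", "yellow"),
                        species = "L. villosulum"),
    choices_from_counts(11, 16, variants = c("blue", "yellow"),
                        species = "O. bicornis")
  )
  tab <- preference_table(ch)
  expect_equal(tab$preferred[tab$species == "L. villosulum"], "yellow")
  expect_equal(tab$preferred[tab$species == "O. bicornis"], "no preference")

  # p exactly equal to alpha must not count as a preference
  p_obs <- preference_table(ch)$p_value[tab$species == "L. villosulum"]
  strict <- preference_table(ch, alpha = p_obs)
  expect_equal(strict$preferred[strict$species == "L. villosulum"],
               "no preference")
})

test_that("depth comparison wires rates into the rank test", {
  rec <- tibble::tibble(
    flower_id = sprintf("F%d", 1:8),
    depth = rep(c("flat", "deep"), each = 4),
    weight_mg_t0 = 1000,
    weight_mg_t40 = 1000 - c(80, 90, 100, 110, 20, 25, 30, 35) * 2 / 3,
    weight_mg_t2h = 1000 - c(80, 90, 100, 110, 20, 25, 30, 35) * 2
  )
  out <- depth_consumption_test(rec, window = "40min")
  expect_equal(out$median_flat, 95)
  expect_equal(out$median_deep, 27.5)
  expect_equal(out$U, 16) # complete ordering
  expect_lt(out$p_value, 0.05)
})
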