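test_that("the adapting background maps to the hexagon centre", {
  sp <- gen_cardboard_spectra()
  sp$self <- sp$green_background
  qc <- quantum_catch(sp, background = "green_background")
  self <- qc[qc$name == "self", ]
  expect_equal(c(self$p_uv, self$p_blue, self$p_green), c(1, 1, 1))

  locus <- hexagon_locus(excitation(self))
  expect_equal(locus$x, 0)
  expect_equal(locus$y, 0)
  expect_equal(locus$center_distance, 0)
  expect_true(is.na(locus$angle_deg))
})

test_that("quantum catch is linear in stimulus reflectance", {
  sp <- gen_cardboard_spectra()
  sp$double <- pmin(2 * sp$green_background, 1.2)
  # keep within the ceiling: use half-background instead where needed
  sp$half <- sp$green_background / 2
  qc <- quantum_catch(sp, background = "green_background")
  half <- qc[qc$name == "half", ]
  expect_equal(c(half$p_uv, half$p_blue, half$p_green), c(0.5, 0.5, 0.5))
})

test_that("quantum catch agrees with a 0.1 nm quadrature oracle", {
  wl <- spectra_grid()
  sp <- tibble::tibble(
    wavelength_nm = wl,
    bump = 0.8 * exp(-((wl - 450) / 30)^2 / 2),
    bg = rep(0.3, length(wl))
  )
  qc <- quantum_catch(sp, background = "bg",
                      illuminant = illuminant_flat(wl))
  ora <- oracle_quantum_catch(sp, "bump", "bg",
                              illum_fun = function(w) rep(1, length(w)),
                              receptors_fun = bee_receptors)
  got <- unlist(qc[qc$name == "bump", c("p_uv", "p_blue", "p_green")],
                use.names = FALSE)
  expect_equal(got, unname(ora), tolerance = 1e-4)
})

test_that("excitation is the saturating transform P/(P+1)", {
  base <- tibble::tibble(name = "s", p_uv = 1, p_blue = 3, p_green = 1e9)
  e <- excitation(base)
  expect_equal(e$e_uv, 0.5)
  expect_equal(e$e_blue, 0.75)
  expect_equal(e$e_green, 1, tolerance = 1e-8)
  expect_error(excitation(dplyr::mutate(base, p_uv = 0)), "positive")
})

test_that("hexagon vertices sit at distance 1 with the documented angles", {
  e <- tibble::tibble(
    name = c("blue_vertex", "green_vertex", "uv_vertex"),
    e_uv = c(0, 0, 1), e_blue = c(1, 0, 0), e_green = c(0, 1, 0)
  )
  loc <- hexagon_locus(e)
  expect_equal(loc$center_distance, c(1, 1, 1))
  expect_equal(loc$x, c(0, sqrt(3) / 2, -sqrt(3) / 2))
  expect_equal(loc$y, c(1, -0.5, -0.5))
  expect_equal(loc$angle_deg, c(0, 120, 240))

  ccw <- hexagon_locus(e, orientation = "counterclockwise")
  expect_equal(ccw$angle_deg, c(0, 240, 120))
})

test_that("centre distance never exceeds the hexagon circumradius", {
  withr::with_seed(42, {
    e <- tibble::tibble(name = as.character(1:10000),
                        e_uv = runif(10000), e_blue = runif(10000),
                        e_green = runif(10000))
    loc <- hexagon_locus(e)
    expect_true(all(loc$center_distance <= 1 + 1e-12))
  })
})

test_that("mixing a stimulus toward the background pulls its locus inward", {
  sp <- gen_cardboard_spectra()
  ws <- c(1, 0.75, 0.5, 0.25, 0.1)
  mixed <- tibble::tibble(wavelength_nm = sp$wavelength_nm)
  for (i in seq_along(ws)) {
    mixed[[paste0("m", i)]] <-
      ws[i] * sp$yellow + (1 - ws[i]) * sp$green_background
  }
  mixed$green_background <- sp$green_background
  loci <- contrast_report(mixed, background = "green_background")
  d <- loci$center_distance[match(paste0("m", seq_along(ws)), loci$name)]
  expect_true(all(diff(d) < 0))
})

test_that("pairwise hexagon distance behaves like a metric", {
  withr::with_seed(7, {
    for (rep in 1:20) {
      e <- tibble::tibble(name = c("p", "q", "r"),
                          e_uv = runif(3), e_blue = runif(3), e_green = runif(3))
      loc <- hexagon_locus(e)
      pw <- hexagon_distances(loc)
      d <- function(i, j) {
        pw$distance[(pw$name_a == i & pw$name_b == j) |
                      (pw$name_a == j & pw$name_b == i)]
      }
      expect_gte(d("p", "q"), 0)
      expect_lte(d("p", "r"), d("p", "q") + d("q", "r") + 1e-12)
      self <- hexagon_distances(loc[c(1, 1), ])
      expect_equal(self$distance, 0)
    }
  })
})

test_that("contrast report covers loci, angles, green contrast and pairs", {
  sp <- gen_cardboard_spectra()
  loci <- contrast_report(sp, background = "green_background")
  expect_setequal(loci$name, c("yellow", "light_yellow", "blue", "light_blue"))
  expect_true(all(c("center_distance", "angle_deg", "green_contrast")
                  %in% names(loci)))
  pw <- hexagon_distances(loci)
  expect_equal(nrow(pw), choose(4, 2))

  # two loci straight across the hexagon are 2 units apart
  e <- tibble::tibble(name = c("up", "down"),
                      e_uv = c(0, 1), e_blue = c(1, 0), e_green = c(0, 1))
  loc <- hexagon_locus(e)
  expect_equal(loc$y, c(1, -1))
  pw2 <- hexagon_distances(loc)
  expect_equal(pw2$distance, 2)

  # a single stimulus equal to the background: distance 0, no pairs
  solo <- sp[c("wavelength_nm", "green_background")]
  solo$probe <- solo$green_background
  rep1 <- contrast_report(solo, background = "green_background")
  expect_equal(rep1$center_distance, 0)
  expect_equal(nrow(hexagon_distances(rep1[0, ])), 0)
})

test_that("a global illuminant rescaling leaves loci untouched", {
  sp <- gen_cardboard_spectra()
  wl <- sp$wavelength_nm
  d65 <- illuminant_d65(wl)
  scaled <- dplyr::mutate(d65, d65 = d65 * 17)
  a <- quantum_catch(sp, "green_background", illuminant = d65)
  b <- quantum_catch(sp, "green_background", illuminant = scaled)
  expect_equal(a, b)
})
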