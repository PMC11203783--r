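#' Synthetic study scenario
#'
#' Bundles every parameter of the synthetic-data generators with a seed, so
#' that one scenario deterministically defines spectra, choice records, EAG
#' tables and consumption weighings (identical seed, identical output).
#'
#' Default scales mirror a two-choice field study on three wild bee species:
#' choice totals per trait and species are the integer reconstructions
#' obtained by inverting published coefficient/standard-error pairs
#' ([recover_counts()]) and are labelled reconstructions, not data; antennae
#' counts are 10, 10 and 6; the flower-depth feeding experiment uses 9 runs
#' per arm at a threefold flat/deep rate ratio.
#'
#' @param seed Integer seed; all generators derive their RNG state from it.
#' @param choice_params Tibble of `trait`, `species`, `variant_a`,
#'   `variant_b`, `p_b` (probability of choosing `variant_b`, the
#'   alphabetically second label), `n`, `block`.
#' @param eag_params Tibble of `species`, `compound`, `p`, `n`.
#' @param consumption_params List: `mean_flat`, `mean_deep` (mg/h), `sdlog`,
#'   `n_flat`, `n_deep`, `initial_mg`.
#' @param spectra_params List of shape parameters for
#'   [gen_cardboard_spectra()].
#' @return A list of class `bee_scenario`.
#' @export
bee_scenario <- function(seed = 1,
                         choice_params = default_choice_params(),
                         eag_params = default_eag_params(),
                         consumption_params = list(
                           mean_flat = 90, mean_deep = 30, sdlog = 0.5,
                           n_flat = 9, n_deep = 9, initial_mg = 4000
                         ),
                         spectra_params = default_spectra_params()) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  if (any(choice_params$p_b < 0 | choice_params$p_b > 1)) {
    abort("Choice probabilities must lie in [0, 1].")
  }
  if (any(choice_params$n < 1) || any(eag_params$n < 1)) {
    abort("Sample sizes must be >= 1.")
  }
  structure(
    list(seed = as.integer(seed), choice_params = choice_params,
         eag_params = eag_params, consumption_params = consumption_params,
         spectra_params = spectra_params),
    class = "bee_scenario"
  )
}

#' @rdname bee_scenario
#' @export
default_choice_params <- function() {
  tibble::tribble(
    ~trait,                ~species,         ~variant_a, ~variant_b, ~p_b,      ~n,   ~block,
    "hue",                 "L. villosulum",  "blue",     "yellow",   39 / 52,   52L,  "none",
    "hue",                 "B. terrestris",  "blue",     "yellow",   148 / 206, 206L, "none",
    "hue",                 "O. bicornis",    "blue",     "yellow",   11 / 27,   27L,  "none",
    "size",                "L. villosulum",  "large",    "small",    12 / 44,   44L,  "yellow",
    "size",                "B. terrestris",  "large",    "small",    18 / 77,   77L,  "yellow",
    "size",                "O. bicornis",    "large",    "small",    10 / 33,   33L,  "yellow",
    "achromatic_contrast", "L. villosulum",  "intense",  "light",    29 / 68,   68L,  "yellow",
    "achromatic_contrast", "B. terrestris",  "intense",  "light",    12 / 133,  133L, "yellow",
    "achromatic_contrast", "O. bicornis",    "intense",  "light",    6 / 36,    36L,  "yellow",
    "scent",               "L. villosulum",  "complex",  "simple",   30 / 52,   52L,  "mix",
    "scent",               "B. terrestris",  "complex",  "simple",   216 / 406, 406L, "mix",
    "scent",               "O. bicornis",    "complex",  "simple",   91 / 193,  193L, "mix",
    "depth",               "B. terrestris",  "deep",     "flat",     0.6,       60L,  "none",
    "depth",               "O. bicornis",    "deep",     "flat",     0.6,       60L,  "none"
  )
}

#' @rdname bee_scenario
#' @export
default_eag_params <- function() {
  panel <- voc_panel()
  resp <- list(
    "O. bicornis"   = c(8, 7, 10, 10, 10, 10, 10, 10, 10, 10, 6, 5) / 10,
    "B. terrestris" = c(8, 4, 10, 9, 10, 10, 10, 10, 10, 9, 8, 9) / 10,
    "L. villosulum" = c(4, 6, 6, 6, 6, 6, 6, 6, 6, 6, 6, 6) / 6
  )
  ns <- c("O. bicornis" = 10L, "B. terrestris" = 10L, "L. villosulum" = 6L)
  purrr::map_dfr(names(resp), function(sp) {
    tibble::tibble(species = sp, compound = panel$compound,
                   p = resp[[sp]], n = ns[[sp]])
  })
}

#' @rdname bee_scenario
#' @export
default_spectra_params <- function() {
  list(
    yellow = list(low = 0.05, high = 0.70, edge_nm = 500, width_nm = 10),
    blue = list(floor = 0.03, amp = 0.80, center_nm = 450, sigma_nm = 30),
    background = list(floor = 0.05, amp = 0.45, center_nm = 550, sigma_nm = 50),
    light_weight = c(light_yellow = 0.39, light_blue = 0.78)
  )
}

logistic_step <- function(wl, low, high, edge_nm, width_nm) {
  low + (high - low) / (1 + exp(-(wl - edge_nm) / width_nm))
}

gauss_bump <- function(wl, floor, amp, center_nm, sigma_nm) {
  floor + amp * exp(-((wl - center_nm) / sigma_nm)^2 / 2)
}

#' Generate synthetic cardboard reflectance spectra
#'
#' Emulates the coloured-cardboard stimulus set of a bee choice experiment:
#' a long-pass step spectrum ("yellow"), a Gaussian short-wavelength bump
#' ("blue"), a mid-band green background, and "light" variants constructed
#' as convex mixtures of each parent colour with the background. Mixing
#' toward the background guarantees by construction that a light variant
#' keeps the parent's hue direction while sitting closer to the hexagon
#' centre, the qualitative structure measured cardboards show.
#'
#' @param params Shape parameters (see [default_spectra_params()]).
#' @param wavelength Wavelength grid in nm.
#' @return Spectra tibble with columns `wavelength_nm`, `yellow`,
#'   `light_yellow`, `blue`, `light_blue`, `green_background`.
#' @examples
#' sp <- gen_cardboard_spectra()
#' contrast_report(sp, background = "green_background")
#' @export
gen_cardboard_spectra <- function(params = default_spectra_params(),
                                  wavelength = spectra_grid()) {
  y <- logistic_step(wavelength, params$yellow$low, params$yellow$high,
                     params$yellow$edge_nm, params$yellow$width_nm)
  b <- gauss_bump(wavelength, params$blue$floor, params$blue$amp,
                  params$blue$center_nm, params$blue$sigma_nm)
  g <- gauss_bump(wavelength, params$background$floor, params$background$amp,
                  params$background$center_nm, params$background$sigma_nm)
  w <- params$light_weight
  if (any(c(y, b, g) > 1.2) || any(c(y, b, g) < 0)) {
    abort("Generated reflectance outside [0, 1.2]; check amplitude parameters.")
  }
  if (any(w < 0 | w > 1)) abort("`light_weight` values must lie in [0, 1].")
  tibble::tibble(
    wavelength_nm = as.numeric(wavelength),
    yellow = y,
    light_yellow = w[["light_yellow"]] * y + (1 - w[["light_yellow"]]) * g,
    blue = b,
    light_blue = w[["light_blue"]] * b + (1 - w[["light_blue"]]) * g,
    green_background = g
  )
}

#' Generate synthetic two-choice records
#'
#' Independent Bernoulli first choices at the scenario's per-cell preference
#' probabilities, tagged with species, trait, block and replicate.
#' Bit-identical output for identical seeds.
#'
#' @param scenario A [bee_scenario()].
#' @return Tibble of choice records: `species`, `trait`, `block`,
#'   `replicate`, `variant_chosen`.
#' @export
gen_choices <- function(scenario) {
  stopifnot(inherits(scenario, "bee_scenario"))
  withr::with_seed(scenario$seed + 101L, {
    purrr::pmap_dfr(scenario$choice_params, function(trait, species, variant_a,
                                                     variant_b, p_b, n, block) {
      draws <- rbinom(n, 1L, p_b)
      blocks <- if (block == "mix") {
        paste0("mix", rep_len(1:3, n))
      } else {
        rep(block, n)
      }
      tibble::tibble(
        species = species, trait = trait, block = blocks,
        replicate = seq_len(n),
        variant_chosen = ifelse(draws == 1L, variant_b, variant_a)
      )
    })
  })
}

#' Generate a synthetic EAG response table
#'
#' Bernoulli antennal responses per antenna and compound at the scenario's
#' response probabilities, or (with `force_counts = TRUE`) a table whose
#' responder counts exactly equal `round(p * n)` per species and compound —
#' useful for reconstructing published percentage grids.
#'
#' @param scenario A [bee_scenario()].
#' @param force_counts Force exact responder counts instead of sampling.
#' @return Wide tibble: `species`, `antenna_id`, one 0/1 column per compound.
#' @export
gen_eag_table <- function(scenario, force_counts = FALSE) {
  stopifnot(inherits(scenario, "bee_scenario"))
  params <- scenario$eag_params
  compounds <- unique(params$compound)
  withr::with_seed(scenario$seed + 202L, {
    purrr::map_dfr(unique(params$species), function(sp) {
      pp <- dplyr::filter(params, .data$species == sp)
      n <- pp$n[1]
      out <- tibble::tibble(species = sp,
                            antenna_id = paste0(substr(sp, 1, 1), seq_len(n)))
      for (cmp in compounds) {
        p <- pp$p[pp$compound == cmp]
        out[[cmp]] <- if (force_counts) {
          k <- round(p * n)
          as.integer(seq_len(n) <= k)
        } else {
          rbinom(n, 1L, p)
        }
      }
      out
    })
  })
}

#' Generate synthetic consumption weighings
#'
#' Draws a lognormal consumption rate per flower with depth-specific mean
#' rates (mg/h) and derives the three weighings (start, 40 minutes, 2 hours)
#' as initial weight minus rate times elapsed time; weights are therefore
#' nonincreasing by construction. `sdlog = 0` makes every flower of an arm
#' consume exactly the arm mean.
#'
#' @param scenario A [bee_scenario()].
#' @return Tibble: `flower_id`, `depth`, `weight_mg_t0`, `weight_mg_t40`,
#'   `weight_mg_t2h`.
#' @export
gen_consumption <- function(scenario) {
  stopifnot(inherits(scenario, "bee_scenario"))
  cp <- scenario$consumption_params
  withr::with_seed(scenario$seed + 303L, {
    rates <- c(
      if (cp$sdlog > 0) {
        rlnorm(cp$n_flat, log(cp$mean_flat) - cp$sdlog^2 / 2, cp$sdlog)
      } else {
        rep(cp$mean_flat, cp$n_flat)
      },
      if (cp$sdlog > 0) {
        rlnorm(cp$n_deep, log(cp$mean_deep) - cp$sdlog^2 / 2, cp$sdlog)
      } else {
        rep(cp$mean_deep, cp$n_deep)
      }
    )
    depth <- c(rep("flat", cp$n_flat), rep("deep", cp$n_deep))
    tibble::tibble(
      flower_id = sprintf("F%02d", seq_along(rates)),
      depth = depth,
      weight_mg_t0 = cp$initial_mg,
      weight_mg_t40 = cp$initial_mg - rates * 40 / 60,
      weight_mg_t2h = cp$initial_mg - rates * 2
    )
  })
}
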