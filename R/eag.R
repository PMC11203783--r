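#' Built-in volatile compound panel
#'
#' The 12-compound panel of common floral volatiles used throughout the
#' package examples: monoterpenes, benzenoids and sesquiterpenes with their
#' gas-chromatographic retention indices (DB-5) and simple-mixture
#' membership. The complex mixture is the union of the three simple
#' mixtures of four compounds each.
#'
#' @return Tibble with columns `compound`, `ri`, `class`, `mix`.
#' @export
voc_panel <- function() {
  tibble::tribble(
    ~compound,                    ~ri,  ~class,          ~mix,
    "beta-myrcene",                986, "monoterpene",    3L,
    "eucalyptol",                 1032, "monoterpene",    2L,
    "(E)-beta-ocimene",           1045, "monoterpene",    1L,
    "gamma-terpinene",            1058, "monoterpene",    2L,
    "beta-linalool",              1099, "monoterpene",    1L,
    "2-phenylethanol",            1112, "benzenoid",      2L,
    "methyl salicylate",          1194, "benzenoid",      3L,
    "2-phenethyl acetate",        1255, "benzenoid",      1L,
    "eugenol",                    1353, "benzenoid",      3L,
    "benzyl isovalerate",         1396, "benzenoid",      1L,
    "beta-caryophyllene",         1426, "sesquiterpene",  3L,
    "hexahydro farnesyl acetone", 1840, "sesquiterpene",  2L
  )
}

#' Summarise antennal responses per compound
#'
#' Counts, for each species and compound, how many tested antennae (each
#' from a distinct female) responded, and expresses it as a fraction and a
#' percentage. The raw fraction is always kept alongside the display
#' percentage so that display rounding conventions cannot affect downstream
#' classification.
#'
#' @param eag Wide tibble: columns `species`, `antenna_id`, then one 0/1
#'   column per compound.
#' @param display One of `"round"` (default; one decimal) or `"truncate"`
#'   (integer truncation, as some published tables print 4/6 as 66%). This
#'   affects `percent_display` only.
#' @return Tibble with `species`, `compound`, `responders`, `n`, `fraction`,
#'   `percent` (one decimal) and `percent_display`.
#' @examples
#' eag <- gen_eag_table(bee_scenario(seed = 1), force_counts = TRUE)
#' activity_summary(eag)
#' @export
activity_summary <- function(eag, display = c("round", "truncate")) {
  display <- match.arg(display)
  eag <- tibble::as_tibble(eag)
  if (!all(c("species", "antenna_id") %in% names(eag))) {
    abort("`eag` needs columns species and antenna_id.")
  }
  compounds <- setdiff(names(eag), c("species", "antenna_id"))
  if (!length(compounds)) abort("`eag` has no compound columns.")
  resp <- as.matrix(eag[compounds])
  if (!all(resp %in% c(0, 1))) abort("Responses must be 0/1.")
  long <- tidyr::pivot_longer(eag, dplyr::all_of(compounds),
                              names_to = "compound", values_to = "response")
  out <- long |>
    dplyr::group_by(.data$species, .data$compound) |>
    dplyr::summarise(
      responders = sum(.data$response),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      fraction = .data$responders / .data$n,
      percent = round(100 * .data$fraction, 1),
      percent_display = if (display == "truncate") {
        trunc(100 * .data$fraction)
      } else {
        round(100 * .data$fraction, 1)
      }
    )
  # keep the compound order of the input table
  out$compound <- factor(out$compound, levels = compounds)
  dplyr::arrange(out, .data$species, .data$compound) |>
    dplyr::mutate(compound = as.character(.data$compound))
}

#' Classify electrophysiologically active compounds
#'
#' A compound is active for a species when it elicited a response in at
#' least half of the tested antennae (inclusive threshold: exactly 50%
#' counts as active).
#'
#' @param summary Output of [activity_summary()].
#' @param threshold Fraction of responding antennae required (default 0.5).
#' @return The summary with an `active` logical column added.
#' @export
classify_active <- function(summary, threshold = 0.5) {
  summary <- tibble::as_tibble(summary)
  if (!"fraction" %in% names(summary)) {
    abort("`summary` must come from activity_summary() (needs `fraction`).")
  }
  dplyr::mutate(summary, active = .data$fraction >= threshold)
}

#' Per-substance concentration in an equal-part mixture
#'
#' Scent mixtures are prepared at a fixed total concentration with all
#' substances in equal amounts, so each substance is present at
#' total / n. Units: micrograms per millilitre of solvent.
#'
#' @param total_ug_ml Total concentration of all substances (ug/mL);
#'   default 10 (i.e. 1e-5 g substances per mL pentane).
#' @param n_substances Number of substances in the mixture (>= 1).
#' @return Per-substance concentration in ug/mL.
#' @examples
#' per_substance_concentration(10, 4)  # 2.5
#' per_substance_concentration(10, 12) # 0.8333...
#' @export
per_substance_concentration <- function(total_ug_ml = 10, n_substances) {
  if (total_ug_ml <= 0) abort("`total_ug_ml` must be positive.")
  if (n_substances < 1) abort("`n_substances` must be >= 1.")
  total_ug_ml / n_substances
}

#' Total substance mass applied to a flower or antenna
#'
#' Mass delivered by an aliquot: volume (uL) times concentration (ug/mL)
#' equals mass in ng. Note that some published protocols print applied
#' masses a factor of ten below what their stated volumes and
#' concentrations imply (e.g. 30 uL of 10 ug/mL is 300 ng, not 30 ng);
#' this function computes strictly from the inputs and leaves any such
#' discrepancy to the caller to flag.
#'
#' @param volume_ul Applied volume in microlitres.
#' @param conc_ug_ml Total concentration in ug/mL.
#' @return Mass in nanograms.
#' @examples
#' applied_mass_ng(30, 10) # 300 ng
#' @export
applied_mass_ng <- function(volume_ul, conc_ug_ml) {
  if (volume_ul < 0 || conc_ug_ml < 0) abort("Inputs must be non-negative.")
  volume_ul * conc_ug_ml
}

#' Substance-class balance of a compound panel
#'
#' Counts compounds of each chemical class per simple mixture and for the
#' complex mixture (all compounds), and flags mixtures whose class
#' composition deviates from an equal split.
#'
#' @param panel Tibble like [voc_panel()] with `compound`, `class`, `mix`.
#' @return Tibble with `mix` (`"1"`, `"2"`, `"3"`, `"complex"`), `class`,
#'   `n`, and a `balanced` flag per mixture.
#' @export
panel_balance_report <- function(panel = voc_panel()) {
  panel <- tibble::as_tibble(panel)
  if (!nrow(panel)) {
    return(tibble::tibble(mix = character(), class = character(),
                          n = integer(), balanced = logical()))
  }
  simple <- panel |>
    dplyr::count(mix = as.character(.data$mix), .data$class)
  complexed <- panel |>
    dplyr::count(.data$class) |>
    dplyr::mutate(mix = "complex", .before = 1)
  out <- dplyr::bind_rows(simple, complexed)
  out |>
    dplyr::group_by(.data$mix) |>
    dplyr::mutate(balanced = length(unique(.data$n)) == 1L) |>
    dplyr::ungroup()
}
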