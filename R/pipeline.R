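#' Run configuration
#'
#' Assembles (or reads from a YAML file) the configuration driving
#' [run_pipeline()]: input CSV paths (or `NULL` to simulate them), the
#' illuminant and receptor sources, the significance level, the hue-angle
#' orientation and the seed.
#'
#' @param path Optional YAML file; fields below override its contents.
#' @param spectra,choices,eag,consumption Optional input CSV paths. Missing
#'   inputs are generated from the scenario.
#' @param background Name of the background spectrum column.
#' @param illuminant `"d65"` or `"flat"`.
#' @param alpha Significance level in (0, 1).
#' @param orientation Hue-angle orientation.
#' @param seed Integer seed for simulated inputs.
#' @return A list of class `bee_config`.
#' @export
bee_config <- function(path = NULL, spectra = NULL, choices = NULL, eag = NULL,
                       consumption = NULL, background = "green_background",
                       illuminant = c("d65", "flat"), alpha = 0.05,
                       orientation = c("clockwise", "counterclockwise"),
                       seed = 1) {
  cfg <- if (!is.null(path)) yaml::read_yaml(path) else list()
  supplied <- list(spectra = spectra, choices = choices, eag = eag,
                   consumption = consumption, background = background,
                   illuminant = illuminant[1], alpha = alpha,
                   orientation = orientation[1], seed = seed)
  for (nm in names(supplied)) {
    if (is.null(cfg[[nm]]) || !missing_default(nm, supplied[[nm]])) {
      cfg[[nm]] <- supplied[[nm]]
    }
  }
  cfg$illuminant <- match.arg(cfg$illuminant, c("d65", "flat"))
  cfg$orientation <- match.arg(cfg$orientation, c("clockwise", "counterclockwise"))
  if (cfg$alpha <= 0 || cfg$alpha >= 1) abort("`alpha` must lie in (0, 1).")
  structure(cfg, class = "bee_config")
}

# helper: TRUE when the value equals the formal default (so YAML wins)
missing_default <- function(nm, value) {
  defaults <- list(spectra = NULL, choices = NULL, eag = NULL,
                   consumption = NULL, background = "green_background",
                   illuminant = "d65", alpha = 0.05,
                   orientation = "clockwise", seed = 1)
  identical(value, defaults[[nm]])
}

#' Validate pipeline inputs
#'
#' Checks the configured input files (or the simulated stand-ins) for the
#' columns and structure each stage needs: a wavelength column and the
#' background spectrum, known choice traits with two variant labels, 0/1
#' EAG responses, and the three weighing columns. Diagnostics only; nothing
#' is modified.
#'
#' @param config A [bee_config()].
#' @return Tibble of diagnostics (`stage`, `severity`, `message`); zero rows
#'   when everything is well-formed.
#' @export
validate_inputs <- function(config) {
  diag <- list()
  note <- function(stage, msg, severity = "error") {
    diag[[length(diag) + 1]] <<- tibble::tibble(stage = stage,
                                                severity = severity,
                                                message = msg)
  }
  inputs <- load_inputs(config)

  sp <- inputs$spectra
  if (!"wavelength_nm" %in% names(sp)) {
    note("spectra", "missing wavelength_nm column")
  } else if (!config$background %in% names(sp)) {
    note("spectra", sprintf("background spectrum '%s' not found", config$background))
  }

  ch <- inputs$choices
  need <- c("species", "trait", "variant_chosen")
  miss <- setdiff(need, names(ch))
  if (length(miss)) {
    note("choices", paste("missing columns:", toString(miss)))
  } else {
    known <- c("hue", "size", "achromatic_contrast", "scent", "depth")
    bad <- setdiff(unique(ch$trait), known)
    if (length(bad)) note("choices", paste("unknown trait(s):", toString(bad)))
    pair_sizes <- ch |>
      dplyr::distinct(.data$trait, .data$variant_chosen) |>
      dplyr::count(.data$trait)
    over <- pair_sizes$trait[pair_sizes$n > 2]
    if (length(over)) {
      note("choices", paste("more than two variants for trait(s):", toString(over)))
    }
  }

  eag <- inputs$eag
  if (!all(c("species", "antenna_id") %in% names(eag))) {
    note("eag", "missing species/antenna_id columns")
  } else {
    vals <- as.matrix(eag[setdiff(names(eag), c("species", "antenna_id"))])
    if (length(vals) && !all(vals %in% c(0, 1))) {
      note("eag", "non-binary response values")
    }
  }

  cons <- inputs$consumption
  needc <- c("flower_id", "depth", "weight_mg_t0", "weight_mg_t40", "weight_mg_t2h")
  missc <- setdiff(needc, names(cons))
  if (length(missc)) note("consumption", paste("missing columns:", toString(missc)))

  if (!length(diag)) {
    return(tibble::tibble(stage = character(), severity = character(),
                          message = character()))
  }
  dplyr::bind_rows(diag)
}

load_inputs <- function(config) {
  scenario <- bee_scenario(seed = config$seed)
  list(
    spectra = if (!is.null(config$spectra)) {
      read_spectra_csv(config$spectra)
    } else {
      gen_cardboard_spectra()
    },
    choices = if (!is.null(config$choices)) {
      readr::read_csv(config$choices, show_col_types = FALSE)
    } else {
      gen_choices(scenario)
    },
    eag = if (!is.null(config$eag)) {
      readr::read_csv(config$eag, show_col_types = FALSE)
    } else {
      gen_eag_table(scenario)
    },
    consumption = if (!is.null(config$consumption)) {
      readr::read_csv(config$consumption, show_col_types = FALSE)
    } else {
      gen_consumption(scenario)
    }
  )
}

#' Run the full analysis pipeline
#'
#' Executes every stage on the configured (or simulated) inputs: hexagon
#' colour loci and pairwise distances, per-trait preference models, EAG
#' activity scoring, and the flower-depth consumption comparison. Writes
#' four CSV reports (`loci.csv`, `preferences.csv`, `activity.csv`,
#' `depth.csv`) plus `run_log.txt` recording the seed and a configuration
#' hash, and returns all results invisibly as a list. The same
#' configuration always produces byte-identical reports.
#'
#' @param config A [bee_config()].
#' @param outdir Output directory (created if needed).
#' @return (Invisibly) a list with `loci`, `pairwise`, `preferences`,
#'   `activity`, `depth`, `diagnostics` and the written file paths.
#' @export
run_pipeline <- function(config = bee_config(), outdir = tempdir()) {
  diags <- validate_inputs(config)
  if (any(diags$severity == "error")) {
    abort(paste0("[validate] invalid inputs:\n",
                 paste(diags$stage, diags$message, sep = ": ", collapse = "\n")))
  }
  inputs <- load_inputs(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  loci <- tryCatch(
    contrast_report(inputs$spectra, background = config$background,
                    illuminant = switch(config$illuminant,
                      d65 = illuminant_d65(inputs$spectra$wavelength_nm),
                      flat = illuminant_flat(inputs$spectra$wavelength_nm)
                    ),
                    orientation = config$orientation),
    error = function(e) abort(paste0("[hexagon] ", conditionMessage(e)))
  )
  prefs <- tryCatch(
    preference_table(inputs$choices, alpha = config$alpha),
    error = function(e) abort(paste0("[prefs] ", conditionMessage(e)))
  )
  activity <- tryCatch(
    activity_summary(inputs$eag) |>
      classify_active() |>
      dplyr::left_join(voc_panel(), by = "compound"),
    error = function(e) abort(paste0("[eag] ", conditionMessage(e)))
  )
  depth <- tryCatch(
    dplyr::bind_rows(
      depth_consumption_test(inputs$consumption, "40min"),
      depth_consumption_test(inputs$consumption, "2h")
    ),
    error = function(e) abort(paste0("[depth] ", conditionMessage(e)))
  )

  paths <- list(
    loci = file.path(outdir, "loci.csv"),
    preferences = file.path(outdir, "preferences.csv"),
    activity = file.path(outdir, "activity.csv"),
    depth = file.path(outdir, "depth.csv"),
    log = file.path(outdir, "run_log.txt")
  )
  readr::write_csv(dplyr::select(tibble::as_tibble(loci), "name", "x", "y",
                                 "center_distance", "angle_deg",
                                 "green_contrast"), paths$loci)
  readr::write_csv(prefs, paths$preferences)
  readr::write_csv(activity, paths$activity)
  readr::write_csv(depth, paths$depth)
  writeLines(c(
    paste0("beechoice version: ", as.character(utils::packageVersion("beechoice"))),
    paste0("seed: ", config$seed),
    paste0("config_hash: ", rlang::hash(unclass(config))),
    paste0("illuminant: ", config$illuminant),
    paste0("orientation: ", config$orientation),
    paste0("alpha: ", config$alpha)
  ), paths$log)

  invisible(list(loci = loci, pairwise = hexagon_distances(loci),
                 preferences = prefs, activity = activity, depth = depth,
                 diagnostics = diags, paths = paths))
}
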