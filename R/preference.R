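#' Fit a two-choice binomial preference model
#'
#' Fits a binomial logistic regression to first-choice records from a
#' two-choice assay. By default the "success" level is the alphabetically
#' second of the two variant labels for the trait, so a positive intercept
#' means that variant was chosen more often (this single rule reproduces the
#' sign conventions of the study tables this package accompanies; override
#' with `success`). Without covariates the model is intercept-only, whose
#' estimate is the empirical log-odds ln(a/b); with `species = NULL` and
#' `by_species = FALSE` a global model pools species as a fixed factor.
#'
#' Complete separation (one variant never chosen) does not raise an error:
#' the fit is returned with `separation = TRUE` and a signed-infinite
#' intercept estimate, so callers can handle it explicitly.
#'
#' @param choices Tibble of choice records with columns `species`, `trait`,
#'   `variant_chosen`, and optionally `block` and `replicate`.
#' @param trait The trait to analyse (e.g. `"hue"`).
#' @param species Optional species label; when given, only that species'
#'   records enter an intercept-only (plus optional covariate) model.
#' @param covariate Optional extra column name entering as a fixed factor
#'   (e.g. `"block"` for the base colour or mixture identity).
#' @param success Optional explicit success variant label.
#' @param species_factor When no single species is selected, add species as a
#'   fixed factor (default TRUE, matching a global model across species).
#' @return An object of class `bee_choice_fit`: a list with the `glm` fit,
#'   the trait, variant pair, success level, choice counts `a` (successes)
#'   and `b` (failures), `n_obs`, and a `separation` flag. Use [tidy()] and
#'   [glance()] to extract results.
#' @examples
#' ch <- gen_choices(bee_scenario(seed = 1))
#' fit <- fit_two_choice(ch, trait = "hue", species = "L. villosulum")
#' tidy(fit)
#' @export
fit_two_choice <- function(choices, trait, species = NULL, covariate = NULL,
                           success = NULL, species_factor = TRUE) {
  choices <- tibble::as_tibble(choices)
  need <- c("species", "trait", "variant_chosen")
  if (!all(need %in% names(choices))) {
    abort("`choices` needs columns species, trait, variant_chosen.")
  }
  dat <- dplyr::filter(choices, .data$trait == !!trait)
  if (!is.null(species)) dat <- dplyr::filter(dat, .data$species == !!species)
  if (!nrow(dat)) abort(sprintf("No records for trait '%s'.", trait))

  variants <- sort(unique(dat$variant_chosen))
  if (length(variants) > 2) {
    abort(sprintf("Trait '%s' has more than two variant labels: %s.",
                  trait, toString(variants)))
  }
  if (is.null(success)) success <- variants[length(variants)]
  dat$.y <- as.integer(dat$variant_chosen == success)

  a <- sum(dat$.y)
  b <- nrow(dat) - a
  separation <- a == 0L || b == 0L

  terms <- "1"
  if (is.null(species) && species_factor && length(unique(dat$species)) > 1) {
    terms <- c(terms, "factor(species)")
  }
  if (!is.null(covariate)) {
    if (!covariate %in% names(dat)) abort(sprintf("Covariate '%s' not found.", covariate))
    terms <- c(terms, sprintf("factor(%s)", covariate))
  }
  fml <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
  # tight IRLS tolerance so the intercept matches the closed form to 1e-6
  fit <- suppressWarnings(glm(fml, family = binomial(), data = dat,
                              control = list(epsilon = 1e-12, maxit = 100)))

  structure(
    list(
      fit = fit, trait = trait, species = species,
      variants = variants, success = success,
      a = a, b = b, n_obs = nrow(dat),
      formula = paste(deparse(fml), collapse = ""),
      separation = separation
    ),
    class = "bee_choice_fit"
  )
}

#' @export
print.bee_choice_fit <- function(x, ...) {
  cat("Two-choice binomial fit -- trait:", x$trait,
      if (!is.null(x$species)) paste0("(", x$species, ")") else "(all species)", "\n")
  cat("  success level:", x$success, " counts:", x$a, "vs", x$b, "\n")
  if (x$separation) cat("  WARNING: complete separation; intercept is infinite\n")
  print(tidy(x))
  invisible(x)
}

#' Tidy a two-choice fit
#'
#' Coefficient table in the broom convention: one row per model term with
#' `estimate` (log-odds), `std.error`, `statistic` (Wald z) and `p.value`
#' (two-sided, standard normal). Under complete separation the intercept row
#' carries a signed infinite estimate and `NA` inference.
#'
#' @param x A `bee_choice_fit`.
#' @param ... Unused.
#' @return A tibble of coefficients.
#' @export
tidy.bee_choice_fit <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  out <- tibble::tibble(
    term = rownames(cf),
    estimate = cf[, "Estimate"],
    std.error = cf[, "Std. Error"],
    statistic = cf[, "z value"],
    p.value = cf[, "Pr(>|z|)"]
  )
  if (x$separation) {
    i <- out$term == "(Intercept)"
    out$estimate[i] <- if (x$a == 0) -Inf else Inf
    out$std.error[i] <- Inf
    out$statistic[i] <- NA_real_
    out$p.value[i] <- NA_real_
  }
  out
}

#' Glance at a two-choice fit
#'
#' @param x A `bee_choice_fit`.
#' @param ... Unused.
#' @return One-row tibble with counts, sample size, deviance, AIC and the
#'   separation flag.
#' @export
glance.bee_choice_fit <- function(x, ...) {
  tibble::tibble(
    trait = x$trait,
    species = x$species %||% "all",
    success = x$success,
    a = x$a, b = x$b, n_obs = x$n_obs,
    deviance = stats::deviance(x$fit),
    AIC = stats::AIC(x$fit),
    separation = x$separation
  )
}

#' Closed-form intercept of the intercept-only binomial logit
#'
#' For a two-choice experiment with `a` successes and `b` failures the
#' maximum-likelihood intercept is ln(a/b) with standard error
#' sqrt(1/a + 1/b). This closed form is the independent oracle against which
#' the iteratively fitted GLM intercept is checked.
#'
#' @param a,b Success and failure counts (both >= 1).
#' @return One-row tibble: `estimate`, `std_error`, `z_value`, `p_value`.
#' @examples
#' intercept_closed_form(39, 13)
#' @export
intercept_closed_form <- function(a, b) {
  if (a < 1 || b < 1) abort("Both counts must be >= 1 (zero cells separate).")
  est <- log(a / b)
  se <- sqrt(1 / a + 1 / b)
  z <- est / se
  tibble::tibble(estimate = est, std_error = se, z_value = z,
                 p_value = 2 * pnorm(-abs(z)))
}

#' Recover integer choice counts from a printed estimate and standard error
#'
#' Published two-choice tables print the intercept estimate and standard
#' error but not the underlying counts. Because the intercept-only fit has
#' the closed form ln(a/b), sqrt(1/a + 1/b), the integer pair (a, b) can be
#' recovered by exhaustive search: among all pairs with a + b <= `max_total`
#' whose closed-form values round to the printed ones at `digits` decimals
#' (and whose Wald z also rounds to `z_value`, when supplied), the pair with
#' the smallest squared discrepancy is returned. Recovered pairs are
#' reconstructions, not data.
#'
#' @param estimate Printed log-odds intercept.
#' @param std_error Printed standard error (> 0).
#' @param z_value Optional printed Wald z used as an additional filter;
#'   useful when several pairs reproduce (estimate, SE) but differ in z.
#' @param max_total Search bound on a + b (default 500).
#' @param digits Decimals at which the printed values were rounded (3).
#' @return One-row tibble: `a`, `b`, exact `estimate`, `std_error`,
#'   `z_value` of the recovered pair, `n_candidates` matching the rounding,
#'   and a `unique` flag.
#' @examples
#' recover_counts(1.099, 0.320) # 39 vs 13
#' @export
recover_counts <- function(estimate, std_error, z_value = NULL,
                           max_total = 500, digits = 3) {
  if (std_error <= 0) abort("`std_error` must be positive.")
  ab <- tidyr::expand_grid(a = seq_len(max_total - 1), b = seq_len(max_total - 1)) |>
    dplyr::filter(.data$a + .data$b <= max_total)
  est <- log(ab$a / ab$b)
  se <- sqrt(1 / ab$a + 1 / ab$b)
  keep <- round(est, digits) == round(estimate, digits) &
    round(se, digits) == round(std_error, digits)
  if (!is.null(z_value)) {
    keep <- keep & round(est / se, digits) == round(z_value, digits)
  }
  if (!any(keep)) {
    abort(sprintf(
      "No integer pair with a+b <= %d reproduces (%.3f, %.3f) at %d decimals.",
      max_total, estimate, std_error, digits
    ))
  }
  cand <- tibble::tibble(a = ab$a[keep], b = ab$b[keep],
                         estimate = est[keep], std_error = se[keep])
  disc <- (cand$estimate - estimate)^2 + (cand$std_error - std_error)^2
  best <- which.min(disc)
  tibble::tibble(
    a = cand$a[best], b = cand$b[best],
    estimate = cand$estimate[best], std_error = cand$std_error[best],
    z_value = cand$estimate[best] / cand$std_error[best],
    n_candidates = nrow(cand),
    unique = nrow(cand) == 1L
  )
}

#' Per-trait preference summary table
#'
#' Fits the intercept-only model per trait and species (plus the optional
#' covariate) and reports the preferred variant: the variant on the
#' favourable side of a significant intercept at level `alpha` (strict
#' two-sided Wald test; p exactly equal to `alpha` counts as no preference).
#'
#' @param choices Choice records (see [fit_two_choice()]).
#' @param alpha Significance level (default 0.05).
#' @param covariate Optional covariate column passed through to the fits.
#' @return Tibble with one row per trait x species: counts, `estimate`,
#'   `std_error`, `z_value`, `p_value` and `preferred` (a variant label or
#'   `"no preference"`).
#' @export
preference_table <- function(choices, alpha = 0.05, covariate = NULL) {
  choices <- tibble::as_tibble(choices)
  cells <- dplyr::distinct(choices, .data$trait, .data$species)
  purrr::pmap_dfr(cells, function(trait, species) {
    f <- fit_two_choice(choices, trait = trait, species = species,
                        covariate = covariate)
    td <- tidy(f)
    i <- td$term == "(Intercept)"
    est <- td$estimate[i]; p <- td$p.value[i]
    preferred <- if (f$separation) {
      if (est > 0) f$success else setdiff(f$variants, f$success)[1]
    } else if (!is.na(p) && p < alpha) {
      if (est > 0) f$success else setdiff(f$variants, f$success)[1]
    } else {
      "no preference"
    }
    tibble::tibble(
      trait = trait, species = species,
      variant_a = f$variants[1], variant_b = f$success,
      a = f$a, b = f$b,
      estimate = est, std_error = td$std.error[i],
      z_value = td$statistic[i], p_value = p,
      preferred = preferred, separation = f$separation
    )
  })
}

#' Consumption rate of rewarding artificial flowers
#'
#' Converts per-flower weighings (before the experiment, after 40 minutes,
#' after 2 hours) into consumption rates in mg per hour over the chosen
#' window. Small negative weight differences (evaporation/weighing noise)
#' are clipped to zero with a warning.
#'
#' @param records Tibble with columns `flower_id`, `depth`, `weight_mg_t0`,
#'   `weight_mg_t40`, `weight_mg_t2h`.
#' @param window `"40min"` or `"2h"`.
#' @return Input tibble with a `rate_mg_h` column added.
#' @export
consumption_rates <- function(records, window = c("40min", "2h")) {
  window <- match.arg(window)
  records <- tibble::as_tibble(records)
  end_col <- if (window == "40min") "weight_mg_t40" else "weight_mg_t2h"
  need <- c("flower_id", "depth", "weight_mg_t0", end_col)
  if (!all(need %in% names(records))) {
    abort(paste0("`records` needs columns: ", toString(need)))
  }
  if (anyNA(records[[end_col]]) || anyNA(records$weight_mg_t0)) {
    abort("Missing weights for the requested window.")
  }
  hours <- if (window == "40min") 40 / 60 else 2
  diff <- records$weight_mg_t0 - records[[end_col]]
  if (any(diff < 0)) {
    warn("Negative consumption (weight gain) clipped to 0 for some flowers.")
    diff <- pmax(diff, 0)
  }
  dplyr::mutate(records, rate_mg_h = diff / hours)
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples with midrank handling of
#' ties. For combined sample sizes up to `exact_max` the two-sided p-value is
#' computed by exact enumeration of all label permutations; above that a
#' normal approximation with tie correction is used. If every value in both
#' samples is identical the test is degenerate and p = 1.
#'
#' @param x,y Numeric samples.
#' @param mode `"auto"` (exact when n_x + n_y <= `exact_max`), `"exact"`, or
#'   `"normal"`.
#' @param exact_max Combined-size threshold for exact enumeration (12).
#' @return One-row tibble: `U` (statistic for `x`), `n_x`, `n_y`, `p_value`,
#'   `method`.
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))
#' @export
mann_whitney <- function(x, y, mode = c("auto", "exact", "normal"),
                         exact_max = 12) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y)) abort("Both samples must be nonempty.")
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) {
    return(tibble::tibble(U = nx * ny / 2, n_x = nx, n_y = ny,
                          p_value = 1, method = "degenerate"))
  }
  u_stat <- function(idx) {
    r <- rank(pooled) # midranks
    sum(r[idx]) - nx * (nx + 1) / 2
  }
  U <- u_stat(seq_len(nx))
  if (mode == "auto") mode <- if (nx + ny <= exact_max) "exact" else "normal"

  if (mode == "exact") {
    r <- rank(pooled)
    combs <- utils::combn(nx + ny, nx)
    us <- apply(combs, 2, function(idx) sum(r[idx])) - nx * (nx + 1) / 2
    mu <- nx * ny / 2
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-12)
    method <- "exact"
  } else {
    r <- rank(pooled)
    n <- nx + ny
    mu <- nx * ny / 2
    ties <- table(pooled)
    tie_corr <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- nx * ny / 12 * (n + 1 - tie_corr)
    z <- (U - mu) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal"
  }
  tibble::tibble(U = U, n_x = nx, n_y = ny, p_value = min(p, 1), method = method)
}

#' Compare consumption between flat and deep flowers
#'
#' Applies [consumption_rates()] and a Mann-Whitney U test between the two
#' depth groups.
#'
#' @inheritParams consumption_rates
#' @inheritParams mann_whitney
#' @return One-row tibble with group medians and the test result.
#' @export
depth_consumption_test <- function(records, window = c("40min", "2h"),
                                   mode = c("auto", "exact", "normal")) {
  window <- match.arg(window)
  mode <- match.arg(mode)
  rates <- consumption_rates(records, window = window)
  groups <- sort(unique(rates$depth))
  if (length(groups) != 2) abort("`depth` must have exactly two levels.")
  x <- rates$rate_mg_h[rates$depth == "flat"]
  y <- rates$rate_mg_h[rates$depth != "flat"]
  mw <- mann_whitney(x, y, mode = mode)
  tibble::tibble(
    window = window,
    median_flat = stats::median(x),
    median_deep = stats::median(y),
    U = mw$U, p_value = mw$p_value, method = mw$method
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
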