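#' Fit the per-species linear mixed effects model
#'
#' Fits, for one species, `persistence ~ design + climate + dispersal +
#' conflict + (1 | budget)`: the four planning factors enter as additive
#' fixed effects (no interactions) and the budget level as a random
#' intercept, absorbing the dominant sensitivity of persistence to the
#' resources available. Factors with a single level in the data are dropped
#' from the fixed part; at least one multi-level fixed factor and at least
#' two budget levels are required. Estimation is REML via \pkg{lme4};
#' singular fits (a variance component estimated at 0) are reported as a
#' warning, not an error.
#'
#' @param results Long results tibble with columns `design`, `climate`,
#'   `dispersal`, `conflict`, `budget`, `species_id`, `persistence` (e.g. the
#'   `results` element of [run_experiment()]).
#' @param species Species to fit (default: the only species present).
#' @param budget_subset `"all"` or a quartile number 1-4; quartiles split the
#'   sorted budget sequence into four consecutive equal blocks.
#' @return A `ccc_effects_fit` object; see [tidy.ccc_effects_fit()],
#'   [glance.ccc_effects_fit()] and [effect_size()].
#' @export
fit_effects_model <- function(results, species = NULL, budget_subset = "all") {
  if (is.null(species)) {
    sp <- unique(results$species_id)
    if (length(sp) != 1) {
      stop("several species present; pick one with `species`", call. = FALSE)
    }
    species <- sp
  }
  dat <- results[results$species_id == species, ]
  if (!identical(budget_subset, "all")) {
    q <- as.integer(budget_subset)
    stopifnot(q %in% 1:4)
    dat <- dat[budget_quartile(dat$budget) == q, ]
  }
  factors <- c("design", "climate", "dispersal", "conflict")
  factors <- factors[factors %in% names(dat)]
  factors <- factors[vapply(factors, function(f) length(unique(dat[[f]])) > 1,
                            logical(1))]
  if (length(factors) == 0) {
    stop("need at least one fixed factor with two or more levels", call. = FALSE)
  }
  if (length(unique(dat$budget)) < 2) {
    stop("the budget random factor is degenerate: need >= 2 budget levels",
         call. = FALSE)
  }
  dat <- dplyr::mutate(dat,
                       dplyr::across(dplyr::all_of(factors), factor),
                       budget = factor(.data$budget))
  form <- stats::as.formula(paste(
    "persistence ~", paste(factors, collapse = " + "), "+ (1 | budget)"))
  fit <- withCallingHandlers(
    lme4::lmer(form, data = dat, REML = TRUE),
    message = function(m) {
      # a singular fit (variance component at 0) is tolerable here
      if (grepl("singular", conditionMessage(m), fixed = TRUE)) {
        warning("singular fit: a variance component was estimated at 0",
                call. = FALSE)
      }
      invokeRestart("muffleMessage")
    }
  )
  structure(
    list(model = fit, data = dat, factors = factors, species = species,
         budget_subset = budget_subset),
    class = "ccc_effects_fit"
  )
}

budget_quartile <- function(budget) {
  lv <- sort(unique(budget))
  blocks <- ceiling(4 * match(budget, lv) / length(lv))
  pmin(pmax(blocks, 1L), 4L)
}

#' @export
print.ccc_effects_fit <- function(x, ...) {
  g <- glance.ccc_effects_fit(x)
  cat("<ccc_effects_fit> species ", x$species, ", budgets: ",
      as.character(x$budget_subset), "\n", sep = "")
  cat("  fixed factors: ", paste(x$factors, collapse = ", "), "\n", sep = "")
  cat(sprintf("  R2m = %.4f, R2c = %.4f\n", g$R2m, g$R2c))
  invisible(x)
}

#' Tidy / summarise an effects-model fit
#'
#' `tidy()` returns the fixed-effect coefficients with standard errors;
#' `glance()` a one-row summary with the variance components and the
#' marginal and conditional coefficients of determination, computed by the
#' fixed/random variance partition: `R2m = Vfix / (Vfix + Vrand + Vres)` and
#' `R2c = (Vfix + Vrand) / (Vfix + Vrand + Vres)`, with `Vfix` the variance
#' of the fixed-effects linear predictor.
#'
#' @param x A `ccc_effects_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ccc_effects_fit <- function(x, ...) {
  cf <- summary(x$model)$coefficients
  tibble::tibble(term = rownames(cf), estimate = cf[, "Estimate"],
                 std.error = cf[, "Std. Error"], statistic = cf[, "t value"])
}

#' @rdname tidy.ccc_effects_fit
#' @export
glance.ccc_effects_fit <- function(x, ...) {
  v <- variance_partition(x$model)
  tibble::tibble(
    species = x$species,
    budget_subset = as.character(x$budget_subset),
    n = stats::nobs(x$model),
    var_fixed = v$vfix, var_budget = v$vrand, var_residual = v$vres,
    R2m = v$r2m, R2c = v$r2c
  )
}

variance_partition <- function(model) {
  vfix <- stats::var(as.vector(lme4::getME(model, "X") %*% lme4::fixef(model)))
  vc <- lme4::VarCorr(model)
  vrand <- sum(vapply(vc, function(m) sum(diag(m)), numeric(1)))
  vres <- stats::sigma(model)^2
  tot <- vfix + vrand + vres
  list(vfix = vfix, vrand = vrand, vres = vres,
       r2m = vfix / tot, r2c = (vfix + vrand) / tot)
}

#' Marginal level estimates and effect size of one factor
#'
#' Level estimates are balanced marginal means: the model prediction for each
#' level of the factor with every other fixed factor averaged with equal
#' weight over its levels (random intercepts at their mean, 0). The factor's
#' marginal estimate `PeffFm` is the mean of its level estimates, the range
#' `PeffFd` their max minus min, and the effect size their ratio
#' `Peff = PeffFd / PeffFm`.
#'
#' @param fit A `ccc_effects_fit`.
#' @param factor One of the fitted fixed factors.
#' @return A `ccc_effect` object: tibble of level estimates with attributes,
#'   summarised by [effect_sizes()].
#' @export
effect_size <- function(fit, factor) {
  stopifnot(inherits(fit, "ccc_effects_fit"))
  if (!factor %in% fit$factors) {
    stop("factor '", factor, "' is not a fitted fixed factor", call. = FALSE)
  }
  beta <- lme4::fixef(fit$model)
  level_means <- function(f) {
    lv <- levels(fit$data[[f]])
    est <- vapply(lv, function(l) {
      nm <- paste0(f, l)
      if (nm %in% names(beta)) beta[[nm]] else 0  # reference level
    }, numeric(1))
    stats::setNames(est, lv)
  }
  others <- setdiff(fit$factors, factor)
  offset <- beta[["(Intercept)"]] +
    sum(vapply(others, function(f) mean(level_means(f)), numeric(1)))
  est <- level_means(factor) + offset
  m <- mean(est)
  if (m <= 0) {
    stop(sprintf(
      "marginal estimate for '%s' is %.4g <= 0: effect size undefined",
      factor, m), call. = FALSE)
  }
  structure(
    tibble::tibble(factor = factor, level = names(est), estimate = unname(est)),
    PeffFm = m, PeffFd = max(est) - min(est), Peff = (max(est) - min(est)) / m,
    class = c("ccc_effect", class(tibble::tibble()))
  )
}

#' @export
print.ccc_effect <- function(x, ...) {
  cat(sprintf("<ccc_effect> %s: PeffFm = %.4g, PeffFd = %.4g, Peff = %.4g\n",
              x$factor[1], attr(x, "PeffFm"), attr(x, "PeffFd"), attr(x, "Peff")))
  print(tibble::as_tibble(x))
  invisible(x)
}

#' Effect sizes of all fitted factors
#'
#' @param fit A `ccc_effects_fit`.
#' @return Tibble with one row per factor: `factor`, `PeffFm`, `PeffFd`,
#'   `Peff`, sorted by `Peff` descending.
#' @export
effect_sizes <- function(fit) {
  purrr::map(fit$factors, function(f) {
    e <- effect_size(fit, f)
    tibble::tibble(species = fit$species,
                   budget_subset = as.character(fit$budget_subset),
                   factor = f, PeffFm = attr(e, "PeffFm"),
                   PeffFd = attr(e, "PeffFd"), Peff = attr(e, "Peff"))
  }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(dplyr::desc(.data$Peff))
}

#' Fraction of the dedicated-plan persistence retained in the joint plan
#'
#' For every matched setting (climate, dispersal, conflict, budget, species),
#' the ratio of the persistence achieved in the multi-species plan to the
#' single-species optimum used as its target. The ratio lies in `[0, 1]`
#' (a joint plan cannot beat the dedicated optimum at equal budget); settings
#' with a zero SS target are recorded as `NA`.
#'
#' @param results_ss Tibble from [run_ss()].
#' @param results_ms Tibble from [run_ms()].
#' @return Tibble keyed by setting and species with columns `ss_persistence`,
#'   `ms_persistence`, `ratio`.
#' @export
ms_ss_ratio <- function(results_ss, results_ms) {
  keys <- c("climate", "dispersal", "conflict", "budget", "species_id")
  ss <- dplyr::select(results_ss, dplyr::all_of(keys),
                      ss_persistence = "persistence")
  ms <- dplyr::select(results_ms, dplyr::all_of(keys),
                      ms_persistence = "persistence")
  unmatched <- dplyr::anti_join(ms, ss, by = keys)
  if (nrow(unmatched) > 0) {
    stop("MS settings with no SS counterpart, e.g.: ",
         paste(utils::capture.output(print(utils::head(unmatched, 3))),
               collapse = "\n"), call. = FALSE)
  }
  dplyr::inner_join(ss, ms, by = keys) |>
    dplyr::mutate(ratio = dplyr::if_else(.data$ss_persistence > 0,
                                         .data$ms_persistence / .data$ss_persistence,
                                         NA_real_))
}

#' Climate effect on persistence, by budget quartile
#'
#' The proportional persistence under a change scenario relative to a
#' reference scenario, computed per (species, design, dispersal, conflict,
#' budget) and averaged within the four consecutive budget quartiles of the
#' sweep. A zero reference persistence gives a missing ratio.
#'
#' @param results Long results tibble (columns as in
#'   `run_experiment()$results`).
#' @param change_scenario,reference_scenario Climate levels to compare
#'   (e.g. the severe-change scenario against no-change).
#' @return Tibble `species_id`, `design`, `dispersal`, `conflict`,
#'   `budget_quartile`, `ratio` (mean over the quartile's budgets, missing
#'   ratios dropped).
#' @export
climate_effect_ratio <- function(results, change_scenario = "A1FI",
                                 reference_scenario = "NC") {
  present <- unique(results$climate)
  if (!all(c(change_scenario, reference_scenario) %in% present)) {
    stop("both scenario levels must be present in the results", call. = FALSE)
  }
  keys <- c("species_id", "design", "dispersal", "conflict", "budget")
  keys <- keys[keys %in% names(results)]
  wide <- results |>
    dplyr::filter(.data$climate %in% c(change_scenario, reference_scenario)) |>
    dplyr::mutate(role = dplyr::if_else(.data$climate == change_scenario,
                                        "change", "reference")) |>
    dplyr::select(dplyr::all_of(keys), "role", "persistence") |>
    tidyr::pivot_wider(names_from = "role", values_from = "persistence")
  wide |>
    dplyr::mutate(
      ratio = dplyr::if_else(.data$reference > 0,
                             .data$change / .data$reference, NA_real_),
      budget_quartile = budget_quartile(.data$budget)
    ) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c(setdiff(keys, "budget"), "budget_quartile")))) |>
    dplyr::summarise(ratio = mean(.data$ratio, na.rm = TRUE), .groups = "drop")
}
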