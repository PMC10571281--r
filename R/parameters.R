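## Parameter bookkeeping: every model input is a "spec" (family, mean, sd,
## source) so the same object drives the base case, one-way sensitivity
## intervals and probabilistic sampling.

param_spec <- function(name, family, mean, sd, source = "") {
  spec <- list(name = name, family = family, mean = mean, sd = sd, source = source)
  validate_spec(spec)
  spec
}

validate_spec <- function(spec) {
  with(spec, {
    if (!family %in% c("beta", "gamma", "fixed"))
      stop("parameter '", name, "': unknown family '", family, "'")
    if (!is.numeric(mean) || !is.numeric(sd) || sd < 0)
      stop("parameter '", name, "': mean/sd must be numeric with sd >= 0")
    if (family == "beta") {
      if (mean < 0 || mean > 1)
        stop("parameter '", name, "': beta mean must lie in [0, 1], got ", mean)
      if (sd > 0 && sd^2 >= mean * (1 - mean))
        stop("parameter '", name, "': sd^2 = ", signif(sd^2, 6),
             " is infeasible for a beta with mean ", mean)
      if (sd == 0)
        stop("parameter '", name, "': sd = 0 requires family 'fixed'")
    }
    if (family == "gamma" && (mean <= 0 || sd <= 0))
      stop("parameter '", name, "': gamma requires mean > 0 and sd > 0")
  })
  invisible(spec)
}

## Table-1 groups, used for (de)serialisation and reporting.
param_groups <- function() {
  list(
    transitions = c("p_edss3", "p_edss6", "p_edss8", "p_edss10", "p_relapse",
                    "p_death_edss0", "p_death_edss3", "p_death_edss6"),
    treatment_effect = c("relapse_effect_rtx", "p_prog_rtx_0to3", "p_prog_rtx_3to6"),
    adverse_events = c("p_infusion_reaction", "p_minor_infection",
                       "p_agranulocytosis", "p_pneumonia"),
    costs = c("c_opd_edss0", "c_opd_edss3", "c_opd_edss6", "c_opd_edss8",
              "c_relapse_edss0", "c_relapse_edss3", "c_relapse_edss6", "c_relapse_edss8",
              "c_nonmed_edss0", "c_nonmed_edss3", "c_nonmed_edss6", "c_nonmed_edss8",
              "c_rituximab_month", "c_biosimilar_month", "c_admin_month",
              "c_infusion_reaction", "c_minor_infection",
              "c_agranulocytosis", "c_pneumonia"),
    utilities = c("u_edss0", "u_relapse0", "u_edss3", "u_relapse3",
                  "u_edss6", "u_edss8")
  )
}

default_settings <- function() {
  list(
    cycle_length = 1,            # months
    horizon_cycles = 720L,       # 60 years; see methods vignette
    discount_cost_annual = 0.03,
    discount_outcome_annual = 0.03,
    wtp = 160000,                # THB per QALY (Thai NLEM threshold)
    thb_per_usd = 37.97,
    psa_draws = 1000L,
    relapse_effect = "relative_risk",   # or "probability"
    relapse_return = "one_cycle",       # or "symmetric"
    relapse_progression = TRUE,         # progression allowed during a relapse cycle
    late_relapse_costs = TRUE,          # expected relapse costs in EDSS 6-7.5 / 8-9.5
    half_cycle = FALSE,
    discount_ly = TRUE,
    ci_method = "quantile"
  )
}

#' Model input parameters for the RRMS cost-utility model
#'
#' Builds the complete parameter set: monthly transition probabilities under
#' best supportive care, rituximab treatment-effect parameters, annual
#' adverse-event probabilities, unit costs in 2022 THB, state utilities, and
#' the model settings (cycle length, horizon, discount rates, willingness to
#' pay, exchange rate). Every uncertain parameter carries a distribution
#' family (`beta` for probabilities and utilities, `gamma` for costs) plus
#' mean and SD, parameterised by the method of moments for sensitivity
#' analysis.
#'
#' Defaults are the published Thai RRMS inputs. The monthly death probability
#' from EDSS 6.0-7.5 is absent from the published table; the default 0.0013 is
#' a calibrated value between the EDSS 3.0-5.5 death probability (0.0011) and
#' the EDSS 8.0-9.5 exit probability (0.0017) -- see the methods vignette.
#'
#' @param ... Named overrides. A numeric value replaces a parameter's mean
#'   (e.g. `p_relapse = 0.05`); a list may replace any spec field
#'   (e.g. `p_relapse = list(mean = 0.05, sd = 0.02)`). Settings are
#'   overridden by name (e.g. `horizon_cycles = 360`).
#' @param settings Optional named list of settings overrides, merged after
#'   `...`.
#' @return An object of class `rrms_parameters`: a list with elements `specs`
#'   (named list of parameter specifications) and `settings`.
#' @examples
#' p <- rrms_parameters()
#' p$specs$p_relapse$mean
#' rrms_parameters(horizon_cycles = 360)$settings$horizon_cycles
#' @export
rrms_parameters <- function(..., settings = list()) {
  s <- list(
    ## -- transition probabilities per monthly cycle, best supportive care --
    param_spec("p_edss3", "beta", 0.0075, 0.0046, "progression EDSS 0.0-2.5 -> 3.0-5.5"),
    param_spec("p_edss6", "beta", 0.0079, 0.0021, "progression EDSS 3.0-5.5 -> 6.0-7.5"),
    param_spec("p_edss8", "beta", 0.0018, 0.0018, "progression EDSS 6.0-7.5 -> 8.0-9.5"),
    param_spec("p_edss10", "beta", 0.0017, 0.0017, "progression EDSS 8.0-9.5 -> death"),
    param_spec("p_relapse", "beta", 0.0755, 0.0755, "relapse, EDSS < 6"),
    param_spec("p_death_edss0", "beta", 0.0009, 0.0009, "MS death from EDSS 0.0-2.5"),
    param_spec("p_death_edss3", "beta", 0.0011, 0.0011, "MS death from EDSS 3.0-5.5"),
    param_spec("p_death_edss6", "fixed", 0.0013, 0, "MS death from EDSS 6.0-7.5; calibrated"),
    ## -- rituximab treatment effect --
    param_spec("relapse_effect_rtx", "beta", 0.4220, 0.1727, "relative risk of relapse on rituximab"),
    param_spec("p_prog_rtx_0to3", "beta", 0.0041, 0.0008, "progression 0.0-2.5 -> 3.0-5.5 on rituximab"),
    param_spec("p_prog_rtx_3to6", "beta", 0.0041, 0.0008, "progression 3.0-5.5 -> 6.0-7.5 on rituximab"),
    ## -- adverse events, probability per year on treatment --
    param_spec("p_infusion_reaction", "beta", 0.1880, 0.0376, "infusion-related reaction"),
    param_spec("p_minor_infection", "beta", 0.1690, 0.0338, "minor infection"),
    param_spec("p_agranulocytosis", "beta", 0.0111, 0.0022, "agranulocytosis"),
    param_spec("p_pneumonia", "beta", 0.0065, 0.0013, "hospitalisation, pneumonia"),
    ## -- costs, THB (2022) --
    param_spec("c_opd_edss0", "gamma", 1317.70, 131.84, "OPD medical cost/month, EDSS 0.0-2.5"),
    param_spec("c_opd_edss3", "gamma", 2408.77, 349.20, "OPD medical cost/month, EDSS 3.0-5.5"),
    param_spec("c_opd_edss6", "gamma", 2202.10, 256.56, "OPD medical cost/month, EDSS 6.0-7.5"),
    param_spec("c_opd_edss8", "gamma", 2013.25, 260.12, "OPD medical cost/month, EDSS 8.0-9.5"),
    param_spec("c_relapse_edss0", "gamma", 40585.63, 4407.76, "medical cost of relapse, EDSS 0.0-2.5"),
    param_spec("c_relapse_edss3", "gamma", 71144.23, 7710.91, "medical cost of relapse, EDSS 3.0-5.5"),
    param_spec("c_relapse_edss6", "gamma", 80814.94, 9688.53, "medical cost of relapse, EDSS 6.0-7.5"),
    param_spec("c_relapse_edss8", "gamma", 55626.19, 7917.58, "medical cost of relapse, EDSS 8.0-9.5"),
    param_spec("c_nonmed_edss0", "gamma", 2686.70, 734.03, "direct non-medical cost/month, EDSS 0.0-2.5"),
    param_spec("c_nonmed_edss3", "gamma", 2975.33, 1172.32, "direct non-medical cost/month, EDSS 3.0-5.5"),
    param_spec("c_nonmed_edss6", "gamma", 10846.59, 1949.11, "direct non-medical cost/month, EDSS 6.0-7.5"),
    param_spec("c_nonmed_edss8", "gamma", 15061.94, 2782.91, "direct non-medical cost/month, EDSS 8.0-9.5"),
    param_spec("c_rituximab_month", "gamma", 8236, 1647, "originator rituximab, THB/month (5-y average)"),
    param_spec("c_biosimilar_month", "gamma", 2967, 590, "rituximab biosimilar, THB/month (5-y average)"),
    param_spec("c_admin_month", "gamma", 506.34, 101, "administration, THB/month"),
    param_spec("c_infusion_reaction", "gamma", 1465.12, 293, "treatment cost, infusion reaction"),
    param_spec("c_minor_infection", "gamma", 4999.92, 1000, "treatment cost, minor infection"),
    param_spec("c_agranulocytosis", "gamma", 23952.00, 4790, "treatment cost, agranulocytosis"),
    param_spec("c_pneumonia", "gamma", 9118.03, 1824, "treatment cost, pneumonia"),
    ## -- utilities (per year of life) --
    param_spec("u_edss0", "beta", 0.600, 0.02, "utility, EDSS 0.0-2.5"),
    param_spec("u_relapse0", "beta", 0.524, 0.10, "utility, EDSS 0.0-2.5 with relapse"),
    param_spec("u_edss3", "beta", 0.490, 0.04, "utility, EDSS 3.0-5.5"),
    param_spec("u_relapse3", "beta", 0.414, 0.08, "utility, EDSS 3.0-5.5 with relapse"),
    param_spec("u_edss6", "beta", 0.170, 0.06, "utility, EDSS 6.0-7.5"),
    param_spec("u_edss8", "beta", 0.026, 0.01, "utility, EDSS 8.0-9.5")
  )
  names(s) <- vapply(s, `[[`, "", "name")
  obj <- structure(list(specs = s, settings = default_settings()),
                   class = "rrms_parameters")

  dots <- list(...)
  setting_names <- names(default_settings())
  for (nm in names(dots)) {
    if (nm %in% setting_names) {
      obj$settings[[nm]] <- dots[[nm]]
    } else if (nm %in% names(obj$specs)) {
      if (is.list(dots[[nm]])) {
        obj$specs[[nm]][names(dots[[nm]])] <- dots[[nm]]
      } else {
        obj$specs[[nm]]$mean <- dots[[nm]]
      }
    } else {
      stop("rrms_parameters: unknown parameter or setting '", nm, "'")
    }
  }
  for (nm in names(settings)) {
    if (!nm %in% setting_names) stop("rrms_parameters: unknown setting '", nm, "'")
    obj$settings[[nm]] <- settings[[nm]]
  }
  validate_parameters(obj)
}

#' Validate a parameter set
#'
#' Checks every parameter specification (distribution feasibility, supports),
#' the utility ordering between relapse and non-relapse bands, and the model
#' settings. Called by all constructors; exported for use after manual edits.
#'
#' @param params An `rrms_parameters` object.
#' @return The validated object, invisibly usable in a pipeline.
#' @export
validate_parameters <- function(params) {
  stopifnot(inherits(params, "rrms_parameters"))
  missing <- setdiff(unlist(param_groups()), names(params$specs))
  if (length(missing))
    stop("parameter set is missing: ", paste(missing, collapse = ", "))
  for (spec in params$specs) validate_spec(spec)
  pv <- param_means(params)
  if (pv[["u_relapse0"]] > pv[["u_edss0"]] || pv[["u_relapse3"]] > pv[["u_edss3"]])
    stop("relapse-state utility exceeds its parent band's utility")
  st <- params$settings
  if (st$horizon_cycles < 1) stop("horizon_cycles must be >= 1")
  for (r in c("discount_cost_annual", "discount_outcome_annual"))
    if (st[[r]] < 0 || st[[r]] > 1) stop(r, " must lie in [0, 1]")
  if (!st$relapse_effect %in% c("relative_risk", "probability"))
    stop("relapse_effect must be 'relative_risk' or 'probability'")
  if (!st$relapse_return %in% c("one_cycle", "symmetric"))
    stop("relapse_return must be 'one_cycle' or 'symmetric'")
  params
}

## Named vector of parameter means (or sampled values).
param_means <- function(params) {
  vapply(params$specs, `[[`, numeric(1), "mean")
}

#' @export
print.rrms_parameters <- function(x, ...) {
  cat("RRMS model parameters:", length(x$specs), "inputs\n")
  grp <- param_groups()
  for (g in names(grp)) {
    cat("  ", g, " (", length(grp[[g]]), ")\n", sep = "")
  }
  st <- x$settings
  cat(sprintf("settings: %d monthly cycles, discount %g%%/%g%%, WTP %s THB/QALY\n",
              st$horizon_cycles, 100 * st$discount_cost_annual,
              100 * st$discount_outcome_annual,
              format(st$wtp, big.mark = ",")))
  invisible(x)
}

#' Read model parameters from a YAML file
#'
#' The file mirrors the published input table: one section per group
#' (`transitions`, `treatment_effect`, `adverse_events`, `costs`,
#' `utilities`), each entry giving `family`, `mean`, `sd` and optionally
#' `source`, plus a `settings` section. All costs are THB; probabilities are
#' per monthly cycle except adverse events, which are per year on treatment.
#' The bundled fixture is at
#' `system.file("extdata", "thai_rrms_parameters.yaml", package = "rrmscea")`.
#'
#' @param path Path to a YAML parameter file.
#' @return An `rrms_parameters` object.
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  doc <- yaml::read_yaml(path)
  grp <- param_groups()
  obj <- rrms_parameters()
  seen <- character(0)
  for (g in names(grp)) {
    if (is.null(doc[[g]])) stop("parameter file is missing section '", g, "'")
    for (nm in names(doc[[g]])) {
      if (!nm %in% names(obj$specs)) stop("unknown parameter '", nm, "' in section '", g, "'")
      e <- doc[[g]][[nm]]
      for (f in c("family", "mean", "sd"))
        if (is.null(e[[f]])) stop("parameter '", nm, "' is missing field '", f, "'")
      obj$specs[[nm]] <- param_spec(nm, e$family, e$mean, e$sd,
                                    if (is.null(e$source)) "" else e$source)
      seen <- c(seen, nm)
    }
  }
  missing <- setdiff(unlist(grp), seen)
  if (length(missing))
    stop("parameter file is missing: ", paste(missing, collapse = ", "))
  if (!is.null(doc$settings))
    for (nm in names(doc$settings)) {
      if (!nm %in% names(obj$settings)) stop("unknown setting '", nm, "'")
      obj$settings[[nm]] <- doc$settings[[nm]]
    }
  obj$settings$horizon_cycles <- as.integer(obj$settings$horizon_cycles)
  obj$settings$psa_draws <- as.integer(obj$settings$psa_draws)
  validate_parameters(obj)
}

#' Write model parameters to a YAML file
#'
#' Inverse of [read_parameters()]: loading the written file reproduces the
#' parameter set exactly.
#'
#' @param params An `rrms_parameters` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "rrms_parameters"))
  grp <- param_groups()
  doc <- lapply(grp, function(nms) {
    lapply(stats::setNames(nms, nms), function(nm) {
      s <- params$specs[[nm]]
      list(family = s$family, mean = s$mean, sd = s$sd, source = s$source)
    })
  })
  doc$settings <- params$settings
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}
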