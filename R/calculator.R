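#' @title Offline AML risk calculator
#' @description Composite clinical decision support: class assignment,
#'   ELN2017 and proposed risk, state-occupancy prediction with
#'   confidence intervals, contributing factors and outlier warnings,
#'   following the calculator input policy (genes default wild-type,
#'   unspecified clinical parameters imputed at cohort medians).
#' @name calculator
NULL

#' Train a calculator bundle on a cohort
#'
#' Classifies and risk-stratifies the cohort, builds the six-state
#' transition dataset and fits the per-transition Cox models over the
#' chosen covariates. The default covariate set is age, white blood cell
#' count, FLT3-ITD and the two proposed-risk indicator variables.
#'
#' @param cohort An \code{aml_cohort} with outcomes.
#' @param covariates Character vector of covariate names; must be
#'   producible by the covariate builder.
#' @param panel,hierarchy,risk_map,vocab Configuration objects.
#' @return An \code{aml_calculator} bundle.
#' @export
train_calculator <- function(cohort,
                             covariates = c("age_years", "wbc",
                                            "flt3_itd",
                                            "risk_intermediate",
                                            "risk_adverse"),
                             panel = NULL,
                             hierarchy = load_hierarchy(),
                             risk_map = load_risk_map(),
                             vocab = lesion_vocabulary()) {
  stopifnot(inherits(cohort, "aml_cohort"))
  if (is.null(panel)) panel <- cohort$panel
  cls <- classify_cohort(cohort, panel, hierarchy, vocab)
  risk <- risk_stratify_cohort(cls, cohort, risk_map, vocab)
  covdf <- calculator_covariates(cohort, risk)
  missing <- setdiff(covariates, names(covdf))
  if (length(missing)) {
    stop("covariate(s) not available: ",
         paste(missing, collapse = ", "))
  }
  msd <- build_multistate_dataset(cohort$outcomes,
                                  covdf[c("patient_id", covariates)])
  model <- fit_transition_cox(msd, covariates)
  clin_medians <- vapply(
    c("age_years", "wbc", "hb", "platelets", "bm_blast_pct"),
    function(v) stats::median(cohort$clinical[[v]], na.rm = TRUE), 0)
  structure(list(model = model, covariates = covariates,
                 panel = panel, hierarchy = hierarchy,
                 risk_map = risk_map, vocab = vocab,
                 clinical_medians = clin_medians,
                 n_excluded = nrow(msd$excluded)),
            class = "aml_calculator")
}

# numeric covariate frame for the multi-state model
calculator_covariates <- function(cohort, risk) {
  idx <- match(risk$patient_id, cohort$clinical$patient_id)
  data.frame(
    patient_id = risk$patient_id,
    age_years = cohort$clinical$age_years[idx],
    wbc = cohort$clinical$wbc[idx],
    bm_blast_pct = cohort$clinical$bm_blast_pct[idx],
    flt3_itd = as.numeric(vapply(cohort$profiles[idx], `[[`, TRUE,
                                 "flt3_itd")),
    risk_intermediate = as.numeric(risk$proposed == "intermediate_p"),
    risk_adverse = as.numeric(risk$proposed == "adverse_p"),
    stringsAsFactors = FALSE)
}

#' Build a calculator request
#'
#' All panel genes and cytogenetic findings default to wild-type /
#' normal unless specified; clinical parameters left NULL are imputed at
#' the training-cohort medians.
#'
#' @param genes Character vector of mutated genes (assumed oncogenic
#'   substitutions), or a full mutation data.frame via
#'   \code{mutations}.
#' @param mutations Optional mutation data.frame (overrides
#'   \code{genes}).
#' @param cytogenetics Character vector of coded lesions.
#' @param flt3_itd Set TRUE to add an ITD call.
#' @param flt3_itd_ratio Optional allelic ratio.
#' @param age_years,wbc Clinical inputs (NULL = impute at median).
#' @param start Prediction start state.
#' @param horizon Time horizon in years for the report grid.
#' @return A \code{calculator_request}.
#' @export
calculator_request <- function(genes = character(),
                               mutations = NULL,
                               cytogenetics = character(),
                               flt3_itd = FALSE,
                               flt3_itd_ratio = NA_real_,
                               age_years = NULL, wbc = NULL,
                               start = "alive_induction",
                               horizon = 5) {
  if (is.null(mutations)) {
    mutations <- if (length(genes))
      mutation_calls(genes) else empty_mutations()
  }
  if (flt3_itd && !any(mutations$gene == "FLT3" &
                         mutations$consequence == "itd")) {
    mutations <- rbind(mutations, mutation_calls(
      "FLT3", consequence = "itd"))
  }
  structure(list(mutations = mutations, cytogenetics = cytogenetics,
                 flt3_itd_ratio = flt3_itd_ratio,
                 age_years = age_years, wbc = wbc,
                 start = start, horizon = horizon),
            class = "calculator_request")
}

#' Run the calculator
#'
#' @param request A [calculator_request()].
#' @param bundle An \code{aml_calculator} from [train_calculator()].
#' @param ci Compute bootstrap confidence bands for the occupancy
#'   curves.
#' @param n_boot Bootstrap replicates when \code{ci = TRUE}.
#' @param seed Seed for the bootstrap.
#' @return An \code{aml_report}: class assignment, ELN2017 stratum,
#'   proposed stratum and shift, state-occupancy curves (+CIs),
#'   per-transition contributing factors, outlier warnings.
#' @export
calculate <- function(request, bundle, ci = FALSE, n_boot = 200,
                      seed = NULL) {
  stopifnot(inherits(request, "calculator_request"),
            inherits(bundle, "aml_calculator"))
  bad <- character()
  if (!is.null(request$age_years) &&
      (!is.numeric(request$age_years) || request$age_years < 0)) {
    bad <- c(bad, "age_years")
  }
  if (!is.null(request$wbc) &&
      (!is.numeric(request$wbc) || request$wbc < 0)) {
    bad <- c(bad, "wbc")
  }
  if (!request$start %in% c("alive_induction", "alive_cr")) {
    bad <- c(bad, "start")
  }
  if (length(bad)) {
    stop("invalid calculator request field(s): ",
         paste(bad, collapse = ", "))
  }
  profile <- lesion_profile(
    "calculator", mutations = request$mutations,
    cytogenetics = request$cytogenetics,
    flt3_itd_ratio = request$flt3_itd_ratio, vocab = bundle$vocab)
  assignment <- classify_patient(profile, bundle$panel,
                                 bundle$hierarchy, bundle$vocab)
  eln <- eln2017_stratify(profile, bundle$vocab)
  risk <- proposed_stratify(assignment, profile, bundle$risk_map)
  # genotype-derived covariates are always known; clinical parameters
  # left unspecified are imputed downstream at the per-transition
  # training medians (so their contributing factors are exactly zero)
  z <- list(
    flt3_itd = as.numeric(profile$flt3_itd),
    risk_intermediate = as.numeric(risk$proposed == "intermediate_p"),
    risk_adverse = as.numeric(risk$proposed == "adverse_p"))
  if (!is.null(request$age_years)) z$age_years <- request$age_years
  if (!is.null(request$wbc)) z$wbc <- request$wbc
  z <- z[names(z) %in% bundle$covariates]
  grid <- seq(0, request$horizon, length.out = 61)
  pred <- predict_state_occupancy(bundle$model, z,
                                  start = request$start, grid = grid,
                                  ci = ci, n_boot = n_boot,
                                  seed = seed)
  factors <- lapply(bundle$model$space$transitions$trans, function(q) {
    f <- bundle$model$fits[[q]]
    if (!f$estimable) return(NULL)
    contributing_factors(bundle$model, z, q)
  })
  names(factors) <- paste0(
    bundle$model$space$states[bundle$model$space$transitions$from],
    "->",
    bundle$model$space$states[bundle$model$space$transitions$to])
  structure(list(assignment = assignment, eln2017 = eln,
                 proposed = risk, occupancy = pred,
                 contributing_factors = factors,
                 outlier_warnings = pred$outliers,
                 request = request),
            class = "aml_report")
}

#' @export
print.aml_report <- function(x, ...) {
  cat("AML risk report\n")
  cat("  class:      ", x$assignment$aml_class, "\n")
  cat("  ELN2017:    ", x$eln2017, "\n")
  cat("  proposed:   ", x$proposed$proposed,
      if (x$proposed$shift_applied != "none")
        paste0(" (", x$proposed$shift_applied, ")"), "\n", sep = "")
  if (length(x$outlier_warnings)) {
    cat("  WARNING: covariate(s) outside the training 95% quantile",
        "range:", paste(x$outlier_warnings, collapse = ", "), "\n")
  }
  horizon_ix <- length(x$occupancy$times)
  p <- x$occupancy$P[horizon_ix, ]
  cat("  occupancy at", round(x$occupancy$times[horizon_ix], 2),
      "years:\n")
  for (s in names(p)) {
    cat(sprintf("    %-22s %5.1f%%\n", s, 100 * p[s]))
  }
  invisible(x)
}

#' Serialize a report to JSON
#'
#' @param report An \code{aml_report}.
#' @param path Output file.
#' @return Invisibly, \code{path}.
#' @export
report_to_json <- function(report, path) {
  occ <- as.data.frame(report$occupancy$P)
  occ$time <- report$occupancy$times
  obj <- list(
    patient = list(class = report$assignment$aml_class,
                   rule_rank = report$assignment$rule_rank,
                   evidence = report$assignment$evidence,
                   eln2017 = report$eln2017,
                   proposed = report$proposed$proposed,
                   shift_applied = report$proposed$shift_applied),
    outlier_warnings = report$outlier_warnings,
    occupancy = occ,
    contributing_factors = lapply(report$contributing_factors,
                                  as.list))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
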