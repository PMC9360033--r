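#' @title Risk stratification
#' @description ELN2017 reference stratification and the proposed 3-tier
#'   class-based risk score with FLT3-ITD shift rules.
#' @name risk
NULL

#' ELN2017 genetic risk stratification (reference standard)
#'
#' Implements the published three-tier ELN2017 genetic table over a lesion
#' profile. Favorable: core-binding-factor fusions (t(8;21), inv(16)),
#' t(15;17), mutated NPM1 without high-ratio FLT3-ITD, biallelic CEBPA.
#' Adverse: t(6;9), KMT2A rearrangements other than t(9;11), inv(3),
#' -5/del(5q), -7, -17/abn(17p), complex karyotype, monosomal karyotype,
#' and RUNX1, ASXL1 or TP53 mutations (which do not override a favorable
#' cytogenetic subtype). Everything else is intermediate, including
#' mutated NPM1 with high-ratio FLT3-ITD and t(9;11). FLT3-ITD is "high"
#' at allelic ratio >= 0.5; an ITD with missing ratio is treated as high.
#'
#' @param profile A [lesion_profile()].
#' @param vocab Lesion vocabulary.
#' @return One of \code{"favorable"}, \code{"intermediate"},
#'   \code{"adverse"}.
#' @export
eln2017_stratify <- function(profile, vocab = lesion_vocabulary()) {
  stopifnot(inherits(profile, "lesion_profile"))
  cyto <- profile$cytogenetics
  m <- profile$mutations
  onc <- m[m$oncogenic, , drop = FALSE]
  genes <- unique(onc$gene)
  kary <- derived_karyotype_features(profile, vocab)
  itd_high <- profile$flt3_itd &&
    (is.na(profile$flt3_itd_ratio) || profile$flt3_itd_ratio >= 0.5)
  bicebpa <- sum(onc$gene == "CEBPA") >= 2L

  fav_cyto <- any(cyto %in% c("t(8;21)", "inv(16)", "t(15;17)"))
  if (fav_cyto) return("favorable")

  adverse_cyto <- any(cyto %in% c("t(6;9)", "t(11;x)", "inv(3)",
                                  "-5", "del(5q)", "-7",
                                  "-17", "del(17p)")) ||
    kary$is_complex || kary$is_monosomal
  if (adverse_cyto || "TP53" %in% genes) return("adverse")

  # RUNX1/ASXL1 are adverse only outside the favorable molecular subtypes
  if (profile$npm1 && !itd_high) return("favorable")
  if (bicebpa) return("favorable")
  if (any(c("RUNX1", "ASXL1") %in% genes)) return("adverse")
  "intermediate"
}

#' Load the proposed base-stratum map
#'
#' @param path Optional YAML file with a top-level \code{proposed_base}
#'   mapping of class label to stratum; defaults to the bundled map.
#' @return Named character vector over the 16 class labels.
#' @export
load_risk_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "risk_map.yaml",
                        package = "amlclass", mustWork = TRUE)
  }
  map <- unlist(yaml::read_yaml(path)$proposed_base)
  missing <- setdiff(aml_classes(), names(map))
  if (length(missing)) {
    stop("risk map lacks a stratum for class(es): ",
         paste(missing, collapse = ", "))
  }
  bad <- !map %in% c("favorable_p", "intermediate_p", "adverse_p")
  if (any(bad)) {
    stop("invalid stratum value(s): ",
         paste(unique(map[bad]), collapse = ", "))
  }
  map[aml_classes()]
}

#' Proposed 3-tier class-based risk stratification
#'
#' Maps the molecular class to a base stratum (Favorable-P:
#' APL/t(15;17), inv(16), t(8;21), biCEBPA, NPM1, no events;
#' Intermediate-P: sAML1, trisomies, WT1, DNMT3A/IDH, t(6;9), mNOS,
#' KMT2A; Adverse-P: sAML2, TP53/complex, inv(3)), then applies the
#' FLT3-ITD shift rules: NPM1-class patients with FLT3-ITD move from
#' Favorable-P to Intermediate-P, and any Intermediate-P patient with
#' FLT3-ITD moves to Adverse-P. Shifts move exactly one tier downward and
#' are independent of the ITD allelic ratio.
#'
#' @param assignment A \code{class_assignment} from [classify_patient()],
#'   or a class label string.
#' @param profile The patient's [lesion_profile()] (source of the
#'   FLT3-ITD flag), or a logical FLT3-ITD indicator.
#' @param risk_map Base-stratum map from [load_risk_map()].
#' @return A list of class \code{risk_assignment}: \code{proposed} (one
#'   of favorable_p / intermediate_p / adverse_p), \code{shift_applied}
#'   (none / npm1_itd_down / itd_down), \code{aml_class},
#'   \code{flt3_itd}.
#' @export
proposed_stratify <- function(assignment, profile,
                              risk_map = load_risk_map()) {
  label <- if (inherits(assignment, "class_assignment"))
    assignment$aml_class else as.character(assignment)
  if (!label %in% names(risk_map)) stop("unknown class label: ", label)
  flt3_itd <- if (inherits(profile, "lesion_profile"))
    profile$flt3_itd else isTRUE(profile)
  base <- unname(risk_map[label])
  proposed <- base
  shift <- "none"
  if (flt3_itd && label == "NPM1" && base == "favorable_p") {
    proposed <- "intermediate_p"
    shift <- "npm1_itd_down"
  } else if (flt3_itd && base == "intermediate_p") {
    proposed <- "adverse_p"
    shift <- "itd_down"
  }
  structure(list(proposed = proposed, shift_applied = shift,
                 aml_class = label, flt3_itd = flt3_itd),
            class = "risk_assignment")
}

#' Full risk assignment (ELN2017 reference + proposed score) for a cohort
#'
#' @param classification A \code{cohort_classification} from
#'   [classify_cohort()].
#' @param cohort The matching \code{aml_cohort} (or list of profiles).
#' @param risk_map Base-stratum map.
#' @param vocab Lesion vocabulary.
#' @return data.frame with columns \code{patient_id}, \code{aml_class},
#'   \code{eln2017}, \code{proposed}, \code{shift_applied}.
#' @export
risk_stratify_cohort <- function(classification, cohort,
                                 risk_map = load_risk_map(),
                                 vocab = lesion_vocabulary()) {
  profiles <- if (inherits(cohort, "aml_cohort")) cohort$profiles
    else cohort
  a <- classification$assignments
  stopifnot(nrow(a) == length(profiles))
  ids <- vapply(profiles, `[[`, "", "patient_id")
  idx <- match(a$patient_id, ids)
  if (anyNA(idx)) stop("assignments and profiles do not match")
  eln <- character(nrow(a))
  prop <- character(nrow(a))
  shift <- character(nrow(a))
  for (i in seq_len(nrow(a))) {
    p <- profiles[[idx[i]]]
    eln[i] <- eln2017_stratify(p, vocab)
    r <- proposed_stratify(a$aml_class[i], p, risk_map)
    prop[i] <- r$proposed
    shift[i] <- r$shift_applied
  }
  data.frame(patient_id = a$patient_id, aml_class = a$aml_class,
             eln2017 = eln, proposed = prop, shift_applied = shift,
             stringsAsFactors = FALSE)
}

#' Re-stratification cross-tabulation
#'
#' Cross-tabulates the ELN2017 reference strata against the proposed
#' strata and reports the fraction of patients whose tier changed (share
#' off the diagonal, matching favorable to favorable_p and so on).
#'
#' @param eln Character vector of ELN2017 strata.
#' @param proposed Character vector of proposed strata (same patients,
#'   same order).
#' @return List with \code{table} (3 x 3 contingency table) and
#'   \code{fraction_restratified}.
#' @export
restratification_table <- function(eln, proposed) {
  if (length(eln) != length(proposed)) {
    stop("eln and proposed must have the same length")
  }
  eln_lv <- c("favorable", "intermediate", "adverse")
  prop_lv <- c("favorable_p", "intermediate_p", "adverse_p")
  tab <- table(eln = factor(eln, levels = eln_lv),
               proposed = factor(proposed, levels = prop_lv))
  frac <- 1 - sum(diag(tab)) / sum(tab)
  list(table = tab, fraction_restratified = frac)
}

#' @export
print.risk_assignment <- function(x, ...) {
  cat("class", x$aml_class, "-> proposed", x$proposed,
      if (x$shift_applied != "none")
        paste0("(shift: ", x$shift_applied, ")"), "\n")
  invisible(x)
}
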