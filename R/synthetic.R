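#' @title Synthetic AML cohort generator
#' @description Generates cohorts with known ground truth: class labels,
#'   class-conditional genotypes and clinical covariates, and six-state
#'   event trajectories with transition-specific hazards and
#'   right-censoring. In strict mode the class-defining lesions are
#'   emitted deterministically and no lesion from an earlier hierarchy
#'   rank contaminates a class, so re-classification recovers the truth
#'   labels exactly; noisy mode adds cross-class contamination for
#'   robustness studies.
#' @name synthetic
NULL

#' Default generator configuration
#'
#' Class prevalences follow the class frequencies reported for large
#' AML trial cohorts (TP53/complex 10.3%, trisomies 11.2%, sAML1 4.7%,
#' sAML2 23.7%, WT1 2%, DNMT3A/IDH 1%, mNOS 6%, no events 2.2%),
#' with the remaining mass
#' over the WHO-entity classes and NPM1 largest. Clinical distributions
#' are class-conditional (older complex-karyotype and secondary-AML-like
#' patients with higher antecedent-hematologic-disease rates, young
#' high-WBC WT1 patients). Baseline transition hazards approximate the
#' observed state flow (roughly 70% CR, half of CR relapsing, most
#' relapses fatal).
#'
#' @param n_patients Cohort size.
#' @param class_prevalences Named numeric over the 16 labels, summing
#'   to 1.
#' @param noise Cross-class contamination probability (0 = strict mode).
#' @param hazards List with \code{base} (named per-transition rates per
#'   year: t12, t14, t23, t25, t36), \code{class_log_hr} (named list:
#'   class -> length-5 log hazard ratios), \code{log_hr_age} (per year,
#'   applied to the three death transitions), \code{log_hr_itd}
#'   (length-5).
#' @param censoring Length-2 numeric: administrative censoring drawn
#'   uniformly between these times (years).
#' @return A \code{generator_config} list.
#' @export
generator_config <- function(n_patients = 500L,
                             class_prevalences = NULL,
                             noise = 0,
                             hazards = NULL,
                             censoring = c(2.5, 8)) {
  if (is.null(class_prevalences)) {
    class_prevalences <- c(
      APL_t15_17 = 0.030, inv16 = 0.035, t8_21 = 0.030,
      KMT2A_t11x = 0.020, t6_9 = 0.005, inv3 = 0.005,
      TP53_complex = 0.103, trisomies = 0.112, sAML2 = 0.237,
      biCEBPA = 0.014, NPM1 = 0.250, sAML1 = 0.047,
      DNMT3A_IDH = 0.010, WT1 = 0.020, mNOS = 0.060,
      no_events = 0.022)
  }
  if (!setequal(names(class_prevalences), aml_classes())) {
    stop("class_prevalences must cover exactly the 16 class labels")
  }
  if (abs(sum(class_prevalences) - 1) > 1e-8) {
    stop("class prevalences must sum to 1")
  }
  if (any(class_prevalences < 0)) stop("negative prevalence")
  default_hazards <- list(
    base = c(t12 = 1.8, t14 = 0.65, t23 = 0.45, t25 = 0.11,
             t36 = 0.8),
    class_log_hr = list(
      APL_t15_17 = c(0.5, -0.9, -0.7, -0.5, -0.5),
      inv16 = c(0.3, -0.5, 0.2, -0.3, -0.7),
      t8_21 = c(0.3, -0.5, 0.0, -0.3, -0.3),
      t6_9 = c(0.2, -0.2, 0.5, 0.0, 0.6),
      inv3 = c(-0.7, 0.9, 0.5, 0.3, 0.7),
      TP53_complex = c(-0.7, 0.9, 0.4, 0.4, 0.7),
      sAML2 = c(-0.5, 0.6, 0.4, 0.3, 0.4),
      sAML1 = c(-0.2, 0.2, 0.1, 0.1, 0.2),
      WT1 = c(0.1, -0.1, 0.5, 0.0, 0.6),
      NPM1 = c(0.2, -0.3, 0.0, 0.0, 0.0),
      no_events = c(0.2, -0.3, 0.0, 0.0, 0.0)),
    log_hr_age = 0.03,
    log_hr_itd = c(-0.2, 0.1, 0.5, 0.1, 0.4))
  if (is.null(hazards)) hazards <- default_hazards
  for (nm in names(default_hazards)) {
    if (is.null(hazards[[nm]])) hazards[[nm]] <- default_hazards[[nm]]
  }
  if (any(hazards$base <= 0)) stop("baseline hazards must be positive")
  structure(list(n_patients = as.integer(n_patients),
                 class_prevalences = class_prevalences[aml_classes()],
                 noise = noise, hazards = hazards,
                 censoring = censoring),
            class = "generator_config")
}

rb <- function(p) stats::runif(1) < p

new_vaf <- function(n = 1) stats::runif(n, 0.15, 0.55)

# one class-conditional genotype: returns list(mutations, cytogenetics)
emit_genotype <- function(label) {
  mut <- list()
  cyto <- character()
  add <- function(gene, consequence = "substitution", vaf = new_vaf()) {
    mut[[length(mut) + 1L]] <<- data.frame(
      gene = gene, vaf = vaf, consequence = consequence,
      oncogenic = TRUE, stringsAsFactors = FALSE)
  }
  saml_pool <- c("SRSF2", "SF3B1", "U2AF1", "ZRSR2", "ASXL1", "EZH2",
                 "BCOR", "STAG2", "RUNX1", "SETBP1")
  passenger <- function() {
    g <- sample(c("NRAS", "KRAS", "TET2", "PTPN11", "KIT"), 1)
    add(g)
  }
  switch(label,
    APL_t15_17 = {
      cyto <- "t(15;17)"
      if (rb(0.3)) add("WT1")
    },
    inv16 = {
      cyto <- "inv(16)"
      if (rb(0.3)) add("KIT")
      if (rb(0.3)) add("NRAS")
      if (rb(0.15)) cyto <- c(cyto, "+8")
    },
    t8_21 = {
      cyto <- "t(8;21)"
      if (rb(0.2)) add("KIT")
      if (rb(0.15)) cyto <- c(cyto, "del(9q)")
    },
    KMT2A_t11x = {
      cyto <- if (rb(0.6)) "t(9;11)" else "t(11;x)"
      if (rb(0.2)) passenger()
    },
    t6_9 = {
      cyto <- "t(6;9)"
    },
    inv3 = {
      cyto <- "inv(3)"
      if (rb(0.4)) cyto <- c(cyto, "-7")
      if (rb(0.2)) passenger()
    },
    TP53_complex = {
      tp53 <- rb(0.65)
      complex <- rb(0.9)
      if (!tp53 && !complex) complex <- TRUE
      if (tp53) {
        add("TP53", vaf = stats::runif(1, 0.2, 0.9))
        if (rb(0.25)) add("TP53", vaf = stats::runif(1, 0.1, 0.5))
      }
      if (complex) {
        k <- sample(3:5, 1)
        cyto <- sample(c("del(5q)", "-5", "-7", "del(7q)",
                         "del(17p)", "-17", "other_unbalanced"), k)
      }
    },
    trisomies = {
      k <- sample(1:4, 1, prob = c(0.45, 0.3, 0.15, 0.1))
      cyto <- sample(c("+8", "+11", "+13", "+21", "+22"), k)
      if (rb(0.2)) passenger()
    },
    sAML2 = {
      k <- sample(2:4, 1, prob = c(0.6, 0.3, 0.1))
      genes <- sample(saml_pool, k)
      for (g in genes) add(g)
      if (rb(0.15)) add("MLL", consequence = "ptd")
      if (rb(0.25)) {
        cyto <- sample(c("del(5q)", "-7", "del(7q)", "-X/-Y"),
                       sample(1:2, 1))
      }
      if (rb(0.3)) passenger()
    },
    biCEBPA = {
      add("CEBPA", consequence = "indel")
      add("CEBPA")
      if (rb(0.2)) add("GATA2")
    },
    NPM1 = {
      add("NPM1", consequence = "indel")
      if (rb(0.5)) add("DNMT3A")
      if (rb(0.15)) add("IDH1")
      if (rb(0.15)) add("IDH2")
      if (rb(0.2)) add("NRAS")
      if (rb(0.1)) add("PTPN11")
    },
    sAML1 = {
      add(sample(saml_pool, 1))
      if (rb(0.3)) add("TET2")
      if (rb(0.2)) add("NRAS")
    },
    DNMT3A_IDH = {
      add("DNMT3A")
      add(if (rb(0.5)) "IDH1" else "IDH2")
    },
    WT1 = {
      add("WT1")
      if (rb(0.2)) add("NRAS")
    },
    mNOS = {
      for (g in sample(c("NRAS", "KRAS", "TET2", "PTPN11", "JAK2",
                         "CBL", "PHF6", "KIT"), sample(1:2, 1))) {
        add(g)
      }
    },
    no_events = {
    }
  )
  list(mutations = if (length(mut)) do.call(rbind, mut) else
    empty_mutations(), cytogenetics = unique(cyto))
}

# lesions that can contaminate a profile in noisy mode
contamination_pool <- function() {
  list(
    list(type = "cyto", code = "t(15;17)"),
    list(type = "cyto", code = "inv(16)"),
    list(type = "cyto", code = "+8"),
    list(type = "cyto", code = "del(5q)"),
    list(type = "mut", gene = "TP53"),
    list(type = "mut", gene = "NPM1"),
    list(type = "mut", gene = "SRSF2"),
    list(type = "mut", gene = "ASXL1"))
}

# class-conditional FLT3-ITD rates
itd_rate <- function(label) {
  switch(label, t6_9 = 0.7, NPM1 = 0.4, WT1 = 0.4, APL_t15_17 = 0.35,
         biCEBPA = 0.1, TP53_complex = 0.05, trisomies = 0.1,
         no_events = 0, 0.15)
}

#' Generate a synthetic cohort with known class labels
#'
#' @param config A [generator_config()].
#' @param seed RNG seed (cohorts are reproducible given the seed).
#' @param panel Gene panel attached to the cohort.
#' @return An \code{aml_cohort} with an extra \code{truth} data.frame
#'   (\code{patient_id}, \code{aml_class}) and outcome columns left NA
#'   until [simulate_trajectories()] fills them.
#' @export
generate_cohort <- function(config = generator_config(), seed = 1L,
                            panel = load_panel()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(seed)
  n <- config$n_patients
  labels <- sample(names(config$class_prevalences), n, replace = TRUE,
                   prob = config$class_prevalences)
  ids <- sprintf("SYN%04d", seq_len(n))
  vocab <- lesion_vocabulary()
  profiles <- vector("list", n)
  names(profiles) <- ids
  clin_rows <- vector("list", n)
  for (i in seq_len(n)) {
    lab <- labels[i]
    g <- emit_genotype(lab)
    if (config$noise > 0 && rb(config$noise)) {
      cont <- sample(contamination_pool(), 1)[[1]]
      if (cont$type == "cyto") {
        g$cytogenetics <- unique(c(g$cytogenetics, cont$code))
      } else {
        g$mutations <- rbind(g$mutations, data.frame(
          gene = cont$gene, vaf = new_vaf(),
          consequence = "substitution", oncogenic = TRUE,
          stringsAsFactors = FALSE))
      }
    }
    itd <- rb(itd_rate(lab))
    ratio <- NA_real_
    if (itd) {
      g$mutations <- rbind(g$mutations, data.frame(
        gene = "FLT3", vaf = new_vaf(), consequence = "itd",
        oncogenic = TRUE, stringsAsFactors = FALSE))
      ratio <- round(stats::rlnorm(1, log(0.5), 0.7), 3)
    }
    # class-conditional clinical presentation
    age_mu <- switch(lab, TP53_complex = 62, sAML1 = 65.5,
                     sAML2 = 65.5, WT1 = 41, 56)
    age <- min(90, max(18, stats::rnorm(1, age_mu, 11)))
    wbc_mu <- if (lab == "WT1") log(45) else log(15)
    wbc <- round(stats::rlnorm(1, wbc_mu, 0.9), 1)
    blast_mu <- if (lab %in% c("sAML1", "sAML2")) 51 else 65
    blasts <- min(100, max(20, stats::rnorm(1, blast_mu, 18)))
    ahd_p <- if (lab %in% c("sAML1", "sAML2")) 0.32 else 0.114
    profiles[[i]] <- lesion_profile(
      ids[i], mutations = g$mutations,
      cytogenetics = g$cytogenetics,
      karyotype_available = TRUE, flt3_itd_ratio = ratio,
      vocab = vocab)
    clin_rows[[i]] <- data.frame(
      patient_id = ids[i],
      age_years = round(age, 1),
      sex = sample(c("M", "F"), 1),
      wbc = wbc,
      hb = round(stats::rnorm(1, 9.5, 1.5), 1),
      platelets = round(stats::rlnorm(1, log(60), 0.6), 0),
      bm_blast_pct = round(blasts, 0),
      ahd = rb(ahd_p),
      performance_status = sample(0:2, 1,
                                  prob = c(0.55, 0.35, 0.10)),
      disease_type = if (lab %in% c("sAML1", "sAML2") && rb(0.3))
        "sAML" else "de_novo",
      flt3_itd_ratio = ratio,
      stringsAsFactors = FALSE)
  }
  clinical <- do.call(rbind, clin_rows)
  outcomes <- data.frame(patient_id = ids, t_cr = NA_real_,
                         t_relapse = NA_real_, t_last = NA_real_,
                         dead = NA, stringsAsFactors = FALSE)
  cohort <- structure(list(profiles = profiles, clinical = clinical,
                           outcomes = outcomes, panel = panel,
                           truth = data.frame(
                             patient_id = ids, aml_class = labels,
                             stringsAsFactors = FALSE)),
                      class = "aml_cohort")
  cohort
}

#' Simulate six-state trajectories for a generated cohort
#'
#' Draws event times from per-transition exponential hazards scaled by
#' exp of the class, age and FLT3-ITD log hazard ratios; competing
#' transitions are resolved by the first event, and administrative
#' right-censoring is applied. Extra covariate effects can be injected
#' for parameter-recovery studies.
#'
#' @param cohort Cohort from [generate_cohort()] (needs \code{truth}).
#' @param config The [generator_config()] used (or a compatible one).
#' @param seed RNG seed.
#' @param extra_covariates Optional data.frame keyed by
#'   \code{patient_id} with additional numeric covariates.
#' @param extra_log_hr Named list: covariate name -> length-5 numeric of
#'   per-transition log hazard ratios.
#' @return The cohort with \code{outcomes} filled in (\code{t_cr},
#'   \code{t_relapse}, \code{t_last} in years, \code{dead}).
#' @export
simulate_trajectories <- function(cohort, config = generator_config(),
                                  seed = 1L, extra_covariates = NULL,
                                  extra_log_hr = NULL) {
  stopifnot(inherits(cohort, "aml_cohort"), !is.null(cohort$truth))
  set.seed(seed)
  hz <- config$hazards
  ids <- cohort$truth$patient_id
  n <- length(ids)
  out <- cohort$outcomes
  for (i in seq_len(n)) {
    lab <- cohort$truth$aml_class[i]
    age <- cohort$clinical$age_years[i]
    itd <- cohort$profiles[[i]]$flt3_itd
    lhr <- rep(0, 5)
    if (!is.null(hz$class_log_hr[[lab]])) {
      lhr <- lhr + hz$class_log_hr[[lab]]
    }
    lhr[c(2, 4, 5)] <- lhr[c(2, 4, 5)] + hz$log_hr_age * (age - 56)
    if (itd) lhr <- lhr + hz$log_hr_itd
    if (!is.null(extra_covariates)) {
      j <- match(ids[i], extra_covariates$patient_id)
      for (v in names(extra_log_hr)) {
        lhr <- lhr + extra_log_hr[[v]] * extra_covariates[[v]][j]
      }
    }
    rate <- hz$base * exp(lhr)
    cens <- stats::runif(1, config$censoring[1], config$censoring[2])
    t12 <- stats::rexp(1, rate["t12"])
    t14 <- stats::rexp(1, rate["t14"])
    if (min(t12, t14) >= cens) {
      out$t_last[i] <- cens
      out$dead[i] <- FALSE
      next
    }
    if (t14 < t12) {
      out$t_last[i] <- t14
      out$dead[i] <- TRUE
      next
    }
    t_cr <- t12
    out$t_cr[i] <- t_cr
    t23 <- stats::rexp(1, rate["t23"])
    t25 <- stats::rexp(1, rate["t25"])
    if (t_cr + min(t23, t25) >= cens) {
      out$t_last[i] <- cens
      out$dead[i] <- FALSE
      next
    }
    if (t25 < t23) {
      out$t_last[i] <- t_cr + t25
      out$dead[i] <- TRUE
      next
    }
    t_rel <- t_cr + t23
    out$t_relapse[i] <- t_rel
    t36 <- stats::rexp(1, rate["t36"])
    if (t_rel + t36 >= cens) {
      out$t_last[i] <- cens
      out$dead[i] <- FALSE
    } else {
      out$t_last[i] <- t_rel + t36
      out$dead[i] <- TRUE
    }
  }
  cohort$outcomes <- out
  cohort
}
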