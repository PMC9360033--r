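#' @title Six-state multi-state model of disease progression
#' @description Dataset construction, non-parametric (Aalen-Johansen)
#'   transition probabilities, per-transition Cox models, patient-level
#'   state-occupancy prediction and contributing-factor decomposition.
#' @name multistate
NULL

#' The six clinical states and five allowed transitions
#'
#' States: alive after induction (1), alive in complete remission (2),
#' relapse (3), death without CR (4), death in CR (5), death after
#' relapse (6). Death states are absorbing; the transition graph
#' (1->2, 1->4, 2->3, 2->5, 3->6) is acyclic. The clock is time from
#' diagnosis in years for every transition.
#'
#' @return List with \code{states} (character vector of length 6) and
#'   \code{transitions} (data.frame with columns \code{trans},
#'   \code{from}, \code{to}).
#' @export
state_space <- function() {
  list(
    states = c("alive_induction", "alive_cr", "relapse",
               "death_no_cr", "death_in_cr", "death_after_relapse"),
    transitions = data.frame(
      trans = 1:5,
      from = c(1L, 1L, 2L, 2L, 3L),
      to = c(2L, 4L, 3L, 5L, 6L))
  )
}

#' Build the long-format multi-state transition dataset
#'
#' Expands per-patient outcome timepoints into one record per transition
#' for which the patient was at risk, with entry/exit times on the
#' time-from-diagnosis clock. Patients with inconsistent or missing
#' timepoints (relapse without CR, non-positive follow-up, times out of
#' order, missing death indicator) are excluded and reported. Death with
#' a recorded relapse time routes through the relapse state; death in CR
#' without relapse is a 2->5 event.
#'
#' @param outcomes data.frame with columns \code{patient_id},
#'   \code{t_cr}, \code{t_relapse}, \code{t_last} (years; NA allowed for
#'   the first two) and \code{dead} (logical).
#' @param covariates Optional data.frame keyed by \code{patient_id};
#'   remaining columns are carried onto every record of that patient.
#' @return An object of class \code{msdataset}: list with \code{data}
#'   (records: patient_id, trans, from, to, t_entry, t_exit, status, and
#'   covariate columns), \code{excluded} (patient_id, reason),
#'   \code{covariates} (names), \code{space}.
#' @export
build_multistate_dataset <- function(outcomes, covariates = NULL) {
  sp <- state_space()
  req <- c("patient_id", "t_cr", "t_relapse", "t_last", "dead")
  missing <- setdiff(req, names(outcomes))
  if (length(missing)) {
    stop("outcomes table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  rows <- list()
  excl <- list()
  for (i in seq_len(nrow(outcomes))) {
    id <- as.character(outcomes$patient_id[i])
    t_cr <- outcomes$t_cr[i]
    t_rel <- outcomes$t_relapse[i]
    t_last <- outcomes$t_last[i]
    dead <- outcomes$dead[i]
    reason <- NULL
    if (is.na(t_last) || is.na(dead)) {
      reason <- "missing follow-up time or vital status"
    } else if (t_last <= 0) {
      reason <- "non-positive follow-up time"
    } else if (!is.na(t_rel) && is.na(t_cr)) {
      reason <- "relapse time without CR time"
    } else if (!is.na(t_cr) && (t_cr <= 0 || t_cr >= t_last)) {
      reason <- "CR time outside (0, t_last)"
    } else if (!is.na(t_rel) && (t_rel <= t_cr || t_rel >= t_last)) {
      reason <- "relapse time outside (t_cr, t_last)"
    }
    if (!is.null(reason)) {
      excl[[length(excl) + 1L]] <- data.frame(
        patient_id = id, reason = reason, stringsAsFactors = FALSE)
      next
    }
    rec <- function(trans, t_entry, t_exit, status) {
      data.frame(patient_id = id, trans = trans,
                 from = sp$transitions$from[trans],
                 to = sp$transitions$to[trans],
                 t_entry = t_entry, t_exit = t_exit,
                 status = as.integer(status),
                 stringsAsFactors = FALSE)
    }
    if (is.na(t_cr)) {
      # never reached CR: at risk for 1->2 and 1->4 until t_last
      rows[[length(rows) + 1L]] <- rbind(
        rec(1L, 0, t_last, 0L),
        rec(2L, 0, t_last, dead))
    } else {
      rows[[length(rows) + 1L]] <- rbind(
        rec(1L, 0, t_cr, 1L),
        rec(2L, 0, t_cr, 0L))
      if (is.na(t_rel)) {
        rows[[length(rows) + 1L]] <- rbind(
          rec(3L, t_cr, t_last, 0L),
          rec(4L, t_cr, t_last, dead))
      } else {
        rows[[length(rows) + 1L]] <- rbind(
          rec(3L, t_cr, t_rel, 1L),
          rec(4L, t_cr, t_rel, 0L),
          rec(5L, t_rel, t_last, dead))
      }
    }
  }
  data <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(), trans = integer(),
               from = integer(), to = integer(), t_entry = numeric(),
               t_exit = numeric(), status = integer(),
               stringsAsFactors = FALSE)
  cov_names <- character()
  if (!is.null(covariates) && nrow(data)) {
    if (!"patient_id" %in% names(covariates)) {
      stop("covariates must have a patient_id column")
    }
    cov_names <- setdiff(names(covariates), "patient_id")
    idx <- match(data$patient_id, as.character(covariates$patient_id))
    data <- cbind(data, covariates[idx, cov_names, drop = FALSE])
    rownames(data) <- NULL
  }
  structure(list(
    data = data,
    excluded = if (length(excl)) do.call(rbind, excl) else
      data.frame(patient_id = character(), reason = character(),
                 stringsAsFactors = FALSE),
    covariates = cov_names,
    space = sp), class = "msdataset")
}

#' @export
print.msdataset <- function(x, ...) {
  cat("Multi-state dataset:", length(unique(x$data$patient_id)),
      "patients,", nrow(x$data), "transition records,",
      nrow(x$excluded), "excluded\n")
  invisible(x)
}

# Per-transition Nelson-Aalen increments: for each transition, the event
# times and dA = d(t)/Y_from(t) with Y the at-risk count in the origin
# state. Returns list per transition of data.frame(time, dA).
na_increments <- function(data, transitions) {
  lapply(transitions$trans, function(q) {
    from <- transitions$from[transitions$trans == q]
    atrisk <- data[data$from == from, , drop = FALSE]
    ev <- data[data$trans == q & data$status == 1L, , drop = FALSE]
    # one origin-state at-risk set per from-state; records of both
    # transitions out of a state duplicate the at-risk interval, so count
    # distinct patients
    atrisk <- atrisk[!duplicated(paste(atrisk$patient_id,
                                       atrisk$t_entry)), , drop = FALSE]
    if (!nrow(ev)) {
      return(data.frame(time = numeric(), dA = numeric()))
    }
    times <- sort(unique(ev$t_exit))
    dA <- vapply(times, function(t) {
      d <- sum(ev$t_exit == t)
      y <- sum(atrisk$t_entry < t & atrisk$t_exit >= t)
      d / y
    }, 0)
    data.frame(time = times, dA = dA)
  })
}

# Product-integration of per-transition hazard increments into state
# occupancy P(t) starting from `start_dist` at time `start_time`.
product_integral <- function(increments, transitions, grid,
                             start_dist, start_time = 0) {
  n_states <- length(start_dist)
  all_times <- sort(unique(unlist(lapply(increments, `[[`, "time"))))
  all_times <- all_times[all_times > start_time]
  P <- matrix(NA_real_, length(grid), n_states)
  p <- start_dist
  gi <- 1L
  record_up_to <- function(tmax, p, gi) {
    while (gi <= length(grid) && grid[gi] < tmax) {
      P[gi, ] <<- p
      gi <- gi + 1L
    }
    gi
  }
  for (t in all_times) {
    gi <- record_up_to(t, p, gi)
    A <- diag(n_states)
    for (qi in seq_len(nrow(transitions))) {
      inc <- increments[[qi]]
      j <- match(t, inc$time)
      if (!is.na(j)) {
        from <- transitions$from[qi]
        to <- transitions$to[qi]
        A[from, to] <- A[from, to] + inc$dA[j]
        A[from, from] <- A[from, from] - inc$dA[j]
      }
    }
    # guard: a hazard increment > 1 (possible with tiny risk sets) would
    # produce a negative diagonal; clip row-wise to keep P a distribution
    for (s in seq_len(n_states)) {
      if (A[s, s] < 0) {
        off <- A[s, -s]
        A[s, -s] <- off / sum(off)
        A[s, s] <- 0
      }
    }
    p <- as.vector(p %*% A)
    gi <- record_up_to(t, p, gi)  # no-op; kept for clarity
  }
  while (gi <= length(grid)) {
    P[gi, ] <- p
    gi <- gi + 1L
  }
  # grid points at or after an event time t get the post-jump value
  for (k in seq_along(grid)) {
    upto <- all_times[all_times <= grid[k]]
    if (!length(upto)) P[k, ] <- start_dist
  }
  P
}

#' Aalen-Johansen state-occupancy probabilities
#'
#' Non-parametric estimate of the probability of occupying each of the
#' six states over time, computed by product-integration of Nelson-Aalen
#' transition-hazard increments. Rows sum to 1 at every grid point;
#' absorbing-state occupancy is non-decreasing.
#'
#' @param msd An \code{msdataset}.
#' @param grid Time grid (years); defaults to the union of event times
#'   plus the 1- and 3-year markers.
#' @param start Starting state name (default \code{"alive_induction"};
#'   \code{"alive_cr"} conditions on being in CR at \code{start_time}).
#' @param start_time Time at which all mass sits in \code{start}.
#' @return Object of class \code{aj_fit}: list with \code{times},
#'   \code{P} (matrix, columns named by state) and \code{space}.
#' @export
aalen_johansen <- function(msd, grid = NULL, start = "alive_induction",
                           start_time = 0) {
  stopifnot(inherits(msd, "msdataset"))
  sp <- msd$space
  start_ix <- match(start, sp$states)
  if (is.na(start_ix)) stop("unknown start state: ", start)
  inc <- na_increments(msd$data, sp$transitions)
  if (is.null(grid)) {
    grid <- sort(unique(c(unlist(lapply(inc, `[[`, "time")), 1, 3)))
    grid <- grid[grid >= start_time]
    if (!length(grid)) grid <- start_time
  }
  start_dist <- rep(0, length(sp$states))
  start_dist[start_ix] <- 1
  P <- product_integral(inc, sp$transitions, grid, start_dist,
                        start_time)
  colnames(P) <- sp$states
  structure(list(times = grid, P = P, space = sp), class = "aj_fit")
}

#' @export
print.aj_fit <- function(x, ...) {
  cat("Aalen-Johansen occupancy over", length(x$times),
      "grid points\n")
  last <- x$P[nrow(x$P), ]
  cat("  at t =", round(x$times[length(x$times)], 2), ":",
      paste(sprintf("%s %.2f", colnames(x$P), last),
            collapse = ", "), "\n")
  invisible(x)
}

#' Fit per-transition Cox proportional hazards models
#'
#' Fits a Cox model with transition-specific baseline hazards
#' h_ij(t|Z) = h_ij0(t) exp(beta_ij' Z) to each of the five transitions
#' (Breslow tie handling, partial likelihood via [survival::coxph()]).
#' Baseline cumulative-hazard increments are computed by the Breslow
#' estimator at covariate value zero; transition-specific covariate
#' medians (used for imputation and contributing factors) are taken over
#' that transition's at-risk records. Transitions with zero events are
#' flagged unestimable.
#'
#' @param msd An \code{msdataset} with covariate columns.
#' @param covariates Character vector of covariate column names; may be
#'   empty, in which case the fit reproduces the non-parametric
#'   estimator.
#' @return Object of class \code{transition_model}: per-transition list
#'   of \code{beta}, \code{se}, \code{baseline} (time, dH0), and
#'   \code{medians}; plus covariate 95% quantile ranges and the training
#'   dataset (for bootstrap).
#' @export
fit_transition_cox <- function(msd, covariates = msd$covariates) {
  stopifnot(inherits(msd, "msdataset"))
  covariates <- as.character(covariates)
  missing <- setdiff(covariates, names(msd$data))
  if (length(missing)) {
    stop("covariate column(s) not in dataset: ",
         paste(missing, collapse = ", "))
  }
  sp <- msd$space
  fits <- lapply(sp$transitions$trans, function(q) {
    d <- msd$data[msd$data$trans == q, , drop = FALSE]
    n_events <- sum(d$status)
    medians <- if (length(covariates))
      vapply(covariates, function(v) stats::median(d[[v]], na.rm = TRUE),
             0) else numeric()
    if (n_events == 0L) {
      return(list(estimable = FALSE, n_events = 0L,
                  beta = stats::setNames(rep(NA_real_,
                                             length(covariates)),
                                         covariates),
                  se = NULL, medians = medians,
                  baseline = data.frame(time = numeric(),
                                        dH0 = numeric())))
    }
    if (length(covariates)) {
      fml <- stats::as.formula(paste(
        "survival::Surv(t_entry, t_exit, status) ~",
        paste(covariates, collapse = " + ")))
      fit <- survival::coxph(fml, data = d, ties = "breslow")
      beta <- stats::coef(fit)
      se <- sqrt(diag(stats::vcov(fit)))
      lp <- as.vector(as.matrix(d[covariates]) %*% beta)
    } else {
      beta <- numeric()
      se <- numeric()
      lp <- rep(0, nrow(d))
    }
    # Breslow baseline at Z = 0: dH0(t) = d(t) / sum_{at risk} exp(lp)
    ev_times <- sort(unique(d$t_exit[d$status == 1L]))
    dH0 <- vapply(ev_times, function(t) {
      dcnt <- sum(d$t_exit == t & d$status == 1L)
      denom <- sum(exp(lp[d$t_entry < t & d$t_exit >= t]))
      dcnt / denom
    }, 0)
    list(estimable = TRUE, n_events = n_events, beta = beta, se = se,
         medians = medians,
         baseline = data.frame(time = ev_times, dH0 = dH0))
  })
  qr <- if (length(covariates)) {
    t(vapply(covariates, function(v)
      stats::quantile(msd$data[[v]], c(0.025, 0.975), na.rm = TRUE,
                      names = FALSE), c(0, 0)))
  } else matrix(numeric(), 0, 2)
  if (length(covariates)) {
    rownames(qr) <- covariates
    colnames(qr) <- c("lo", "hi")
  }
  structure(list(fits = fits, covariates = covariates,
                 quantile_range = qr, space = sp, dataset = msd),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  sp <- x$space
  cat("Per-transition Cox models (",
      paste(x$covariates, collapse = ", "), ")\n", sep = "")
  for (q in sp$transitions$trans) {
    f <- x$fits[[q]]
    cat(sprintf("  %s -> %s: %d events%s\n",
                sp$states[sp$transitions$from[q]],
                sp$states[sp$transitions$to[q]], f$n_events,
                if (!f$estimable) " (unestimable)" else ""))
  }
  invisible(x)
}

# Resolve a patient covariate vector against the model: missing entries
# imputed at the transition-specific medians; returns per-transition z and
# outlier flags against the training 95% quantile range.
resolve_covariates <- function(model, z) {
  covs <- model$covariates
  z_in <- stats::setNames(rep(NA_real_, length(covs)), covs)
  if (length(z)) {
    z <- unlist(z)
    unknown <- setdiff(names(z), covs)
    if (length(unknown)) {
      stop("unknown covariate(s): ", paste(unknown, collapse = ", "))
    }
    z_in[names(z)] <- as.numeric(z)
  }
  outliers <- character()
  for (v in covs) {
    if (!is.na(z_in[v]) && nrow(model$quantile_range)) {
      rng <- model$quantile_range[v, ]
      if (z_in[v] < rng["lo"] || z_in[v] > rng["hi"]) {
        outliers <- c(outliers, v)
      }
    }
  }
  per_trans <- lapply(model$fits, function(f) {
    zq <- z_in
    imp <- is.na(zq)
    zq[imp] <- f$medians[imp]
    zq
  })
  list(per_trans = per_trans, outliers = outliers, input = z_in)
}

#' Predict patient-level state occupancy from a fitted transition model
#'
#' Scales each transition's Breslow baseline increments by
#' exp(beta' z) and product-integrates into stacked state-occupancy
#' probabilities. Covariates not supplied are imputed at the
#' transition-specific training medians; covariates outside the training
#' 95% quantile range are flagged as outliers (prediction still
#' returned). Optional bootstrap confidence bands resample patients and
#' refit.
#'
#' @param model A \code{transition_model}.
#' @param z Named numeric vector/list of covariate values (may be
#'   partial or empty).
#' @param start Starting state (\code{"alive_induction"} or
#'   \code{"alive_cr"}).
#' @param grid Time grid; defaults to event times plus 1y/3y markers.
#' @param start_time Time at which the patient is in \code{start}.
#' @param ci Logical: compute bootstrap percentile confidence bands.
#' @param n_boot Bootstrap replicates (default 200).
#' @param conf_level Confidence level for the bands.
#' @param seed Optional seed for the bootstrap.
#' @return Object of class \code{occupancy_prediction}: \code{times},
#'   \code{P}, optional \code{lower}/\code{upper}, \code{outliers}
#'   (covariate names outside the training range), \code{z}.
#' @export
predict_state_occupancy <- function(model, z = list(),
                                    start = "alive_induction",
                                    grid = NULL, start_time = 0,
                                    ci = FALSE, n_boot = 200,
                                    conf_level = 0.95, seed = NULL) {
  stopifnot(inherits(model, "transition_model"))
  sp <- model$space
  start_ix <- match(start, sp$states)
  if (is.na(start_ix)) stop("unknown start state: ", start)
  rz <- resolve_covariates(model, z)
  inc <- scaled_increments(model, rz$per_trans)
  if (is.null(grid)) {
    grid <- sort(unique(c(unlist(lapply(inc, `[[`, "time")), 1, 3)))
    grid <- grid[grid >= start_time]
    if (!length(grid)) grid <- start_time
  }
  start_dist <- rep(0, length(sp$states))
  start_dist[start_ix] <- 1
  P <- product_integral(inc, sp$transitions, grid, start_dist,
                        start_time)
  colnames(P) <- sp$states
  out <- structure(list(times = grid, P = P, outliers = rz$outliers,
                        z = rz$input, start = start, space = sp),
                   class = "occupancy_prediction")
  if (ci) {
    if (!is.null(seed)) set.seed(seed)
    msd <- model$dataset
    ids <- unique(msd$data$patient_id)
    boots <- array(NA_real_, c(n_boot, length(grid),
                               length(sp$states)))
    for (b in seq_len(n_boot)) {
      take <- sample(ids, length(ids), replace = TRUE)
      pieces <- lapply(seq_along(take), function(k) {
        d <- msd$data[msd$data$patient_id == take[k], , drop = FALSE]
        d$patient_id <- paste0("b", k)
        d
      })
      bmsd <- structure(list(data = do.call(rbind, pieces),
                             excluded = msd$excluded,
                             covariates = msd$covariates,
                             space = sp), class = "msdataset")
      bmod <- tryCatch(
        fit_transition_cox(bmsd, model$covariates),
        error = function(e) NULL)
      if (is.null(bmod)) next
      brz <- resolve_covariates(bmod, z)
      binc <- scaled_increments(bmod, brz$per_trans)
      boots[b, , ] <- product_integral(binc, sp$transitions, grid,
                                       start_dist, start_time)
    }
    alpha <- (1 - conf_level) / 2
    out$lower <- apply(boots, c(2, 3), stats::quantile, alpha,
                       na.rm = TRUE)
    out$upper <- apply(boots, c(2, 3), stats::quantile, 1 - alpha,
                       na.rm = TRUE)
    colnames(out$lower) <- colnames(out$upper) <- sp$states
  }
  out
}

scaled_increments <- function(model, z_per_trans) {
  lapply(seq_along(model$fits), function(q) {
    f <- model$fits[[q]]
    if (!f$estimable || !nrow(f$baseline)) {
      return(data.frame(time = numeric(), dA = numeric()))
    }
    mult <- if (length(f$beta))
      exp(sum(f$beta * z_per_trans[[q]][names(f$beta)])) else 1
    data.frame(time = f$baseline$time, dA = f$baseline$dH0 * mult)
  })
}

#' Contributing factors for a transition
#'
#' Decomposes a patient's log-hazard for one transition into
#' per-covariate contributions beta_k (z_k - median_k), the
#' contributing-factor formula. A value of zero means the patient sits at
#' the training median for that covariate; negative values indicate a
#' lower-risk-than-median covariate value for that transition.
#'
#' @param model A \code{transition_model}.
#' @param z Named covariate values (missing entries are imputed at the
#'   transition medians and hence contribute exactly zero).
#' @param transition Transition index 1..5 (see [state_space()]).
#' @return Named numeric vector of per-covariate contributions.
#' @export
contributing_factors <- function(model, z, transition) {
  stopifnot(inherits(model, "transition_model"))
  if (!transition %in% model$space$transitions$trans) {
    stop("unknown transition: ", transition)
  }
  f <- model$fits[[transition]]
  if (!f$estimable) stop("transition ", transition, " is unestimable")
  rz <- resolve_covariates(model, z)
  zq <- rz$per_trans[[transition]]
  f$beta * (zq[names(f$beta)] - f$medians[names(f$beta)])
}

#' Serialize a transition model to JSON
#'
#' Writes coefficients, baseline cumulative-hazard step functions,
#' per-transition covariate medians and training quantile ranges.
#'
#' @param model A \code{transition_model}.
#' @param path Output file.
#' @return Invisibly, \code{path}.
#' @export
save_transition_model <- function(model, path) {
  obj <- list(
    covariates = model$covariates,
    quantile_range = if (nrow(model$quantile_range))
      as.data.frame(cbind(covariate = rownames(model$quantile_range),
                          as.data.frame(model$quantile_range)))
      else NULL,
    transitions = model$space$transitions,
    states = model$space$states,
    fits = lapply(model$fits, function(f)
      list(estimable = f$estimable, n_events = f$n_events,
           beta = as.list(f$beta), medians = as.list(f$medians),
           baseline = f$baseline)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
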