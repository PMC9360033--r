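#' @title Dirichlet-process mixture clustering of binary lesion matrices
#' @description The two-step DP mixture procedure that derived the
#'   molecular classes: collapsed Gibbs sampling with a Gamma hyperprior
#'   on the concentration parameter, cosine-similarity component merging,
#'   hyperparameter grid search and rule-based post-processing.
#' @name clustering
NULL

#' Hyperparameters for the DP mixture
#'
#' @param n_init_clusters Number of clusters for the random
#'   initialisation before Gibbs sweeps.
#' @param base_distribution \code{"bernoulli_beta"} (conjugate for binary
#'   lesions, the default) or \code{"gaussian"}.
#' @param alpha_shape,alpha_rate Shape/rate of the Gamma hyperprior on
#'   the DP concentration parameter.
#' @param n_iter Total Gibbs sweeps.
#' @param burn_in Sweeps discarded before samples are kept.
#' @param thin Keep every \code{thin}-th post-burn-in sweep.
#' @param beta_a,beta_b Beta base-measure pseudo-counts
#'   (bernoulli_beta base).
#' @param gauss_sigma2,gauss_tau2 Observation and prior-mean variance
#'   (gaussian base).
#' @param confidence_threshold Minimum top assignment probability for a
#'   patient to count as high-confidence.
#' @param seed Optional RNG seed for the fit.
#' @return A \code{dp_params} list.
#' @export
dp_params <- function(n_init_clusters = 10L,
                      base_distribution = c("bernoulli_beta",
                                            "gaussian"),
                      alpha_shape = 2, alpha_rate = 1,
                      n_iter = 300L, burn_in = 100L, thin = 5L,
                      beta_a = 1, beta_b = 1,
                      gauss_sigma2 = 0.25, gauss_tau2 = 1,
                      confidence_threshold = 0.7,
                      seed = NULL) {
  base_distribution <- match.arg(base_distribution)
  stopifnot(alpha_shape > 0, alpha_rate > 0, n_iter > burn_in,
            n_init_clusters >= 1, thin >= 1,
            confidence_threshold >= 0, confidence_threshold <= 1)
  structure(list(n_init_clusters = as.integer(n_init_clusters),
                 base_distribution = base_distribution,
                 alpha_shape = alpha_shape, alpha_rate = alpha_rate,
                 n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 beta_a = beta_a, beta_b = beta_b,
                 gauss_sigma2 = gauss_sigma2, gauss_tau2 = gauss_tau2,
                 confidence_threshold = confidence_threshold,
                 seed = seed),
            class = "dp_params")
}

# log predictive of row x under cluster sufficient stats (s = feature sums,
# nk = size); vectorised over clusters: S is K x d, nk length K.
log_pred_rows <- function(x, S, nk, params) {
  if (params$base_distribution == "bernoulli_beta") {
    a <- params$beta_a
    b <- params$beta_b
    p1 <- sweep(a + S, 1, a + b + nk, "/")
    lp <- log(p1) %*% x + log1p(-p1) %*% (1 - x)
    as.vector(lp)
  } else {
    s2 <- params$gauss_sigma2
    t2 <- params$gauss_tau2
    # posterior mean of cluster mean per feature; predictive variance
    post_var <- 1 / (nk / s2 + 1 / t2)            # length K
    post_mean <- sweep(S / s2, 1, 1 / (nk / s2 + 1 / t2), "*")
    pred_var <- post_var + s2                      # length K
    d <- length(x)
    sq <- sweep(post_mean, 2, x)^2
    -0.5 * d * log(2 * pi * pred_var) -
      0.5 * rowSums(sq) / pred_var
  }
}

# Escobar-West resampling of the DP concentration parameter.
resample_alpha <- function(alpha, n, K, shape, rate) {
  eta <- stats::rbeta(1, alpha + 1, n)
  odds <- (shape + K - 1) / (n * (rate - log(eta)))
  pi1 <- odds / (1 + odds)
  if (stats::runif(1) < pi1) {
    stats::rgamma(1, shape + K, rate - log(eta))
  } else {
    stats::rgamma(1, shape + K - 1, rate - log(eta))
  }
}

#' Fit a Dirichlet-process mixture to a binary lesion matrix
#'
#' Collapsed Gibbs sampling in the Chinese-restaurant representation with
#' per-sweep resampling of the concentration parameter under its
#' Gamma(shape, rate) hyperprior. The number of components is learned
#' from the data; lesions may be shared across components. The reported
#' partition is the posterior sample closest (least squares) to the
#' posterior co-assignment matrix; per-patient assignment probabilities
#' are post-burn-in co-assignment frequencies against the final
#' components. A fixed seed yields identical output.
#'
#' @param x Binary matrix, patients x features (column names = feature
#'   names).
#' @param params A [dp_params()] list.
#' @return Object of class \code{dp_clustering}: \code{components}
#'   (K x d feature-weight profiles), \code{weights}, \code{labels}
#'   (final partition), \code{prob} (n x K assignment probabilities,
#'   rows sum to 1), \code{high_confidence}, \code{delta} (top1 - top2
#'   probability), \code{alpha_trace}, \code{params},
#'   \code{feature_names}.
#' @export
fit_dp_mixture <- function(x, params = dp_params()) {
  x <- as.matrix(x)
  if (!all(x %in% c(0, 1))) stop("matrix entries must be 0/1")
  if (any(is.na(x))) stop("matrix must not contain missing values")
  n <- nrow(x)
  d <- ncol(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(d))
  if (!is.null(params$seed)) set.seed(params$seed)

  K0 <- min(params$n_init_clusters, n)
  z <- sample(rep_len(seq_len(K0), n))
  # sufficient stats as lists so clusters can be created/destroyed
  stats_from_z <- function(z) {
    ks <- sort(unique(z))
    list(nk = vapply(ks, function(k) sum(z == k), 0L),
         S = t(vapply(ks, function(k)
           colSums(x[z == k, , drop = FALSE]), numeric(d))),
         ids = ks)
  }
  st <- stats_from_z(z)
  # relabel 1..K
  z <- match(z, st$ids)
  nk <- st$nk
  S <- st$S
  alpha <- params$alpha_shape / params$alpha_rate
  alpha_trace <- numeric(params$n_iter)

  keep <- list()
  prior_S <- matrix(0, 1, d)
  for (it in seq_len(params$n_iter)) {
    for (i in seq_len(n)) {
      k <- z[i]
      nk[k] <- nk[k] - 1L
      S[k, ] <- S[k, ] - x[i, ]
      if (nk[k] == 0L) {
        nk <- nk[-k]
        S <- S[-k, , drop = FALSE]
        z[z > k] <- z[z > k] - 1L
      }
      K <- length(nk)
      lp_exist <- log_pred_rows(x[i, ], S, nk, params) + log(nk)
      lp_new <- log_pred_rows(x[i, ], prior_S, 0, params) + log(alpha)
      lp <- c(lp_exist, lp_new)
      lp <- lp - max(lp)
      pnew <- exp(lp)
      knew <- sample.int(K + 1L, 1L, prob = pnew)
      if (knew == K + 1L) {
        nk <- c(nk, 1L)
        S <- rbind(S, x[i, ])
      } else {
        nk[knew] <- nk[knew] + 1L
        S[knew, ] <- S[knew, ] + x[i, ]
      }
      z[i] <- knew
    }
    alpha <- resample_alpha(alpha, n, length(nk),
                            params$alpha_shape, params$alpha_rate)
    alpha_trace[it] <- alpha
    if (it > params$burn_in &&
        (it - params$burn_in) %% params$thin == 0L) {
      keep[[length(keep) + 1L]] <- z
    }
  }
  if (!length(keep)) keep <- list(z)
  Z <- do.call(rbind, keep)  # samples x patients

  # posterior co-assignment matrix and least-squares representative sample
  co <- matrix(0, n, n)
  for (s in seq_len(nrow(Z))) {
    zs <- Z[s, ]
    co <- co + outer(zs, zs, "==")
  }
  co <- co / nrow(Z)
  loss <- vapply(seq_len(nrow(Z)), function(s) {
    zs <- Z[s, ]
    sum((outer(zs, zs, "==") - co)^2)
  }, 0)
  best <- which.min(loss)
  zfin <- Z[best, ]
  ks <- sort(unique(zfin))
  zfin <- match(zfin, ks)
  K <- length(ks)

  # assignment probabilities: map each sample's clusters to the final
  # components by maximal overlap, then tally
  prob <- matrix(0, n, K)
  for (s in seq_len(nrow(Z))) {
    zs <- Z[s, ]
    tab <- table(zs, zfin)
    mapping <- apply(tab, 1, which.max)
    prob[cbind(seq_len(n), mapping[as.character(zs)])] <-
      prob[cbind(seq_len(n), mapping[as.character(zs)])] + 1
  }
  prob <- prob / nrow(Z)

  nk_fin <- vapply(seq_len(K), function(k) sum(zfin == k), 0L)
  S_fin <- t(vapply(seq_len(K), function(k)
    colSums(x[zfin == k, , drop = FALSE]), numeric(d)))
  components <- if (params$base_distribution == "bernoulli_beta") {
    sweep(params$beta_a + S_fin, 1,
          params$beta_a + params$beta_b + nk_fin, "/")
  } else {
    sweep(S_fin, 1, nk_fin, "/")
  }
  colnames(components) <- colnames(x)
  top2 <- t(apply(prob, 1, function(p)
    sort(p, decreasing = TRUE)[1:2]))
  if (K == 1L) top2 <- cbind(prob[, 1], 0)
  delta <- top2[, 1] - top2[, 2]
  structure(list(components = components,
                 weights = nk_fin / n,
                 labels = zfin,
                 prob = prob,
                 high_confidence = top2[, 1] >=
                   params$confidence_threshold,
                 delta = delta,
                 alpha_trace = alpha_trace,
                 params = params,
                 feature_names = colnames(x)),
            class = "dp_clustering")
}

#' @export
print.dp_clustering <- function(x, ...) {
  cat("DP mixture:", ncol(x$prob), "components,", nrow(x$prob),
      "patients,", sum(x$high_confidence), "high-confidence\n")
  invisible(x)
}

cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Merge similar mixture components
#'
#' Components whose feature profiles have pairwise cosine similarity at
#' or above the threshold are merged (transitive closure); assignment
#' probabilities are re-aggregated and profiles recomputed as
#' weight-averaged profiles.
#'
#' @param result A \code{dp_clustering}.
#' @param threshold Cosine similarity threshold in \[0,1\].
#' @return A \code{dp_clustering} with merged components.
#' @export
merge_components <- function(result, threshold) {
  stopifnot(inherits(result, "dp_clustering"))
  if (threshold < 0 || threshold > 1) {
    stop("threshold must be in [0,1]")
  }
  K <- nrow(result$components)
  parent <- seq_len(K)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      if (j <= i) next
      if (cosine_sim(result$components[i, ],
                     result$components[j, ]) >= threshold) {
        ri <- find(i)
        rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(K), find, 0L)
  groups <- match(roots, sort(unique(roots)))
  Knew <- max(groups)
  if (Knew == K) return(result)
  prob <- matrix(0, nrow(result$prob), Knew)
  comps <- matrix(0, Knew, ncol(result$components))
  weights <- numeric(Knew)
  for (g in seq_len(Knew)) {
    members <- which(groups == g)
    prob[, g] <- rowSums(result$prob[, members, drop = FALSE])
    w <- result$weights[members]
    comps[g, ] <- colSums(result$components[members, , drop = FALSE] *
                            w) / sum(w)
    weights[g] <- sum(w)
  }
  colnames(comps) <- result$feature_names
  labels <- groups[result$labels]
  top2 <- t(apply(prob, 1, function(p)
    c(sort(p, decreasing = TRUE), 0)[1:2]))
  out <- result
  out$components <- comps
  out$weights <- weights
  out$labels <- labels
  out$prob <- prob
  out$high_confidence <- top2[, 1] >=
    result$params$confidence_threshold
  out$delta <- top2[, 1] - top2[, 2]
  out
}

#' Two-step DP mixture fit
#'
#' First iteration on the full matrix; patients whose top assignment
#' probability falls below the confidence threshold are refit in a
#' second iteration on their own sub-matrix, and the two sets of
#' assignments are combined (step-1 components first, step-2 components
#' appended).
#'
#' @param x Binary matrix.
#' @param params A [dp_params()].
#' @param confidence_threshold Overrides
#'   \code{params$confidence_threshold} when given.
#' @return A \code{dp_clustering} with an extra \code{step} vector
#'   recording which iteration assigned each patient.
#' @export
two_step_fit <- function(x, params = dp_params(),
                         confidence_threshold = NULL) {
  if (!is.null(confidence_threshold)) {
    params$confidence_threshold <- confidence_threshold
  }
  step1 <- fit_dp_mixture(x, params)
  low <- !step1$high_confidence
  if (!any(low) || sum(low) < 3L) {
    step1$step <- rep(1L, nrow(step1$prob))
    return(step1)
  }
  p2 <- params
  if (!is.null(p2$seed)) p2$seed <- p2$seed + 1L
  p2$n_init_clusters <- min(p2$n_init_clusters, sum(low))
  step2 <- fit_dp_mixture(x[low, , drop = FALSE], p2)

  K1 <- ncol(step1$prob)
  K2 <- ncol(step2$prob)
  n <- nrow(x)
  prob <- matrix(0, n, K1 + K2)
  prob[!low, seq_len(K1)] <- step1$prob[!low, , drop = FALSE]
  prob[low, K1 + seq_len(K2)] <- step2$prob
  labels <- integer(n)
  labels[!low] <- step1$labels[!low]
  labels[low] <- K1 + step2$labels
  comps <- rbind(step1$components, step2$components)
  # component weights over the combined assignment
  w1 <- vapply(seq_len(K1), function(k)
    sum(labels[!low] == k), 0L) / n
  weights <- c(w1, step2$weights * sum(low) / n)
  top2 <- t(apply(prob, 1, function(p)
    c(sort(p, decreasing = TRUE), 0)[1:2]))
  structure(list(components = comps, weights = weights,
                 labels = labels, prob = prob,
                 high_confidence = top2[, 1] >=
                   params$confidence_threshold,
                 delta = top2[, 1] - top2[, 2],
                 alpha_trace = step1$alpha_trace,
                 params = params,
                 feature_names = step1$feature_names,
                 step = ifelse(low, 2L, 1L)),
            class = "dp_clustering")
}

#' Hyperparameter grid search
#'
#' Scores each configuration on (1) the number of high-confidence
#' components (components that are the top assignment of at least one
#' high-confidence patient), (2) the mean top assignment probability and
#' (3) the mean top1 - top2 probability delta, ranked lexicographically
#' in that order; ties keep grid order.
#'
#' @param x Binary matrix.
#' @param grid List of [dp_params()] configurations.
#' @return List with \code{ranking} (data.frame of scores, best first)
#'   and \code{fits} (the fitted \code{dp_clustering} objects, in grid
#'   order).
#' @export
grid_search <- function(x, grid) {
  if (!length(grid)) stop("empty hyperparameter grid")
  fits <- lapply(grid, function(p) fit_dp_mixture(x, p))
  scores <- t(vapply(fits, function(f) {
    top <- apply(f$prob, 1, which.max)
    hc_comp <- length(unique(top[f$high_confidence]))
    c(n_high_conf_components = hc_comp,
      mean_top1 = mean(apply(f$prob, 1, max)),
      mean_delta = mean(f$delta))
  }, numeric(3)))
  ord <- order(-scores[, 1], -scores[, 2], -scores[, 3],
               seq_len(nrow(scores)))
  ranking <- data.frame(config = ord,
                        scores[ord, , drop = FALSE],
                        row.names = NULL)
  list(ranking = ranking, fits = fits)
}

#' Rule-based post-processing of component assignments
#'
#' Applies the class-defining-lesion constraint: a patient may only be
#' assigned to a component if at least one of that component's defining
#' lesions is present in the patient's row. Patients are assigned to the
#' highest-probability component whose defining lesion they carry;
#' patients satisfying no component's constraint become unassigned (NA,
#' feeding the molecularly-not-otherwise-specified pool). Optional
#' manual splits partition a component into two by the presence of a
#' discriminating lesion before the constraint is applied.
#'
#' @param result A \code{dp_clustering}.
#' @param x The binary matrix the clustering was fitted to.
#' @param class_defining_map Named list: component index (as character)
#'   or component name -> character vector of defining feature names
#'   (any-of). Components without an entry are unconstrained (warned).
#' @param manual_splits Optional list of \code{list(component =, by =)}
#'   entries splitting a component by a feature.
#' @return List with \code{labels} (integer component per patient, NA =
#'   unassigned), \code{components} (profiles after splits) and
#'   \code{prob}.
#' @export
postprocess_assignments <- function(result, x, class_defining_map,
                                    manual_splits = NULL) {
  stopifnot(inherits(result, "dp_clustering"))
  x <- as.matrix(x)
  prob <- result$prob
  comps <- result$components
  map <- class_defining_map
  # manual splits: duplicate the component column, gate by the feature
  if (!is.null(manual_splits)) {
    for (spl in manual_splits) {
      k <- spl$component
      feat <- spl$by
      if (!feat %in% colnames(x)) {
        stop("split feature not in matrix: ", feat)
      }
      carrier <- x[, feat] == 1
      Kcur <- ncol(prob)
      newcol <- prob[, k] * carrier
      prob[, k] <- prob[, k] * !carrier
      prob <- cbind(prob, newcol)
      comps <- rbind(comps, comps[k, ])
      comps[Kcur + 1L, ] <- comps[k, ]
      map[[as.character(Kcur + 1L)]] <- feat
      # the original component keeps its map entry minus the split feature
      orig <- map[[as.character(k)]]
      if (!is.null(orig)) {
        map[[as.character(k)]] <- setdiff(orig, feat)
      }
    }
  }
  K <- ncol(prob)
  allowed <- matrix(TRUE, nrow(x), K)
  for (k in seq_len(K)) {
    feats <- map[[as.character(k)]]
    if (is.null(feats)) {
      warning("component ", k,
              " has no class-defining entry; left unconstrained")
      next
    }
    feats <- intersect(feats, colnames(x))
    allowed[, k] <- if (length(feats))
      rowSums(x[, feats, drop = FALSE]) > 0 else FALSE
  }
  gated <- prob * allowed
  labels <- apply(gated, 1, function(p)
    if (all(p == 0)) NA_integer_ else which.max(p))
  list(labels = labels, components = comps, prob = prob)
}
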