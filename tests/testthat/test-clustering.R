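test_that("degenerate inputs collapse to a single component", {
  x <- matrix(rep(c(1, 0, 1, 0, 0, 1), each = 40), nrow = 40)
  colnames(x) <- paste0("f", 1:6)
  fit <- fit_dp_mixture(x, dp_params(seed = 1, n_iter = 120,
                                     burn_in = 40))
  expect_equal(ncol(fit$prob), 1)
  expect_true(all(fit$prob == 1))
  x0 <- matrix(0, 30, 5)
  fit0 <- fit_dp_mixture(x0, dp_params(seed = 2, n_iter = 120,
                                       burn_in = 40))
  expect_equal(ncol(fit0$prob), 1)
  expect_error(fit_dp_mixture(matrix(2, 3, 3), dp_params()),
               "0/1")
})

test_that("assignment probabilities are proper and fits are seeded", {
  pl <- planted_matrix(120, 2, seed = 3)
  prm <- dp_params(seed = 4, n_iter = 150, burn_in = 50)
  fit <- fit_dp_mixture(pl$x, prm)
  expect_true(all(abs(rowSums(fit$prob) - 1) < 1e-12))
  fit2 <- fit_dp_mixture(pl$x, prm)
  expect_identical(fit$labels, fit2$labels)
  expect_identical(fit$prob, fit2$prob)
})

test_that("planted two-block structure is recovered", {
  pl <- planted_matrix(150, 2, seed = 5)
  fit <- fit_dp_mixture(pl$x, dp_params(seed = 6, n_iter = 200,
                                        burn_in = 80))
  expect_equal(adjusted_rand(fit$labels, pl$labels), 1,
               tolerance = 0.05)
})

test_that("component merging: identical merge, orthogonal stay, sweep
           is monotone", {
  pl <- planted_matrix(150, 3, seed = 7)
  fit <- fit_dp_mixture(pl$x, dp_params(seed = 8, n_iter = 200,
                                        burn_in = 80))
  # identical components merge at threshold 1
  dup <- fit
  dup$components <- rbind(fit$components, fit$components[1, ])
  dup$weights <- c(fit$weights, fit$weights[1])
  dup$prob <- cbind(fit$prob, fit$prob[, 1])
  dup$prob <- dup$prob / rowSums(dup$prob)
  merged <- merge_components(dup, 0.9999)
  expect_lt(ncol(merged$prob), ncol(dup$prob))
  # orthogonal profiles never merge
  orth <- fit
  orth$components <- diag(3)[, c(1, 2, 3)]
  colnames(orth$components) <- fit$feature_names[1:3]
  orth$components <- cbind(orth$components,
                           matrix(0, 3, length(fit$feature_names) - 3))
  colnames(orth$components) <- fit$feature_names
  expect_equal(ncol(merge_components(orth, 0.5)$prob),
               ncol(orth$prob))
  # decreasing the threshold never increases the component count
  counts <- vapply(c(0.95, 0.8, 0.5, 0.2), function(th)
    ncol(merge_components(fit, th)$prob), 0L)
  expect_true(all(diff(counts) <= 0))
  expect_error(merge_components(fit, 1.5), "\\[0,1\\]")
})

test_that("two-step refit is a no-op when all are confident and refits
           improve low-confidence assignment", {
  pl <- planted_matrix(150, 2, seed = 9)
  prm <- dp_params(seed = 10, n_iter = 150, burn_in = 50,
                   confidence_threshold = 0.5)
  ts <- two_step_fit(pl$x, prm)
  if (all(ts$step == 1L)) {
    expect_equal(ncol(ts$prob), length(unique(ts$labels)))
  }
  # noisy rows: step 2 must improve their mean top probability
  set.seed(11)
  x <- planted_matrix(270, 3, seed = 11)$x
  noisy <- matrix(rbinom(30 * ncol(x), 1, 0.5), 30)
  colnames(noisy) <- colnames(x)
  xx <- rbind(x, noisy)
  prm2 <- dp_params(seed = 12, n_iter = 150, burn_in = 50,
                    confidence_threshold = 0.9)
  step1 <- fit_dp_mixture(xx, prm2)
  ts2 <- two_step_fit(xx, prm2)
  low <- !step1$high_confidence
  if (any(low)) {
    top1_before <- apply(step1$prob[low, , drop = FALSE], 1, max)
    top1_after <- apply(ts2$prob[low, , drop = FALSE], 1, max)
    expect_gte(mean(top1_after), mean(top1_before))
  }
  # determinism of the full two-step path
  ts3 <- two_step_fit(xx, prm2)
  expect_identical(ts2$labels, ts3$labels)
})

test_that("grid search scores and orders configurations
           deterministically", {
  pl <- planted_matrix(100, 2, seed = 13)
  g1 <- dp_params(seed = 14, n_iter = 100, burn_in = 40)
  g2 <- dp_params(seed = 14, n_iter = 100, burn_in = 40,
                  n_init_clusters = 2)
  gs <- grid_search(pl$x, list(g1, g2))
  expect_equal(nrow(gs$ranking), 2)
  expect_true(all(c("n_high_conf_components", "mean_top1",
                    "mean_delta") %in% names(gs$ranking)))
  # one-point grid returns that configuration
  gs1 <- grid_search(pl$x, list(g1))
  expect_equal(gs1$ranking$config, 1)
  # identical configurations tie and keep grid order
  gs1b <- grid_search(pl$x, list(g1, g1))
  expect_equal(gs1b$ranking$config, c(1, 2))
  expect_error(grid_search(pl$x, list()), "empty")
})

test_that("post-processing enforces class-defining lesions and manual
           splits", {
  pl <- planted_matrix(120, 2, seed = 15)
  fit <- fit_dp_mixture(pl$x, dp_params(seed = 16, n_iter = 150,
                                        burn_in = 50))
  K <- ncol(fit$prob)
  # defining feature of each component = its strongest feature
  map <- stats::setNames(
    lapply(seq_len(K), function(k)
      colnames(pl$x)[which.max(fit$components[k, ])]),
    as.character(seq_len(K)))
  pp <- postprocess_assignments(fit, pl$x, map)
  for (i in which(!is.na(pp$labels))) {
    feats <- map[[as.character(pp$labels[i])]]
    expect_true(any(pl$x[i, feats] == 1))
  }
  # a patient lacking every defining lesion is unassigned
  x2 <- rbind(pl$x, 0)
  fit2 <- fit
  fit2$prob <- rbind(fit$prob, rep(1 / K, K))
  pp2 <- postprocess_assignments(fit2, x2, map)
  expect_true(is.na(pp2$labels[nrow(x2)]))
  # manual split partitions a mixed component by the discriminating flag
  set.seed(17)
  xm <- matrix(rbinom(80 * 4, 1, 0.05), 80, 4)
  colnames(xm) <- c("t15_17", "t11x", "shared1", "shared2")
  xm[1:40, "t15_17"] <- 1
  xm[41:80, "t11x"] <- 1
  xm[, c("shared1", "shared2")] <- rbinom(160, 1, 0.8)
  one <- structure(list(
    components = matrix(colMeans(xm), 1,
                        dimnames = list(NULL, colnames(xm))),
    weights = 1, labels = rep(1L, 80),
    prob = matrix(1, 80, 1), high_confidence = rep(TRUE, 80),
    delta = rep(1, 80), params = dp_params(),
    feature_names = colnames(xm)), class = "dp_clustering")
  pp3 <- postprocess_assignments(
    one, xm,
    class_defining_map = list(`1` = c("t15_17", "t11x")),
    manual_splits = list(list(component = 1, by = "t11x")))
  expect_setequal(stats::na.omit(unique(pp3$labels)), c(1, 2))
  expect_true(all(pp3$labels[41:80] == 2, na.rm = TRUE))
  expect_true(all(pp3$labels[setdiff(1:40, which(xm[, "t11x"] == 1))]
                  == 1, na.rm = TRUE))
  # unmapped components warn and stay unconstrained
  w <- testthat::capture_warnings(
    postprocess_assignments(fit, pl$x, list()))
  expect_true(all(grepl("no class-defining entry", w)))
  expect_gt(length(w), 0)
})
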