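test_that("case matrix has the designed dimensions and preserved keys", {
  avg <- cache_get("dummy26", dummy_average_set(26))
  x <- build_case_matrix(avg, "placebo", "go")
  expect_equal(dim(x), c(988, 218)) # 26 x 2 x 19
  expect_equal(round(nrow(x) / ncol(x), 2), 4.53)
  keys <- attr(x, "keys")
  expect_equal(nrow(keys), 988)
  expect_equal(unname(table(keys$channel)["Cz"]), 52L)
  # single subject, single block
  avg1 <- dummy_average_set(1, blocks = 1)
  x1 <- build_case_matrix(avg1, "placebo", "go")
  expect_equal(nrow(x1), 19)
  # missing cell rejected
  avg2 <- dummy_average_set(2)
  avg2$counts[1, 1, "placebo", "go"] <- NA
  expect_error(build_case_matrix(avg2, "placebo", "go"), "missing cells")
  expect_error(build_case_matrix(avg, "tea", "go"), "no averages")
})

test_that("covariance PCA matches the closed-form 2x2 eigendecomposition", {
  # four centered cases whose sample covariance is [[2,1],[1,2]]
  a <- 1.5
  b <- sqrt(0.75)
  x <- rbind(c(a, a), c(-a, -a), c(b, -b), c(-b, b))
  expect_equal(crossprod(x) / 3, matrix(c(2, 1, 1, 2), 2), tolerance = 1e-12)
  p <- erp_pca(x, rotate = "none")
  expect_equal(p$eigenvalues, c(3, 1), tolerance = 1e-12)
  expect_equal(p$pct_variance, c(75, 25), tolerance = 1e-10)
})

test_that("rank-1 data loads on a single factor carrying all variance", {
  set.seed(8)
  x <- outer(rnorm(30), rnorm(12))
  p <- erp_pca(x, rotate = "none")
  expect_equal(p$pct_variance[1], 100, tolerance = 1e-8)
  expect_equal(ncol(p$loadings), 1) # epsilon guard drops null factors
})

test_that("keeping all factors reconstructs every case exactly", {
  set.seed(21)
  x <- matrix(rnorm(40 * 15), 40, 15) %*% diag(seq(0.2, 3, length.out = 15))
  for (rot in c("none", "varimax")) {
    p <- erp_pca(x, rotate = rot)
    expect_equal(fitted(p), x, tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(max(abs(residuals(p, x))), 0, tolerance = 1e-9)
  }
  # scores are standardized and uncorrelated
  p <- erp_pca(x)
  expect_equal(unname(apply(p$scores, 2, stats::sd)), rep(1, 15),
               tolerance = 1e-8)
})

test_that("varimax fixes simple structure and recovers a known 45-degree mixing", {
  mk <- make_mixed_loadings(45 * pi / 180)
  # already-simple loadings are a fixed point (up to sign/order)
  v0 <- varimax_kaiser(mk$true, kaiser = FALSE)
  agree <- abs(crossprod(v0$loadings, mk$true)) /
    sqrt(outer(colSums(v0$loadings^2), colSums(mk$true^2)))
  expect_equal(sort(apply(agree, 1, max)), c(1, 1), tolerance = 1e-6)
  # the mixed version is rotated back to the grid-search optimum
  v <- varimax_kaiser(mk$mixed, kaiser = FALSE)
  best_angle <- oracle_varimax_angle(mk$mixed)
  expect_equal(abs(best_angle - 45 * pi / 180) < 1e-3, TRUE)
  R <- matrix(c(cos(best_angle), -sin(best_angle),
                sin(best_angle), cos(best_angle)), 2, 2)
  expect_equal(varimax_criterion(v$loadings),
               varimax_criterion(mk$mixed %*% R), tolerance = 1e-6)
  cong <- abs(crossprod(v$loadings, mk$true)) /
    sqrt(outer(colSums(v$loadings^2), colSums(mk$true^2)))
  expect_true(all(apply(cong, 1, max) > 0.999))
})

test_that("rotation is orthonormal, criterion non-decreasing, invariants preserved", {
  set.seed(13)
  L <- matrix(rnorm(60 * 6), 60, 6) %*% diag(c(3, 2.5, 2, 1.5, 1, 0.5))
  v <- varimax_kaiser(L)
  expect_lt(max(abs(crossprod(v$rotmat) - diag(6))), 1e-8)
  expect_true(all(diff(v$criterion) > -1e-8))
  # communalities (row sums of squares) are rotation-invariant
  expect_equal(rowSums(v$loadings^2), rowSums(L^2), tolerance = 1e-8)
  # total retained variance preserved
  expect_equal(sum(v$loadings^2), sum(L^2), tolerance = 1e-8)
})

test_that("rotation agrees with the reference varimax implementation", {
  set.seed(99)
  L <- matrix(rnorm(80 * 5), 80, 5) %*% diag(c(3, 2, 1.5, 1, 0.8))
  mine <- varimax_kaiser(L, kaiser = TRUE)
  ref <- stats::varimax(L, normalize = TRUE, eps = 1e-7)
  sc <- sqrt(rowSums(L^2))
  expect_equal(varimax_criterion(mine$loadings / sc),
               varimax_criterion(unclass(ref$loadings) / sc),
               tolerance = 1e-6)
})

test_that("percent variances after rotation are consistent and ordered", {
  set.seed(3)
  x <- matrix(rnorm(60 * 10), 60, 10) %*% diag(seq(3, 0.5, length.out = 10))
  p0 <- erp_pca(x, rotate = "none")
  p1 <- erp_pca(x, rotate = "varimax")
  expect_equal(sum(p1$pct_variance), sum(p0$pct_variance), tolerance = 1e-8)
  expect_true(all(p1$pct_variance >= 0))
  expect_lte(sum(p1$pct_variance), 100 + 1e-8)
  expect_true(!is.unsorted(rev(p1$pct_variance)))
  # sign convention: every factor's peak loading is positive
  peaks <- apply(p1$loadings, 2, function(L) L[which.max(abs(L))])
  expect_true(all(peaks > 0))
  # peak latencies index the stored time axis correctly
  expect_equal(p1$peak_latency_ms,
               p1$times_ms[apply(abs(p1$loadings), 2, which.max)])
})

test_that("variance-floor selection follows the primary and fallback rules", {
  pct <- c(40, 20, 15, 6, 3, 2.5, 1.9, 1.4, 0.9, 0.5)
  p <- fake_pca(pct)
  p <- select_components(p, floor = 2, fallback = 1)
  expect_equal(which(p$selected), 1:6)
  # fallback: a caffeine factor matching a selected placebo label
  ref <- fake_pca(c(40, 3), labels = c("P3b", "PN"))
  ref$selected <- c(TRUE, TRUE)
  caff <- fake_pca(c(41, 1.4), labels = c("P3b", "PN"))
  caff <- select_components(caff, floor = 2, fallback = 1, reference = ref)
  expect_true(caff$selected[2]) # 1.4% > 1% fallback
  caff2 <- fake_pca(c(41, 0.9), labels = c("P3b", "PN"))
  caff2 <- select_components(caff2, floor = 2, fallback = 1, reference = ref)
  expect_false(caff2$selected[2]) # 0.9% below fallback
  expect_error(select_components(p, floor = 2, fallback = 2), "below")
})

test_that("component amplitude maps apply score x peak-loading", {
  times <- seq(-99.6, 750, length.out = 218)
  L <- matrix(0, 218, 1)
  L[100, 1] <- 3 # peak loading 3 uV
  keys <- data.frame(subject = "1", block = "1", channel = "Cz")
  p <- fake_pca(100, loadings = L, scores = matrix(2, 1, 1), keys = keys,
                peaks = times[100], times = times)
  colnames(p$loadings) <- "F1"
  m <- component_amplitude_map(p, 1)
  expect_equal(unname(m[1, 1]), 6) # 2.0 x 3.0
  p$scores[] <- 0
  expect_equal(unname(component_amplitude_map(p, 1)[1, 1]), 0)
  expect_error(component_amplitude_map(p, 1, channels = "Oz"), "absent")
  expect_error(component_amplitude_map(p, 5), "unknown factor")
})

test_that("labelling assigns schema names by latency window and topography", {
  res <- default_run()
  p <- res$pca$placebo_go
  expect_setequal(p$labels[p$selected],
                  c("N1-1", "PN", "P3a", "P3b", "SW2"))
  # planted peaks fall in their windows
  w <- default_label_windows()
  for (lb in p$labels[p$selected]) {
    j <- which(p$labels == lb)
    expect_true(p$peak_latency_ms[j] >= w[[lb]][1] &&
                  p$peak_latency_ms[j] <= w[[lb]][2])
  }
})

test_that("label competition: higher congruence wins, tie broken by variance", {
  times <- seq(-99.6, 750, length.out = 218)
  mont <- gonogo_montage()
  chs <- scalp_channels(mont)
  topo <- erpca:::topography_focus(mont, 0, 0.3, 0.8)
  shape <- -12 * exp(-((times - 100)^2) / (2 * 22^2))
  keys <- data.frame(subject = "1", block = "1", channel = chs)
  # two factors both peaking at 100 ms; factor 1 matches the N1-1 map
  # exactly, factor 2 is distorted
  L <- cbind(abs(shape), abs(shape))
  s1 <- -(topo - mean(topo))
  s2 <- -(rev(topo) - mean(topo))
  p <- fake_pca(c(10, 8), loadings = L, scores = cbind(s1, s2), keys = keys,
                peaks = c(100, 100), times = times)
  colnames(p$loadings) <- c("F1", "F2")
  p$selected <- c(TRUE, TRUE)
  tpl <- default_component_templates(mont)
  out <- label_components(p, tpl, which = "selected")
  expect_equal(out$labels[1], "N1-1")
  expect_false(out$labels[2] == "N1-1")
  # exact tie: identical maps, the higher-variance factor takes the label
  p2 <- fake_pca(c(4, 9), loadings = L, scores = cbind(s1, s1), keys = keys,
                 peaks = c(100, 100), times = times)
  colnames(p2$loadings) <- c("F1", "F2")
  p2$selected <- c(TRUE, TRUE)
  out2 <- label_components(p2, tpl, which = "selected")
  expect_equal(out2$labels[2], "N1-1")
  expect_equal(out2$labels[1], "unknown")
})

test_that("reconstitution is exact with all factors and centered with none", {
  res <- default_run()
  p <- res$pca$placebo_go
  cm <- build_case_matrix(res$averages, "placebo", "go")
  all_sel <- p
  all_sel$selected <- rep(TRUE, ncol(p$loadings))
  rc <- reconstitute(all_sel, cm, channels = c("Fz", "Cz", "Pz"))
  expect_equal(unname(rc$correlations), rep(1, 3), tolerance = 1e-8)
  none <- p
  none$selected <- rep(FALSE, ncol(p$loadings))
  rc0 <- reconstitute(none, cm, channels = "Cz")
  expect_equal(unname(rc0$reconstituted["Cz", ]), unname(p$center))
})

test_that("split-half decompositions agree at default SNR", {
  res <- default_run()
  avg <- res$averages
  cm <- build_case_matrix(avg, "placebo", "go")
  keys <- attr(cm, "keys")
  half1 <- as.numeric(keys$subject) <= 12
  mk <- function(rows) {
    x <- cm[rows, ]
    attr(x, "times_ms") <- attr(cm, "times_ms")
    x
  }
  p1 <- erp_pca(mk(half1))
  p2 <- erp_pca(mk(!half1))
  # each leading factor of one half has a counterpart in the other
  for (j in 1:5) {
    cc <- max(abs(apply(p2$loadings[, 1:8], 2, tucker_congruence,
                        a = p1$loadings[, j])))
    expect_gte(cc, 0.9)
  }
})
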