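tiny_set <- function(R, G, Rb = R * 0, Gb = G * 0) {
  structure(list(R = R, G = G, Rb = Rb, Gb = Gb,
                 probes = sprintf("p%d", seq_len(nrow(R))),
                 arrays = data.frame(array_id = sprintf("a%d", seq_len(ncol(R))))),
            class = "loop_array_set")
}

test_that("background correction subtracts with a floor of 0.5", {
  s <- tiny_set(R = matrix(c(100, 10), 2), G = matrix(c(60, 5), 2),
                Rb = matrix(c(20, 50), 2), Gb = matrix(c(0, 0), 2))
  bc <- background_correct(s)
  expect_equal(as.vector(bc$E_R), c(80, 0.5))
  expect_equal(as.vector(bc$E_G), c(60, 5))   # zero background = identity
  s$R[1] <- -1
  expect_error(background_correct(s), "negative")
})

test_that("loess normalization removes an injected intensity-dependent dye curve", {
  set.seed(5)
  A <- seq(6, 12, length.out = 2000)
  M <- rnorm(2000, 0, 0.08) + 0.4 * sin(A / 2) + 0.1 * (A - 9)  # curved dye effect
  s <- tiny_set(R = cbind(2^(A + M / 2)), G = cbind(2^(A - M / 2)))
  nw <- normalize_within_loess(background_correct(s))
  Mn <- nw$logR[, 1] - nw$logG[, 1]
  An <- (nw$logR[, 1] + nw$logG[, 1]) / 2
  dec <- cut(An, quantile(An, 0:10 / 10), include.lowest = TRUE)
  expect_true(all(abs(tapply(Mn, dec, mean)) < 0.02))
})

test_that("loess leaves centered null data nearly unchanged and absorbs constants", {
  set.seed(6)
  A <- seq(6, 12, length.out = 1500)
  M <- rnorm(1500, 0, 0.05)
  M <- M - mean(M)
  s <- tiny_set(R = cbind(2^(A + M / 2)), G = cbind(2^(A - M / 2)))
  nw <- normalize_within_loess(background_correct(s))
  expect_lt(max(abs((nw$logR[, 1] - nw$logG[, 1]) - M)), 0.05)

  s2 <- tiny_set(R = cbind(2^(A + (M + 0.5) / 2)), G = cbind(2^(A - (M + 0.5) / 2)))
  nw2 <- normalize_within_loess(background_correct(s2))
  expect_lt(abs(mean(nw2$logR[, 1] - nw2$logG[, 1])), 0.02)
})

test_that("loess normalization refuses tiny probe sets", {
  set <- simulate_loop_arrays(hyb_assignment(), n_probes = 40, seed = 1)
  expect_error(normalize_within_loess(background_correct(set)), "50")
})

test_that("quantile normalization equalizes distributions and is idempotent", {
  set.seed(41)
  x <- cbind(rnorm(500, 8), rnorm(500, 8) + 1)
  q <- normalize_between_quantile(x)
  expect_equal(sort(q[, 1]), sort(q[, 2]), tolerance = 1e-12)
  expect_equal(cor(rank(x[, 1]), rank(q[, 1])), 1)
  # idempotent
  expect_equal(normalize_between_quantile(q), q, tolerance = 1e-12)
  # random arrays: all pairwise sorted-vector gaps are zero
  y <- matrix(rnorm(500 * 4, 9), ncol = 4)
  qy <- normalize_between_quantile(y)
  srt <- apply(qy, 2, sort)
  expect_lt(max(apply(srt, 1, max) - apply(srt, 1, min)), 1e-12)
  expect_error(normalize_between_quantile(x[, 1, drop = FALSE]), "2 arrays")
})

test_that("the loop model recovers injected effects and the dye coefficient", {
  de <- list(P_vs_A = effect_vec(100, 1))
  set <- simulate_loop_arrays(hyb_assignment(), n_probes = 2000,
                              de_config = de, dye_bias = 0.5, seed = 7)
  # fit on background-corrected, un-loessed channels so the model's dye
  # coefficient (not the loess) absorbs the injected bias
  bc <- background_correct(set)
  bc$logR <- log2(bc$E_R); bc$logG <- log2(bc$E_G)
  fit <- fit_loop_model(bc)
  expect_lt(abs(mean(fit$dye_coef) - 0.5), 0.05)
  est <- fit$contrasts$P_vs_A$log2FC[1:100]
  expect_lt(abs(mean(est) - 1), 0.1)
  # loop consistency of truth: G_vs_A effect = G_vs_P + P_vs_A
  expect_equal(set$truth$effects$G_vs_A,
               set$truth$effects$G_vs_P + set$truth$effects$P_vs_A)
})

test_that("pure-null moderated p-values are calibrated", {
  nset <- normalized_loop_set(n_probes = 2000, seed = 8)
  fit <- fit_loop_model(nset)
  for (cn in names(fit$contrasts)) {
    fr <- mean(fit$contrasts[[cn]]$p_value < 0.05)
    expect_gte(fr, 0.02)
    expect_lte(fr, 0.08)
  }
})

test_that("swapping every array's channels flips every contrast estimate exactly", {
  nset <- normalized_loop_set(n_probes = 500,
                              de_config = list(G_vs_P = effect_vec(50, 0.8)),
                              dye_bias = 0.3, seed = 9)
  fit1 <- fit_loop_model(nset)
  swapped <- nset
  swapped$logR <- nset$logG
  swapped$logG <- nset$logR
  fit2 <- fit_loop_model(swapped)
  for (cn in names(fit1$contrasts))
    expect_equal(fit2$contrasts[[cn]]$log2FC,
                 -fit1$contrasts[[cn]]$log2FC, tolerance = 1e-12)
})

test_that("variance squeezing matches the independent limma oracle", {
  nset <- normalized_loop_set(n_probes = 1000, seed = 10)
  fit <- fit_loop_model(nset)
  M <- nset$logR - nset$logG
  X <- cbind(as.numeric(nset$arrays$red_stage == "plateau") -
               as.numeric(nset$arrays$green_stage == "plateau"),
             as.numeric(nset$arrays$red_stage == "atretic") -
               as.numeric(nset$arrays$green_stage == "atretic"),
             1)
  # limma warns about the zero-variance probes it offsets; expected here
  lf <- suppressWarnings(
    limma::eBayes(limma::contrasts.fit(limma::lmFit(M, X),
                                       cbind(PA = c(-1, 1, 0)))))
  expect_equal(fit$d0, lf$df.prior, tolerance = 1e-6)
  expect_equal(fit$s0_2, lf$s2.prior, tolerance = 1e-6)
  expect_equal(fit$contrasts$P_vs_A$log2FC, unname(lf$coefficients[, 1]),
               tolerance = 1e-9)
  expect_equal(fit$contrasts$P_vs_A$p_value, unname(lf$p.value[, 1]),
               tolerance = 1e-9)
})

test_that("posterior variances interpolate between observed and prior", {
  set.seed(12)
  s2 <- 0.05 * rchisq(500, 8) / 8 * exp(rnorm(500, 0, 0.5))
  sq <- squeeze_variances(s2, 8)
  expect_true(is.finite(sq$d0) && sq$d0 > 0)
  between <- (sq$s2_post >= pmin(s2, sq$s0_2) - 1e-12) &
    (sq$s2_post <= pmax(s2, sq$s0_2) + 1e-12)
  expect_true(all(between))
  # d0 -> 0 leaves observed variances; d0 -> Inf collapses to the prior
  expect_equal((0 * sq$s0_2 + 8 * s2) / (0 + 8), s2)
  # homogeneous variances drive the prior df estimate up
  s2h <- 0.05 * rchisq(500, 8) / 8
  expect_gt(squeeze_variances(s2h, 8)$d0, sq$d0)
})

test_that("detection power rises monotonically with effect size", {
  power <- vapply(c(0.1, 0.5, 1.5), function(eff) {
    nset <- normalized_loop_set(n_probes = 1000,
                                de_config = list(G_vs_P = effect_vec(80, eff)),
                                seed = 13)
    fit <- fit_loop_model(nset)
    mean(fit$contrasts$G_vs_P$p_value[1:80] < 0.05)
  }, numeric(1))
  expect_true(all(diff(power) >= 0))
  expect_gt(power[3], power[1])
})

test_that("DEG selection applies strict fold-change/p rules and inclusive intensity", {
  res <- data.frame(probe = c("a", "b", "c", "d", "e"),
                    log2FC = c(log2(1.6), log2(1.5), -log2(1.7), log2(2), log2(1.8)),
                    A = c(8, 9, 9, 6.9, 7),
                    p_value = c(0.01, 0.001, 0.001, 0.01, 0.06))
  out <- select_degs(res, deg_criteria())
  expect_equal(out$probe, c("a", "c"))
  expect_equal(out$direction, c("up", "down"))
  expect_true("fdr" %in% names(out))
})

test_that("cross-contrast partition matches set arithmetic and a brute-force oracle", {
  gp <- data.frame(probe = c("a", "b", "c"), direction = c("up", "up", "up"))
  pa <- data.frame(probe = c("b", "c", "d"), direction = c("up", "up", "down"))
  part <- partition_contrasts(gp, pa)
  expect_equal(sort(part$table$probe[part$table$category == "continuous"]),
               c("b", "c"))
  expect_equal(part$counts$specific_G_vs_P, 1)
  expect_equal(part$counts$specific_P_vs_A, 1)
  # disjoint tables share nothing
  part2 <- partition_contrasts(data.frame(probe = "x", direction = "up"),
                               data.frame(probe = "y", direction = "down"))
  expect_equal(part2$counts$shared, 0)
  expect_error(partition_contrasts(
    data.frame(probe = c("x", "x"), direction = c("up", "up")), pa),
    "duplicate")

  # brute-force oracle: classify every gene by direct per-gene enumeration
  set.seed(14)
  for (rep in 1:10) {
    genes <- sample(letters, 12)
    g1 <- sort(sample(genes, 6)); g2 <- sort(sample(genes, 6))
    t1 <- data.frame(probe = g1, direction = sample(c("up", "down"), 6, TRUE))
    t2 <- data.frame(probe = g2, direction = sample(c("up", "down"), 6, TRUE))
    part <- partition_contrasts(t1, t2)
    oracle <- sapply(union(g1, g2), function(g) {
      in1 <- g %in% g1; in2 <- g %in% g2
      if (in1 && in2) {
        if (t1$direction[t1$probe == g] == t2$direction[t2$probe == g])
          "continuous" else "reversal"
      } else if (in1) "specific_G_vs_P" else "specific_P_vs_A"
    })
    got <- setNames(part$table$category, part$table$probe)
    expect_equal(got[names(oracle)], oracle)
    expect_equal(part$counts$specific_G_vs_P + part$counts$shared,
                 part$counts$total_G_vs_P)
  }
})
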