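test_that("noiseless ideal dilution series gives 100% efficiency and exact Cq spacing", {
  genes <- default_qpcr_genes()[1, ]
  genes$slope <- -log2(10) / log2(2)   # -3.321928, the 100%-efficiency slope
  sim <- simulate_qpcr(stage7(2), genes = genes, cq_sd = 0, seed = 1)
  expect_equal(diff(sim$standards$Cq), rep(log2(10) / log2(2) * 1, 4),
               tolerance = 1e-9)
  curve <- fit_standard_curve(sim$standards)
  expect_equal(curve$efficiency, 1, tolerance = 1e-9)
  expect_equal(curve$r2, 1, tolerance = 1e-9)
})

test_that("default dilution series has five decade-spaced points per gene", {
  sim <- simulate_qpcr(stage7(2), seed = 2)
  per_gene <- table(sim$standards$gene)
  expect_true(all(per_gene == 5))
  expect_equal(sort(unique(sim$standards$input_ng)), 10^-(8:4))
  curve <- fit_standard_curve(sim$standards[sim$standards$gene == "VNN1", ])
  expect_equal(curve$n_points, 5)
})

test_that("standard-curve slope is recovered under noise", {
  genes <- default_qpcr_genes()[3, ]
  genes$slope <- -3.5
  sim <- simulate_qpcr(stage7(2), genes = genes, cq_sd = 0.1, seed = 3)
  curve <- fit_standard_curve(sim$standards)
  expect_lt(abs(curve$slope - (-3.5)), 0.1)
})

test_that("curve fitting rejects malformed input", {
  expect_error(fit_standard_curve(data.frame(input_ng = c(1e-4, 1e-5),
                                             Cq = c(20, 23))), "3 dilution")
  expect_error(fit_standard_curve(data.frame(input_ng = c(1e-4, 1e-6, 1e-5),
                                             Cq = c(20, 26, 23))), "monotone")
  expect_error(fit_standard_curve(data.frame(input_ng = 10^-(4:8),
                                             Cq = c(20, 18, 16, 14, 12))),
               "positive")
  expect_error(simulate_qpcr(stage7(2), dilution_ng = c(1e-4, 1e-6, 1e-5)),
               "monotone")
})

test_that("quantification inverts the curve and propagates missing wells", {
  curve <- structure(list(gene = "X", slope = -3.4, intercept = 18,
                          efficiency = 10^(1 / 3.4) - 1, r2 = 1, n_points = 5),
                     class = "standard_curve")
  panel <- data.frame(gene = "X", sample = c("s1", "s2", "s3"),
                      Cq = c(18, 18 + 3.4 * 4, NA))
  q <- quantify(panel, list(X = curve))
  expect_equal(q$quantity[1], 1)
  expect_equal(q$quantity[2], 1e-4, tolerance = 1e-9)
  expect_true(is.na(q$quantity[3]))
  expect_error(quantify(data.frame(gene = "Y", sample = "s", Cq = 20),
                        list(X = curve)), "no standard curve")
})

test_that("geNORM factor is the geometric mean of reference quantities", {
  panel <- data.frame(
    gene = rep(c("EIF2B2", "SF3A1", "T1"), 2),
    sample = rep(c("s1", "s2"), each = 3),
    quantity = c(4, 9, 10, 2, 8, 10))
  out <- genorm_normalize(panel)
  expect_equal(unname(out$factors["s1"]), 6)
  expect_equal(unname(out$factors["s2"]), 4)
  expect_equal(out$panel$normalized_quantity[out$panel$gene == "T1"],
               c(10 / 6, 10 / 4))
})

test_that("geNORM is invariant to constant references and global sample scaling", {
  set.seed(61)
  samples <- paste0("s", 1:6)
  panel <- expand.grid(gene = c("EIF2B2", "SF3A1", "T1", "T2"),
                       sample = samples, stringsAsFactors = FALSE)
  panel$quantity <- runif(nrow(panel), 1, 5)
  panel$quantity[panel$gene %in% c("EIF2B2", "SF3A1")] <- 3  # constant refs
  out <- genorm_normalize(panel)
  t1 <- out$panel$normalized_quantity[out$panel$gene == "T1"]
  raw <- panel$quantity[panel$gene == "T1"]
  expect_equal(t1, raw / 3)
  expect_equal(t1[1] / t1[2], raw[1] / raw[2])

  # multiply everything in one sample by 10: normalized targets unchanged
  panel2 <- panel
  panel2$quantity[panel2$sample == "s3"] <- panel2$quantity[panel2$sample == "s3"] * 10
  out2 <- genorm_normalize(panel2)
  expect_equal(out2$panel$normalized_quantity[out2$panel$gene == "T1"], t1,
               tolerance = 1e-12)

  panel$quantity[panel$gene == "SF3A1" & panel$sample == "s2"] <- NA
  expect_error(genorm_normalize(panel), "s2")
})

test_that("homogeneous marker panels raise no contamination flags", {
  n_sig <- 0
  for (s in 1:20) {
    sim <- simulate_qpcr(stage7(7), seed = s)
    q <- quantify(sim$panel, lapply(split(sim$standards, sim$standards$gene),
                                    fit_standard_curve))
    qc <- contamination_qc(q, "CYP17A1", value_col = "quantity")
    expect_equal(nrow(qc$flagged), 0)
    if (is.finite(qc$bartlett_p) && qc$bartlett_p < 0.05) n_sig <- n_sig + 1
  }
  expect_lte(n_sig, 4)  # Bartlett keeps near-nominal size under the null
})

test_that("a strongly contaminated sample is flagged by leave-one-out Bartlett", {
  sim <- simulate_qpcr(stage7(7), contaminated_sample = "A2",
                       contamination_factor = 100, seed = 7)
  q <- quantify(sim$panel, lapply(split(sim$standards, sim$standards$gene),
                                  fit_standard_curve))
  qc <- contamination_qc(q, "CYP17A1", value_col = "quantity")
  expect_lt(qc$bartlett_p, 0.05)
  expect_equal(qc$flagged$sample, "A2")
})

test_that("degenerate constant groups are handled without flags", {
  panel <- data.frame(gene = "CYP17A1",
                      sample = paste0("s", 1:12),
                      stage = rep(c("growing", "plateau", "atretic"), each = 4),
                      quantity = 2)
  qc <- contamination_qc(panel, "CYP17A1", value_col = "quantity")
  expect_equal(nrow(qc$flagged), 0)
  expect_true(is.na(qc$bartlett_p))
})

test_that("the variance transform maps 1e-12 to zero and is applied iff Bartlett rejects", {
  expect_equal(follistage:::log_variance_transform(1e-12), 0)
  set.seed(62)
  # heteroscedastic gene: variances scale with the mean
  panel <- data.frame(
    gene = "T1", sample = paste0("s", 1:21),
    stage = rep(c("growing", "plateau", "atretic"), each = 7),
    normalized_quantity = c(rlnorm(7, log(1e-7), 0.1), rlnorm(7, log(1e-6), 0.4),
                            rlnorm(7, log(1e-5), 0.9)))
  st <- stage_stats(panel)
  expect_lt(st$bartlett_p_raw, 0.05)
  expect_true(st$transform_applied)
  expect_true(is.finite(st$bartlett_p_used))
  # homoscedastic gene: no transform, pre == post
  panel$normalized_quantity <- rlnorm(21, log(1e-6), 0.3)
  st2 <- stage_stats(panel)
  if (st2$bartlett_p_raw >= 0.05) {
    expect_false(st2$transform_applied)
    expect_equal(st2$bartlett_p_used, st2$bartlett_p_raw)
  }
})

test_that("null panels rarely show a linear trend", {
  n_ns <- 0
  for (s in 1:200) {
    set.seed(1000 + s)
    panel <- data.frame(
      gene = "T1", sample = paste0("s", 1:21),
      stage = rep(c("growing", "plateau", "atretic"), each = 7),
      normalized_quantity = rlnorm(21, log(1e-6), 0.3))
    st <- stage_stats(panel)
    if (is.na(st$trend_p) || st$trend_p >= 0.05) n_ns <- n_ns + 1
  }
  expect_gte(n_ns, 180)  # trend stays non-significant in >= 90% of null panels
})

test_that("monotone separated means give a significant trend and distinct letters", {
  set.seed(63)
  panel <- data.frame(
    gene = "T1", sample = paste0("s", 1:21),
    stage = rep(c("growing", "plateau", "atretic"), each = 7),
    normalized_quantity = rep(c(1, 2, 3), each = 7) * exp(rnorm(21, 0, 0.05)))
  st <- stage_stats(panel)
  expect_lt(st$trend_p, 0.05)
  expect_lt(st$anova_p, 0.001)
  lt <- strsplit(gsub(".*=|;", " ", st$letters), " +")[[1]]
  lt <- unlist(regmatches(st$letters, gregexpr("(?<==)[a-z]+", st$letters, perl = TRUE)))
  expect_equal(length(unique(lt)), 3)
  # cross-check against all-pairs Welch comparisons: all pairs significant
  y <- panel$normalized_quantity; g <- panel$stage
  for (pair in list(c("growing", "plateau"), c("plateau", "atretic"),
                    c("growing", "atretic")))
    expect_lt(t.test(y[g == pair[1]], y[g == pair[2]])$p.value, 0.05)
})

test_that("Newman-Keuls never separates groups when ANOVA and all pairwise t agree on null", {
  set.seed(64)
  checked <- 0
  for (s in 1:30) {
    y <- rnorm(21, 5, 1)
    g <- rep(c("growing", "plateau", "atretic"), each = 7)
    pw <- c(t.test(y[g == "growing"], y[g == "plateau"])$p.value,
            t.test(y[g == "plateau"], y[g == "atretic"])$p.value,
            t.test(y[g == "growing"], y[g == "atretic"])$p.value)
    an <- summary(aov(y ~ factor(g)))[[1]][["Pr(>F)"]][1]
    if (an < 0.05 || any(pw < 0.05)) next
    checked <- checked + 1
    panel <- data.frame(gene = "T1", sample = paste0("s", 1:21), stage = g,
                        normalized_quantity = exp(y) * 1e-7)
    st <- stage_stats(panel)
    lt <- unlist(regmatches(st$letters, gregexpr("(?<==)[a-z]+", st$letters,
                                                 perl = TRUE)))
    expect_equal(length(unique(lt)), 1)
  }
  expect_gte(checked, 10)
})

test_that("one-tailed p is half the two-tailed p when the direction matches", {
  set.seed(65)
  panel <- data.frame(
    gene = "T1", sample = paste0("s", 1:14),
    stage = rep(c("growing", "plateau"), each = 7),
    normalized_quantity = c(rlnorm(7, 0, 0.2), rlnorm(7, 0.8, 0.2)))
  st <- stage_stats(panel, stage_levels = c("growing", "plateau", "atretic"),
                    directions = list(T1 = c(G_vs_P = 1)))
  y <- panel$normalized_quantity
  two <- t.test(y[8:14], y[1:7])$p.value
  expect_equal(st$p_G_vs_P, two / 2, tolerance = 1e-9)
})

test_that("undetected wells are excluded pairwise and counted per stage", {
  set.seed(66)
  panel <- data.frame(
    gene = "RELN", sample = paste0("s", 1:21),
    stage = rep(c("growing", "plateau", "atretic"), each = 7),
    normalized_quantity = rlnorm(21, log(1e-6), 0.3))
  panel$normalized_quantity[c(1, 2, 3, 4)] <- NA  # undetected in growing
  st <- stage_stats(panel)
  expect_match(st$detection, "growing:3/7")
  expect_match(st$detection, "plateau:7/7")
  expect_false(st$untestable)
  # zero-variance gene reported untestable, not an exception
  panel$normalized_quantity <- 1e-6
  st2 <- stage_stats(panel)
  expect_true(st2$untestable)
})
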