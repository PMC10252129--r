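test_that("TMM factors are unity for depth-only differences", {
  set.seed(1)
  one <- rpois(50, 60) + 1L
  base <- matrix(one, 50, 4,
                 dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:4)))
  expect_equal(unname(tmm_factors(base, trim_m = 0.3, trim_a = 0.05)),
               rep(1, 4), tolerance = 1e-12)
  # doubling every count in one sample is absorbed by library-size scaling
  doubled <- cbind(s1 = base[, 1], s2 = 2L * base[, 1])
  expect_equal(unname(tmm_factors(doubled)), c(1, 1), tolerance = 1e-12)
})

test_that("TMM matches the brute-force trimmed-mean oracle on a toy matrix", {
  # 8 genes, 2 samples, one strongly up-shifted gene in sample 2
  counts <- matrix(c(100, 200, 300, 400, 500, 600, 700, 800,
                     110, 190, 310, 390, 510, 590, 710, 4000),
                   nrow = 8,
                   dimnames = list(paste0("g", 1:8), c("a", "b")))
  f <- tmm_factors(counts, trim_m = 0.25, trim_a = 0)
  # sample "a" is the reference (closest 75th-percentile fraction to mean)
  oracle <- oracle_tmm_factor(counts[, "b"], counts[, "a"],
                              trim_m = 0.25, trim_a = 0)
  # geometric-mean rescaling spreads the pair factor across both samples
  expect_equal(unname(f["b"] / f["a"]), oracle, tolerance = 1e-10)
  expect_equal(prod(f), 1, tolerance = 1e-12)
})

test_that("TMM agrees with edgeR's implementation", {
  skip_if_not_installed("edgeR")
  set.seed(42)
  counts <- matrix(rnbinom(300 * 6, mu = 100, size = 5), 300, 6,
                   dimnames = list(sprintf("g%03d", 1:300), paste0("s", 1:6)))
  counts[1:30, 4:6] <- counts[1:30, 4:6] * 4L
  ours <- tmm_factors(counts)
  theirs <- edgeR::calcNormFactors(counts, method = "TMM")
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-8)
})

test_that("TMM factors always have geometric mean one", {
  for (s in 1:5) {
    set.seed(s)
    counts <- matrix(rnbinom(100 * 5, mu = 50, size = 2), 100, 5)
    rownames(counts) <- sprintf("g%03d", 1:100)
    f <- tmm_factors(counts)
    expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
    expect_true(all(f > 0))
  }
})

test_that("TMM rejects zero library sizes", {
  counts <- cbind(a = c(0L, 0L), b = c(5L, 5L))
  rownames(counts) <- c("g1", "g2")
  expect_error(tmm_factors(counts), "positive library size")
})

test_that("log-CPM follows its closed form and is monotone", {
  counts <- matrix(c(0, 10, 100, 0, 20, 100), 3, 2,
                   dimnames = list(c("g1", "g2", "g3"), c("a", "b")))
  lib <- colSums(counts)
  lc <- log_cpm(counts, factors = c(1, 1), prior_count = 0.5)
  expect_equal(lc["g1", "a"], log2(0.5 / lib[1] * 1e6), ignore_attr = TRUE)
  # hand oracle at count 0, library 1e6, factor 1: log2(0.5) = -1
  one_m <- matrix(c(0, 999990, 10), 3, 1,
                  dimnames = list(c("z", "big", "ten"), "s"))
  expect_equal(log_cpm(one_m, 1, 0.5)["z", "s"], log2(0.5), tolerance = 1e-12)
  # monotone in the count
  bumped <- counts; bumped["g2", "a"] <- 20
  expect_gt(log_cpm(bumped, c(1, 1))["g2", "a"], lc["g2", "a"])
  # equal counts and factors give identical columns
  eq <- matrix(c(5, 7, 5, 7), 2, 2, dimnames = list(c("g1", "g2"), c("a", "b")))
  lceq <- log_cpm(eq, c(1, 1))
  expect_identical(lceq[, 1], lceq[, 2], ignore_attr = TRUE)
})

test_that("unpaired fit reproduces the textbook two-sample t-test", {
  ctrl <- c(1, 2, 3, 4, 5); case <- c(3, 4, 5, 6, 7)
  m <- rbind(gene1 = c(ctrl, case),
             flat = rep(4, 10))
  colnames(m) <- paste0("s", 1:10)
  st <- expression_study(m, rep(c("control", "case"), each = 5), "toy")
  expect_warning(res <- fit_dge(st, moderated = FALSE), "zero residual")
  expect_equal(res$log2fc[res$gene == "gene1"], 2.0)
  # textbook pooled-variance oracle
  sp2 <- (sum((ctrl - mean(ctrl))^2) + sum((case - mean(case))^2)) / 8
  t_oracle <- (mean(case) - mean(ctrl)) / sqrt(sp2 * (1 / 5 + 1 / 5))
  p_oracle <- 2 * pt(-abs(t_oracle), df = 8)
  expect_equal(res$t[res$gene == "gene1"], t_oracle, tolerance = 1e-12)
  expect_equal(res$p[res$gene == "gene1"], p_oracle, tolerance = 1e-12)
  expect_equal(res$df[res$gene == "gene1"], 8)
  # gene identical in both groups: fc 0, t 0, p 1
  expect_equal(res$log2fc[res$gene == "flat"], 0)
  expect_equal(res$t[res$gene == "flat"], 0)
  expect_equal(res$p[res$gene == "flat"], 1)
})

test_that("unpaired log2FC is antisymmetric under group-label swap", {
  st <- make_array_study(n_genes = 30, effect = 1, de_genes = 1:10, seed = 5)
  swapped <- st
  swapped$samples$group <- ifelse(st$samples$group == "case", "control",
                                  "case")
  a <- fit_dge(st, moderated = FALSE)
  b <- fit_dge(swapped, moderated = FALSE)
  expect_equal(a$log2fc, -b$log2fc)
  expect_equal(a$p, b$p)
})

test_that("paired fit models within-pair differences", {
  set.seed(2)
  n_pairs <- 8
  pid <- rep(sprintf("p%d", 1:n_pairs), 2)
  grp <- rep(c("control", "case"), each = n_pairs)
  subject <- rnorm(n_pairs, 8, 2)  # strong subject effect
  m <- rbind(g1 = c(subject, subject + 1 + rnorm(n_pairs, 0, 0.1)),
             g2 = c(subject, subject + rnorm(n_pairs, 0, 0.1)))
  colnames(m) <- paste0("s", 1:(2 * n_pairs))
  st <- expression_study(m, grp, "paired_toy", pair_id = pid)
  res <- fit_dge(st, paired = TRUE, moderated = FALSE)
  # oracle: one-sample t on the differences
  d <- m["g1", grp == "case"] - m["g1", grp == "control"]
  t_or <- mean(d) / (sd(d) / sqrt(n_pairs))
  expect_equal(res$log2fc[1], mean(d))
  expect_equal(res$t[1], t_or, tolerance = 1e-12)
  expect_equal(unique(res$df), n_pairs - 1)
  # unpaired analysis of the same data is far less powerful here
  res_un <- fit_dge(st, paired = FALSE, moderated = FALSE)
  expect_lt(res$p[1], res_un$p[1])
  # mismatched pairs rejected
  st_bad <- st
  st_bad$samples$pair_id[1] <- "p2"
  expect_error(fit_dge(st_bad, paired = TRUE), "exactly one case")
})

test_that("variance moderation limits behave as designed", {
  st <- make_array_study(n_genes = 60, effect = 0.8, de_genes = 1:10,
                         seed = 7)
  plain <- fit_dge(st, moderated = FALSE)
  # d0 = 0: moderated equals ordinary exactly
  d0zero <- fit_dge(st, moderated = TRUE, d0 = 0, s0_2 = 1)
  expect_equal(d0zero$t, plain$t, tolerance = 1e-12)
  expect_equal(d0zero$p, plain$p, tolerance = 1e-12)
  # d0 = Inf: all variances equal the prior, t ordering = log2FC ordering
  dinf <- fit_dge(st, moderated = TRUE, d0 = Inf, s0_2 = 0.25)
  expect_equal(order(dinf$t), order(dinf$log2fc))
  expect_equal(unique(round(dinf$se, 12)),
               round(sqrt(0.25 * (1 / 6 + 1 / 6)), 12))
})

test_that("moment-based variance moderation agrees with limma", {
  skip_if_not_installed("limma")
  set.seed(9)
  df <- 10
  s2 <- 0.3 * rchisq(500, df) / df * rlnorm(500, 0, 0.5)
  sq <- squeeze_variances(s2, df)
  lf <- limma::squeezeVar(s2, df)
  expect_equal(sq$d0, lf$df.prior, tolerance = 1e-6)
  expect_equal(sq$s0_2, lf$var.prior, tolerance = 1e-6)
  expect_equal(sq$s2_post, lf$var.post, tolerance = 1e-6)
})

test_that("BH adjustment matches the step-down enumeration oracle", {
  expect_equal(bh_adjust(c(0.005, 0.5)), c(0.01, 0.5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "finite")
  set.seed(3)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
  # monotone: ordering of adjusted values never contradicts the p ordering
  p <- runif(100)
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15))
})

test_that("per-study p-values are uniform under the null simulation", {
  cfg <- simulation_config(n_studies = 2, n_genes = 1500, de_fraction = 0,
                           tau = 0, coverage_fraction = 1,
                           sample_sizes = data.frame(n_control = c(20, 15),
                                                     n_case = c(20, 15)),
                           platform_mix = c("array", "array"), seed = 19)
  sim <- simulate_multistudy(cfg)
  res <- fit_dge(normalize_study(sim$studies[[1]]))
  expect_gt(ks.test(res$p, "punif")$p.value, 0.01)
})

test_that("normalize_study handles raw counts and linear-scale arrays", {
  cfg <- simulation_config(
    n_studies = 1, n_genes = 100, de_fraction = 0, coverage_fraction = 1,
    sample_sizes = data.frame(n_control = 5, n_case = 5),
    platform_mix = "rnaseq", seed = 6)
  sim <- simulate_multistudy(cfg)
  norm <- normalize_study(sim$studies[[1]])
  expect_identical(norm$normalization_state, "normalized_log2")
  expect_lt(max(norm$matrix), 30)
  expect_error(fit_dge(sim$studies[[1]]), "log2")
  # linear-scale array triggers the log2(x + 1) heuristic
  m <- matrix(2^rnorm(200, 8), 20, 10,
              dimnames = list(sprintf("g%d", 1:20), sprintf("s%d", 1:10)))
  st <- expression_study(m, rep(c("control", "case"), each = 5), "lin")
  expect_message(norm2 <- normalize_study(st), "log2")
  expect_equal(norm2$matrix, log2(m + 1))
})
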