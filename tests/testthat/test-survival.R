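test_that("z-scoring standardizes rows and drops degenerate genes", {
  set.seed(1)
  m <- matrix(rnorm(50, 5, 2), 5, 10,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
  z <- zscore_matrix(m)
  expect_equal(unname(rowMeans(z)), rep(0, 5), tolerance = 1e-9)
  expect_equal(unname(apply(z, 1, sd)), rep(1, 5), tolerance = 1e-9)
  expect_equal(unname(zscore_matrix(rbind(a = c(1, 2, 3),
                                          b = c(5, 1, 3)))["a", ]),
               c(-1, 0, 1))
  m2 <- rbind(m, flat = rep(3, 10))
  expect_warning(z2 <- zscore_matrix(m2), "1 zero-variance")
  expect_false("flat" %in% rownames(z2))
  expect_error(zscore_matrix(rbind(flat = rep(1, 4))), "zero variance")
})

test_that("quartile groups use strict inequalities on interpolated quartiles", {
  v <- setNames(1:8, paste0("s", 1:8))
  qg <- quartile_groups(v)
  expect_identical(qg$low, c("s1", "s2"))
  expect_identical(qg$high, c("s7", "s8"))
  # 180 distinct values: the 45 / 45 split of the gene-wise cohort screen
  v180 <- setNames(sample(seq_len(180)), sprintf("p%03d", 1:180))
  qg180 <- quartile_groups(v180)
  expect_length(qg180$low, 45)
  expect_length(qg180$high, 45)
  # degenerate distribution: all mass at the quartiles
  expect_error(quartile_groups(setNames(rep(2, 10), paste0("s", 1:10)),
                               label = "GENE7"), "GENE7")
  expect_error(quartile_groups(1:5), "at least 8")
})

test_that("Kaplan-Meier matches hand product-limit fixtures", {
  # 4 deaths at distinct times, no censoring
  km <- km_estimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$survival, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$n_risk, c(4, 3, 2, 1))
  # censoring between events: S = 0.75 after t=1, 0.375 after t=3, 0 at t=4
  km2 <- km_estimate(c(1, 2, 3, 4), c(1, 0, 1, 1))
  expect_equal(km2$survival[km2$time == 1], 0.75)
  expect_equal(km2$survival[km2$time == 3], 0.375)
  expect_equal(km2$survival[km2$time == 4], 0)
  # all censored: S identically 1
  km3 <- km_estimate(c(2, 5, 7), c(0, 0, 0))
  expect_true(all(km3$survival == 1))
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "non-negative")
  # random fixture against the hand oracle; no censoring means the KM curve
  # is the empirical survival function
  set.seed(6)
  tm <- round(rexp(30, 0.1), 2); ev <- rbinom(30, 1, 0.7)
  got <- km_estimate(tm, ev)
  want <- oracle_km(tm, ev)
  expect_equal(got$survival, want$survival, tolerance = 1e-12)
  tm2 <- rexp(25, 0.1)
  km4 <- km_estimate(tm2, rep(1, 25))
  ecdf_surv <- vapply(km4$time, function(t) mean(tm2 > t), numeric(1))
  expect_equal(km4$survival, ecdf_surv, tolerance = 1e-12)
})

test_that("log-rank matches the risk-table enumeration oracle", {
  tm <- c(2.1, 4.3, 6.2, 8.5, 10.4, 12.9, 1.2, 1.9, 3.4, 5.1, 6.8, 9.3)
  ev <- rep(1, 12)
  grp <- rep(c("a", "b"), each = 6)
  got <- logrank_test(tm, ev, grp)
  want <- oracle_logrank(tm, ev, grp)
  expect_equal(got$statistic, want$statistic, tolerance = 1e-9)
  expect_equal(got$p, want$p, tolerance = 1e-9)
  # identical groups: statistic 0, p 1
  same <- logrank_test(rep(c(1, 2, 3), 2), rep(1, 6), rep(c("a", "b"), 3))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)
  # symmetry in group order and invariance under common time rescaling
  flip <- logrank_test(tm, ev, rev(grp))
  expect_equal(got$statistic,
               logrank_test(tm * 7, ev, grp)$statistic, tolerance = 1e-12)
  expect_equal(got$statistic,
               logrank_test(tm, ev, ifelse(grp == "a", "b", "a"))$statistic)
  expect_error(logrank_test(tm, rep(0, 12), grp), "zero events")
  expect_error(logrank_test(tm, ev, rep("a", 12)), "two non-empty")
})

test_that("log-rank p agrees with a censored-fixture oracle too", {
  tm <- c(3.2, 5.1, 8.4, 9.9, 12.3, 2.2, 4.4, 6.1, 7.7, 11.5)
  ev <- c(1, 0, 1, 1, 0, 1, 1, 0, 1, 1)
  grp <- rep(c("a", "b"), each = 5)
  got <- logrank_test(tm, ev, grp)
  want <- oracle_logrank(tm, ev, grp)
  expect_equal(got$statistic, want$statistic, tolerance = 1e-9)
})

test_that("signature scoring implements the count/median-cutoff rule", {
  set.seed(10)
  n <- 40
  z <- rbind(matrix(rnorm(5 * n), 5, n,
                    dimnames = list(paste0("sig", 1:5), sprintf("s%02d", 1:n))),
             matrix(rnorm(2 * n), 2, n,
                    dimnames = list(c("other1", "other2"), sprintf("s%02d", 1:n))))
  coh <- survival_cohort(rexp(n, 0.05) + 0.01, rbinom(n, 1, 0.8), z)
  expect_warning(res <- signature_score(coh, c(paste0("sig", 1:5), "ghost")),
                 "ghost")
  expect_identical(res$genes, paste0("sig", 1:5))
  # indicator: strict upper-quartile exceedance per gene
  q3 <- apply(z[paste0("sig", 1:5), ], 1, quantile, 0.75, names = FALSE)
  expect_equal(unname(res$indicator), unname((z[paste0("sig", 1:5), ] > q3) * 1L))
  expect_equal(res$counts, colSums(res$indicator))
  expect_equal(res$cutoff, median(res$counts))
  # risk rule: count >= cutoff is high risk
  expect_identical(unname(res$risk),
                   unname(ifelse(res$counts >= res$cutoff, "high", "low")))
  # a sample above Q3 for every gene has the maximum count and is high risk
  top <- which.max(res$counts)
  expect_identical(unname(res$risk[top]), "high")
  expect_error(suppressWarnings(signature_score(coh, "ghost")),
               "no signature gene")
})

test_that("risk labels at the published cutoffs follow count >= median", {
  # cutoff 6: counts (6, 5) -> (high, low); cutoff 3: count 3 -> high
  risk_at <- function(counts, cutoff) ifelse(counts >= cutoff, "high", "low")
  expect_identical(risk_at(c(6, 5), 6), c("high", "low"))
  expect_identical(risk_at(3, 3), "high")
})

test_that("signature risk labels are invariant to gene order and monotone z", {
  sim <- simulate_survival_cohort(n_samples = 60, signature_size = 6,
                                  n_noise_genes = 10, seed = 14)
  coh <- sim$cohort
  base <- signature_score(coh, sim$truth$signature)
  shuf <- signature_score(coh, rev(sim$truth$signature))
  expect_identical(base$risk[names(shuf$risk)], shuf$risk)
  # monotone per-gene transform of z leaves the quartile indicators alone
  coh2 <- coh
  coh2$z <- coh$z^3
  trans <- signature_score(coh2, sim$truth$signature)
  expect_identical(base$risk, trans$risk)
})

test_that("high-count group has worse survival on hazard-linked cohorts", {
  sim <- simulate_survival_cohort(n_samples = 240, signature_size = 10,
                                  hazard_ratio = 2.2, seed = 20)
  res <- signature_score(sim$cohort, sim$truth$signature)
  expect_lt(res$logrank$p, 0.01)
  med_surv <- function(km) km$time[which(km$survival <= 0.5)[1]]
  expect_lt(med_surv(res$km$high), med_surv(res$km$low))
})

test_that("co-occurrence grouping recovers block structure", {
  # two disjoint perfect blocks
  ind <- rbind(matrix(rep(c(1, 0), c(6, 6)), 3, 12, byrow = TRUE),
               matrix(rep(c(0, 1), c(6, 6)), 3, 12, byrow = TRUE))
  rownames(ind) <- paste0("g", 1:6)
  res <- cooccurrence_groups(ind, k = 2)
  expect_equal(length(unique(res$clusters[1:3])), 1)
  expect_equal(length(unique(res$clusters[4:6])), 1)
  expect_false(res$clusters[1] == res$clusters[4])
  # duplicated gene rows have Jaccard 1 and merge first
  expect_equal(res$jaccard["g1", "g2"], 1)
  expect_equal(res$hclust$height[1], 0)
  # 4-gene fixture against the set-arithmetic oracle
  set.seed(3)
  ind4 <- matrix(rbinom(4 * 15, 1, 0.4), 4, 15,
                 dimnames = list(paste0("g", 1:4), NULL))
  res4 <- cooccurrence_groups(ind4, k = 2)
  for (i in 1:4) for (j in 1:4) {
    expect_equal(res4$jaccard[i, j],
                 if (i == j) 1 else oracle_jaccard(ind4[i, ], ind4[j, ]),
                 tolerance = 1e-12)
    expect_equal(res4$cooccurrence[i, j], sum(ind4[i, ] * ind4[j, ]))
  }
  expect_error(cooccurrence_groups(matrix(0, 3, 4)), "all-zero")
})

test_that("Cox fit recovers known hazards and flags the null", {
  # null covariate: coefficient within 3 SE of zero
  set.seed(7)
  n <- 400
  tm <- rexp(n, 0.1); ev <- rbinom(n, 1, 0.9)
  x <- rbinom(n, 1, 0.5)
  z <- matrix(rnorm(2 * n), 2, n,
              dimnames = list(c("a", "b"), sprintf("s%03d", 1:n)))
  coh <- survival_cohort(tm, ev, z)
  cf <- cox_fit(coh, data.frame(x = x))
  expect_lt(abs(cf$coefficients$coef[1]), 3 * cf$coefficients$se[1])
  expect_true(cf$converged)
  expect_equal(cf$coefficients$hr, exp(cf$coefficients$coef))
  expect_equal(cf$coefficients$ci_upper,
               exp(cf$coefficients$coef + 1.96 * cf$coefficients$se))
  # two exponential groups with true HR 2
  set.seed(8)
  grp <- rep(0:1, each = 1000)
  tm2 <- rexp(2000, 0.05 * 2^grp)
  cens <- rexp(2000, 0.002)
  coh2 <- survival_cohort(pmin(tm2, cens), as.integer(tm2 <= cens),
                          matrix(rnorm(4000), 2, 2000,
                                 dimnames = list(c("a", "b"), paste0("s", 1:2000))))
  cf2 <- cox_fit(coh2, data.frame(grp = grp))
  expect_gt(cf2$coefficients$hr[1], 1.8)
  expect_lt(cf2$coefficients$hr[1], 2.2)
  expect_error(cox_fit(coh2, data.frame()), "at least one covariate")
})

test_that("Cox score test equals the log-rank statistic on tie-free data", {
  set.seed(9)
  n <- 30
  tm <- sort(runif(n, 1, 50) + runif(n) / 97)  # tie-free by construction
  ev <- rep(1, n)
  grp <- rbinom(n, 1, 0.5)
  z <- matrix(rnorm(n), 1, n, dimnames = list("g", sprintf("s%02d", 1:n)))
  coh <- survival_cohort(tm, ev, z)
  cf <- cox_fit(coh, data.frame(grp = grp))
  lr <- logrank_test(tm, ev, ifelse(grp == 1, "a", "b"))
  expect_lt(abs(cf$score_test - lr$statistic) / lr$statistic, 1e-6)
})
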