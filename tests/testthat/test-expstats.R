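cq_row <- function(id, assay, cq, group = "case") {
  data.frame(sample_id = id, group = group, assay = assay,
             replicate = seq_along(cq), cq = cq, stringsAsFactors = FALSE)
}

test_that("delta_cq aggregates replicates and censors the sentinel", {
  tab <- rbind(cq_row("s1", "target", 25), cq_row("s1", "reference", 20))
  expect_equal(as.numeric(delta_cq(tab)), 5)
  tab2 <- rbind(cq_row("s2", "target", c(24, 26)),
                cq_row("s2", "reference", 20))
  expect_equal(as.numeric(delta_cq(tab2)), 5)
  tab3 <- rbind(cq_row("s3", "target", c(45, 45)),
                cq_row("s3", "reference", 20),
                cq_row("s4", "target", c(30, 45)),
                cq_row("s4", "reference", 20))
  expect_warning(d3 <- delta_cq(tab3), "s3")
  expect_equal(attr(d3, "dropped"), "s3")
  expect_equal(unname(d3["s4"]), 10)   # undetected replicate excluded
  tab4 <- cq_row("s5", "target", 30)
  expect_error(delta_cq(tab4), "s5")
})

test_that("fold change follows the 2^-ddCq algebra", {
  expect_equal(unname(fold_change(c(a = 5), 5)), 1)
  expect_equal(unname(fold_change(c(a = 4), 5)), 2)
  expect_equal(unname(fold_change(c(a = 5 + 3.3219), 5)), 0.1,
               tolerance = 1e-3)
  # calibrator identity: any sample normalized to itself is 1
  set.seed(2)
  dcq <- rnorm(10)
  expect_equal(unname(fold_change(dcq, dcq)), 2^-(dcq - median(dcq)))
  expect_true(all(fold_change(dcq, dcq) > 0))
  expect_error(fold_change(dcq, numeric(0)), "empty")
})

test_that("spike-in recovery halves per extra cycle and flags anomalies", {
  tab <- rbind(cq_row("s1", "spikein", 22), cq_row("s2", "spikein", 23),
               cq_row("s3", "spikein", 20))
  rec <- spikein_recovery(tab, reference_cq = 22)
  expect_equal(rec$recovery[rec$sample_id == "s1"], 1)
  expect_equal(rec$recovery[rec$sample_id == "s2"], 0.5)
  expect_equal(rec$recovery[rec$sample_id == "s3"], 4)
  expect_true(rec$flagged[rec$sample_id == "s3"])   # > 1 is anomalous
  expect_false(rec$flagged[rec$sample_id == "s1"])
  expect_error(spikein_recovery(cq_row("s1", "target", 20)), "spikein")
})

test_that("median dichotomization applies the documented tie rule", {
  ref <- c(0.5, 1.0, 1.5)
  lab <- dichotomize_median(c(a = 0.4, b = 2), ref)
  expect_equal(as.character(lab), c("low", "high"))
  expect_message(tie <- dichotomize_median(c(a = 1.0), ref), "cut-off")
  expect_equal(unname(tie["a"]), "high")
  expect_error(dichotomize_median(1, numeric(0)), "non-empty")
})

test_that("dichotomization recovers a planted low-expression component", {
  # controls sit at fold change 1 (the cut-off itself); the planted
  # component at fold change 0.25 must be recovered as "low"
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    ctrl <- 2^rnorm(10, 0, 0.1)
    case <- 2^rnorm(10, -2, 0.1)         # planted fold change 0.25
    mean(dichotomize_median(case, ctrl) == "low")
  }, numeric(1))
  expect_gte(mean(hits), 0.95)
})

test_that("product-limit estimator matches hand computation", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km$n_risk, c(3, 2, 1))
  allc <- km_estimate(c(4, 5, 6), c(0, 0, 0))
  expect_length(allc$time, 0)
  expect_equal(km_survival_at(allc, c(1, 10)), c(1, 1))
  expect_error(km_estimate(c(0, 1), c(1, 1)), "non-positive")
})

test_that("without censoring the estimator is the empirical survival function", {
  set.seed(4)
  t <- rexp(40)
  km <- km_estimate(t, rep(1, 40))
  for (q in quantile(t, c(0.2, 0.5, 0.8))) {
    expect_equal(km_survival_at(km, q), mean(t > q))
  }
})

test_that("published cohort table drives KM/log-rank identically to the survival package", {
  skip_if_not_installed("survival")
  t1 <- nsclc_cohort()
  expect_equal(nrow(t1), 32)
  for (endpoint in list(c("os_months", "death"), c("dfs_months", "relapse"))) {
    time <- t1[[endpoint[1]]]; event <- t1[[endpoint[2]]]
    km <- km_estimate(time, event)
    sf <- survival::survfit(survival::Surv(time, event) ~ 1)
    ref <- summary(sf, times = km$time)$surv
    expect_equal(km$survival, ref, tolerance = 1e-9)
    grp <- ifelse(t1$histology == "SCC", "scc", "non-scc")
    lr <- logrank_test(time, event, grp)
    sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
    expect_equal(lr$chisq, sd$chisq, tolerance = 1e-9)
  }
})

test_that("log-rank is symmetric, null on clone data, and exact on a worked example", {
  time <- c(1, 2, 3, 4); event <- c(1, 1, 1, 1)
  clone <- logrank_test(c(time, time), c(event, event),
                        rep(c("a", "b"), each = 4))
  expect_equal(clone$chisq, 0)
  expect_equal(clone$p, 1)
  # group A events at 1, 2; group B at 3, 4: O1 = 2,
  # E1 = 2/4 + 1/3 + 0 + 0; V = sum of hypergeometric variances
  lr <- logrank_test(time, event, c("a", "a", "b", "b"))
  e1 <- 2 / 4 + 1 / 3
  v <- (2 / 4) * (1 - 2 / 4) + (1 / 3) * (1 - 1 / 3)
  expect_equal(lr$chisq, (2 - e1)^2 / v, tolerance = 1e-9)
  sw <- logrank_test(time, event, c("b", "b", "a", "a"))
  expect_equal(lr$chisq, sw$chisq, tolerance = 1e-12)
  expect_error(logrank_test(time, event, rep("a", 4)), "two groups")
})

test_that("kappa matches its closed form and flags the degenerate case", {
  perfect <- kappa_agreement(diag(c(5, 5)))
  expect_equal(perfect$kappa, 1)
  expect_equal(perfect$percent_agreement, 100)
  indep <- kappa_agreement(matrix(2, 2, 2))
  expect_equal(indep$kappa, 0)
  expect_equal(indep$percent_agreement, 50)
  worked <- kappa_agreement(matrix(c(20, 10, 5, 15), 2, 2))
  expect_equal(worked$kappa, 0.4)
  degen <- kappa_agreement(matrix(c(7, 0, 0, 0), 2, 2))
  expect_true(degen$undefined)
  expect_true(is.na(degen$kappa))
  set.seed(6)
  for (i in 1:20) {
    m <- matrix(rpois(9, 4), 3, 3)
    k <- kappa_agreement(m)
    if (!k$undefined) expect_true(k$kappa >= -1 && k$kappa <= 1)
  }
  expect_error(kappa_agreement(matrix(1, 2, 3)), "square")
})
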