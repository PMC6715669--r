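# cohort_analysis: RIP-Seq consensus, paired comparison, biomarker ROC

toy_counts <- function(calls, universe = letters[1:6]) {
  # counts whose RPM/enrichment calls are exactly `calls` at
  # min_rpm = 1000, min_enrichment = 4: called miRNAs are IP-enriched
  # 100:1, the rest depleted 1:100
  called <- universe %in% calls
  data.frame(mirna = universe,
             ip = ifelse(called, 100L, 1L),
             input = ifelse(called, 1L, 100L))
}

test_that("consensus intersection matches hand enumeration on toy tables", {
  tabs <- list(s1 = toy_counts(c("a", "b", "c")),
               s2 = toy_counts(c("b", "c", "d")),
               s3 = toy_counts(c("b", "c", "e")),
               s4 = toy_counts(c("a", "b", "c", "f")))
  res <- consensus_methylated(tabs, min_rpm = 1000, min_enrichment = 4)
  expect_equal(res$per_sample$s1, c("a", "b", "c"))
  expect_equal(res$intersection, c("b", "c"))
  expect_equal(length(res$intersection), 2)
  expect_equal(unname(res$venn[["s1&s2&s3&s4"]]), 2)
  expect_equal(unname(res$venn[["s1&s4"]]), 1)   # only "a"
})

test_that("consensus edge cases and validation", {
  tabs <- list(s1 = toy_counts(c("a", "b")), s2 = toy_counts(character()))
  res <- consensus_methylated(tabs, min_rpm = 1000, min_enrichment = 4)
  expect_equal(length(res$per_sample$s2), 0)
  expect_equal(length(res$intersection), 0)
  # infinite enrichment threshold empties every set
  res_inf <- consensus_methylated(tabs, min_rpm = 0, min_enrichment = Inf)
  expect_true(all(lengths(res_inf$per_sample) == 0))
  expect_error(consensus_methylated(list(), 1, 1), "at least one")
  expect_error(consensus_methylated(
    list(s1 = data.frame(mirna = "a", ip = 1)), 1, 1), "channel")
  expect_error(consensus_methylated(
    list(s1 = data.frame(mirna = "a", ip = 0L, input = 0L)), 1, 1),
    "zero library")
})

test_that("raising thresholds never grows consensus sets", {
  set.seed(31)
  tabs <- lapply(1:3, function(i) {
    data.frame(mirna = letters[1:10],
               ip = as.integer(rpois(10, 40)),
               input = as.integer(rpois(10, 20)))
  })
  names(tabs) <- paste0("s", 1:3)
  base <- consensus_methylated(tabs, min_rpm = 100, min_enrichment = 1)
  for (rpm in c(100, 1000, 10000)) {
    for (enr in c(1, 2, 4)) {
      res <- consensus_methylated(tabs, min_rpm = rpm, min_enrichment = enr)
      for (s in names(tabs)) {
        expect_true(all(res$per_sample[[s]] %in% base$per_sample[[s]]))
      }
      expect_true(all(res$intersection %in% base$intersection))
    }
  }
})

make_paired <- function(case, control) {
  n <- length(case)
  data.frame(sample_id = c(paste0("c", 1:n), paste0("n", 1:n)),
             group = rep(c("case", "control"), each = n),
             pair_id = rep(paste0("p", 1:n), 2),
             fraction = c(case, control))
}

test_that("paired t-test matches the closed form", {
  # differences {1, 2, 3}: t = 2*sqrt(3), df = 2
  tb <- make_paired(c(2, 4, 6), c(1, 2, 3))
  res <- paired_test(tb)
  expect_equal(res$statistic, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$p_value,
               2 * stats::pt(-2 * sqrt(3), df = 2), tolerance = 1e-12)
  # identical pairs: t = 0, p = 1
  tb0 <- make_paired(c(1, 2, 3), c(1, 2, 3))
  res0 <- paired_test(tb0)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  # constant nonzero difference: infinite t, p = 0 (documented convention)
  tbc <- make_paired(c(2, 3, 4), c(1, 2, 3))
  resc <- paired_test(tbc)
  expect_true(is.infinite(resc$statistic))
  expect_equal(resc$p_value, 0)
  expect_error(paired_test(make_paired(1, 0)), ">= 2")
})

test_that("paired t agrees with stats::t.test and wilcoxon flag works", {
  set.seed(13)
  tb <- make_paired(runif(10, 0.2, 0.6), runif(10, 0, 0.3))
  res <- paired_test(tb)
  d <- tb$fraction[tb$group == "case"] - tb$fraction[tb$group == "control"]
  ref <- stats::t.test(d)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  resw <- paired_test(tb, method = "wilcoxon")
  expect_true(resw$p_value >= 0 && resw$p_value <= 1)
  expect_equal(resw$method, "wilcoxon")
})

make_cohort <- function(cases, controls) {
  data.frame(group = rep(c("case", "control"),
                         c(length(cases), length(controls))),
             fraction = c(cases, controls))
}

test_that("ROC/AUC matches brute force and handles ties and zeros", {
  # cases {3, 1}, controls {2, 0}: 3 of 4 pairs won -> 0.75
  res <- roc_auc(make_cohort(c(3, 1), c(2, 0)))
  expect_equal(res$auc, 0.75)
  # perfectly separated
  expect_equal(roc_auc(make_cohort(c(5, 6), c(1, 2)))$auc, 1.0)
  # all identical: tie convention gives 0.5
  expect_equal(roc_auc(make_cohort(c(2, 2), c(2, 2)))$auc, 0.5)
  # NA treated as below detection limit (zero)
  res_na <- roc_auc(make_cohort(c(3, NA), c(2, 0)))
  expect_equal(res_na$auc, oracle_auc(c(3, 0), c(2, 0)))
  expect_error(roc_auc(make_cohort(numeric(), c(1))), "non-empty")
})

test_that("rank-based AUC equals brute-force pairwise AUC (property)", {
  set.seed(17)
  for (rep in 1:40) {
    n1 <- sample(2:25, 1); n0 <- sample(2:25, 1)
    vals <- sample(0:8, n1 + n0, replace = TRUE) / 4  # many ties
    tb <- make_cohort(vals[1:n1], vals[-(1:n1)])
    expect_equal(roc_auc(tb)$auc,
                 oracle_auc(vals[1:n1], vals[-(1:n1)]),
                 tolerance = 1e-12)
  }
})

test_that("ROC points trace a valid monotone curve", {
  set.seed(19)
  tb <- make_cohort(runif(15, 0.3, 1), runif(20, 0, 0.6))
  pts <- roc_auc(tb)$points
  expect_equal(pts$fpr[1], 0)
  expect_equal(pts$tpr[1], 0)
  expect_equal(pts$fpr[nrow(pts)], 1)
  expect_equal(pts$tpr[nrow(pts)], 1)
  expect_true(all(diff(pts$fpr) >= 0))
  expect_true(all(diff(pts$tpr) >= 0))
})
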