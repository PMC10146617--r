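test_that("Cohen's d follows the pooled-SD and paired conventions", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  # hand-checked: arms {0,1} vs {1,2}, pooled sd sqrt(0.5)
  expect_equal(abs(cohens_d(c(0, 1), c(1, 2))), 1 / sqrt(0.5), tolerance = 1e-12)
  # antisymmetric under arm exchange; invariant under common shifts
  set.seed(40)
  a <- rnorm(10); b <- rnorm(12, 1)
  expect_equal(cohens_d(a, b), -cohens_d(b, a))
  expect_equal(cohens_d(a + 5, b + 5), cohens_d(a, b))
  expect_equal(cohens_d(a[1:10] + 5, b[1:10] + 5, paired = TRUE),
               cohens_d(a[1:10], b[1:10], paired = TRUE))
  # paired: mean(diff)/sd(diff)
  x <- c(1, 2, 4); y <- c(0, 1, 2)
  expect_equal(cohens_d(x, y, paired = TRUE), mean(x - y) / sd(x - y))
  # zero variance flags degenerate infinity
  expect_true(is.infinite(cohens_d(c(1, 1), c(0, 0))))
  expect_error(cohens_d(1, c(1, 2)), ">= 2 values")
})

mk_energies <- function(pat = list(), con = list(), pattern_code = 0L) {
  rows <- list()
  add <- function(g, cond, e) {
    ids <- sprintf("%s%02d", toupper(substr(g, 1, 1)), seq_along(e))
    data.frame(subject = ids, group = g, site = "left_motor", condition = cond,
               network = "toy", pattern_code = pattern_code,
               pattern_string = "--", energy = e, stringsAsFactors = FALSE)
  }
  do.call(rbind, list(add("patient", "pre", pat$pre), add("patient", "post", pat$post),
                      add("control", "pre", con$pre), add("control", "post", con$post)))
}

test_that("the four comparisons use paired and Welch tests appropriately", {
  set.seed(41)
  en <- mk_energies(pat = list(pre = rnorm(8), post = rnorm(8) + 3),
                    con = list(pre = rnorm(10), post = rnorm(10)))
  rec <- run_comparisons(en)
  expect_setequal(rec$comparison,
                  c("controls_pre_vs_post", "patients_pre_vs_post",
                    "pre_controls_vs_patients", "post_controls_vs_patients"))
  # the planted patient pre/post shift shows up in the paired test and the
  # post between-group test, not in the control or pre comparisons
  p <- setNames(rec$p_value, rec$comparison)
  expect_lt(p["patients_pre_vs_post"], 0.01)
  expect_lt(p["post_controls_vs_patients"], 1e-3)
  expect_gt(p["controls_pre_vs_post"], 0.01)
  # cross-check against stats::t.test directly (Welch, two-sided)
  a <- en$energy[en$group == "control" & en$condition == "post"]
  b <- en$energy[en$group == "patient" & en$condition == "post"]
  expect_equal(unname(p["post_controls_vs_patients"]),
               t.test(a, b, var.equal = FALSE)$p.value)
  # paired cross-check with subjects matched by id
  pre <- en$energy[en$group == "patient" & en$condition == "pre"]
  post <- en$energy[en$group == "patient" & en$condition == "post"]
  expect_equal(unname(p["patients_pre_vs_post"]),
               t.test(post, pre, paired = TRUE)$p.value)
})

test_that("identical arms yield p = 1 and insufficient data is flagged", {
  e <- rnorm(6)
  en <- mk_energies(pat = list(pre = e, post = e), con = list(pre = e, post = e))
  rec <- run_comparisons(en)
  expect_true(all(rec$p_value == 1))
  expect_true(all(!rec$untestable))
  # one observation per arm -> untestable, not dropped
  en1 <- mk_energies(pat = list(pre = 1, post = 2), con = list(pre = 1, post = 2))
  rec1 <- run_comparisons(en1)
  expect_equal(nrow(rec1), 4L)
  expect_true(all(rec1$untestable))
  expect_true(all(is.na(rec1$p_value)))
})

test_that("the Bonferroni gate applies alpha/n per network with the relevance cut", {
  rec <- data.frame(site = "s", network = rep(c("n1", "n2"), c(5, 2)),
                    pattern_code = c(1:5, 1:2), pattern_string = "x",
                    comparison = "post_controls_vs_patients",
                    n_a = 5, n_b = 5,
                    p_value = c(0.009, 0.02, 4e-5, 0.5, 0.011, 0.024, 0.026),
                    cohens_d = 1, untestable = FALSE, stringsAsFactors = FALSE)
  out <- bonferroni_gate(rec, alpha = 0.05)
  expect_equal(out$bonferroni_threshold[1:5], rep(0.01, 5))  # n = 5 -> 0.01
  expect_equal(out$bonferroni_threshold[6:7], rep(0.025, 2)) # n = 2 -> 0.025
  expect_equal(out$passes_bonferroni,
               c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE))
  # p = 0.009 passes the gate but not the 5e-5 relevance cut; 4e-5 passes both
  expect_equal(out$passes_relevance,
               c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_error(bonferroni_gate(rec[0, ]), "n = 0")
})

test_that("signature tables render region status per passing record", {
  nws <- default_networks()
  empty <- build_signature_table(NULL, nws)
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("region", "status", "p_value") %in% names(empty)))
  rec <- data.frame(site = "left_motor", network = "sensorimotor",
                    pattern_code = pattern_code(c(1, 1, 1, -1, -1)),
                    pattern_string = "+++--",
                    comparison = "post_controls_vs_patients", n_a = 27, n_b = 22,
                    p_value = 3e-5, cohens_d = 0.85, untestable = FALSE,
                    stringsAsFactors = FALSE)
  rec <- bonferroni_gate(rec)
  tab <- build_signature_table(rec, nws)
  expect_equal(nrow(tab), 5L)
  expect_equal(tab$region, nws$sensorimotor$regions)
  expect_equal(tab$status, c(1, 1, 1, -1, -1))
  expect_true(all(tab$passes_relevance))
})

test_that("the six reported signatures average to the published effect size", {
  sig <- reported_signatures()
  expect_equal(nrow(sig), 6L)
  expect_equal(round(mean(abs(sig$cohens_d)), 2), 1.22)
})
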