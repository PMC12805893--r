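test_that("PSI follows the length-normalized junction-count formula", {
  expect_equal(psi_from_junctions(50, 50, 7, 7), 0.5)
  expect_equal(psi_from_junctions(0, 30), 0)
  expect_equal(psi_from_junctions(30, 10, 2, 1), 0.6)  # (15)/(15+10)
  expect_true(is.na(psi_from_junctions(0, 0)))
  psi <- psi_from_junctions(c(3, 10, 0), c(5, 0, 2))
  expect_true(all(psi >= 0 & psi <= 1))
  expect_error(psi_from_junctions(-1, 5), "non-negative")
  expect_error(psi_from_junctions(1, 5, len_inc = 0), "positive")
})

test_that("BH adjustment reproduces the step-up formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  # permutation invariance
  p <- c(0.001, 0.2, 0.04, 0.9, 0.015)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("the two-binomial LR test behaves at the extremes", {
  # identical counts in both groups -> LR 0 -> p = 1
  expect_equal(delta_psi_test(c(10, 10, 10, 10), c(5, 5, 5, 5),
                              rep(c("a", "b"), each = 2)), 1)
  # complete separation at depth 100 per group
  p <- delta_psi_test(c(50, 50, 0, 0), c(0, 0, 50, 50),
                      rep(c("a", "b"), each = 2))
  expect_lt(p, 1e-6)
  # closed form: LR = 2 * (0 - 200 * log(0.5))
  expect_equal(p, pchisq(-400 * log(0.5), df = 1, lower.tail = FALSE))
  # a group without reads gives a missing p
  expect_true(is.na(delta_psi_test(c(0, 0, 5, 5), c(0, 0, 5, 5),
                                   rep(c("a", "b"), each = 2))))
  expect_error(delta_psi_test(1, 1, c("a", "b")), "two samples")
})

test_that("type-I error is near nominal on null simulations", {
  set.seed(501)
  p <- replicate(2000, {
    tot <- pmax(1, rpois(6, 60))
    ijc <- rbinom(6, tot, 0.5)
    delta_psi_test(ijc, tot - ijc, rep(c("a", "b"), each = 3))
  })
  alpha <- mean(p < 0.05)
  tol <- 3 * sqrt(0.05 * 0.95 / 2000)
  expect_gt(alpha, 0.05 - tol)
  expect_lt(alpha, 0.05 + tol)
})

test_that("the event filter enforces all three thresholds", {
  sim <- simulate_event_table(n_events = 60, n_true = 10,
                              delta_psi_true = 0.45, depth = 120, seed = 21)
  an <- analyze_splice_events(sim$events)
  th <- event_filter_thresholds()
  surv <- filter_events(an, th)
  expect_true(all(abs(surv$delta_psi) >= th$min_abs_delta_psi))
  expect_true(all(surv$fdr < th$fdr_max))
  expect_true(all(surv$best_support >= th$min_avg_junction_reads))
  expect_true(all(surv$event_id %in% an$event_id))
  expect_true(all(surv$verdict %in% c("increased_inclusion",
                                      "increased_skipping")))
  expect_equal(surv$verdict == "increased_inclusion", surv$delta_psi > 0)

  # a large, significant effect is rejected when its support is too thin
  shallow <- simulate_event_table(n_events = 20, n_true = 20,
                                  delta_psi_true = 0.6, depth = 5, seed = 22)
  surv2 <- filter_events(analyze_splice_events(shallow$events), th)
  expect_equal(nrow(surv2), 0)

  # threshold unit cases on a hand-built summary: strong significance with a
  # small delta-PSI fails the delta rule; a large delta with weak FDR fails
  # the FDR rule
  summ <- data.frame(event_id = c("e1", "e2"), gene = c("g1", "g2"),
                     psi_control = c(0.50, 0.20),
                     psi_treated = c(0.55, 0.70),
                     delta_psi = c(0.05, 0.50),
                     p_value = c(0.0005, 0.15),
                     best_support = c(100, 100),
                     fdr = c(0.001, 0.2), stringsAsFactors = FALSE)
  class(summ) <- c("splice_event_table", "data.frame")
  expect_equal(nrow(filter_events(summ, th)), 0)
})

test_that("undefined-PSI events are dropped with a logged reason", {
  ev <- data.frame(
    event_id = rep(c("ok", "dead"), each = 6),
    gene = "g", group = rep(rep(c("control", "treated"), each = 3), 2),
    sample = rep(sprintf("s%d", 1:6), 2),
    ijc = c(30, 28, 31, 5, 6, 4, rep(0, 6)),
    sjc = c(10, 12, 9, 40, 41, 39, rep(0, 6)),
    stringsAsFactors = FALSE)
  an <- analyze_splice_events(ev)
  expect_message(surv <- filter_events(an), "dropped")
  expect_false("dead" %in% surv$event_id)
  expect_equal(attr(surv, "dropped")$event_id, "dead")
})

test_that("gel densitometry percentages partition the lane signal", {
  expect_equal(unname(gel_percent_inclusion(c(FL = 75, dE7 = 25))),
               c(75, 25))
  expect_equal(unname(gel_percent_inclusion(c(only = 42))), 100)
  expect_equal(unname(gel_percent_inclusion(c(10, 30, 60))), c(10, 30, 60))
  expect_equal(sum(gel_percent_inclusion(c(3, 7, 11))), 100)
  expect_error(gel_percent_inclusion(c(0, 0)), "positive")
  expect_error(gel_percent_inclusion(c(-1, 5)), "non-negative")
})

test_that("delta-delta-Ct doubles per planted cycle and is 1 for control", {
  mk <- function(shift) {
    data.frame(sample = sprintf("s%d", 1:6),
               condition = rep(c("control", "treated"), each = 3),
               target_ct = c(24, 24, 24, 24 + shift, 24 + shift, 24 + shift),
               normalizer_ct = 18, stringsAsFactors = FALSE)
  }
  rq <- function(shift) {
    out <- ddct_relative_expression(mk(shift))
    out$rq[out$condition == "treated"]
  }
  expect_equal(ddct_relative_expression(mk(0))$rq, c(1, 1))
  expect_equal(rq(1), 0.5)
  expect_equal(rq(-2), 4)
  # a missing normalizer excludes the sample with a message
  broken <- mk(1)
  broken$normalizer_ct[4] <- NA
  expect_message(out <- ddct_relative_expression(broken), "excluded")
  expect_equal(out$n[out$condition == "treated"], 2)
  expect_error(ddct_relative_expression(mk(1), "mock"), "not present")
})

test_that("planted qPCR fold changes are recovered within 3 standard errors", {
  for (f in c(-2, -1, 1.5)) {
    q <- simulate_qpcr_table(log2fc = c(treated = f), n_reps = 6,
                             sd = 0.1, seed = 97 + round(10 * abs(f)))
    out <- ddct_relative_expression(q)
    tr <- out[out$condition == "treated", ]
    expect_lte(abs(tr$log2_rq - f), 3 * tr$se_log2_rq)
  }
})

test_that("DE-table summaries count thresholded genes exactly", {
  empty <- data.frame(gene = character(0), log2fc = numeric(0),
                      padj = numeric(0))
  expect_equal(summarize_de_table(empty),
               c(significant = 0L, fc_gt2 = 0L, up = 0L, down = 0L))
  one <- data.frame(gene = "g", log2fc = -1.5, padj = 0.01)
  expect_equal(unname(summarize_de_table(one)), c(1L, 1L, 0L, 1L))

  sim <- simulate_de_table(n_genes = 1000, n_sig = 100, seed = 55)
  counts <- summarize_de_table(sim$table)
  expect_equal(unname(counts["significant"]), 100L)
  expect_equal(unname(counts["up"]),
               sum(sim$truth$is_sig & sim$truth$direction == "up"))
  expect_equal(unname(counts["down"]),
               sum(sim$truth$is_sig & sim$truth$direction == "down"))
  expect_error(summarize_de_table(data.frame(gene = "g", log2fc = 1,
                                             padj = 2)), "\\[0, 1\\]")
})
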