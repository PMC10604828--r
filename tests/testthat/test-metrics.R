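test_that("micro-averaged confusion counts match a brute-force one-vs-rest sum", {
  truth <- c("a", "a", "b", "b", "b", "c", "c", "c", "c")
  pred  <- c("a", "b", "b", "b", "c", "c", "a", "c", "b")
  got <- micro_confusion(truth, pred)
  # independent oracle: explicit one-vs-rest tabulation per class
  exp_tp <- exp_tn <- exp_fp <- exp_fn <- 0
  for (cls in c("a", "b", "c")) {
    t_pos <- truth == cls; p_pos <- pred == cls
    exp_tp <- exp_tp + sum(t_pos & p_pos)
    exp_tn <- exp_tn + sum(!t_pos & !p_pos)
    exp_fp <- exp_fp + sum(!t_pos & p_pos)
    exp_fn <- exp_fn + sum(t_pos & !p_pos)
  }
  expect_equal(got$tp, exp_tp); expect_equal(got$tn, exp_tn)
  expect_equal(got$fp, exp_fp); expect_equal(got$fn, exp_fn)
  expect_error(micro_confusion(c("a", "b"), "a"), "equal length")
})

test_that("binary micro-averaging forces TP = TN and FP = FN", {
  set.seed(13)
  for (i in 1:25) {
    truth <- sample(c("normal", "lesion"), 40, replace = TRUE)
    pred <- sample(c("normal", "lesion"), 40, replace = TRUE)
    cc <- micro_confusion(truth, pred, classes = c("lesion", "normal"))
    expect_equal(cc$tp, cc$tn)
    expect_equal(cc$fp, cc$fn)
  }
  perfect <- micro_confusion(rep(c("a", "b"), 5), rep(c("a", "b"), 5))
  expect_equal(perfect$tp, 10); expect_equal(perfect$tn, 10)
  expect_equal(perfect$fp, 0); expect_equal(perfect$fn, 0)
})

test_that("count metrics satisfy their algebraic identities", {
  r <- compute_metrics(confusion_counts(1, 1, 0, 0))
  for (m in c("accuracy", "f1", "precision", "recall", "specificity",
              "iou", "dice", "npv", "youden_index"))
    expect_equal(r[[m]], 100)
  set.seed(31)
  for (i in 1:50) {
    tp <- sample(0:50, 1); fp <- sample(0:50, 1)
    cc <- confusion_counts(tp, tp, fp, fp)  # binary micro symmetry
    rep <- compute_metrics(cc)
    if (tp + fp == 0) next
    # equality chain under TP=TN, FP=FN
    expect_equal(rep$precision, rep$accuracy)
    expect_equal(rep$recall, rep$accuracy)
    expect_equal(rep$specificity, rep$accuracy)
    if (tp > 0) expect_equal(rep$f1, rep$accuracy)  # F1 undefined at P=R=0
    expect_equal(rep$npv, rep$accuracy)
    expect_equal(rep$sensitivity, rep$recall)
    expect_equal(rep$youden_index, rep$sensitivity + rep$specificity - 100)
    if (tp > 0) {
      iou <- rep$iou / 100
      expect_equal(rep$dice / 100, 2 * iou / (1 + iou))
    }
  }
  # zero denominators yield NA, not errors
  z <- compute_metrics(confusion_counts(0, 5, 0, 0))
  expect_true(is.na(z$precision))
  expect_error(compute_metrics(confusion_counts(0, 0, 0, 0)), "all counts")
})

test_that("rank AUC matches its boundary laws and an independent implementation", {
  truth <- rep(c("neg", "pos"), each = 10)
  perfect <- c(runif(10, 0, 0.4), runif(10, 0.6, 1))
  expect_equal(auc_rank(truth, perfect, positive = "pos"), 100)
  expect_equal(auc_rank(truth, 1 - perfect, positive = "pos"), 0)
  set.seed(17)
  truth_big <- sample(c("neg", "pos"), 4000, replace = TRUE)
  noise <- runif(4000)
  expect_lt(abs(auc_rank(truth_big, noise, positive = "pos") - 50), 3)
  skip_if_not_installed("pROC")
  scores <- rnorm(200) + (truth_big[1:200] == "pos")
  ours <- auc_rank(truth_big[1:200], scores, positive = "pos")
  ref <- 100 * as.numeric(pROC::auc(pROC::roc(
    truth_big[1:200], scores, levels = c("neg", "pos"),
    direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-10)
  expect_error(auc_rank(rep("pos", 5), runif(5)), "undefined AUC")
})

test_that("cosine similarity handles exact, uniform and orthogonal predictions", {
  truth <- diag(2)[c(1, 2, 1, 2), ]
  expect_equal(cosine_similarity(truth, truth), 100)
  uniform <- matrix(0.5, 4, 2)
  expect_equal(cosine_similarity(truth, uniform), 100 / sqrt(2),
               tolerance = 1e-10)
  wrong <- truth[, c(2, 1)]
  expect_equal(cosine_similarity(truth, wrong), 0)
  expect_error(cosine_similarity(truth, matrix(0, 4, 2)), "degenerate")
})

test_that("the weighted sum is the equal-weight mean of the twelve metrics", {
  all_same <- do.call(metric_report, as.list(rep(88, 12)))
  expect_equal(weighted_sum(all_same), 88)
  bumped <- all_same
  bumped$iou <- 88 + 12
  expect_equal(weighted_sum(bumped), 89)  # +12 on one metric -> +1 overall
  with_na <- all_same; with_na$auc <- NA_real_
  expect_error(weighted_sum(with_na), "undefined")
})

test_that("report aggregation averages per metric and is identity for one report", {
  r1 <- do.call(metric_report, as.list(rep(90, 12)))
  r2 <- do.call(metric_report, as.list(rep(100, 12)))
  agg <- aggregate_reports(list(r1, r2))
  expect_equal(agg$accuracy, 95)
  expect_equal(aggregate_reports(list(r1)), r1)
  expect_error(aggregate_reports(list()), "contract violation")
})

test_that("report tables serialize with presentation rounding", {
  r <- compute_metrics(confusion_counts(5351, 5351, 25, 25))
  r$auc <- 99.95; r$cosine_similarity <- 99.61
  path <- withr::local_tempfile(fileext = ".csv")
  write_report_table(list(Xception = r), path)
  df <- read.csv(path)
  expect_equal(df$Xception[df$metric == "accuracy"], 99.53)
  jpath <- withr::local_tempfile(fileext = ".json")
  write_report_table(list(Xception = r), jpath, format = "json")
  back <- jsonlite::read_json(jpath)
  expect_equal(back$Xception$accuracy, r$accuracy, tolerance = 1e-12)
})

test_that("presentation rounding is half-up at two decimals", {
  expect_equal(round_half_up(97.275), 97.28)
  expect_equal(round_half_up(99.525), 99.53)
  expect_equal(round_half_up(0.125), 0.13)
  expect_equal(round_half_up(-0.125), -0.13)
})
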