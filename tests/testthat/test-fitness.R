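test_that("the surrogate peaks at its designated optimum and decays with distance", {
  be <- surrogate_backend()
  space <- build_default_space(TRUE)
  opt <- surrogate_optimum()
  # encode the optimum through span midpoints: loss 3/6, batch 6/12,
  # optimizer 5/11, scaling 3/4, augmentation "no" 2/2
  v <- rep(0.5, 15)
  v[1] <- 2.5 / 6; v[2] <- 5.5 / 12; v[5] <- 4.5 / 11
  v[6] <- 2.5 / 4; v[7] <- 1.5 / 2
  cfg <- decode_solution(v, space)
  expect_equal(cfg$loss_function, opt$loss_function)
  expect_equal(cfg$batch_size, opt$batch_size)
  expect_equal(surrogate_distance(cfg), 0)
  at_opt <- be$evaluate(cfg)
  expect_equal(at_opt$score, 100)
  # one batch step away: strictly lower score, monotone in Hamming distance
  v1 <- v; v1[2] <- 6.5 / 12
  s1 <- be$evaluate(decode_solution(v1, space))$score
  v2 <- v1; v2[1] <- 0.5 / 6  # also move the loss two options
  s2 <- be$evaluate(decode_solution(v2, space))$score
  expect_lt(s1, 100)
  expect_lt(s2, s1)
  # deterministic
  expect_identical(be$evaluate(cfg), be$evaluate(cfg))
})

test_that("solution evaluation through the surrogate is bounded and deterministic", {
  space <- build_default_space(TRUE)
  be <- surrogate_backend()
  set.seed(2)
  for (i in 1:5) {
    v <- runif(15)
    res <- evaluate_solution(v, space, be, seed = 1)
    expect_true(is.finite(res$fitness))
    expect_gte(res$fitness, 0); expect_lte(res$fitness, 100)
    res2 <- evaluate_solution(v, space, be, seed = 1)
    expect_equal(res$fitness, res2$fitness)
    expect_equal(res$report, res2$report)
  }
  # switching the fitness metric changes only the scalar, not the report
  v <- rep(0.4, 15)
  acc <- evaluate_solution(v, space, be, seed = 1,
                           fitness_metric = "accuracy")
  ws <- evaluate_solution(v, space, be, seed = 1,
                          fitness_metric = "weighted_sum")
  expect_equal(acc$report, ws$report)
  expect_equal(acc$fitness, acc$report$accuracy)
  expect_equal(ws$fitness, weighted_sum(ws$report))
})

test_that("the tiny classifier honors the decoded batch size", {
  ds <- make_synthetic_imageset(c(50, 50), size = c(16, 16), noise_sd = 5,
                                seed = 4)
  split <- partition_dataset(ds, seed = 4)
  be <- tiny_classifier_backend()
  space <- build_default_space(TRUE)
  v <- rep(0.5, 15); v[2] <- 0.75; v[7] <- 0.9  # batch 36, augmentation off
  res <- evaluate_solution(v, space, be, split, epochs = 1, seed = 1)
  sizes <- res$backend_detail$batch_sizes
  expect_true(length(sizes) > 0)
  expect_true(all(sizes <= 36))
  expect_equal(max(sizes), 36)  # full batches consume 36 samples
})

test_that("the tiny classifier learns separable data and is at chance untrained", {
  ds <- make_synthetic_imageset(c(80, 80), size = c(16, 16),
                                separability = 1, noise_sd = 5, seed = 7)
  split <- partition_dataset(ds, seed = 7)
  be <- tiny_classifier_backend()
  space <- build_default_space(TRUE)
  v <- rep(0.5, 15); v[7] <- 0.9
  trained <- evaluate_solution(v, space, be, split, epochs = 5, seed = 1)
  expect_gt(trained$fitness, 90)
  # untrained: average accuracy over seeds sits at chance on balanced data
  untrained <- vapply(1:3, function(s)
    evaluate_solution(v, space, be, split, epochs = 0, seed = s)$fitness,
    numeric(1))
  expect_lt(abs(mean(untrained) - 50), 10)
  # determinism of the full path
  again <- evaluate_solution(v, space, be, split, epochs = 5, seed = 1)
  expect_equal(trained$fitness, again$fitness)
})

test_that("every decodable loss and parameter optimizer is trainable", {
  ds <- make_synthetic_imageset(c(20, 20), size = c(16, 16), noise_sd = 5,
                                seed = 12)
  split <- partition_dataset(ds, seed = 12)
  be <- tiny_classifier_backend(width = 8)
  space <- build_default_space(TRUE)
  base <- rep(0.5, 15); base[7] <- 0.9
  for (k in seq_len(6)) {       # losses
    v <- base; v[1] <- (k - 0.5) / 6
    res <- evaluate_solution(v, space, be, split, epochs = 1, seed = 1)
    expect_true(is.finite(res$fitness))
  }
  for (k in seq_len(11)) {      # parameter optimizers
    v <- base; v[5] <- (k - 0.5) / 11
    res <- evaluate_solution(v, space, be, split, epochs = 1, seed = 1)
    expect_true(is.finite(res$fitness))
  }
})

test_that("augmentation gating drives balancing inside the evaluation pathway", {
  ds <- make_synthetic_imageset(c(10, 16), size = c(16, 16), noise_sd = 5,
                                seed = 3)
  split <- partition_dataset(ds, seed = 3)
  be <- tiny_classifier_backend(width = 8)
  space <- build_default_space(TRUE)
  v_on <- rep(0.4, 15); v_on[7] <- 0.1   # augmentation on
  res <- evaluate_solution(v_on, space, be, split, epochs = 1, seed = 1)
  expect_true(is.finite(res$fitness))
  expect_true(res$configuration$apply_augmentation)
})
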