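test_that("default space has the documented dimensionality and spans", {
  with_aug <- build_default_space(TRUE)
  without <- build_default_space(FALSE)
  expect_equal(with_aug$D, 15)
  expect_equal(without$D, 7)
  batch <- with_aug$spans[[2]]
  expect_equal(span_length(batch), 12)
  expect_equal(batch$options, seq(4, 48, by = 4))
  expect_equal(span_length(with_aug$spans[[1]]), 6)   # losses
  expect_equal(span_length(with_aug$spans[[5]]), 11)  # optimizers
  expect_equal(span_length(with_aug$spans[[6]]), 4)   # scaling
  expect_equal(span_length(with_aug$spans[[4]]), 100) # TL learn ratio
  expect_equal(span_length(with_aug$spans[[8]]), 46)  # rotation 0..45
  expect_equal(with_aug$spans[[1]]$options[1], "categorical cross-entropy")
  expect_equal(with_aug$spans[[5]]$options[1], "adam")
})

test_that("population initialization is bounded, deterministic and uniform", {
  space <- build_default_space(TRUE)
  p1 <- init_population(10, space, seed = 7)
  p2 <- init_population(10, space, seed = 7)
  expect_equal(dim(p1), c(10, 15))
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_identical(p1, p2)
  expect_error(init_population(1, space, seed = 1), "invalid population")
  small <- init_population(10, build_default_space(FALSE), seed = 123)
  expect_lt(abs(mean(small) - 0.5), 0.1)  # 70 uniform draws
  # clipping an in-bounds population is a no-op
  expect_identical(clip_to_bounds(p1), p1)
})

test_that("element decoding follows the span-index mapping", {
  space <- build_default_space(TRUE)
  batch <- space$spans[[2]]
  expect_equal(decode_element(0.75, batch), 36)  # index 9 of 12
  expect_equal(decode_element(0, batch), 4)
  expect_equal(decode_element(1, batch), 48)
  expect_equal(decode_element(0.33, space$spans[[1]]), "categorical hinge")
  expect_equal(decode_element(0, space$spans[[7]]), "yes")
  expect_equal(decode_element(0.5, space$spans[[3]]), 0.3)  # dropout midpoint
  expect_error(decode_element(1.2, batch), "decode domain")
  expect_error(decode_element(-0.1, batch), "decode domain")
})

test_that("discrete midpoints round-trip to their own option", {
  space <- build_default_space(TRUE)
  for (span in space$spans) {
    len <- span_length(span)
    if (is.na(len)) next
    for (k in seq_len(len)) {
      expect_identical(decode_element((k - 0.5) / len, span),
                       span$options[[k]])
    }
  }
})

test_that("full-vector decoding honors the gate and the span order", {
  space <- build_default_space(TRUE)
  zero <- decode_solution(rep(0, 15), space)
  expect_equal(zero$loss_function, "categorical cross-entropy")
  expect_equal(zero$batch_size, 4)
  expect_equal(zero$dropout, 0)
  expect_equal(zero$parameter_optimizer, "adam")
  expect_true(zero$apply_augmentation)
  expect_true(zero$augmentation$horizontal_flip)
  expect_true(zero$augmentation$vertical_flip)
  expect_equal(zero$augmentation$brightness, c(0.5, 0.5))

  v <- runif(15); v[2] <- 0.75
  expect_equal(decode_solution(v, space)$batch_size, 36)

  v_off <- rep(0.5, 15); v_off[7] <- 0.9  # gate decodes to "no"
  cfg <- decode_solution(v_off, space)
  expect_false(cfg$apply_augmentation)
  expect_null(cfg$augmentation)

  expect_error(decode_solution(rep(0.5, 7), space), "dimensionality")
})

test_that("decoded configurations satisfy their span invariants under fuzz", {
  space <- build_default_space(TRUE)
  set.seed(99)
  for (i in seq_len(1000)) {
    cfg <- decode_solution(runif(15), space)
    expect_true(cfg$loss_function %in% space$spans[[1]]$options)
    expect_true(cfg$batch_size %in% seq(4, 48, by = 4))
    expect_gte(cfg$dropout, 0); expect_lte(cfg$dropout, 0.6)
    expect_true(cfg$tl_learn_ratio %in% 1:100)
    expect_identical(is.null(cfg$augmentation), !cfg$apply_augmentation)
    if (cfg$apply_augmentation) {
      a <- cfg$augmentation
      expect_gte(a$brightness[1], 0.5)
      expect_lte(a$brightness[2], 2)
      expect_lte(a$brightness[1], a$brightness[2])
      expect_true(a$rotation_deg %in% 0:45)
    }
  }
})

test_that("bound clipping clamps, preserves and is idempotent", {
  expect_equal(clip_to_bounds(c(-0.2, 0.5, 1.3)), c(0, 0.5, 1))
  v <- c(0, 0.25, 1)
  expect_identical(clip_to_bounds(v), v)
  w <- c(-3, 0.1, 7)
  expect_identical(clip_to_bounds(clip_to_bounds(w)), clip_to_bounds(w))
})

test_that("search spaces survive a YAML round trip", {
  space <- build_default_space(TRUE)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_search_space(space, path)
  back <- read_search_space(path)
  expect_equal(back$D, space$D)
  for (i in seq_len(space$D)) {
    expect_equal(back$spans[[i]]$name, space$spans[[i]]$name)
    expect_equal(back$spans[[i]]$kind, space$spans[[i]]$kind)
    expect_equal(back$spans[[i]]$options, space$spans[[i]]$options)
  }
  v <- runif(15)
  expect_equal(decode_solution(v, back), decode_solution(v, space))
})
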