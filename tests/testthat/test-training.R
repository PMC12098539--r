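test_that("EMA update is the element-wise convex combination with endpoints", {
  m <- build_backbone(model_config(base_width = 2L, n_levels = 2L,
                                   n_scales = 1L), seed = 1L)
  teach <- semiseg:::param_values(m$params)
  stud <- lapply(teach, function(v) v + 1)
  expect_identical(ema_update(teach, stud, alpha = 1), teach)   # frozen
  up0 <- ema_update(teach, stud, alpha = 0)                     # copy
  expect_equal(up0, stud)
  # scalar case of the update rule
  expect_equal(ema_update(list(a = 1), list(a = 0), 0.99)$a, 0.99)
  up <- ema_update(teach, stud, alpha = 0.9)
  for (nm in names(up)) expect_equal(up[[nm]], 0.9 * teach[[nm]] + 0.1 * stud[[nm]])
  expect_error(ema_update(list(a = 1), list(b = 1), 0.5), "congruent")
  expect_error(ema_update(list(a = matrix(0, 2, 2)), list(a = matrix(0, 3, 3)), 0.5),
               "shape")
})

test_that("Gaussian ramp-up follows the printed formula and is monotone", {
  expect_equal(rampup_weight(100, 100), 0.001)
  expect_equal(rampup_weight(0, 100), 0.001 * exp(-5))
  expect_equal(rampup_weight(50, 100), 0.001 * exp(-5 * 0.25))
  w <- sapply(0:50, rampup_weight, t_max = 50)
  expect_true(all(diff(w) > 0))
  expect_error(rampup_weight(1, 0), "t_max")
})

test_that("threshold schedule ramps the entropy threshold between its endpoints", {
  th0 <- threshold_schedule(0, 200)
  thT <- threshold_schedule(200, 200)
  expect_equal(th0$xi_e, 0.75 * log(2))
  expect_equal(thT$xi_e, log(2))
  xs <- sapply(seq(0, 200, by = 10), function(t) threshold_schedule(t, 200)$xi_e)
  expect_true(all(diff(xs) > 0))
  expect_equal(threshold_schedule(10, 200, xi_t = 0.6)$xi_t, 0.6)
})

test_that("supervised loss: perfect and uniform predictions, toy oracle", {
  # strongly correct logits: both CE and Dice losses vanish
  lab <- random_mask(4, 4)
  logits <- array(0, c(4, 4, 2))
  logits[, , 1] <- 50 * (1 - lab); logits[, , 2] <- 50 * lab
  expect_lt(supervised_loss(logits, lab), 1e-4)
  # uniform prediction: CE component is exactly ln 2
  zl <- array(0, c(4, 4, 2))
  y <- sum(lab)
  dice_unif <- 1 - (2 * 0.5 * y + 1e-5) / (0.5 * 16 + y + 1e-5)
  expect_equal(supervised_loss(zl, lab), (log(2) + dice_unif) / 2)
  # 2x2 toy case against hand-computed (CE + Dice)/2
  set.seed(13)
  lg <- array(stats::rnorm(8), c(2, 2, 2))
  lb <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
  p <- exp(lg) / array(rep(apply(exp(lg), c(1, 2), sum), 2), dim(lg))
  ce <- -mean(ifelse(lb == 1, log(p[, , 2]), log(p[, , 1])))
  dice <- (2 * sum(p[, , 2] * lb) + 1e-5) / (sum(p[, , 2]) + sum(lb) + 1e-5)
  expect_equal(supervised_loss(lg, lb), (ce + (1 - dice)) / 2, tolerance = 1e-10)
  expect_error(supervised_loss(lg, lb + 2L), "classes")
})

test_that("a lambda = 0 step reproduces plain supervised training bit-for-bit", {
  ds <- Filter(function(s) s$has_tumor, small_dataset())
  tcfg <- train_config(epochs = 1L, lambda = 0, T_mc = 2L, seed = 3L)
  run_one <- function(unlabeled) {
    set.seed(99)
    m <- build_model(tiny_model_config(), seed = 11L)
    st <- init_train_state(m, t_max = 10L)
    res <- train_step(m, st, ds[[1]], unlabeled, tcfg, tiny_contrastive_config())
    list(params = semiseg:::param_values(m$params), res = res)
  }
  semi <- run_one(ds[[2]])
  sup <- run_one(NULL)
  expect_identical(semi$params, sup$params)
  expect_equal(semi$res$breakdown$L_csy, 0)
  expect_equal(semi$res$breakdown$L_mscl, 0)
})

test_that("the teacher is only ever moved by the EMA rule", {
  ds <- Filter(function(s) s$has_tumor, small_dataset())
  set.seed(7)
  m <- build_model(tiny_model_config(), seed = 5L)
  st <- init_train_state(m, t_max = 4L)
  # teacher starts as an exact copy of the student
  expect_identical(st$teacher, semiseg:::param_values(m$params))
  tcfg <- train_config(epochs = 1L, T_mc = 2L, seed = 3L, alpha_ema = 0.95)
  prev_teacher <- st$teacher
  res <- train_step(m, st, ds[[1]], ds[[2]], tcfg, tiny_contrastive_config())
  new_student <- semiseg:::param_values(m$params)
  expected <- ema_update(prev_teacher, new_student, 0.95)
  expect_equal(res$state$teacher, expected, tolerance = 1e-14)
})

test_that("loss identities hold at every logged step of a short run", {
  f <- smoke_fit()
  lg <- f$log
  expect_gt(nrow(lg), 4L)
  expect_equal(lg$L_u, lg$omega * (lg$L_csy + lg$L_mscl), tolerance = 1e-12)
  expect_equal(lg$L_total, lg$L_s + 1.0 * lg$L_u, tolerance = 1e-12)
  expect_true(all(lg$omega > 0 & lg$omega <= 0.001))
  expect_true(all(lg$L_s >= 0))
})

test_that("the fit harness logs per-epoch validation and is seed-reproducible", {
  f <- smoke_fit()
  expect_equal(nrow(f$history), 2L)
  expect_true(all(is.finite(f$history$val_dsc)))
  expect_equal(f$best_dsc, max(f$history$val_dsc))
  ds <- Filter(function(s) s$has_tumor, small_dataset())
  ids <- vapply(ds, function(s) s$id, character(1))
  split <- list(labeled = ids[1:2], unlabeled = ids[3:6], val = ids[7:8])
  f2 <- fit_semiseg(ds, split, tiny_model_config(),
                    train_config(epochs = 2L, T_mc = 2L, seed = 5L),
                    tiny_contrastive_config(), boundary = TRUE)
  expect_identical(f$log$L_total, f2$log$L_total)
  expect_identical(f$history, f2$history)
  expect_error(fit_semiseg(ds, list(labeled = character(0), unlabeled = ids,
                                    val = ids[1]),
                           tiny_model_config()), "labeled")
})
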