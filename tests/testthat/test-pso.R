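test_that("inertia schedules evaluate to their closed-form values", {
  w6 <- mldw_strategy("w6")
  expect_identical(inertia_weight(w6, 0), 0.9)
  expect_identical(inertia_weight(w6, 25), 0.5)
  expect_identical(inertia_weight(w6, 50), 0.4)
  w2 <- mldw_strategy("w2")
  expect_identical(inertia_weight(w2, 25), 0.8)
  ldw <- mldw_strategy("w0")
  expect_identical(inertia_weight(ldw, 50), 0.4)
  expect_identical(inertia_weight(ldw, 0), 0.9)
  expect_equal(inertia_weight(ldw, 25), (0.9 + 0.4) / 2)
  expect_identical(inertia_weight(inertia_schedule("constant"), 37), 0.9)
  expect_error(inertia_weight(w6, 51), "tmax")
  expect_error(inertia_weight(w6, -1), "tmax")
  expect_error(mldw_strategy("w9"), "unknown strategy")
})

test_that("multi-stage schedule is continuous at the stage boundaries", {
  for (nm in paste0("w", 1:6)) {
    s <- mldw_strategy(nm)
    eps <- 1e-9
    expect_equal(inertia_weight(s, s$t1 - eps), inertia_weight(s, s$t1),
                 tolerance = 1e-6)
    expect_equal(inertia_weight(s, s$t1), s$wm)
    expect_equal(inertia_weight(s, s$t2), s$wm)
    expect_equal(inertia_weight(s, s$t2 + eps), inertia_weight(s, s$t2),
                 tolerance = 1e-6)
  }
  # MLDW with plateau at the LDW midpoint approaches the LDW line as the
  # plateau shrinks to the midpoint
  mid <- (0.9 + 0.4) / 2
  s <- inertia_schedule("MLDW", wm = mid, t1 = 24.999, t2 = 25.001, tmax = 50)
  ldw <- mldw_strategy("w0")
  for (t in c(0, 10, 25, 40, 50)) {
    expect_equal(inertia_weight(s, t), inertia_weight(ldw, t), tolerance = 1e-3)
  }
})

test_that("velocity update follows the swarm equation with clamping", {
  # attraction terms vanish at the personal/global best point
  v <- update_velocity(c(0.1, -0.2), c(0.5, 0.5), c(0.5, 0.5), c(0.5, 0.5),
                       w = 0.7, r1 = c(1, 1), r2 = c(1, 1))
  expect_equal(v, 0.7 * c(0.1, -0.2))
  # hand evaluation with forced R1 = R2 = 1, w = 0, x = 0, pbest = gbest = v
  v2 <- update_velocity(c(0, 0), c(0, 0), c(0.05, -0.02), c(0.05, -0.02),
                        w = 0, r1 = c(1, 1), r2 = c(1, 1))
  expect_equal(v2, 4 * c(0.05, -0.02))
  # clamp contract
  v3 <- update_velocity(c(0, 0), c(0, 0), c(10, -10), c(10, -10),
                        w = 0, r1 = c(1, 1), r2 = c(1, 1), clamp = 0.4)
  expect_equal(v3, c(0.4, -0.4))
  # position update is plain addition and idempotent at zero velocity
  expect_equal(update_position(c(0.5), c(0.2)), 0.7)
  expect_equal(update_position(c(0.3, 0.9), c(0, 0)), c(0.3, 0.9))
})

test_that("mask decoding uses a strict threshold with a degenerate guard", {
  expect_equal(decode_mask(c(0.9, 0.8, 0.81), 0.8), c(TRUE, FALSE, TRUE))
  m <- decode_mask(c(0.1, 0.7, 0.3), 0.8)
  expect_equal(m, c(FALSE, TRUE, FALSE))  # argmax fallback, never empty
  expect_true(all(decode_mask(c(0.2, 0.5), 0)))
})

test_that("fitness is zero on separable data and at chance under the null", {
  sep <- make_separable_design(1)
  informative <- c(TRUE, TRUE, rep(FALSE, 8))
  expect_equal(fitness_error(informative, sep$x, sep$y), 0)
  # pure-noise mask scores strictly worse
  noise_mask <- !informative
  expect_gt(fitness_error(noise_mask, sep$x, sep$y), 0)
  # permutation null: mean error ~ 0.5 on balanced random labels
  set.seed(7)
  x <- matrix(rnorm(100 * 5), 100)
  y <- rep(c(1, -1), each = 50)
  errs <- vapply(1:200, function(r) {
    fitness_error(rep(TRUE, 5), x, sample(y), seed = r)
  }, numeric(1))
  expect_equal(mean(errs), 0.5, tolerance = 0.1)
  expect_error(fitness_error(rep(FALSE, 5), x, y), "no features")
  expect_error(fitness_error(rep(TRUE, 5), x, rep(1, 100)), "two classes")
})

test_that("selection history is monotone and runs are seed-deterministic", {
  dg <- make_planted_design(1, n = 40, n_features = 30)
  res <- select_features(dg$x, dg$y, schedule = mldw_strategy("w6", tmax = 8),
                         n_particles = 8, seed = 3)
  expect_false(is.unsorted(rev(res$history$gbest_fitness)))
  expect_identical(res$mask, decode_mask(res$gbest_position, res$theta))
  expect_equal(res$history$w, inertia_weight(res$schedule, 1:8))
  res2 <- select_features(dg$x, dg$y, schedule = mldw_strategy("w6", tmax = 8),
                          n_particles = 8, seed = 3)
  expect_identical(res, res2)
  res3 <- select_features(dg$x, dg$y, schedule = mldw_strategy("w6", tmax = 8),
                          n_particles = 8, seed = 4)
  expect_false(identical(res$gbest_position, res3$gbest_position))
})

test_that("swarm trajectory matches a straight-line oracle at tiny scale", {
  # independent re-implementation of the velocity/position recursion and
  # best-keeping rules, consuming the documented random stream order
  set.seed(11)
  x <- matrix(rnorm(12 * 4), 12)
  y <- rep(c(1L, -1L), each = 6)
  K <- 2; F_ <- 4; tmax <- 2; theta <- 0.8; clamp <- 0.4; folds <- 2
  seed <- 5

  oracle <- local({
    set.seed(seed)
    fold <- integer(12)
    for (cl in unique(y)) {
      idx <- which(y == cl)
      idx <- sample(idx)
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
    score <- function(pos) {
      mask <- pos > theta
      if (!any(mask)) mask[which.max(pos)] <- TRUE
      wrong <- 0
      for (f in unique(fold)) {
        tr <- fold != f
        fit <- e1071::svm(x[tr, mask, drop = FALSE], factor(y[tr]),
                          kernel = "linear", cost = 1, scale = FALSE,
                          type = "C-classification")
        wrong <- wrong + sum(predict(fit, x[!tr, mask, drop = FALSE]) != y[!tr])
      }
      wrong / length(y)
    }
    pos <- matrix(runif(K * F_, 0, 1), K, F_, byrow = TRUE)
    vel <- matrix(runif(K * F_, -0.1, 0.1), K, F_, byrow = TRUE)
    pbest <- pos
    pfit <- apply(pos, 1, score)
    g <- which.min(pfit); gbest <- pos[g, ]; gfit <- pfit[g]
    sched <- mldw_strategy("w6", tmax = 50)
    for (t in 1:tmax) {
      w <- inertia_weight(sched, t)
      for (i in 1:K) {
        r1 <- runif(F_); r2 <- runif(F_)
        v <- w * vel[i, ] + 2 * r1 * (pbest[i, ] - pos[i, ]) +
          2 * r2 * (gbest - pos[i, ])
        vel[i, ] <- pmin(pmax(v, -clamp), clamp)
        pos[i, ] <- pos[i, ] + vel[i, ]
        fit <- score(pos[i, ])
        if (fit < pfit[i]) { pfit[i] <- fit; pbest[i, ] <- pos[i, ] }
        if (fit < gfit) { gfit <- fit; gbest <- pos[i, ] }
      }
    }
    list(gbest = gbest, gfit = gfit, pos = pos, vel = vel)
  })

  sched <- mldw_strategy("w6", tmax = 50)
  sched$tmax <- 2  # evaluate the same two schedule points as the oracle
  res <- select_features(x, y, schedule = sched, n_particles = K,
                         theta = theta, inner_folds = folds, seed = seed)
  expect_equal(res$gbest_position, oracle$gbest, tolerance = 1e-12)
  expect_equal(res$gbest_fitness, oracle$gfit, tolerance = 1e-12)
})

test_that("planted informative columns are recovered above a random baseline", {
  recalls <- t(sapply(1:6, function(s) {
    dg <- make_planted_design(s)
    res <- select_features(dg$x, dg$y,
                           schedule = mldw_strategy("w6", tmax = 12),
                           n_particles = 10, seed = s)
    set.seed(s + 500)
    rnd_mask <- sample(ncol(dg$x), sum(res$mask))
    c(pso = mean(res$mask[dg$informative]),
      random = mean(dg$informative %in% rnd_mask))
  }))
  expect_gt(mean(recalls[, "pso"]), mean(recalls[, "random"]))
})

test_that("Relief keeps the requested fraction and ranks planted columns", {
  set.seed(13)
  x <- matrix(rnorm(20 * 748), 20)
  y <- rep(c(1, -1), each = 10)
  mask <- relief_select(x, y, 0.5)
  expect_equal(sum(mask), 374L)
  # strongly separated single column ranks first
  x2 <- matrix(rnorm(40 * 20), 40)
  y2 <- rep(c(1, -1), each = 20)
  x2[, 7] <- ifelse(y2 == 1, 10, -10) + rnorm(40, sd = 0.1)
  w <- attr(relief_select(x2, y2, 0.1), "weights")
  expect_equal(which.max(w), 7L)
  expect_true(all(relief_select(x2, y2, 1)))
  expect_error(relief_select(x2[1:2, ], c(1, 1), 0.5), "two classes")
})
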