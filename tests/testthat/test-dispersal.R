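test_that("movement syndrome presets match the shy-bold parameter sets", {
  shy <- movement_syndrome("shy")
  mid <- movement_syndrome("intermediate")
  bold <- movement_syndrome("bold")
  expect_equal(sapply(list(shy, mid, bold), `[[`, "p_matrix"),
               c(0.03, 0.06, 0.12))
  expect_equal(sapply(list(shy, mid, bold), `[[`, "p_corr"), rep(0.5, 3))
  expect_equal(sapply(list(shy, mid, bold), `[[`, "max_matrix_run"),
               c(10L, 20L, 40L))
})

test_that("step distribution follows the power function", {
  d <- build_step_distribution(5, 2)
  expect_equal(d$weights, c(1, 0.5625, 0.25, 0.0625, 0))
  expect_equal(d$probs, c(1, 0.5625, 0.25, 0.0625, 0) / 1.875)
  expect_equal(sum(d$probs), 1)
  # weight at s = 1 is the maximum, weight at s_max is 0 for x > 0
  d2 <- build_step_distribution(45, 11)
  expect_equal(d2$weights[1], 1)
  expect_equal(d2$weights[45], 0)
  expect_true(all(diff(d2$weights) < 0))
  expect_error(build_step_distribution(1, 2), "s_max")
})

test_that("empirical mean daily steps matches the distribution mean", {
  d <- build_step_distribution(45, 11)
  set.seed(42)
  draws <- draw_steps(d, 1e5)
  expect_lt(abs(mean(draws) - d$mean_steps) / d$mean_steps, 0.01)
})

test_that("with only matrix habitat the step choice is uniform over 9 cells", {
  g <- uniform_grid(5, 5, HABITAT[["MATRIX"]])
  ms <- movement_syndrome("shy")
  set.seed(1)
  picks <- replicate(9000, {
    s <- choose_step(c(3, 3), NA, g, ms)
    (s$row - 1) * 5 + s$col
  })
  freq <- table(picks)
  expect_equal(length(freq), 9)
  expect_true(all(abs(freq / 9000 - 1 / 9) < 0.02))
})

test_that("matrix candidates are admitted with probability p_matrix", {
  # centre row dispersal, rest matrix: 3 dispersal candidates, 6 matrix
  cl <- matrix(HABITAT[["MATRIX"]], 5, 5)
  cl[3, ] <- HABITAT[["DISPERSAL"]]
  g <- habitat_grid(cl, matrix(PATCH[["CONNECTIVITY"]], 5, 5))
  ms <- movement_syndrome("custom", p_matrix = 0.2, p_corr = 0,
                          max_matrix_run = 10)
  set.seed(2)
  n <- 2e4
  into_matrix <- replicate(n, {
    s <- choose_step(c(3, 3), NA, g, ms)
    g$classes[s$row, s$col] == HABITAT[["MATRIX"]]
  })
  # each of the 6 matrix candidates admitted w.p. 0.2 alongside 3 dispersal
  # candidates; P(matrix chosen) = E[m / (3 + m)], m ~ Binomial(6, 0.2)
  m <- 0:6
  p_m <- dbinom(m, 6, 0.2)
  expected <- sum(p_m * m / (3 + m))
  expect_lt(abs(mean(into_matrix) - expected), 0.01)
})

test_that("with p_matrix = 0 agents never enter matrix while dispersal exists", {
  cl <- matrix(HABITAT[["MATRIX"]], 9, 30)
  cl[4:6, ] <- HABITAT[["DISPERSAL"]] # corridor
  g <- habitat_grid(cl, matrix(PATCH[["CONNECTIVITY"]], 9, 30))
  ms <- movement_syndrome("custom", p_matrix = 0, p_corr = 0.5,
                          max_matrix_run = 10)
  set.seed(3)
  for (i in 1:50) {
    w <- walk_one_day(c(5, 15), g, ms, n_steps = 30)
    cls <- g$classes[w$trajectory]
    expect_true(all(cls == HABITAT[["DISPERSAL"]]))
  }
})

test_that("agents never occupy barrier cells or leave the grid", {
  cl <- matrix(HABITAT[["DISPERSAL"]], 8, 8)
  cl[cbind(c(2, 5, 7, 3), c(2, 5, 1, 8))] <- HABITAT[["BARRIER"]]
  g <- habitat_grid(cl, matrix(PATCH[["CONNECTIVITY"]], 8, 8))
  set.seed(4)
  for (i in 1:100) {
    w <- walk_one_day(c(4, 4), g, "bold", n_steps = 20)
    expect_true(all(w$trajectory[, 1] >= 1 & w$trajectory[, 1] <= 8))
    expect_true(all(w$trajectory[, 2] >= 1 & w$trajectory[, 2] <= 8))
    expect_true(all(g$classes[w$trajectory] != HABITAT[["BARRIER"]]))
  }
})

test_that("an agent on a barrier cell signals trapped", {
  cl <- matrix(HABITAT[["BARRIER"]], 3, 3)
  g <- habitat_grid(cl, matrix(PATCH[["CONNECTIVITY"]], 3, 3))
  expect_error(choose_step(c(2, 2), NA, g, "shy"), "trapped")
})

test_that("the consecutive-matrix limit bounds forays and forces return", {
  # all-matrix world (CS1-like connectivity): run counter never exceeds limit
  g <- uniform_grid(30, 30, HABITAT[["MATRIX"]])
  ms <- movement_syndrome("custom", p_matrix = 1, p_corr = 0.5,
                          max_matrix_run = 10)
  set.seed(5)
  state <- list(run = 0L, last_row = 15, last_col = 15)
  pos <- c(15, 15)
  for (day in 1:20) {
    w <- walk_one_day(pos, g, ms, state = state)
    # every trajectory point is within max_matrix_run steps of the anchor
    expect_true(all(abs(w$trajectory[, 1] - 15) <= 10))
    expect_true(all(abs(w$trajectory[, 2] - 15) <= 10))
    expect_lte(w$state$run, 10L)
    state <- w$state
    pos <- c(w$row, w$col)
  }
  # on pure dispersal habitat the counter never advances
  g2 <- uniform_grid(10, 10)
  w2 <- walk_one_day(c(5, 5), g2, "shy", n_steps = 50)
  expect_identical(w2$state$run, 0L)
})

test_that("penetration depth into pure matrix increases from shy to bold", {
  # CS1-like strip: breeding columns 1:5, matrix beyond
  cl <- matrix(HABITAT[["MATRIX"]], 21, 60)
  cl[, 1:5] <- HABITAT[["BREEDING"]]
  g <- habitat_grid(cl, matrix(PATCH[["CONNECTIVITY"]], 21, 60))
  depth <- function(ms) {
    set.seed(6)
    mean(replicate(200, {
      pos <- c(11, 5)
      state <- list(run = 0L, last_row = 11, last_col = 5)
      dmax <- 0
      for (day in 1:10) {
        w <- walk_one_day(pos, g, ms, state = state)
        dmax <- max(dmax, max(w$trajectory[, 2]) - 5)
        state <- w$state
        pos <- c(w$row, w$col)
      }
      dmax
    }))
  }
  d <- c(shy = depth("shy"), intermediate = depth("intermediate"),
         bold = depth("bold"))
  expect_true(d[["shy"]] < d[["intermediate"]],
              info = paste(round(d, 2), collapse = " "))
  expect_true(d[["intermediate"]] < d[["bold"]],
              info = paste(round(d, 2), collapse = " "))
})
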