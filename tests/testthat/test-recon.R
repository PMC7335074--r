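test_that("the toy sensitivity matrix satisfies its geometric contract", {
  p <- default_probe()
  s <- build_toy_sensitivity(p)
  expect_equal(nrow(s$a), 52)
  expect_true(all(s$a >= 0))
  expect_equal(rowSums(s$a), rep(1, 52), tolerance = 1e-12)
  # narrow kernels concentrate on the channel midpoint voxel
  s0 <- build_toy_sensitivity(p, width_scale = 0.02)
  long <- p$channels[p$channels$type == "long", ]
  for (ch in c(1, 20)) {
    v <- s0$grid[which.max(s0$a[ch, ]), ]
    expect_lt(sqrt((v$x - long$x[ch])^2 + (v$y - long$y[ch])^2), 0.5)
  }
  # channels sharing a source overlap
  shared <- which(long$source == long$source[1])
  expect_gt(sum(s$a[shared[1], ] * s$a[shared[2], ]), 0)
})

test_that("the regularized inverse matches the dense normal-equation formula", {
  set.seed(1)
  a <- matrix(abs(rnorm(8 * 50)), 8, 50)
  y <- rnorm(8)
  x <- reconstruct_map(y, a, lambda = 0.01)
  dense <- t(a) %*% solve(a %*% t(a) + 0.01 * diag(8)) %*% y
  expect_lt(max(abs(x - dense)) / max(abs(dense)), 1e-10)
  # identity operator with no regularization is exact
  expect_equal(reconstruct_map(y, diag(8), lambda = 0), y)
  expect_equal(reconstruct_map(rep(0, 8), a), rep(0, 50))
  expect_error(reconstruct_map(y[1:3], a), class = "nirsflow_config_error")
  expect_error(reconstruct_map(y, a, lambda = -1),
               class = "nirsflow_config_error")
})

test_that("regularization shrinks and vanishes in the right limits", {
  set.seed(2)
  a <- matrix(abs(rnorm(6 * 40)), 6, 40)
  y <- rnorm(6)
  norms <- sapply(c(1e-4, 1e-2, 1, 100),
                  function(l) sqrt(sum(reconstruct_map(y, a, l)^2)))
  expect_true(all(diff(norms) <= 1e-12))
  # well-conditioned square operator: lambda -> 0 recovers the exact inverse
  aq <- diag(5) + 0.1 * matrix(runif(25), 5)
  yq <- rnorm(5)
  x0 <- solve(aq, yq)
  xl <- reconstruct_map(yq, aq, lambda = 1e-12)
  expect_lt(max(abs(xl - x0)) / max(abs(x0)), 1e-6)
  # linearity in y
  y2 <- rnorm(6)
  expect_equal(reconstruct_map(2 * y + 3 * y2, a, 0.01),
               2 * reconstruct_map(y, a, 0.01) +
                 3 * reconstruct_map(y2, a, 0.01),
               tolerance = 1e-10)
})

test_that("window maps cover baseline plus consecutive 3 s windows", {
  p <- default_probe()
  sens <- build_toy_sensitivity(p)
  lag <- hrf_lag_grid(25)
  conds <- c("a", "b")
  hrf <- array(0, c(1, 52, 2, 2, length(lag)))
  hrf[1, , 1, 1, ] <- 2e-6   # constant response everywhere
  dimnames(hrf) <- list(NULL, NULL, conds, c("hbo", "hbr"), NULL)
  g <- structure(list(hrf = hrf, lag = lag,
                      channels = p$channels[p$channels$type == "long", ],
                      conditions = conds, n_subjects = 1),
                 class = "nirs_group_hrf")
  maps <- window_maps(g, sens)
  wins <- dplyr::distinct(maps[, c("window_start", "window_end")])
  expect_equal(nrow(wins), 6)
  expect_equal(wins$window_start, c(-2, 0, 3, 6, 9, 12))
  expect_equal(wins$window_end, c(0, 3, 6, 9, 12, 15))
  # a constant response reconstructs identically in every window
  ref <- reconstruct_map(rep(2e-6, 52), sens)$image$value
  for (w in 2:6) {
    v <- maps$value[maps$condition == "a" & maps$chromophore == "hbo" &
                    maps$window_start == wins$window_start[w]]
    expect_equal(v, ref, tolerance = 1e-12)
  }
})

test_that("a focal activation reconstructs near its true location", {
  p <- default_probe()
  sens <- build_toy_sensitivity(p)
  long <- p$channels[p$channels$type == "long", ]
  # activation focused at one channel's midpoint: weight channels by
  # proximity of their sensitivity kernels
  focus <- c(long$x[10], long$y[10])
  y <- exp(-((long$x - focus[1])^2 + (long$y - focus[2])^2) / (2 * 1.5^2))
  rec <- reconstruct_map(y, sens, lambda = 0.01)
  peak <- rec$image[which.max(rec$image$value), ]
  kernel_width <- 0.5 * long$separation[10]
  expect_lt(sqrt((peak$x - focus[1])^2 + (peak$y - focus[2])^2),
            kernel_width + 0.5)
})
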