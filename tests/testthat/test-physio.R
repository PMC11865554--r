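# small synthetic epoch set used across the physio tests
make_epochs <- function(n_sub = 6, n_ep = 30, n_ch = 6, n_tp = 20,
                        amplitude = 0, noise_sd = 1, pattern = 2:3,
                        window = c(400, 800), seed = 1) {
  set.seed(seed)
  nb <- channel_neighbors(n_ch)
  dat <- array(0, c(n_sub, n_ep, n_ch, n_tp))
  sur <- matrix(runif(n_sub * n_ep, 0, 4), n_sub, n_ep)
  for (s in seq_len(n_sub)) {
    e <- simulate_eeg(sur[s, ], channel_pattern = pattern,
                      time_window = window, amplitude = amplitude,
                      noise_sd = noise_sd, n_channels = n_ch,
                      n_timepoints = n_tp, neighbors = nb)
    dat[s, , , ] <- e$data
  }
  tcg_epochs(dat, sur, nb, seq(0, 1200, length.out = n_tp))
}

test_that("baseline correction removes the window mean and is idempotent", {
  ep <- make_epochs(n_sub = 2, n_ep = 4, noise_sd = 0.5)
  # constant epochs go to zero
  const <- ep
  const$data[] <- 3.7
  z <- baseline_correct(const, c(0, 100))
  expect_true(all(abs(z$data) < 1e-12))
  # idempotent
  b1 <- baseline_correct(ep, c(0, 200))
  b2 <- baseline_correct(b1, c(0, 200))
  expect_equal(b1$data, b2$data, tolerance = 1e-12)
  # linear trend: shifted by the exact window mean
  lin <- ep
  tp <- seq_along(lin$times)
  lin$data <- array(rep(tp, each = prod(dim(lin$data)[1:3])),
                    dim(lin$data))
  win <- lin$times >= 0 & lin$times <= 200
  shifted <- baseline_correct(lin, c(0, 200))
  expect_equal(shifted$data[1, 1, 1, ], tp - mean(tp[win]),
               tolerance = 1e-12)
  expect_error(baseline_correct(ep, c(-500, -400)), "empty")
})

test_that("epoch regression is exact without noise and linear in amplitude", {
  ep <- make_epochs(amplitude = 0.5, noise_sd = 0)
  betas <- epoch_regression(ep)
  win <- ep$times >= 400 & ep$times <= 800
  expect_equal(unname(betas[1, 2, win]), rep(0.5, sum(win)),
               tolerance = 1e-10)
  expect_true(all(abs(betas[, 1, ]) < 1e-10))     # untouched channel
  expect_true(all(abs(betas[, 2, !win]) < 1e-10)) # outside the window
  # doubling all surprises halves the slopes
  ep2 <- ep
  ep2$step_surprise <- ep$step_surprise * 2
  expect_equal(epoch_regression(ep2)[1, 2, win], betas[1, 2, win] / 2,
               tolerance = 1e-10)
  # zero surprise variance flags the subject
  ep3 <- ep
  ep3$step_surprise[1, ] <- 1
  b3 <- epoch_regression(ep3)
  expect_equal(attr(b3, "excluded"), 1L)
  expect_true(anyNA(b3[1, , ]))
})

test_that("cluster permutation recovers an injected effect", {
  ep <- make_epochs(n_sub = 12, n_ep = 40, amplitude = 1, noise_sd = 1,
                    seed = 3)
  betas <- epoch_regression(ep)
  set.seed(4)
  cl <- cluster_permutation_test(betas, ep$neighbors, n_perm = 300)
  expect_true(nrow(cl$clusters) >= 1)
  top <- cl$clusters[which.max(abs(cl$clusters$mass)), ]
  expect_lt(top$p, 0.05)
  expect_equal(top$sign, 1)
  # the winning cluster lies on the injected channels/window
  mask <- cluster_mask(cl)
  win <- ep$times >= 400 & ep$times <= 800
  expect_gt(sum(mask[2:3, win]), 0.5 * sum(mask))
  # observed mass equals the null sample under the identity sign-flip
  obs <- tcgsurprise:::.max_cluster_mass(cl$tmap, cl$threshold,
                                         ep$neighbors)
  expect_equal(obs, max(abs(cl$clusters$mass)), tolerance = 1e-10)
})

test_that("null epochs rarely produce significant clusters", {
  sig <- logical(12)
  for (r in seq_len(12)) {
    ep <- make_epochs(n_sub = 8, n_ep = 30, amplitude = 0, seed = 100 + r)
    betas <- epoch_regression(ep)
    cl <- cluster_permutation_test(betas, ep$neighbors, n_perm = 150)
    sig[r] <- nrow(cl$clusters) > 0 && any(cl$clusters$p < 0.05)
  }
  expect_lte(mean(sig), 0.25)
})

test_that("two-stage pupil slope test is exact without noise", {
  set.seed(6)
  sub <- rep(sprintf("P%02d", 1:8), each = 40)
  s <- runif(length(sub), 0, 4)
  pdr <- 0.1 + 0.02 * s
  res <- pdr_slope_test(pdr, s, sub)
  expect_equal(res$slope, 0.02, tolerance = 1e-12)
  expect_true(res$ci[1] <= 0.02 && res$ci[2] >= 0.02)
  # degenerate subject gets dropped with a warning
  s2 <- s; s2[sub == "P01"] <- 1
  expect_warning(res2 <- pdr_slope_test(pdr, s2, sub), "dropped")
  expect_equal(res2$dropped, "P01")
  expect_error(pdr_slope_test(1:10, 1:10, rep("a", 10)), "3 subjects")
})

test_that("per-type regression tracks the injected amplitude ordering", {
  n_sub <- 6; n_ep <- 30; n_ch <- 6; n_tp <- 20
  set.seed(8)
  nb <- channel_neighbors(n_ch)
  types <- matrix(sample(c("enter_exit", "pass_by"), n_sub * n_ep, TRUE),
                  n_sub, n_ep)
  amp <- c(enter_exit = 1, pass_by = 0.3)
  dat <- array(0, c(n_sub, n_ep, n_ch, n_tp))
  sur <- matrix(runif(n_sub * n_ep, 0.5, 4), n_sub, n_ep)
  times <- seq(0, 1200, length.out = n_tp)
  win <- times >= 400 & times <= 800
  for (s in seq_len(n_sub)) for (e in seq_len(n_ep))
    dat[s, e, 2:3, win] <- amp[[types[s, e]]] * sur[s, e]
  ep <- tcg_epochs(dat, sur, nb, times)
  mask <- matrix(FALSE, n_ch, n_tp)
  mask[2:3, win] <- TRUE
  out <- regression_by_message_type(ep, types, mask)
  expect_gt(mean(out$time_course["enter_exit", win]),
            mean(out$time_course["pass_by", win]))
  # single type reduces to the masked plain regression average
  types1 <- matrix("enter_exit", n_sub, n_ep)
  out1 <- regression_by_message_type(ep, types1, mask)
  betas <- epoch_regression(ep)
  expect_equal(unname(out1$time_course["enter_exit", ]),
               unname(apply(betas[, 2:3, , drop = FALSE], 3, mean)),
               tolerance = 1e-10)
})
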