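small_protocol <- function() {
  training_protocol(phase_steps = 2000, validation_interval = 200,
                    validation_steps = 200, test_steps = 1000,
                    sorn_interval = 500)
}

test_that("training is deterministic given the seed", {
  proto <- small_protocol()
  a <- train_rmsorn(task_spec("counting", 2), 50, proto, seed = 5)
  b <- train_rmsorn(task_spec("counting", 2), 50, proto, seed = 5)
  expect_identical(a$performance, b$performance)
  expect_identical(a$net$W_OE, b$net$W_OE)
  expect_identical(a$val_trace, b$val_trace)
  c <- train_rmsorn(task_spec("counting", 2), 50, proto, seed = 6)
  expect_false(identical(a$net$W_OE, c$net$W_OE))
})

test_that("phase 2 freezes the reservoir of the phase-1 winner", {
  proto <- small_protocol()
  fit <- train_rmsorn(task_spec("counting", 2), 50, proto, seed = 7)
  expect_identical(fit$net$W_EE, fit$net_phase1$W_EE)
  expect_identical(fit$net$T_E, fit$net_phase1$T_E)
  expect_equal(length(fit$val_trace$phase1), proto$n_snapshots)
  expect_equal(length(fit$val_trace$phase2), proto$n_snapshots)
})

test_that("the SORN baseline fits a non-negative readout per snapshot", {
  proto <- small_protocol()
  fit <- train_sorn_baseline(task_spec("counting", 2), 50, proto, seed = 8)
  expect_true(all(fit$readout >= 0))
  expect_equal(length(fit$val_trace$snapshots), 4) # 2000 / 500 candidates
  expect_true(fit$performance > 0.5)
  expect_error(train_sorn_baseline(task_spec("motion_generation", 4), 50,
                                   proto, seed = 1),
               "labeled")
})

test_that("non-negative least squares recovers a separable readout", {
  # states where each target class has its own indicator unit: a
  # non-negative combination reproduces the one-hot targets exactly
  set.seed(20)
  classes <- sample(1:3, 200, TRUE)
  x <- matrix(0, 200, 6)
  x[cbind(1:200, classes)] <- 1
  x[, 4:6] <- matrix(runif(600) < 0.2, 200, 3) # distractor units
  w <- rmsorn:::nnls_readout(x, classes, rep(FALSE, 200), 3, TRUE)
  expect_true(all(w >= 0))
  expect_equal(rmsorn:::readout_predict(w, x, TRUE), classes)
})

test_that("the static baseline permutes weights without renormalizing", {
  proto <- small_protocol()
  streams <- make_task_streams(task_spec("counting", 2), proto, 9)
  sorn <- train_sorn_baseline(task_spec("counting", 2), 50, proto, seed = 9,
                              streams = streams)
  static <- make_static_baseline(sorn, n_shuffles = 3, seed = 9,
                                 streams = streams)
  expect_equal(sort(static$net$W_EE[static$net$mask]),
               sort(sorn$net$W_EE[sorn$net$mask])) # weight multiset preserved
  expect_identical(static$net$T_E, sorn$net$T_E)   # thresholds kept
  rs <- rowSums(static$net$W_EE)
  expect_true(any(abs(rs[rs > 0] - 1) > 1e-6))     # rows no longer sum to 1
  expect_equal(length(static$val_trace$shuffles), 3)
})

test_that("the random baseline scatters the same update mass", {
  # craft one step where every excitatory neuron fires and the readout
  # reward is +1; without output SN the total readout-weight increment must
  # match between the faithful and the scattered update
  ne <- 20
  net <- blank_network(ne, no = 3, wta = TRUE)
  net$mask <- matrix(TRUE, ne, ne); diag(net$mask) <- FALSE
  net$T_E <- rep(-1, ne) # everything fires
  net$x <- rep(1L, ne)
  net$W_OE <- matrix(1 / ne, 3, ne)
  net$T_O <- c(0, 0.5, 0.5)
  task <- task_spec("counting", 2)
  task$encoding <- matrix(0, ne, 6, dimnames = list(NULL, task$alphabet))
  pl <- plasticity_config(mu_ip_output = task$mu_ip_output, sn_output = FALSE)
  cfg_n <- rmsorn:::engine_cfg(plastic_rec = FALSE, plastic_out = TRUE,
                               plasticity = pl, task = task,
                               wrong_reward = 0)
  cfg_r <- rmsorn:::engine_cfg(plastic_rec = FALSE, plastic_out = TRUE,
                               plasticity = pl, task = task,
                               wrong_reward = 0, random_baseline = TRUE)
  # target "a" = output 1, the WTA winner given T_O
  inp <- 1L; tgt <- 1L
  normal <- rmsorn:::run_engine(net, rmsorn:::fresh_state(), cfg_n, inp, tgt,
                                FALSE, task$encoding)
  set.seed(1)
  random <- rmsorn:::run_engine(net, rmsorn:::fresh_state(), cfg_r, inp, tgt,
                                FALSE, task$encoding)
  d_normal <- sum(normal$net$W_OE) - sum(net$W_OE)
  d_random <- sum(random$net$W_OE) - sum(net$W_OE)
  expect_gt(d_normal, 0)
  expect_equal(d_random, d_normal)
  expect_false(identical(random$net$W_OE, normal$net$W_OE))
})

test_that("bit-flip noise changes the winner at the configured frequency", {
  task <- task_spec("memory_capacity", 1)
  task$encoding <- make_encoding(task, 50, seed = 30)
  net <- init_network(50, 6, seed = 30)
  stream <- generate_stream(task, 4000, seed = 31)
  codes <- rmsorn:::stream_codes(task, stream)
  base_cfg <- rmsorn:::engine_cfg(task = task)
  clean <- rmsorn:::run_engine(unclass(net), rmsorn:::fresh_state(), base_cfg,
                               codes$inputs, codes$targets, codes$excluded,
                               task$encoding)
  noisy_cfg <- rmsorn:::engine_cfg(task = task, noise_prob = 0.15)
  set.seed(32)
  noisy <- rmsorn:::run_engine(unclass(net), rmsorn:::fresh_state(),
                               noisy_cfg, codes$inputs, codes$targets,
                               codes$excluded, task$encoding)
  flip_rate <- mean(noisy$pred != clean$pred)
  expect_lt(abs(flip_rate - 0.15), 3 * sqrt(0.15 * 0.85 / 4000))
  # zero noise is bit-identical to the deterministic run
  zero <- rmsorn:::run_engine(unclass(net), rmsorn:::fresh_state(),
                              rmsorn:::engine_cfg(task = task,
                                                  noise_prob = 0),
                              codes$inputs, codes$targets, codes$excluded,
                              task$encoding)
  expect_identical(zero$pred, clean$pred)
})

test_that("noise mode calibrates and freezes the readout thresholds", {
  proto <- small_protocol()
  nm <- noise_exploration_mode(task_spec("counting", 2), 50, proto,
                               noise_prob = 0.05, seed = 11,
                               calibration_steps = 2000, average_last = 500)
  expect_false(nm$plasticity$ip_output)
  expect_equal(length(nm$net$T_O), 6)
  init <- init_network(50, 6, seed = 11)
  expect_false(identical(nm$net$T_O, init$T_O)) # calibrated averages
  expect_identical(nm$net$W_EE, init$W_EE)      # otherwise the initial state
  expect_error(noise_exploration_mode(task_spec("counting", 2), 50, proto,
                                      noise_prob = 2, seed = 1),
               "noise_prob")
})

test_that("grid search enumerates cells and honors the m0 tie-break", {
  proto <- training_protocol(phase_steps = 400, validation_interval = 200,
                             validation_steps = 100, test_steps = 200,
                             sorn_interval = 200)
  one <- data.frame(strategy = "mk", k = 5, wrong_reward = 0,
                    mu_ip_recurrent = 0.1, stringsAsFactors = FALSE)
  res <- grid_search(task_spec("counting", 2), 40, proto, grid = one,
                     runs_per_cell = 1, seed = 3)
  expect_equal(nrow(res$table), 1)
  expect_equal(res$best$strategy, "mk")

  konly <- data.frame(strategy = "mk", k = c(1, 5, 10, 20), wrong_reward = 0,
                      mu_ip_recurrent = 0.1, stringsAsFactors = FALSE)
  res_k <- grid_search(task_spec("counting", 2), 40, proto, grid = konly,
                       runs_per_cell = 1, seed = 3)
  expect_equal(nrow(res_k$table), 4)

  # equal-scoring cells resolve toward the direct strategy
  tie <- data.frame(strategy = c("mk", "m0"), k = c(5, 1),
                    wrong_reward = c(0, 0), mu_ip_recurrent = c(0.1, 0.1),
                    stringsAsFactors = FALSE)
  res_tie <- grid_search(task_spec("memory_capacity", 0), 40, proto,
                         grid = tie, runs_per_cell = 1, seed = 3)
  if (abs(diff(res_tie$table$mean_performance)) < 1e-12) {
    expect_equal(res_tie$best$strategy, "m0")
  }
  expect_true(res_tie$best$mean_performance ==
                max(res_tie$table$mean_performance))
})
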