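#' Training protocol
#'
#' Lengths and cadences of the two-phase reward-modulated training protocol:
#' each phase processes `phase_steps` of training data, validating the
#' network every `validation_interval` steps on `validation_steps` of
#' validation data; the snapshot with the best validation performance enters
#' the next stage. Supervised (SORN) baselines snapshot every
#' `sorn_interval` steps instead, and static baselines evaluate `n_shuffles`
#' weight shuffles.
#'
#' @param phase_steps training steps per phase.
#' @param validation_interval steps between validations.
#' @param validation_steps length of the validation stream.
#' @param test_steps length of the test stream (or of the generated test
#'   sequence).
#' @param sorn_interval snapshot interval of the SORN baseline.
#' @param n_shuffles weight shuffles evaluated for the static baseline.
#' @return a list of class `rmsorn_protocol`.
#' @export
training_protocol <- function(phase_steps = 20000, validation_interval = 100,
                              validation_steps = 500, test_steps = 10000,
                              sorn_interval = 1000, n_shuffles = 20) {
  stopifnot(phase_steps %% validation_interval == 0,
            phase_steps %% sorn_interval == 0)
  structure(
    list(phase_steps = as.integer(phase_steps),
         validation_interval = as.integer(validation_interval),
         validation_steps = as.integer(validation_steps),
         test_steps = as.integer(test_steps),
         sorn_interval = as.integer(sorn_interval),
         n_snapshots = as.integer(phase_steps / validation_interval),
         n_shuffles = as.integer(n_shuffles)),
    class = "rmsorn_protocol"
  )
}

#' Per-task reward-modulation defaults
#'
#' Modulation strategy, moving-average window, wrong-output reward and
#' reservoir firing-rate target used by default for each task. The values
#' were fixed once by the package's parameter grid search ([grid_search()]):
#' direct reward modulation for the counting and pattern-recognition tasks,
#' reward-prediction-error modulation elsewhere; recurrent-layer modulation
#' only for pattern recognition, the one task where ignoring non-target
#' input conditions pays off.
#'
#' @param name task name.
#' @return list with `strategy`, `k`, `wrong_reward`, `mu_ip_recurrent` and
#'   `modulate_recurrent`.
#' @export
task_defaults <- function(name) {
  base <- list(strategy = "mk", k = 5L, wrong_reward = 0,
               mu_ip_recurrent = 0.1, modulate_recurrent = FALSE,
               eta_ip = 0.01, eta_stdp = 0.004, eta_ip_output = 0.001)
  tweaks <- list(
    counting            = list(strategy = "m0", k = 1L, wrong_reward = -1),
    motion_prediction   = list(wrong_reward = -1),
    occluder            = list(wrong_reward = -1, mu_ip_recurrent = 0.05),
    memory_capacity     = list(),
    markov85            = list(),
    parity              = list(),
    motion_generation   = list(),
    pattern_recognition = list(wrong_reward = -1, mu_ip_recurrent = 0.05,
                               modulate_recurrent = TRUE, eta_ip = 5e-4,
                               eta_stdp = 0.01)
  )
  tw <- tweaks[[name]]
  if (is.null(tw)) stop(sprintf("unknown task '%s'", name))
  utils::modifyList(base, tw)
}

default_plasticity <- function(task) {
  d <- task_defaults(task$name)
  plasticity_config(eta_ip = d$eta_ip, eta_stdp = d$eta_stdp,
                    eta_ip_output = d$eta_ip_output,
                    mu_ip_recurrent = d$mu_ip_recurrent,
                    mu_ip_output = task$mu_ip_output,
                    modulate_recurrent = d$modulate_recurrent)
}

#' Generate the train/validation/test streams of one data set
#'
#' Derives three sub-seeds from `seed` so the streams are independent but
#' fully reproducible; the symbol-to-unit encoding of a data set uses `seed`
#' itself.
#'
#' @param task an `rmsorn_task`.
#' @param protocol an `rmsorn_protocol`.
#' @param seed data-set seed.
#' @return list with `train`, `val`, `test` streams (all `NULL` for the
#'   generation task) and `encoding_seed`.
#' @export
make_task_streams <- function(task, protocol, seed) {
  list(train = generate_stream(task, protocol$phase_steps, seed * 7L + 1L),
       val = generate_stream(task, protocol$validation_steps, seed * 7L + 2L),
       test = generate_stream(task, protocol$test_steps, seed * 7L + 3L),
       encoding_seed = seed)
}

# One training phase: alternate plastic blocks with frozen validations and
# return the snapshot with the best validation performance.
run_training_phase <- function(net, task, phase, protocol, plasticity,
                               modulation, streams, wrong_reward,
                               noise_prob = 0, random_baseline = FALSE,
                               record_outputs = FALSE) {
  is_gen <- task$name == "motion_generation"
  vi <- protocol$validation_interval
  n_blocks <- protocol$phase_steps / vi
  if (is_gen) {
    inputs <- rep(NA_integer_, protocol$phase_steps)
    targets <- rep(0L, protocol$phase_steps)
    excluded <- rep(FALSE, protocol$phase_steps)
  } else {
    codes <- stream_codes(task, streams$train)
    inputs <- codes$inputs
    targets <- codes$targets
    excluded <- codes$excluded
  }
  cfg <- engine_cfg(plastic_rec = phase == 1, plastic_out = TRUE,
                    plasticity = plasticity, modulation = modulation,
                    task = task, is_generation = is_gen,
                    random_baseline = random_baseline,
                    noise_prob = noise_prob, wrong_reward = wrong_reward)
  state <- fresh_state()
  best <- NULL
  best_perf <- -Inf
  trace <- numeric(n_blocks)
  outputs <- if (record_outputs) character(0) else NULL
  for (b in seq_len(n_blocks)) {
    ix <- ((b - 1) * vi + 1):(b * vi)
    res <- run_engine(net, state, cfg, inputs[ix], targets[ix], excluded[ix],
                      task$encoding)
    net <- res$net
    state <- res$state
    if (record_outputs) outputs <- c(outputs, pred_to_symbols(task, res$pred))
    val <- evaluate_network(net, task, stream = streams$val,
                            steps = protocol$validation_steps,
                            encoding = task$encoding)
    trace[b] <- val$performance
    if (val$performance > best_perf) {
      best_perf <- val$performance
      best <- net
    }
  }
  list(best = best, best_perf = best_perf, trace = trace, final = net,
       outputs = outputs)
}

#' Train an RM-SORN network
#'
#' Runs the full two-phase protocol: phase 1 trains with all plasticity
#' active (reservoir STDP modulated only if the configuration says so),
#' snapshotting every validation interval; the snapshot with the best
#' validation performance enters phase 2, where the reservoir is frozen and
#' only the readout keeps learning. The best phase-2 snapshot is scored on a
#' fresh test stream, or generates `test_steps` symbols for the generation
#' task.
#'
#' @param task an `rmsorn_task`, or a task name.
#' @param n_excitatory reservoir size `N`.
#' @param protocol an `rmsorn_protocol`.
#' @param plasticity an `rmsorn_plasticity`; by default built from the task's
#'   defaults ([task_defaults()]) with the readout rate targets set to the
#'   task's symbol frequencies.
#' @param modulation an `rmsorn_modulation`; defaults per task.
#' @param wrong_reward reward for wrong outputs (0 or -1); defaults per task.
#' @param seed integer seed controlling network initialization and, when no
#'   `streams` are passed, the data streams.
#' @param net optionally a pre-built `rmsorn_network` (e.g. from
#'   [noise_exploration_mode()]).
#' @param streams optionally pre-generated streams from
#'   [make_task_streams()], so several networks can share one data set.
#' @param noise_prob bit-flip probability of the readout winner (noise
#'   exploration mode; 0 for the deterministic model).
#' @param random_baseline if `TRUE`, every STDP update's values are
#'   redistributed across random eligible weights (the "lucky guessing"
#'   control).
#' @param record_outputs keep the phase-1 output symbol history (for
#'   exploration analysis).
#' @return a list of class `rmsorn_fit`: the best network (`net`), test
#'   `performance` and `counting_performance`, per-phase validation traces,
#'   and the resolved configuration.
#' @export
train_rmsorn <- function(task, n_excitatory = 100,
                         protocol = training_protocol(), plasticity = NULL,
                         modulation = NULL, wrong_reward = NULL, seed = 1,
                         net = NULL, streams = NULL, noise_prob = 0,
                         random_baseline = FALSE, record_outputs = FALSE) {
  if (is.character(task)) task <- task_spec(task)
  defaults <- task_defaults(task$name)
  if (is.null(plasticity)) plasticity <- default_plasticity(task)
  if (is.null(plasticity$mu_ip_output)) {
    plasticity$mu_ip_output <- task$mu_ip_output
  }
  if (is.null(modulation)) {
    modulation <- make_modulation(defaults$strategy, defaults$k)
  }
  if (is.null(wrong_reward)) wrong_reward <- defaults$wrong_reward
  if (is.null(streams)) streams <- make_task_streams(task, protocol, seed)
  if (is.null(task$encoding) && task$name != "motion_generation") {
    task$encoding <- make_encoding(task, n_excitatory,
                                   seed = streams$encoding_seed)
  }
  if (task$name == "motion_generation") {
    # feedback enters through the same symbol-to-unit encoding as input would
    task$encoding <- make_encoding(task, n_excitatory,
                                   seed = streams$encoding_seed)
  }
  if (is.null(net)) {
    net <- init_network(n_excitatory, task$n_outputs, seed = seed)
  }

  p1 <- with_seed(seed * 13L + 5L, run_training_phase(
    unclass(net), task, 1, protocol, plasticity, modulation, streams,
    wrong_reward, noise_prob, random_baseline, record_outputs
  ))
  p2 <- with_seed(seed * 13L + 6L, run_training_phase(
    p1$best, task, 2, protocol, plasticity, modulation, streams,
    wrong_reward, noise_prob, random_baseline, FALSE
  ))
  test <- evaluate_network(p2$best, task, stream = streams$test,
                           steps = protocol$test_steps,
                           encoding = task$encoding)
  if (any(!is.finite(unlist(p2$best[c("W_EE", "W_OE", "T_E", "T_O")])))) {
    stop("non-finite weights or thresholds: runaway learning rate")
  }
  best_net <- p2$best
  class(best_net) <- "rmsorn_network"
  structure(
    list(net = best_net, net_phase1 = p1$best, task = task,
         performance = test$performance,
         counting_performance = test$counting_performance,
         val_trace = list(phase1 = p1$trace, phase2 = p2$trace),
         phase1_outputs = p1$outputs, seed = seed, plasticity = plasticity,
         modulation = modulation, wrong_reward = wrong_reward,
         noise_prob = noise_prob, random_baseline = random_baseline,
         protocol = protocol, n_excitatory = n_excitatory),
    class = "rmsorn_fit"
  )
}

#' @export
print.rmsorn_fit <- function(x, ...) {
  cat(sprintf("RM-SORN fit: task %s (n = %d), N = %d\n",
              x$task$name, x$task$n, x$n_excitatory))
  cat(sprintf("  test performance: %.4f\n", x$performance))
  if (!is.na(x$counting_performance)) {
    cat(sprintf("  counting performance: %.4f\n", x$counting_performance))
  }
  invisible(x)
}

#' Train the random-update baseline
#'
#' Identical to [train_rmsorn()] except that at every step the multiset of
#' nonzero STDP update values is reassigned to uniformly random eligible
#' weights before application. The gap between RM-SORN and this control is
#' the gap between reward-modulated STDP and lucky guessing.
#'
#' @inheritParams train_rmsorn
#' @param ... passed on to [train_rmsorn()].
#' @return an `rmsorn_fit`.
#' @export
train_random_baseline <- function(task, ...) {
  train_rmsorn(task, ..., random_baseline = TRUE)
}

#' Configure the noise-exploration mode
#'
#' Replaces intrinsic plasticity in the readout by bit-flip noise: readout
#' IP is disabled and, at each training step with probability `noise_prob`,
#' the active output neuron is silenced and another randomly chosen output
#' neuron activated. To align the average firing rates of the two
#' exploration modes, the readout thresholds are first calibrated: a
#' preliminary run with plain (unmodulated) plasticity is made and the
#' thresholds averaged over its last `average_last` steps; the returned
#' network is the initial network with those averages as frozen thresholds.
#'
#' @inheritParams train_rmsorn
#' @param noise_prob bit-flip probability (the canonical levels are 0.05,
#'   0.15 and 1).
#' @param calibration_steps length of the preliminary run.
#' @param average_last steps over which the thresholds are averaged.
#' @return list with the calibrated `net`, the adjusted `plasticity`
#'   configuration (`ip_output = FALSE`) and `noise_prob`; pass these to
#'   [train_rmsorn()] together with the same `task`, `streams` and `seed`.
#' @export
noise_exploration_mode <- function(task, n_excitatory = 100,
                                   protocol = training_protocol(),
                                   plasticity = NULL, noise_prob = 0.05,
                                   seed = 1, streams = NULL,
                                   calibration_steps = 20000,
                                   average_last = 1000) {
  if (noise_prob < 0 || noise_prob > 1) stop("noise_prob outside [0, 1]")
  if (is.character(task)) task <- task_spec(task)
  defaults <- task_defaults(task$name)
  if (is.null(plasticity)) {
    plasticity <- plasticity_config(
      mu_ip_recurrent = defaults$mu_ip_recurrent,
      mu_ip_output = task$mu_ip_output,
      modulate_recurrent = defaults$modulate_recurrent
    )
  }
  if (is.null(streams)) streams <- make_task_streams(task, protocol, seed)
  is_gen <- task$name == "motion_generation"
  task$encoding <- make_encoding(task, n_excitatory,
                                 seed = streams$encoding_seed)
  net <- init_network(n_excitatory, task$n_outputs, seed = seed)

  if (is_gen) {
    inputs <- rep(NA_integer_, calibration_steps)
    targets <- rep(0L, calibration_steps)
    excluded <- rep(FALSE, calibration_steps)
  } else {
    tr <- generate_stream(task, calibration_steps, streams$encoding_seed * 7L + 1L)
    codes <- stream_codes(task, tr)
    inputs <- codes$inputs
    targets <- codes$targets
    excluded <- codes$excluded
  }
  cfg <- engine_cfg(plastic_rec = TRUE, plastic_out = TRUE,
                    plasticity = plasticity, task = task,
                    is_generation = is_gen, unmodulated = TRUE,
                    record_thresholds = TRUE)
  res <- run_engine(unclass(net), fresh_state(), cfg, inputs, targets,
                    excluded, task$encoding)
  to_hist <- res$threshold_history
  last <- (nrow(to_hist) - average_last + 1):nrow(to_hist)
  net$T_O <- colMeans(to_hist[last, , drop = FALSE])
  plasticity$ip_output <- FALSE
  list(net = net, plasticity = plasticity, noise_prob = noise_prob,
       task = task, streams = streams)
}

#' Parameter grid search
#'
#' Exhaustively evaluates combinations of modulation strategy, window `k`,
#' wrong-output reward and reservoir rate target, and returns the cell with
#' the best mean validation performance (ties broken toward the simpler
#' direct strategy `m0`).
#'
#' @inheritParams train_rmsorn
#' @param grid data frame with columns `strategy`, `k`, `wrong_reward`,
#'   `mu_ip_recurrent`; by default the canonical grid.
#' @param runs_per_cell training runs averaged per cell.
#' @return list with `best` (one-row data frame) and `table` (all cells with
#'   their mean performance).
#' @export
grid_search <- function(task, n_excitatory = 100,
                        protocol = training_protocol(), grid = NULL,
                        runs_per_cell = 2, seed = 1) {
  if (is.character(task)) task <- task_spec(task)
  if (is.null(grid)) {
    grid <- expand.grid(strategy = c("m0", "mk"), k = c(1, 5, 10, 20),
                        wrong_reward = c(0, -1),
                        mu_ip_recurrent = c(0.05, 0.1, 0.15, 0.2, 0.25),
                        stringsAsFactors = FALSE)
    grid <- grid[grid$strategy == "mk" | grid$k == 1, ]
  }
  grid <- grid[order(grid$strategy != "m0"), , drop = FALSE] # m0 first: tie-break
  score <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    perfs <- vapply(seq_len(runs_per_cell), function(r) {
      pl <- default_plasticity(task)
      pl$mu_ip_recurrent <- g$mu_ip_recurrent
      fit <- train_rmsorn(task, n_excitatory, protocol, plasticity = pl,
                          modulation = make_modulation(g$strategy, g$k),
                          wrong_reward = g$wrong_reward,
                          seed = seed + 97L * r)
      max(fit$val_trace$phase2)
    }, numeric(1))
    score[i] <- mean(perfs)
  }
  grid$mean_performance <- score
  list(best = grid[which.max(score), , drop = FALSE], table = grid)
}
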