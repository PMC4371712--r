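# Supervised comparison models: SORN (plastic reservoir + readout fitted by
# non-negative least squares) and the static control (shuffled reservoir
# weights, readout refitted).

# Fit non-negative readout weights mapping reservoir states to one-hot
# targets. The least-squares problem is compressed through the Cholesky
# factor of the Gram matrix, so the active-set solver works on an
# n_excitatory-sized system regardless of stream length; the solution is
# identical to solving on the raw state matrix.
nnls_readout <- function(x_states, target_codes, excluded, n_outputs, wta) {
  keep <- !excluded
  x <- x_states[keep, , drop = FALSE]
  ne <- ncol(x)
  g <- crossprod(x) + diag(1e-8, ne)
  r <- chol(g)
  if (wta) {
    y <- matrix(0, nrow(x), n_outputs)
    y[cbind(seq_len(nrow(x)), target_codes[keep])] <- 1
  } else {
    y <- matrix(as.numeric(target_codes[keep]), ncol = 1)
  }
  b <- crossprod(x, y)
  w <- matrix(0, n_outputs, ne)
  for (i in seq_len(ncol(y))) {
    f <- forwardsolve(t(r), b[, i])
    w[i, ] <- pracma::lsqnonneg(r, f)$x
  }
  w
}

# Readout prediction codes from recorded states: argmax for WTA readouts,
# >= 0.5 for a single binary readout.
readout_predict <- function(w, x_states, wta) {
  drive <- x_states %*% t(w)
  if (wta) {
    max.col(drive, ties.method = "first")
  } else {
    as.integer(drive[, 1] >= 0.5)
  }
}

# Run the frozen network over a stream, recording reservoir states, and
# score a fitted readout on them.
score_readout <- function(net, task, stream, w) {
  codes <- stream_codes(task, stream)
  cfg <- engine_cfg(task = task, update_output = FALSE, record_x = TRUE)
  res <- run_engine(net, fresh_state(), cfg, codes$inputs, codes$targets,
                    codes$excluded, task$encoding)
  pred <- pred_to_symbols(task, readout_predict(w, res$x_history, task$wta))
  cperf <- if (!is.null(stream$final) && any(stream$final)) {
    counting_performance(pred, stream$targets, stream$final)
  } else NA_real_
  list(performance = performance(pred, stream$targets, stream$excluded),
       counting_performance = cperf, net = res$net)
}

# Harvest states on the training stream from the frozen network, fit the
# non-negative readout, then validate on the validation stream (processed as
# a continuation of the training stream).
fit_and_validate <- function(net, task, streams) {
  codes <- stream_codes(task, streams$train)
  cfg <- engine_cfg(task = task, update_output = FALSE, record_x = TRUE)
  res <- run_engine(net, fresh_state(), cfg, codes$inputs, codes$targets,
                    codes$excluded, task$encoding)
  w <- nnls_readout(res$x_history, codes$targets, codes$excluded,
                    task$n_outputs, task$wta)
  val <- score_readout(res$net, task, streams$val, w)
  list(w = w, val_perf = val$performance, harvested_net = res$net)
}

#' Train the SORN comparison baseline
#'
#' The reservoir runs with unmodulated plasticity (plain STDP, synaptic
#' normalization, intrinsic plasticity; no readout layer). Every
#' `sorn_interval` steps the weights are frozen, the frozen network processes
#' the whole training stream, and readout weights are fitted to the resulting
#' states by non-negative least squares (mirroring the positivity of the
#' plastic model's weights). The intermediary network with the best
#' validation performance is scored on the test stream.
#'
#' @inheritParams train_rmsorn
#' @return a list of class `rmsorn_fit` with the extra field `readout` (the
#'   fitted weight matrix) and `snapshot` (index of the selected candidate).
#' @export
train_sorn_baseline <- function(task, n_excitatory = 100,
                                protocol = training_protocol(),
                                plasticity = NULL, seed = 1,
                                streams = NULL) {
  if (is.character(task)) task <- task_spec(task)
  if (task$name == "motion_generation") {
    stop("supervised baselines are defined for the tasks with labeled streams")
  }
  if (is.null(plasticity)) {
    plasticity <- default_plasticity(task)
    plasticity$modulate_recurrent <- FALSE # SORN reservoir is unmodulated
  }
  if (is.null(streams)) streams <- make_task_streams(task, protocol, seed)
  if (is.null(task$encoding)) {
    task$encoding <- make_encoding(task, n_excitatory,
                                   seed = streams$encoding_seed)
  }
  net <- unclass(init_network(n_excitatory, task$n_outputs, seed = seed))

  codes <- stream_codes(task, streams$train)
  cfg <- engine_cfg(plastic_rec = TRUE, update_output = FALSE,
                    plasticity = plasticity, task = task)
  vi <- protocol$sorn_interval
  n_snap <- protocol$phase_steps / vi
  state <- fresh_state()
  best <- NULL
  best_perf <- -Inf
  best_k <- NA_integer_
  trace <- numeric(n_snap)
  for (k in seq_len(n_snap)) {
    ix <- ((k - 1) * vi + 1):(k * vi)
    res <- run_engine(net, state, cfg, codes$inputs[ix], codes$targets[ix],
                      codes$excluded[ix], task$encoding)
    net <- res$net
    state <- res$state
    cand <- fit_and_validate(net, task, streams)
    trace[k] <- cand$val_perf
    if (cand$val_perf > best_perf) {
      best_perf <- cand$val_perf
      best <- list(net = net, w = cand$w, harvested = cand$harvested_net)
      best_k <- k
    }
  }
  test <- score_readout(best$harvested, task, streams$test, best$w)
  structure(
    list(net = best$net, readout = best$w, task = task,
         performance = test$performance,
         counting_performance = test$counting_performance,
         val_trace = list(snapshots = trace), snapshot = best_k, seed = seed,
         plasticity = plasticity, protocol = protocol,
         n_excitatory = n_excitatory, variant = "sorn"),
    class = "rmsorn_fit"
  )
}

#' Build the static (shuffled-weight) baseline
#'
#' Takes a trained SORN baseline, permutes the nonzero reservoir weights
#' across the eligibility mask `n_shuffles` times (thresholds kept, no
#' re-normalization — the static network is non-plastic), refits the
#' non-negative readout for each shuffle and keeps the shuffle with the best
#' validation performance.
#'
#' @param sorn_fit an `rmsorn_fit` from [train_sorn_baseline()].
#' @param n_shuffles number of weight shuffles evaluated (20 by default,
#'   200 for pattern recognition to match the candidate count of the plastic
#'   model).
#' @param seed integer seed for the permutations.
#' @param streams the data set used to train `sorn_fit`.
#' @return an `rmsorn_fit` for the best static network.
#' @export
make_static_baseline <- function(sorn_fit, n_shuffles = 20, seed = 1,
                                 streams = NULL) {
  task <- sorn_fit$task
  protocol <- sorn_fit$protocol
  if (is.null(streams)) streams <- make_task_streams(task, protocol, sorn_fit$seed)
  src <- sorn_fit$net
  maskpos <- which(src$mask)
  vals <- src$W_EE[maskpos]
  best <- NULL
  best_perf <- -Inf
  trace <- numeric(n_shuffles)
  with_seed(seed, {
    for (s in seq_len(n_shuffles)) {
      net <- src
      net$W_EE[maskpos] <- vals[sample(length(vals))]
      cand <- fit_and_validate(net, task, streams)
      trace[s] <- cand$val_perf
      if (cand$val_perf > best_perf) {
        best_perf <- cand$val_perf
        best <- list(net = net, w = cand$w, harvested = cand$harvested_net)
      }
    }
  })
  test <- score_readout(best$harvested, task, streams$test, best$w)
  structure(
    list(net = best$net, readout = best$w, task = task,
         performance = test$performance,
         counting_performance = test$counting_performance,
         val_trace = list(shuffles = trace), seed = seed,
         protocol = protocol, n_excitatory = src$n_excitatory,
         variant = "static"),
    class = "rmsorn_fit"
  )
}
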