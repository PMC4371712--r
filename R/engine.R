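# R-side interface to the compiled simulation core. The compiled loop
# replicates, step for step, the composition of step_recurrent(),
# step_output(), the reward/modulation rules and plasticity_step(); the pure
# R functions remain the reference implementation and the test oracle.

fresh_state <- function() {
  list(history = numeric(0), tail = integer(0), last_out = 0L)
}

engine_cfg <- function(plastic_rec = FALSE, plastic_out = FALSE,
                       update_output = TRUE, plasticity = NULL,
                       modulation = NULL, task = NULL,
                       is_generation = FALSE, random_baseline = FALSE,
                       noise_prob = 0, wrong_reward = 0,
                       gen_punishment = NULL, record_x = FALSE,
                       record_thresholds = FALSE, unmodulated = FALSE) {
  if (is.null(plasticity)) plasticity <- plasticity_config()
  mu_out <- plasticity$mu_ip_output
  if (is.null(mu_out) && !is.null(task)) mu_out <- task$mu_ip_output
  if (is.null(mu_out)) mu_out <- 0.1
  n <- if (!is.null(task)) task$n else 0L
  if (is.null(gen_punishment)) gen_punishment <- if (n > 0) 1 / n else 0
  strategy <- 0L
  k <- 1L
  if (!is.null(modulation)) {
    strategy <- if (modulation$strategy == "mk") 1L else 0L
    k <- modulation$k
  }
  list(plastic_rec = plastic_rec, plastic_out = plastic_out,
       update_output = update_output, ip_output = plasticity$ip_output,
       sn_output = plasticity$sn_output,
       modulate_recurrent = plasticity$modulate_recurrent,
       is_generation = is_generation, random_baseline = random_baseline,
       record_x = record_x, record_thresholds = record_thresholds,
       eta_stdp = plasticity$eta_stdp, eta_ip = plasticity$eta_ip,
       eta_ip_out = if (is.null(plasticity$eta_ip_output)) plasticity$eta_ip else plasticity$eta_ip_output,
       mu_ip_rec = plasticity$mu_ip_recurrent,
       mu_ip_out = as.numeric(mu_out),
       strategy = strategy, k = as.integer(k),
       wrong_reward = as.numeric(wrong_reward),
       gen_punishment = as.numeric(gen_punishment),
       noise_prob = as.numeric(noise_prob), unmodulated = unmodulated)
}

# Convert a labeled stream into the integer encoding the compiled core uses:
# input symbol indices into the task alphabet and, for supervised reward,
# the readout code of each target (neuron index for WTA, 0/1 for Heaviside).
stream_codes <- function(task, stream) {
  inputs <- match(stream$inputs, task$alphabet)
  if (anyNA(inputs)) stop("stream contains symbols outside the task alphabet")
  t_idx <- match(stream$targets, task$out_alphabet)
  targets <- if (task$wta) t_idx else t_idx - 1L
  list(inputs = as.integer(inputs), targets = as.integer(targets),
       excluded = stream$excluded)
}

# Map readout codes returned by the core back to output-alphabet symbols.
pred_to_symbols <- function(task, pred) {
  if (task$wta) task$out_alphabet[pred] else task$out_alphabet[pred + 1L]
}

run_engine <- function(net, state, cfg, inputs, targets, excluded, encoding) {
  cpp_sim(unclass(net), state, cfg, as.integer(inputs), as.integer(targets),
          as.logical(excluded), encoding)
}

# Run the network over a stream (or freely for the generation task) with all
# plasticity off, and score it. The caller's network is untouched.
evaluate_network <- function(net, task, stream = NULL, steps = NULL,
                             encoding = NULL, record_x = FALSE) {
  if (is.null(encoding)) encoding <- task$encoding
  is_gen <- task$name == "motion_generation"
  if (is_gen) {
    if (is.null(steps)) stop("generation evaluation needs a step count")
    cfg <- engine_cfg(task = task, is_generation = TRUE, record_x = record_x)
    res <- run_engine(net, fresh_state(), cfg, rep(NA_integer_, steps),
                      rep(0L, steps), rep(FALSE, steps), encoding)
    out <- pred_to_symbols(task, res$pred)
    return(list(performance = generation_performance(out, task$target_words),
                counting_performance = NA_real_, outputs = out,
                x_history = res$x_history))
  }
  codes <- stream_codes(task, stream)
  cfg <- engine_cfg(task = task, record_x = record_x)
  res <- run_engine(net, fresh_state(), cfg, codes$inputs, codes$targets,
                    codes$excluded, encoding)
  pred <- pred_to_symbols(task, res$pred)
  cperf <- if (!is.null(stream$final) && any(stream$final)) {
    counting_performance(pred, stream$targets, stream$final)
  } else NA_real_
  list(performance = performance(pred, stream$targets, stream$excluded),
       counting_performance = cperf, predictions = pred,
       x_history = res$x_history)
}
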