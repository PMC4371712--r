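# Small hand-built networks and an R-level reference simulator used to
# cross-check the compiled core against the composition of the exported
# single-rule functions.

# A tiny all-zero network whose weights and thresholds tests fill in by hand.
blank_network <- function(ne, ni = max(1, round(ne / 5)), no = 1,
                          wta = no > 1) {
  net <- list(
    W_EE = matrix(0, ne, ne), mask = matrix(FALSE, ne, ne),
    W_EI = matrix(0, ne, ni), W_IE = matrix(0, ni, ne),
    W_OE = matrix(0, no, ne),
    T_E = rep(0.5, ne), T_I = rep(0.5, ni), T_O = rep(0.5, no),
    x = integer(ne), y = integer(ni), o = integer(no),
    n_excitatory = as.integer(ne), n_inhibitory = as.integer(ni),
    n_outputs = as.integer(no), wta = wta
  )
  class(net) <- "rmsorn_network"
  net
}

# Reference simulator: advances a network over a supervised symbol stream by
# composing step_recurrent(), step_output(), the reward rules and
# plasticity_step(), mirroring the per-step schedule of the compiled loop.
reference_sim <- function(net, task, stream, plasticity, mod_state,
                          wrong_reward, phase, steps) {
  preds <- character(steps)
  for (t in seq_len(steps)) {
    u <- encode_symbol(task, stream$inputs[t])
    x_prev <- net$x
    net <- step_recurrent(net, u)
    net <- step_output(net)
    pred <- if (net$wta) task$out_alphabet[which(net$o == 1)] else
      task$out_alphabet[net$o[1] + 1]
    preds[t] <- pred
    skip <- stream$excluded[t] || (!net$wta && net$o[1] == 0)
    m_o <- 0
    if (!skip) {
      r <- reward_supervised(pred, stream$targets[t], wrong_reward)
      mres <- modulation(mod_state, r)
      m_o <- mres$m
      mod_state <- mres$state
    }
    net <- plasticity_step(net, plasticity, m_o, x_prev, phase)
  }
  list(net = net, preds = preds, mod_state = mod_state)
}

# Engine invocation with the same semantics, for direct comparison.
engine_sim <- function(net, task, stream, plasticity, modulation,
                       wrong_reward, phase, steps) {
  codes <- rmsorn:::stream_codes(task, stream)
  cfg <- rmsorn:::engine_cfg(plastic_rec = phase == 1, plastic_out = TRUE,
                             plasticity = plasticity, modulation = modulation,
                             task = task, wrong_reward = wrong_reward)
  res <- rmsorn:::run_engine(unclass(net), rmsorn:::fresh_state(), cfg,
                             codes$inputs[seq_len(steps)],
                             codes$targets[seq_len(steps)],
                             codes$excluded[seq_len(steps)], task$encoding)
  res$preds <- rmsorn:::pred_to_symbols(task, res$pred)
  res
}
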