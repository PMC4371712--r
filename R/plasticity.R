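#' Plasticity configuration
#'
#' Collects the learning rates and switches of the three plasticity rules:
#' intrinsic plasticity (IP, threshold homeostasis toward a target firing
#' rate), reward-modulated STDP, and synaptic normalization (SN, incoming
#' weights scaled to sum to 1).
#'
#' @param eta_ip IP learning rate.
#' @param eta_stdp STDP learning rate.
#' @param mu_ip_recurrent target firing rate of excitatory reservoir neurons,
#'   typically in `[0.05, 0.25]`.
#' @param mu_ip_output per-output-neuron target rates; defaults to the task's
#'   expected symbol frequencies when a trainer fills them in.
#' @param modulate_recurrent if `TRUE` the recurrent STDP is multiplied by the
#'   same modulation factor as the readout (`m_r = m_o`); if `FALSE` the
#'   reservoir self-organizes unmodulated (`m_r = 1`).
#' @param sn_output apply SN to the readout weights (ablation switch).
#' @param ip_output apply IP to the readout thresholds (disabled only in the
#'   noise-exploration mode).
#' @return a list of class `rmsorn_plasticity`.
#' @export
plasticity_config <- function(eta_ip = 0.01, eta_stdp = 0.004,
                              mu_ip_recurrent = 0.1, mu_ip_output = NULL,
                              modulate_recurrent = FALSE, sn_output = TRUE,
                              ip_output = TRUE, eta_ip_output = NULL) {
  stopifnot(eta_ip > 0, eta_stdp > 0,
            mu_ip_recurrent > 0, mu_ip_recurrent < 1)
  if (!is.null(mu_ip_output)) {
    stopifnot(all(mu_ip_output > 0), all(mu_ip_output < 1))
  }
  structure(
    list(eta_ip = eta_ip, eta_stdp = eta_stdp, eta_ip_output = eta_ip_output,
         mu_ip_recurrent = mu_ip_recurrent, mu_ip_output = mu_ip_output,
         modulate_recurrent = modulate_recurrent, sn_output = sn_output,
         ip_output = ip_output),
    class = "rmsorn_plasticity"
  )
}

#' Intrinsic plasticity update
#'
#' Moves each threshold toward the value at which the neuron's average firing
#' rate equals its target: active neurons have their threshold raised by
#' `eta_ip * (1 - mu_ip)`, inactive ones lowered by `eta_ip * mu_ip`. The
#' fixed point of the resulting stochastic approximation is a mean firing
#' rate of `mu_ip`.
#'
#' @param thresholds current threshold vector.
#' @param activity binary activity vector of matching length.
#' @param eta_ip learning rate.
#' @param mu_ip target rate, scalar or per-neuron vector.
#' @return updated threshold vector.
#' @export
ip_update <- function(thresholds, activity, eta_ip, mu_ip) {
  if (length(activity) != length(thresholds)) stop("shape mismatch")
  thresholds + eta_ip * (as.numeric(activity) - mu_ip)
}

#' Reward-modulated STDP delta for recurrent weights
#'
#' Pre-before-post firing (`x_j(t-1) = 1`, `x_i(t) = 1`) potentiates the
#' synapse `j -> i`, post-before-pre depresses it; the whole update is scaled
#' by the modulation factor `m_r`, so negative modulation inverts the rule
#' (anti-STDP under punishment). Deltas exist only on the eligibility mask.
#'
#' @param w_ee recurrent weight matrix (used for its dimensions).
#' @param mask logical eligibility mask.
#' @param x_prev,x_curr binary excitatory states at `t-1` and `t`.
#' @param m_r modulation factor.
#' @param eta_stdp learning rate.
#' @return delta matrix, zero off the mask. The caller adds it to the weights
#'   and clips at zero from below (see [plasticity_step()]).
#' @export
stdp_recurrent <- function(w_ee, mask, x_prev, x_curr, m_r, eta_stdp) {
  timing <- tcrossprod(as.numeric(x_curr), as.numeric(x_prev)) -
    tcrossprod(as.numeric(x_prev), as.numeric(x_curr))
  delta <- m_r * eta_stdp * timing
  delta[!mask] <- 0
  delta
}

#' Reward-modulated STDP delta for readout weights
#'
#' Purely potentiating form: only pre-before-post pairs (`x_j(t-1) = 1`,
#' `o_i(t) = 1`) contribute, scaled by the readout modulation `m_o`. With
#' `m_o = 0` (no reward under direct modulation) nothing changes; negative
#' `m_o` depresses the active connections.
#'
#' @param w_oe readout weight matrix (used for its dimensions).
#' @param x_prev binary excitatory state that produced the current output.
#' @param o_curr binary output state.
#' @param m_o modulation factor.
#' @param eta_stdp learning rate.
#' @return delta matrix of the same shape as `w_oe`.
#' @export
stdp_output <- function(w_oe, x_prev, o_curr, m_o, eta_stdp) {
  m_o * eta_stdp * tcrossprod(as.numeric(o_curr), as.numeric(x_prev))
}

#' Synaptic normalization
#'
#' Rescales every row (the incoming weights of one neuron) to sum to 1,
#' preserving relative synaptic strengths. Rows summing to zero carry no
#' information to rescale and are left unchanged; their indices are attached
#' as the `zero_rows` attribute so callers can flag the degeneracy.
#'
#' @param w non-negative weight matrix.
#' @return row-normalized matrix.
#' @export
synaptic_normalize <- function(w) {
  if (any(w < 0)) stop("negative weights: non-negativity invariant violated upstream")
  sums <- rowSums(w)
  pos <- sums > 0
  out <- w / ifelse(pos, sums, 1) # divides row i by its sum (column-major recycling)
  if (any(!pos)) attr(out, "zero_rows") <- which(!pos)
  out
}

#' One composite plasticity step
#'
#' Applies the per-step plasticity schedule in the fixed order
#' STDP -> synaptic normalization -> intrinsic plasticity: STDP deltas are
#' applied and clipped at zero, SN immediately restores the unit row sums,
#' and IP adjusts the thresholds independently of the weights. In phase 2 the
#' recurrent layer is frozen (no recurrent STDP, SN or IP) and only the
#' readout keeps learning.
#'
#' @param net an `rmsorn_network` whose states have just been advanced;
#'   `x_prev` is the excitatory state before that advance.
#' @param config an `rmsorn_plasticity` configuration.
#' @param m_o readout modulation factor for this step.
#' @param x_prev binary excitatory state at `t-1`.
#' @param phase training phase, 1 (all plasticity) or 2 (readout only).
#' @return the network with updated weights and thresholds.
#' @export
plasticity_step <- function(net, config, m_o, x_prev, phase = 1) {
  if (!phase %in% c(1, 2)) stop("unknown phase")
  recurrent_on <- phase == 1
  m_r <- if (config$modulate_recurrent) m_o else 1

  if (recurrent_on && m_r != 0) {
    d <- stdp_recurrent(net$W_EE, net$mask, x_prev, net$x, m_r, config$eta_stdp)
    net$W_EE <- pmax(net$W_EE + d, 0)
  }
  if (m_o != 0) {
    d <- stdp_output(net$W_OE, net$x, net$o, m_o, config$eta_stdp)
    net$W_OE <- pmax(net$W_OE + d, 0)
  }
  if (recurrent_on) net$W_EE <- synaptic_normalize(net$W_EE)
  if (config$sn_output) net$W_OE <- synaptic_normalize(net$W_OE)
  if (recurrent_on) {
    net$T_E <- ip_update(net$T_E, net$x, config$eta_ip, config$mu_ip_recurrent)
  }
  if (config$ip_output) {
    mu_out <- config$mu_ip_output
    if (is.null(mu_out)) mu_out <- rep(0.1, net$n_outputs)
    net$T_O <- ip_update(net$T_O, net$o, config$eta_ip, mu_out)
  }
  net
}
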