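#' Initialize an RM-SORN network
#'
#' Builds the two-layer binary threshold network: a recurrent reservoir of
#' `n_excitatory` excitatory and `n_excitatory / 5` inhibitory neurons, and a
#' readout layer of `n_outputs` neurons. Excitatory-to-excitatory connectivity
#' is sparse with a fixed eligibility mask (no self-connections, support never
#' grows); excitatory/inhibitory cross-connections and the readout are dense.
#' Weights are drawn as `|N(0, 1)|` and immediately row-normalized so every
#' neuron's incoming weights sum to 1 (the fixed point of synaptic
#' normalization); thresholds are drawn uniformly from `[0, t_max]`.
#'
#' With more than one output neuron the readout activation is winner-take-all
#' (exactly one output active per step, ties to the lowest index); with a
#' single output neuron it is the Heaviside step, with the boundary convention
#' `theta(0) = 1` used throughout the package.
#'
#' @param n_excitatory number of excitatory reservoir neurons (5 to 400).
#' @param n_outputs number of readout neurons.
#' @param sparsity fraction of eligible excitatory-to-excitatory connections,
#'   between 0.05 and 0.10.
#' @param seed integer seed; identical seeds give bit-identical networks.
#' @param t_max_exc,t_max_inh,t_max_out upper bounds of the uniform initial
#'   threshold draws for excitatory, inhibitory and output neurons.
#' @return an object of class `rmsorn_network`: a list holding the weight
#'   matrices `W_EE`, `W_EI`, `W_IE`, `W_OE`, the eligibility `mask`,
#'   thresholds `T_E`, `T_I`, `T_O`, binary states `x`, `y`, `o`, the counts
#'   `n_excitatory`, `n_inhibitory`, `n_outputs`, and the readout mode `wta`.
#' @export
init_network <- function(n_excitatory, n_outputs, sparsity = 0.10, seed = NULL,
                         t_max_exc = 0.5, t_max_inh = 0.5, t_max_out = 0.5) {
  if (sparsity < 0 || sparsity > 1) stop("sparsity must lie in [0, 1]")
  if (n_excitatory < 5) stop("need at least 5 excitatory neurons to form the inhibitory pool")
  if (n_outputs < 1) stop("need at least one output neuron")
  ne <- as.integer(n_excitatory)
  ni <- as.integer(round(ne / 5))
  no <- as.integer(n_outputs)

  with_seed(seed, {
    n_elig <- floor(sparsity * ne * (ne - 1))
    off_diag <- which(diag(ne) == 0)
    mask <- matrix(FALSE, ne, ne)
    mask[sample(off_diag, n_elig)] <- TRUE

    w_ee <- matrix(0, ne, ne)
    w_ee[mask] <- abs(stats::rnorm(n_elig))
    w_ee <- synaptic_normalize(w_ee)
    w_ei <- synaptic_normalize(matrix(abs(stats::rnorm(ne * ni)), ne, ni))
    w_ie <- synaptic_normalize(matrix(abs(stats::rnorm(ni * ne)), ni, ne))
    w_oe <- synaptic_normalize(matrix(abs(stats::rnorm(no * ne)), no, ne))

    net <- list(
      W_EE = w_ee, mask = mask, W_EI = w_ei, W_IE = w_ie, W_OE = w_oe,
      T_E = stats::runif(ne, 0, t_max_exc),
      T_I = stats::runif(ni, 0, t_max_inh),
      T_O = stats::runif(no, 0, t_max_out),
      x = integer(ne), y = integer(ni), o = integer(no),
      n_excitatory = ne, n_inhibitory = ni, n_outputs = no,
      wta = no > 1L, sparsity = sparsity, seed = seed, step = 0L
    )
    class(net) <- "rmsorn_network"
    net
  })
}

#' @export
print.rmsorn_network <- function(x, ...) {
  cat(sprintf(
    "RM-SORN network: %d excitatory + %d inhibitory neurons, %d output(s) [%s]\n",
    x$n_excitatory, x$n_inhibitory, x$n_outputs,
    if (x$wta) "winner-take-all" else "heaviside"
  ))
  cat(sprintf("  eligible recurrent connections: %d (%.1f%%)\n",
              sum(x$mask), 100 * mean(x$mask[!diag(nrow(x$mask)) == 1])))
  invisible(x)
}

#' One update of the recurrent layer
#'
#' Applies the binary threshold dynamics of the reservoir: each excitatory
#' neuron sums its recurrent excitation, subtracts inhibition, adds the
#' external input and its threshold is compared against the result; inhibitory
#' neurons are driven by the excitatory population only. The threshold
#' function fires at exactly zero drive (`theta(0) = 1`).
#'
#' @param net an `rmsorn_network`.
#' @param u binary external input vector of length `n_excitatory` (entered
#'   additively with weight 1).
#' @return the network with updated binary states `x` and `y`.
#' @export
step_recurrent <- function(net, u) {
  if (length(u) != net$n_excitatory) {
    stop("input vector length does not match the number of excitatory neurons")
  }
  x_prev <- net$x
  y_prev <- net$y
  drive_x <- as.numeric(net$W_EE %*% x_prev) -
    as.numeric(net$W_EI %*% y_prev) + as.numeric(u) - net$T_E
  drive_y <- as.numeric(net$W_IE %*% x_prev) - net$T_I
  net$x <- as.integer(drive_x >= 0)
  net$y <- as.integer(drive_y >= 0)
  net
}

#' One update of the readout layer
#'
#' Computes the net drive `W_OE x - T_O` of every output neuron. In
#' winner-take-all mode the unit with the maximal drive fires (ties broken
#' toward the lowest index so trajectories stay deterministic); in Heaviside
#' mode the single output fires iff its drive is `>= 0`.
#'
#' @param net an `rmsorn_network`.
#' @param x binary excitatory state feeding the readout (defaults to `net$x`).
#' @return the network with updated binary output state `o`.
#' @export
step_output <- function(net, x = net$x) {
  if (length(x) != net$n_excitatory) {
    stop("state vector length does not match the number of excitatory neurons")
  }
  drive <- as.numeric(net$W_OE %*% x) - net$T_O
  o <- integer(net$n_outputs)
  if (net$wta) {
    o[which.max(drive)] <- 1L
  } else {
    o[1] <- as.integer(drive[1] >= 0)
  }
  net$o <- o
  net
}

#' Build a seeded symbol-to-input-unit encoding
#'
#' Assigns each symbol of the task alphabet a fixed, disjoint subset of
#' excitatory units; presenting a symbol sets those units' external input to
#' 1. The default subset size is `ceiling(0.05 * n_excitatory)` units per
#' symbol, shrunk to `floor(n_excitatory / |alphabet|)` when the alphabet is
#' too large for disjoint subsets at the default size.
#'
#' @param task an `rmsorn_task` (or any list with an `alphabet` field).
#' @param n_excitatory number of excitatory units in the target network.
#' @param seed integer seed fixing the unit assignment.
#' @param subset_size optional override of the per-symbol subset size.
#' @return an encoding matrix of 0/1 values, `n_excitatory` rows, one column
#'   per alphabet symbol.
#' @export
make_encoding <- function(task, n_excitatory, seed = NULL, subset_size = NULL) {
  alphabet <- task$alphabet
  nsym <- length(alphabet)
  if (nsym > n_excitatory) stop("alphabet larger than the excitatory population")
  if (is.null(subset_size)) {
    subset_size <- min(ceiling(0.05 * n_excitatory), floor(n_excitatory / nsym))
    subset_size <- max(1L, subset_size)
  }
  if (subset_size * nsym > n_excitatory) {
    stop("subset_size too large for disjoint per-symbol subsets")
  }
  with_seed(seed, {
    units <- sample(n_excitatory, subset_size * nsym)
    map <- matrix(0, n_excitatory, nsym, dimnames = list(NULL, alphabet))
    for (s in seq_len(nsym)) {
      map[units[((s - 1) * subset_size + 1):(s * subset_size)], s] <- 1
    }
    map
  })
}

#' Encode one symbol as a binary input vector
#'
#' @param task an `rmsorn_task` carrying an `encoding` matrix (see
#'   [make_encoding()]).
#' @param symbol a single symbol from the task alphabet.
#' @return binary input vector `u` of length `n_excitatory`.
#' @export
encode_symbol <- function(task, symbol) {
  if (is.null(task$encoding)) {
    stop("task carries no encoding; call make_encoding() first")
  }
  j <- match(as.character(symbol), colnames(task$encoding))
  if (is.na(j)) stop(sprintf("unknown symbol '%s'", symbol))
  task$encoding[, j]
}
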