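#' Save a network snapshot
#'
#' Writes a single-file archive holding all weight matrices, the eligibility
#' mask, thresholds, binary states, neuron counts, the seed and the readout
#' mode as named arrays. The round-trip through [load_network()] is
#' bit-exact.
#'
#' @param net an `rmsorn_network`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
save_network <- function(net, path) {
  fields <- c("W_EE", "mask", "W_EI", "W_IE", "W_OE", "T_E", "T_I", "T_O",
              "x", "y", "o", "n_excitatory", "n_inhibitory", "n_outputs",
              "wta", "sparsity", "seed", "step")
  snap <- net[intersect(fields, names(net))]
  saveRDS(snap, path)
  invisible(path)
}

#' Load a network snapshot
#'
#' @param path file written by [save_network()].
#' @return the restored `rmsorn_network`.
#' @export
load_network <- function(path) {
  net <- readRDS(path)
  class(net) <- "rmsorn_network"
  net
}

#' Read an experiment configuration file
#'
#' Reads a YAML configuration with the keys used by the `rmsorn` command
#' line script and by [run_experiment()]: `task`, `n`, `size`, `variant`,
#' `datasets`, `networks`, `seed`, `noise_prob`, plus optional plasticity
#' overrides (`eta_ip`, `eta_stdp`, `mu_ip_recurrent`, `modulate_recurrent`,
#' `sn_output`, `ip_output`) and protocol overrides (`phase_steps`,
#' `validation_interval`, `validation_steps`, `test_steps`, `sorn_interval`,
#' `n_shuffles`).
#'
#' @param path YAML file path.
#' @return a named list of configuration values.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  # YAML 1.1 reads a bare `n` key as the boolean FALSE; restore it
  names(cfg)[names(cfg) == "FALSE"] <- "n"
  if (is.null(cfg$task)) stop("config misses the 'task' key")
  cfg
}
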