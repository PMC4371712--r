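#' Run a replicated experiment
#'
#' Executes the full training and evaluation pipeline for one task/variant
#' combination over `datasets` independent data sets with `networks`
#' independently initialized networks per data set (the generation task has
#' no data sets; `networks` networks are run). Rows are emitted in a fixed
#' order, so reruns with the same configuration give identical tables.
#'
#' @param task an `rmsorn_task` or task name.
#' @param n task difficulty (used when `task` is a name).
#' @param n_excitatory reservoir size.
#' @param variant one of `"rmsorn"`, `"sorn"`, `"static"`, `"random"`,
#'   `"noise"`.
#' @param datasets,networks replicate counts.
#' @param seed_base base seed; data-set and network seeds are derived from
#'   it.
#' @param protocol an `rmsorn_protocol`.
#' @param noise_prob bit-flip probability for the `"noise"` variant.
#' @param plasticity optional `rmsorn_plasticity` overriding the task
#'   defaults.
#' @param csv optional path; when given, the per-run table is written there.
#' @return a data frame with one row per run: `task`, `n`, `N`, `variant`,
#'   `data_seed`, `net_seed`, `performance`, `counting_performance`.
#' @export
run_experiment <- function(task, n = 4, n_excitatory = 100,
                           variant = c("rmsorn", "sorn", "static", "random",
                                       "noise"),
                           datasets = 10, networks = 10, seed_base = 1,
                           protocol = training_protocol(), noise_prob = 0.05,
                           plasticity = NULL, csv = NULL) {
  variant <- match.arg(variant)
  if (is.character(task)) task <- task_spec(task, n)
  is_gen <- task$name == "motion_generation"
  if (is_gen) datasets <- 1L

  rows <- list()
  for (d in seq_len(datasets)) {
    data_seed <- seed_base + 1009L * d
    streams <- make_task_streams(task, protocol, data_seed)
    for (m in seq_len(networks)) {
      net_seed <- seed_base + 1009L * d + 31L * m
      fit <- switch(variant,
        rmsorn = train_rmsorn(task, n_excitatory, protocol,
                              plasticity = plasticity, seed = net_seed,
                              streams = streams),
        random = train_rmsorn(task, n_excitatory, protocol,
                              plasticity = plasticity, seed = net_seed,
                              streams = streams, random_baseline = TRUE),
        sorn = train_sorn_baseline(task, n_excitatory, protocol,
                                   plasticity = plasticity, seed = net_seed,
                                   streams = streams),
        static = {
          sorn <- train_sorn_baseline(task, n_excitatory, protocol,
                                      plasticity = plasticity,
                                      seed = net_seed, streams = streams)
          make_static_baseline(sorn, n_shuffles = protocol$n_shuffles,
                               seed = net_seed, streams = streams)
        },
        noise = {
          nm <- noise_exploration_mode(task, n_excitatory, protocol,
                                       plasticity = plasticity,
                                       noise_prob = noise_prob,
                                       seed = net_seed, streams = streams)
          train_rmsorn(nm$task, n_excitatory, protocol,
                       plasticity = nm$plasticity, seed = net_seed,
                       net = nm$net, streams = streams,
                       noise_prob = nm$noise_prob)
        }
      )
      rows[[length(rows) + 1]] <- data.frame(
        task = task$name, n = task$n, N = n_excitatory, variant = variant,
        data_seed = data_seed, net_seed = net_seed,
        performance = fit$performance,
        counting_performance = fit$counting_performance
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(csv)) utils::write.csv(out, csv, row.names = FALSE)
  out
}

#' Summarize an experiment table
#'
#' @param results a data frame from [run_experiment()].
#' @param json optional path for a JSON summary.
#' @return a one-row data frame with mean and standard deviation of the
#'   performance measures.
#' @export
summarize_experiment <- function(results, json = NULL) {
  s <- data.frame(
    task = results$task[1], n = results$n[1], N = results$N[1],
    variant = results$variant[1], runs = nrow(results),
    mean_performance = mean(results$performance),
    sd_performance = stats::sd(results$performance),
    mean_counting = mean(results$counting_performance),
    sd_counting = stats::sd(results$counting_performance)
  )
  if (!is.null(json)) {
    jsonlite::write_json(as.list(s), json, auto_unbox = TRUE, digits = NA)
  }
  s
}

#' Neuron selectivity over two-symbol contexts
#'
#' Estimates, for every reservoir neuron, the probability of firing given
#' the two input symbols just presented, by counting spikes over a probe
#' stream processed with frozen weights. In a trained pattern-recognition
#' network, neurons selective for parts of the target word show up as rows
#' firing for one context only.
#'
#' @param net an `rmsorn_network` (or the `net` of an `rmsorn_fit`).
#' @param task the task (must carry its `encoding`).
#' @param probe_steps probe stream length.
#' @param seed probe stream seed.
#' @return matrix of firing probabilities, one row per two-symbol context
#'   (named e.g. `"12"`), one column per excitatory neuron; contexts that
#'   never occur are omitted.
#' @export
selectivity_analysis <- function(net, task, probe_steps = 10000, seed = 1) {
  if (is.null(task$encoding)) stop("task carries no encoding")
  stream <- generate_stream(task, probe_steps, seed)
  codes <- stream_codes(task, stream)
  cfg <- engine_cfg(task = task, update_output = FALSE, record_x = TRUE)
  res <- run_engine(unclass(net), fresh_state(), cfg, codes$inputs,
                    codes$targets, codes$excluded, task$encoding)
  # context at step t is the pair (s[t-1], s[t]); the state x(t) follows it
  ctx <- paste0(stream$inputs[seq_len(probe_steps - 1)],
                stream$inputs[1 + seq_len(probe_steps - 1)])
  x <- res$x_history[-1, , drop = FALSE]
  groups <- split(seq_along(ctx), ctx)
  probs <- t(vapply(groups, function(ix) colMeans(x[ix, , drop = FALSE]),
                    numeric(ncol(x))))
  probs
}
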