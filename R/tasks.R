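#' Task specification
#'
#' Builds the specification of one of the eight benchmark tasks: its alphabet,
#' difficulty parameter `n`, output layer layout (number of readout neurons
#' and activation mode) and the expected per-symbol frequencies that feed the
#' readout intrinsic-plasticity targets.
#'
#' Tasks:
#' * `counting`: random alternations of the words `a b...b c` and
#'   `e d...d f` (`n` b's or d's); predict the next letter.
#' * `motion_prediction`: random renewal sequences of `1 2 ... n` and
#'   `n ... 2 1`; predict the next symbol.
#' * `occluder`: alternations of "12345678", "87654321", "19999998",
#'   "89999991" (`n` fixed at 8); predict the next symbol.
#' * `memory_capacity`: uniform random stream over 6 symbols; reproduce the
#'   symbol from `n` steps back.
#' * `markov85`: 6-state first-order Markov chain with cyclic transitions of
#'   probability 0.85; signed shift `n` (negative = recall of `|n|` steps
#'   back, positive = prediction `n` steps ahead).
#' * `parity`: binary stream; output the parity of the last `n` inputs.
#' * `motion_generation`: no input; generate `1 2 ... n` or `n ... 2 1`.
#' * `pattern_recognition`: alternations of "1234", "4321", "4213", "2431";
#'   a single Heaviside output labels every letter of "1234" with 1.
#'
#' @param name task name.
#' @param n task difficulty (word length, delay, window or shift; ignored
#'   where the task fixes it).
#' @return a list of class `rmsorn_task` with fields `name`, `n`, `alphabet`
#'   (input symbols), `out_alphabet` (symbols coded by the readout neurons),
#'   `n_outputs`, `wta`, `mu_ip_output`, and for word tasks `words` /
#'   `target_words`.
#' @export
task_spec <- function(name = c("counting", "motion_prediction", "occluder",
                               "memory_capacity", "markov85", "parity",
                               "motion_generation", "pattern_recognition"),
                      n = 4) {
  name <- match.arg(name)
  spec <- switch(name,
    counting = {
      if (n < 1) stop("counting needs n >= 1")
      alpha <- c("a", "b", "c", "d", "e", "f")
      freq <- c(a = 1, b = n, c = 1, d = n, e = 1, f = 1) / (2 * (n + 2))
      list(alphabet = alpha, out_alphabet = alpha, n_outputs = 6L,
           mu_ip_output = unname(freq[alpha]),
           words = list(c("a", rep("b", n), "c"), c("e", rep("d", n), "f")))
    },
    motion_prediction = {
      if (n < 2) stop("motion prediction needs n >= 2")
      alpha <- as.character(seq_len(n))
      list(alphabet = alpha, out_alphabet = alpha, n_outputs = as.integer(n),
           mu_ip_output = rep(1 / n, n),
           words = list(alpha, rev(alpha)))
    },
    occluder = {
      n <- 8
      alpha <- as.character(1:9)
      words <- lapply(c("12345678", "87654321", "19999998", "89999991"),
                      function(w) strsplit(w, "")[[1]])
      freq <- table(factor(unlist(words), levels = alpha)) / 32
      list(alphabet = alpha, out_alphabet = alpha, n_outputs = 9L,
           mu_ip_output = as.numeric(freq), words = words)
    },
    memory_capacity = {
      if (n < 0) stop("memory capacity needs n >= 0")
      alpha <- as.character(1:6)
      list(alphabet = alpha, out_alphabet = alpha, n_outputs = 6L,
           mu_ip_output = rep(1 / 6, 6))
    },
    markov85 = {
      alpha <- as.character(1:6)
      list(alphabet = alpha, out_alphabet = alpha, n_outputs = 6L,
           mu_ip_output = rep(1 / 6, 6)) # stationary distribution is uniform
    },
    parity = {
      if (n < 1) stop("parity needs n >= 1")
      alpha <- c("0", "1")
      list(alphabet = alpha, out_alphabet = alpha, n_outputs = 2L,
           mu_ip_output = c(0.5, 0.5))
    },
    motion_generation = {
      if (n < 2) stop("motion generation needs n >= 2")
      alpha <- as.character(seq_len(n))
      list(alphabet = alpha, out_alphabet = alpha, n_outputs = as.integer(n),
           mu_ip_output = rep(1 / n, n),
           target_words = list(alpha, rev(alpha)))
    },
    pattern_recognition = {
      n <- 4
      alpha <- as.character(1:4)
      # the target word occurs in 1 of 4 word draws -> output is 1 a quarter
      # of the time
      list(alphabet = alpha, out_alphabet = c("0", "1"), n_outputs = 1L,
           mu_ip_output = 0.25,
           words = lapply(c("1234", "4321", "4213", "2431"),
                          function(w) strsplit(w, "")[[1]]))
    }
  )
  spec$name <- name
  spec$n <- as.integer(n)
  spec$wta <- spec$n_outputs > 1L
  class(spec) <- "rmsorn_task"
  spec
}

labeled_stream <- function(inputs, targets, excluded, final = NULL,
                           task = NULL, n = NULL) {
  stopifnot(length(inputs) == length(targets),
            length(inputs) == length(excluded))
  structure(list(inputs = inputs, targets = targets, excluded = excluded,
                 final = final, task = task, n = n),
            class = "rmsorn_stream")
}

# Concatenate uniformly sampled words (as symbol vectors) up to `length`
# symbols; returns symbols plus per-position word metadata.
sample_word_stream <- function(words, length, seed) {
  with_seed(seed, {
    min_len <- min(lengths(words))
    syms <- character(0)
    word_id <- integer(0)
    pos_in_word <- integer(0)
    word_len <- integer(0)
    while (base::length(syms) < length) {
      k <- ceiling((length - base::length(syms)) / min_len)
      idx <- sample(base::length(words), k, replace = TRUE)
      for (i in idx) {
        w <- words[[i]]
        syms <- c(syms, w)
        word_id <- c(word_id, rep(i, base::length(w)))
        pos_in_word <- c(pos_in_word, seq_along(w))
        word_len <- c(word_len, rep(base::length(w), base::length(w)))
      }
    }
    keep <- seq_len(length)
    list(syms = syms[keep], word_id = word_id[keep],
         pos_in_word = pos_in_word[keep], word_len = word_len[keep])
  })
}

# Next-symbol prediction labels for a word stream. Predictions whose target
# falls within the first `n_excl` letters of a word are unpredictable and
# excluded, as is the stream-final position (no next symbol).
predict_next_labels <- function(ws, n_excl) {
  L <- length(ws$syms)
  targets <- c(ws$syms[-1], NA)
  excluded <- c(ws$pos_in_word[-1] <= n_excl, TRUE)
  final <- c(ws$pos_in_word[-1] == ws$word_len[-1], FALSE)
  targets[is.na(targets)] <- ws$syms[L] # placeholder, always excluded
  list(targets = targets, excluded = excluded, final = final)
}

#' Counting-task stream
#'
#' Random alternations of the two words `a b...b c` and `e d...d f` with
#' `n + 2` letters each; the target is the next input symbol. Predictions of
#' word-initial letters are unpredictable and excluded from scoring.
#'
#' @param n number of b's / d's per word.
#' @param length stream length in symbols.
#' @param seed integer seed.
#' @return an `rmsorn_stream` with fields `inputs`, `targets`, `excluded` and
#'   `final` (positions whose target is a word-final letter, scored by the
#'   counting performance).
#' @export
gen_counting <- function(n, length, seed = NULL) {
  task <- task_spec("counting", n)
  if (length < n + 2) stop("stream shorter than one word")
  ws <- sample_word_stream(task$words, length, seed)
  lab <- predict_next_labels(ws, 1)
  labeled_stream(ws$syms, lab$targets, lab$excluded, lab$final, "counting", n)
}

#' Motion-prediction stream
#'
#' Random renewal sequences of the words `1 2 ... n` and `n ... 2 1`; the
#' target is the next symbol, with word-initial targets excluded (the
#' direction after a word ends is unpredictable).
#'
#' @inheritParams gen_counting
#' @export
gen_motion <- function(n, length, seed = NULL) {
  task <- task_spec("motion_prediction", n)
  ws <- sample_word_stream(task$words, length, seed)
  lab <- predict_next_labels(ws, 1)
  labeled_stream(ws$syms, lab$targets, lab$excluded, lab$final,
                 "motion_prediction", n)
}

#' Occluder stream
#'
#' Random alternations of "12345678", "87654321", "19999998" and "89999991";
#' because the occluded words share their first letters with the plain words,
#' both the first and the second letter of a word are unpredictable and
#' excluded.
#'
#' @inheritParams gen_counting
#' @export
gen_occluder <- function(length, seed = NULL) {
  task <- task_spec("occluder")
  ws <- sample_word_stream(task$words, length, seed)
  lab <- predict_next_labels(ws, 2)
  labeled_stream(ws$syms, lab$targets, lab$excluded, lab$final, "occluder", 8)
}

#' Memory-capacity stream
#'
#' Uniform random stream over 6 symbols; the target at step `t` is the input
#' from `n` steps back, the first `n` positions are excluded.
#'
#' @param n recall delay (`n = 0` is the identity task).
#' @inheritParams gen_counting
#' @export
gen_memory <- function(n, length, seed = NULL) {
  if (n < 0) stop("delay must be >= 0")
  syms <- with_seed(seed, sample(as.character(1:6), length, replace = TRUE))
  targets <- if (n == 0) syms else c(rep(syms[1], n), syms[seq_len(length - n)])
  excluded <- seq_len(length) <= n
  labeled_stream(syms, targets, excluded, NULL, "memory_capacity", n)
}

#' Markov-85 stream
#'
#' First-order Markov chain on states 1..6 with transition probability 0.85
#' for the cyclic successor (1->2, ..., 6->1) and 0.03 for each of the other
#' five states. A signed shift selects the goal: `n < 0` recalls the input
#' `|n|` steps back, `n > 0` predicts the state `n` steps ahead, `n = 0` is
#' the identity; boundary positions without a defined target are excluded.
#'
#' @param n signed shift.
#' @inheritParams gen_counting
#' @export
gen_markov85 <- function(n, length, seed = NULL) {
  syms <- with_seed(seed, {
    cand <- t(vapply(1:6, function(s) setdiff(1:6, s %% 6 + 1), integer(5)))
    r <- stats::runif(length)
    alt <- sample(5, length, replace = TRUE)
    s <- integer(length)
    cur <- sample(6, 1)
    for (t in seq_len(length)) {
      cur <- if (r[t] < 0.85) cur %% 6 + 1 else cand[cur, alt[t]]
      s[t] <- cur
    }
    as.character(s)
  })
  L <- length
  idx <- seq_len(L) + n
  ok <- idx >= 1 & idx <= L
  targets <- syms
  targets[ok] <- syms[idx[ok]]
  labeled_stream(syms, targets, !ok, NULL, "markov85", n)
}

#' Parity stream
#'
#' Uniform random binary stream; the target at step `t` is the parity (XOR)
#' of the inputs at steps `t - n + 1 ... t`. The first `n - 1` positions have
#' an incomplete window and are excluded.
#'
#' @param n parity window size.
#' @inheritParams gen_counting
#' @export
gen_parity <- function(n, length, seed = NULL) {
  if (n < 1) stop("window must be >= 1")
  bits <- with_seed(seed, sample(0:1, length, replace = TRUE))
  csum <- cumsum(bits)
  win <- csum - c(rep(0, n), csum[seq_len(length - n)])
  targets <- as.character(win %% 2)
  excluded <- seq_len(length) < n
  labeled_stream(as.character(bits), targets, excluded, NULL, "parity", n)
}

#' Pattern-recognition stream
#'
#' Random alternations of "1234", "4321", "4213" and "2431"; the binary
#' target is 1 for every letter inside an occurrence of the word "1234" and
#' 0 elsewhere. No positions are excluded.
#'
#' @inheritParams gen_counting
#' @export
gen_pattern_words <- function(length, seed = NULL) {
  task <- task_spec("pattern_recognition")
  ws <- sample_word_stream(task$words, length, seed)
  targets <- as.character(as.integer(ws$word_id == 1L))
  labeled_stream(ws$syms, targets, rep(FALSE, length), NULL,
                 "pattern_recognition", 4)
}

#' Generate a stream for a task specification
#'
#' Dispatches to the task's generator; `motion_generation` has no input and
#' returns `NULL`.
#'
#' @param task an `rmsorn_task`.
#' @param length stream length.
#' @param seed integer seed.
#' @return an `rmsorn_stream`, or `NULL` for the generation task.
#' @export
generate_stream <- function(task, length, seed = NULL) {
  switch(task$name,
    counting = gen_counting(task$n, length, seed),
    motion_prediction = gen_motion(task$n, length, seed),
    occluder = gen_occluder(length, seed),
    memory_capacity = gen_memory(task$n, length, seed),
    markov85 = gen_markov85(task$n, length, seed),
    parity = gen_parity(task$n, length, seed),
    pattern_recognition = gen_pattern_words(length, seed),
    motion_generation = NULL
  )
}

#' Overall prediction performance
#'
#' Fraction of non-excluded positions where the prediction matches the
#' target.
#'
#' @param predictions,targets symbol vectors of equal length.
#' @param excluded logical mask of positions excluded from scoring.
#' @return fraction in `[0, 1]`.
#' @export
performance <- function(predictions, targets, excluded = NULL) {
  if (length(predictions) == 0) stop("empty stream")
  if (is.null(excluded)) excluded <- rep(FALSE, length(predictions))
  keep <- !excluded
  if (!any(keep)) stop("no scorable positions")
  mean(as.character(predictions[keep]) == as.character(targets[keep]))
}

#' Counting performance
#'
#' Accuracy restricted to the memory-demanding positions whose target is a
#' word-final letter (the c/f predictions in the counting task).
#'
#' @param predictions,targets symbol vectors.
#' @param final logical mask of positions whose target is word-final.
#' @return fraction in `[0, 1]`.
#' @export
counting_performance <- function(predictions, targets, final) {
  if (length(predictions) == 0) stop("empty stream")
  if (!any(final)) stop("no word-final positions")
  mean(as.character(predictions[final]) == as.character(targets[final]))
}

#' Generation performance
#'
#' Fraction of output positions covered by at least one complete occurrence
#' of a target word.
#'
#' @param outputs generated symbol sequence.
#' @param target_words list of target words (symbol vectors).
#' @return fraction in `[0, 1]`.
#' @export
generation_performance <- function(outputs, target_words) {
  outputs <- as.character(outputs)
  L <- length(outputs)
  if (L == 0) stop("empty output sequence")
  covered <- logical(L)
  for (w in target_words) {
    w <- as.character(w)
    m <- length(w)
    if (m > L) next
    for (s in seq_len(L - m + 1)) {
      if (all(outputs[s:(s + m - 1)] == w)) covered[s:(s + m - 1)] <- TRUE
    }
  }
  mean(covered)
}

#' Exploration statistic for generation runs
#'
#' For consecutive windows of the output history, counts the unique
#' subsequences (of lengths 2 to `max_len`) that are not substrings of any
#' target word — a measure of how much the network still explores output
#' sequences outside the rewarded words.
#'
#' @param outputs output symbol sequence recorded during training.
#' @param target_words list of target words.
#' @param window window size in steps.
#' @param max_len longest subsequence length counted.
#' @return data frame with columns `window` (index) and `unique_sequences`.
#' @export
exploration_trace <- function(outputs, target_words, window = 100,
                              max_len = 4) {
  outputs <- as.character(outputs)
  target_sub <- unlist(lapply(target_words, function(w) {
    w <- as.character(w)
    unlist(lapply(2:max_len, function(l) {
      if (length(w) < l) return(character(0))
      vapply(seq_len(length(w) - l + 1),
             function(s) paste(w[s:(s + l - 1)], collapse = "."), character(1))
    }))
  }))
  n_win <- floor(length(outputs) / window)
  counts <- vapply(seq_len(n_win), function(b) {
    seg <- outputs[((b - 1) * window + 1):(b * window)]
    subs <- unlist(lapply(2:max_len, function(l) {
      if (length(seg) < l) return(character(0))
      m <- stats::embed(seq_along(seg), l)
      apply(m[, l:1, drop = FALSE], 1,
            function(ix) paste(seg[ix], collapse = "."))
    }))
    length(setdiff(unique(subs), target_sub))
  }, numeric(1))
  data.frame(window = seq_len(n_win), unique_sequences = counts)
}
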