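#' Supervised reward
#'
#' Reward 1 for a correct output, `wrong_reward` (0 or -1) for a wrong one.
#' Positions excluded by the task's exclusion rule (unpredictable symbols such
#' as word-initial letters) carry no learning signal and yield reward 0.
#'
#' @param predicted,target symbols from the task's output alphabet.
#' @param wrong_reward reward on mismatch, 0 (suppression) or -1 (punishment,
#'   i.e. anti-STDP).
#' @param excluded is this position excluded from the performance measure?
#' @return scalar reward.
#' @export
reward_supervised <- function(predicted, target, wrong_reward = 0,
                              excluded = FALSE) {
  if (excluded) return(0)
  if (identical(as.character(predicted), as.character(target))) 1 else wrong_reward
}

#' Generation-task reward
#'
#' The network is rewarded for producing a target word from its beginning:
#' the reward is `L / n` where `L` is the length of the longest suffix of the
#' last `n` outputs that is a prefix of one of the target words (the full
#' word earns reward 1 at the step emitting its last symbol). A doubled
#' word-initial symbol (e.g. "11" when a target word starts with "1") is
#' punished with `-punishment` to block the trivial repetition strategy.
#'
#' @param output_tail the most recent output symbols (up to `n`), oldest
#'   first.
#' @param target_words list of target words, each a vector of symbols.
#' @param n word length.
#' @param punishment magnitude of the repetition punishment; defaults to
#'   `1 / n`, the granularity of the partial rewards.
#' @return scalar reward.
#' @export
reward_generation <- function(output_tail, target_words, n,
                              punishment = 1 / n) {
  if (length(target_words) == 0) stop("empty target word list")
  tail_chr <- as.character(output_tail)
  len <- length(tail_chr)
  if (len > n) {
    tail_chr <- tail_chr[(len - n + 1):len]
    len <- n
  }
  firsts <- vapply(target_words, function(w) as.character(w[1]), character(1))
  if (len >= 2 && tail_chr[len] == tail_chr[len - 1] &&
      tail_chr[len] %in% firsts) {
    return(-punishment)
  }
  best <- 0L
  for (w in target_words) {
    w <- as.character(w)
    for (p in seq_len(min(len, length(w)))) {
      if (all(tail_chr[(len - p + 1):len] == w[seq_len(p)])) best <- max(best, p)
    }
  }
  best / n
}

#' Create a reward-modulation state
#'
#' Strategy `m0` uses the raw reward as the modulation factor
#' (`m(t) = r(t)`); strategy `mk` uses a reward-prediction error, the current
#' reward minus the moving average of the previous `k` rewards
#' (`m(t) = r(t) - rbar(t, k)`). Under `mk` a constant reward stream drives
#' the modulation to zero.
#'
#' @param strategy `"m0"` or `"mk"`.
#' @param k moving-average window for `mk`; the values 1, 5, 10 and 20 are
#'   the canonical choices, other `k >= 1` are accepted with a warning.
#' @return a list of class `rmsorn_modulation` holding the strategy and the
#'   (initially empty) reward history.
#' @export
make_modulation <- function(strategy = c("m0", "mk"), k = 5) {
  strategy <- match.arg(strategy)
  if (k < 1) stop("k must be >= 1")
  if (strategy == "mk" && !k %in% c(1, 5, 10, 20)) {
    warning("k outside the canonical set {1, 5, 10, 20}")
  }
  structure(list(strategy = strategy, k = as.integer(k), history = numeric(0)),
            class = "rmsorn_modulation")
}

#' Convert a reward into a modulation factor
#'
#' @param state an `rmsorn_modulation` state.
#' @param r current reward.
#' @return a list with the modulation factor `m` and the updated `state`
#'   (the reward is appended to the history after `m` is computed; while
#'   fewer than `k` rewards exist, the average of those available is used).
#' @export
modulation <- function(state, r) {
  m <- if (state$strategy == "m0") {
    r
  } else {
    rbar <- if (length(state$history) == 0) 0 else mean(state$history)
    r - rbar
  }
  state$history <- c(state$history, r)
  if (length(state$history) > state$k) {
    state$history <- state$history[(length(state$history) - state$k + 1):length(state$history)]
  }
  list(m = m, state = state)
}
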