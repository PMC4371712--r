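test_that("counting streams alternate the two words with correct labels", {
  st <- gen_counting(3, 200, seed = 1)
  expect_equal(sort(unique(st$inputs)), sort(c("a", "b", "c", "e", "d", "f")))
  # reconstruct words: every 'a' starts "abbbc", every 'e' starts "edddf"
  starts <- which(st$inputs %in% c("a", "e"))
  for (s in starts[starts + 4 <= 200]) {
    w <- paste(st$inputs[s:(s + 4)], collapse = "")
    expect_true(w %in% c("abbbc", "edddf"))
  }
  # targets are the next input symbol; predictions of word-initial letters
  # are excluded, as is the stream-final position
  expect_equal(st$targets[-200], st$inputs[-1])
  inner_starts <- starts[starts > 1]
  expect_true(all(st$excluded[inner_starts - 1]))
  expect_true(st$excluded[200])
  expect_equal(sum(st$excluded), length(inner_starts) + 1)
  # word-final targets (the counting positions) are the c/f predictions
  expect_true(all(st$targets[st$final] %in% c("c", "f")))
  expect_error(gen_counting(3, 4, seed = 1), "shorter")
})

test_that("counting streams are enumerable at n = 1", {
  st <- gen_counting(1, 9, seed = 5)
  words <- c("abc", "edf")
  w <- paste(st$inputs, collapse = "")
  expect_true(substr(w, 1, 3) %in% words)
  expect_true(substr(w, 4, 6) %in% words)
  expect_identical(gen_counting(1, 9, seed = 5), gen_counting(1, 9, seed = 5))
})

test_that("motion streams are renewal sequences of the two direction words", {
  st <- gen_motion(4, 120, seed = 2)
  expect_equal(sort(unique(st$inputs)), as.character(1:4))
  st2 <- gen_motion(2, 40, seed = 3)
  expect_equal(st2$targets[-40], st2$inputs[-1])
  # brute-force: every non-excluded position's target continues its word
  for (t in which(!st2$excluded)) {
    expect_equal(st2$targets[t], st2$inputs[t + 1])
  }
})

test_that("occluder streams use the four 8-letter words and exclude two letters", {
  st <- gen_occluder(400, seed = 4)
  expect_true(all(st$inputs %in% as.character(1:9)))
  # '9' only occurs in the occluded words, in runs of six
  runs <- rle(st$inputs == "9")
  expect_true(all(runs$lengths[runs$values] <= 6))
  inner <- runs$lengths[runs$values]
  expect_true(all(inner[-length(inner)] == 6))
  # first and second letters of each word are unpredictable
  starts <- which(diff(c(0, cumsum(rep(1, 400)))) > 0) # positions 1..400
  word_starts <- seq(1, 400, by = 8)
  pred_of_first <- word_starts[word_starts > 1] - 1
  pred_of_second <- word_starts
  expect_true(all(st$excluded[pred_of_first]))
  expect_true(all(st$excluded[pred_of_second[pred_of_second <= 399]]))
})

test_that("memory streams delay the input by n", {
  st0 <- gen_memory(0, 50, seed = 6)
  expect_equal(st0$targets, st0$inputs)
  expect_false(any(st0$excluded))
  st3 <- gen_memory(3, 50, seed = 6)
  expect_equal(st3$targets[4:50], st3$inputs[1:47])
  expect_equal(which(st3$excluded), 1:3)
})

test_that("markov85 streams follow the transition matrix", {
  st <- gen_markov85(0, 100000, seed = 7)
  s <- as.integer(st$inputs)
  expect_equal(st$targets, st$inputs) # n = 0: identity
  trans <- table(factor(s[-length(s)], levels = 1:6),
                 factor(s[-1], levels = 1:6))
  p <- trans / rowSums(trans)
  for (i in 1:6) {
    succ <- i %% 6 + 1
    expect_lt(abs(p[i, succ] - 0.85), 0.01)
    others <- setdiff(1:6, succ)
    expect_true(all(abs(p[i, others] - 0.03) < 0.01))
  }
  # signed shift: negative = recall, positive = prediction
  rec <- gen_markov85(-2, 30, seed = 8)
  expect_equal(rec$targets[3:30], rec$inputs[1:28])
  expect_equal(which(rec$excluded), 1:2)
  pre <- gen_markov85(2, 30, seed = 8)
  expect_equal(pre$targets[1:28], pre$inputs[3:30])
  expect_equal(which(pre$excluded), 29:30)
})

test_that("parity targets equal the sliding-window XOR", {
  st1 <- gen_parity(1, 30, seed = 9)
  expect_equal(st1$targets, st1$inputs)
  st <- gen_parity(3, 50, seed = 10)
  bits <- as.integer(st$inputs)
  for (t in 3:50) {
    expect_equal(as.integer(st$targets[t]),
                 (bits[t] + bits[t - 1] + bits[t - 2]) %% 2)
  }
  expect_equal(which(st$excluded), 1:2)
})

test_that("pattern streams label exactly the letters of the target word", {
  st <- gen_pattern_words(400, seed = 11)
  expect_true(all(st$targets %in% c("0", "1")))
  expect_false(any(st$excluded))
  # positive labels come in runs of 4 that spell out 1234
  r <- rle(st$targets)
  pos <- cumsum(c(1, r$lengths))[-(length(r$lengths) + 1)]
  for (k in which(r$values == "1" & pos + 3 <= 400)) {
    run_start <- pos[k]
    len <- r$lengths[k]
    expect_equal(len %% 4, 0) # whole words (adjacent words may merge runs)
    expect_equal(paste(st$inputs[run_start:(run_start + 3)], collapse = ""),
                 "1234")
  }
})

test_that("performance measures count matches over scorable positions", {
  expect_equal(performance(c("a", "b"), c("a", "b"), c(FALSE, FALSE)), 1)
  expect_equal(performance(c("a", "b"), c("b", "a"), c(FALSE, FALSE)), 0)
  preds <- c(rep("x", 17), rep("y", 3), "z", "z")
  targs <- c(rep("x", 20), "q", "q")
  excl <- c(rep(FALSE, 20), TRUE, TRUE)
  expect_equal(performance(preds, targs, excl), 0.85)
  expect_error(performance(character(0), character(0), logical(0)), "empty")
})

test_that("counting performance scores only the word-final predictions", {
  # stream "abbbc abbbc": always predicting b
  targets <- c("b", "b", "b", "c", "a", "b", "b", "b", "c", "a")
  final <- targets == "c"
  excl <- targets == "a"
  preds <- rep("b", 10)
  expect_equal(counting_performance(preds, targets, final), 0)
  expect_equal(performance(preds, targets, excl), 6 / 8)
  preds2 <- ifelse(final, "c", "x")
  expect_equal(counting_performance(preds2, targets, final), 1)
  expect_error(counting_performance(character(0), character(0), logical(0)),
               "empty")
})

test_that("generation performance is complete-word coverage", {
  words <- list(as.character(1:4), as.character(4:1))
  expect_equal(generation_performance(strsplit("12341234", "")[[1]], words), 1)
  expect_equal(generation_performance(rep("1", 10), words), 0)
  expect_equal(generation_performance(strsplit("12x4321x", "")[[1]], words),
               4 / 8)
})

test_that("exploration counts unique non-target subsequences per window", {
  words <- list(as.character(1:4), as.character(4:1))
  # a perfect word stream only produces the few boundary-crossing
  # subsequences; a random stream explores far more
  pure <- rep(as.character(1:4), 50)
  tr <- exploration_trace(pure, words, window = 100)
  expect_true(all(tr$unique_sequences <= 6))
  set.seed(13)
  noisy <- as.character(sample(1:4, 200, TRUE))
  tr2 <- exploration_trace(noisy, words, window = 100)
  expect_true(all(tr2$unique_sequences > max(tr$unique_sequences)))
})

test_that("generators are pure functions of their arguments", {
  expect_identical(gen_occluder(100, seed = 3), gen_occluder(100, seed = 3))
  expect_identical(gen_parity(3, 100, seed = 3), gen_parity(3, 100, seed = 3))
  expect_false(identical(gen_memory(2, 100, seed = 1),
                         gen_memory(2, 100, seed = 2)))
  # generation does not disturb the caller's RNG state
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(gen_counting(4, 100, seed = 1))
  expect_equal(runif(1), before)
})
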