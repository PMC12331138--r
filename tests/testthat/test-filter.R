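test_that("threshold filter reproduces the hand-computed example", {
  # candidates t in {1,2,3,5}: FDP-hat = 3/3, 2/3, 1/2, 1/1 -> first <= 0.5 is t = 3
  res <- knockoff_threshold(c(3, -1, 2, -2, 5), q = 0.5, offset = 1)
  expect_equal(res$threshold, 3)
  expect_equal(res$selected, c(1L, 5L))
})

test_that("all-negative statistics select nothing", {
  res <- knockoff_threshold(c(-1, -2, -0.5), q = 0.3)
  expect_equal(res$threshold, Inf)
  expect_length(res$selected, 0)
})

test_that("threshold filter matches the exhaustive brute-force scan", {
  for (i in 1:200) {
    W <- random_W(sample(5:20, 1), seed = i)
    q <- runif(1, 0.05, 0.6)
    res <- knockoff_threshold(W, q = q)
    oracle <- brute_threshold(W, q)
    expect_equal(res$threshold, oracle$threshold)
    expect_equal(res$selected, oracle$selected)
  }
})

test_that("sequential filter evaluates FDP-hat per step and rejects the positive tail", {
  W <- rep(1, 20) # all positive: FDP-hat_0 = 1/20 = 0.05 <= 0.1
  res <- sequential_filter(W, seq_len(20), q = 0.1)
  expect_equal(res$fdphat_path[1], 0.05)
  expect_equal(res$stop_k, 0L)
  expect_equal(res$selected, 1:20)

  res_neg <- sequential_filter(rep(-1, 10), 1:10, q = 0.5)
  expect_length(res_neg$selected, 0)
  expect_true(all(res_neg$fdphat_path > 0.5))

  expect_error(sequential_filter(W, c(1:19, 19)), "permutation")
})

test_that("sequential filter with ascending-|W| ordering equals the threshold filter", {
  for (i in 1:300) {
    W <- random_W(sample(5:30, 1), seed = 1000 + i)
    q <- runif(1, 0.05, 0.6)
    a <- knockoff_threshold(W, q = q)
    b <- sequential_filter(W, threshold_ordering(W), q = q)
    expect_identical(a$selected, b$selected)
    # with ties broken by index alone the sequential form can cut inside a
    # tie group, so it selects a superset at the same estimated-FDP level
    loose <- sequential_filter(W, order(abs(W), seq_along(W)), q = q)
    expect_true(all(a$selected %in% loose$selected))
  }
})

test_that("enlarging q never shrinks the rejection set", {
  for (i in 1:50) {
    W <- random_W(25, seed = 2000 + i)
    qs <- c(0.05, 0.1, 0.2, 0.4, 0.6)
    prev_t <- integer(0)
    prev_s <- integer(0)
    ord <- threshold_ordering(W)
    for (q in qs) {
      cur_t <- knockoff_threshold(W, q = q)$selected
      cur_s <- sequential_filter(W, ord, q = q)$selected
      expect_true(all(prev_t %in% cur_t))
      expect_true(all(prev_s %in% cur_s))
      prev_t <- cur_t
      prev_s <- cur_s
    }
  }
})

test_that("fdphat path from the reverse cumulative pass equals a naive recount", {
  W <- random_W(40, seed = 9)
  ord <- sample(40)
  res <- sequential_filter(W, ord, q = 0.2)
  naive <- sapply(0:39, function(k) {
    tail_idx <- ord[setdiff(seq_len(40), seq_len(k))]
    (1 + sum(W[tail_idx] < 0)) / max(sum(W[tail_idx] > 0), 1)
  })
  expect_equal(res$fdphat_path, naive)
})

test_that("zero statistics are never rejected and offset 0 warns", {
  W <- c(0, 0, 2, 3, 1.5, 0, -1)
  res <- knockoff_threshold(W, q = 0.9)
  expect_false(any(W[res$selected] == 0))
  expect_warning(knockoff_threshold(W, q = 0.2, offset = 0), "offset")
  expect_error(knockoff_threshold(W, q = 1.2), "q")
})
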