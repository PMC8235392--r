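test_that("exact MWU reproduces textbook cases", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6), method = "exact")
  expect_equal(res$U, 0)
  expect_equal(res$p_value, 0.1)       # 2 * (1 / choose(6, 3)) * 2 tails
  same <- mann_whitney_u(c(2, 5, 5, 9), c(2, 5, 5, 9), method = "exact")
  expect_equal(same$p_value, 1)
})

test_that("exact MWU matches brute-force enumeration, ties included", {
  set.seed(17)
  for (rep in 1:40) {
    n_a <- sample(2:4, 1L); n_b <- sample(2:4, 1L)
    a <- sample(1:5, n_a, replace = TRUE)   # small support forces ties
    b <- sample(1:5, n_b, replace = TRUE)
    got <- mann_whitney_u(a, b, method = "exact")
    want <- mwu_brute_force(a, b)
    expect_equal(got$U, want$U, label = paste("U for", rep))
    expect_equal(got$p_value, want$p_value, tolerance = 1e-12,
                 label = paste("p for", rep))
  }
})

test_that("normal approximation tracks the exact test at n = 10 vs 10", {
  set.seed(23)
  for (rep in 1:10) {
    a <- stats::rnorm(10); b <- stats::rnorm(10, mean = rep / 10)
    p_ex <- mann_whitney_u(a, b, method = "exact")$p_value
    p_no <- mann_whitney_u(a, b, method = "normal")$p_value
    expect_lt(abs(p_ex - p_no), 0.01)
  }
})

test_that("the normal path agrees with the reference implementation", {
  set.seed(31)
  a <- stats::rnorm(15); b <- stats::rnorm(15, 0.4)   # continuous: no ties
  ours <- mann_whitney_u(a, b, method = "normal")
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("MWU is invariant under strictly monotone transforms", {
  set.seed(41)
  a <- stats::rnorm(8); b <- stats::rnorm(6, 0.5)
  base <- mann_whitney_u(a, b, method = "exact")
  for (f in list(function(x) exp(x), function(x) x^3,
                 function(x) 5 * x - 2)) {
    tr <- mann_whitney_u(f(a), f(b), method = "exact")
    expect_equal(tr$U, base$U)
    expect_equal(tr$p_value, base$p_value)
  }
})

test_that("two-sample t handles identity, shift and the Welch identity", {
  x <- c(1, 2, 3, 4, 5)
  same <- two_sample_t(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  set.seed(5)
  a <- stats::rnorm(10); b <- a + 10
  expect_lt(two_sample_t(a, b)$p_value, 1e-3)
  # equal variances and ns: Welch df equals pooled df, same t and p
  b2 <- rev(a) + 0.5
  w <- two_sample_t(a, b2, equal_var = FALSE)
  p <- two_sample_t(a, b2, equal_var = TRUE)
  expect_equal(w$t, p$t, tolerance = 1e-12)
  expect_equal(w$p_value, p$p_value, tolerance = 1e-12)
  flat <- two_sample_t(c(2, 2), c(2, 2))
  expect_true(flat$flagged)
  expect_equal(flat$p_value, 1)
})

test_that("drip loss percentage and time normalization are linear", {
  expect_equal(drip_loss_percent(200, 190), 5)
  expect_equal(drip_loss_percent(200, 190, 25, normalize_hours = 20), 4)
  expect_equal(drip_loss_percent(150, 150, 20, normalize_hours = 16), 0)
  expect_error(drip_loss_percent(200, 190, 0, normalize_hours = 20),
               "storage_hours")
})

test_that("comparison_table lays out one row pair per temperature plus next day", {
  set.seed(9)
  labs <- c(as.character(seq(0, 4, 0.5)), "next_day")
  py <- do.call(rbind, lapply(labs, function(l) {
    data.frame(temperature_label = l,
               group = rep(c("fast_thaw", "slow_thaw"), each = 10),
               py = c(stats::rnorm(10, 16, 3), stats::rnorm(10, 10, 3)))
  }))
  tab <- comparison_table(py)
  expect_equal(nrow(tab), 2L * (length(labs)))
  expect_true(all(!is.na(tab$p_value)))
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
  expect_true(all(tab$p_holm >= tab$p_value - 1e-12))
  expect_true(all(tab$count == 10))
  expect_false(any(tab$flagged))
})

test_that("a missing cell yields a flagged row without an exception", {
  py <- data.frame(temperature_label = "0", group = "fast_thaw",
                   py = stats::rnorm(5, 15))
  tab <- comparison_table(py, temperatures = 0)
  expect_equal(nrow(tab), 4L)  # 0 and next_day, two groups each
  row0 <- tab[tab$temperature_label == "0" & tab$group == "slow_thaw", ]
  expect_true(row0$flagged)
  expect_true(is.na(row0$p_value))
  expect_equal(tab$count[tab$group == "fast_thaw" &
                           tab$temperature_label == "0"], 5L)
})

test_that("py_by_temperature maps fits onto the schedule", {
  co <- small_cohort(n_fast = 1L, n_slow = 1L)
  fits <- fit_cole_cohort(co)
  py <- py_by_temperature(fits)
  expect_equal(nrow(py), nrow(fits))
  expect_true("next_day" %in% py$temperature_label)
  expect_setequal(unique(py$group), c("fast_thaw", "slow_thaw"))
})
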