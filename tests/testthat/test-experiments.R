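test_that("rank-sum comparison matches an exhaustive permutation oracle", {
  a <- c(1, 2, 3, 4, 5, 6, 7, 8)
  b <- c(11, 12, 13, 14, 15, 16, 17, 18)
  r <- compare_conditions(a, b)
  expect_equal(r$statistic, 0)          # complete separation
  expect_equal(r$method, "exact")
  expect_equal(r$p_value, mw_exact_oracle(a, b))
  # a handful of random small-sample cases against the oracle
  set.seed(10)
  for (i in 1:5) {
    x <- rnorm(6)
    y <- rnorm(7, mean = 0.5)
    expect_equal(compare_conditions(x, y)$p_value, mw_exact_oracle(x, y),
                 tolerance = 1e-10)
  }
})

test_that("rank-sum comparison handles identity, shifts and errors", {
  x <- c(1.2, 3.4, 2.2, 5.1, 0.3)
  expect_gt(compare_conditions(x, x)$p_value, 0.9)   # identical samples
  a <- c(1, 5, 3, 8); b <- c(2, 9, 4, 7)
  expect_equal(compare_conditions(a + 100, b + 100)$statistic,
               compare_conditions(a, b)$statistic)
  expect_error(compare_conditions(numeric(0), 1:3), "empty")
})

test_that("condition summaries agree with direct percentile computation", {
  set.seed(11)
  v <- rnorm(40)
  cs <- condition_summary("baseline", v)
  q <- unname(quantile(v, c(0.25, 0.5, 0.75)))
  expect_equal(cs$median, q[2])
  expect_equal(cs$q1, q[1])
  expect_equal(cs$q3, q[3])
  iqr <- q[3] - q[1]
  inside <- v[v >= q[1] - 1.5 * iqr & v <= q[3] + 1.5 * iqr]
  expect_equal(cs$whiskers, range(inside))
  expect_setequal(cs$outliers, setdiff(v, inside))
  expect_true(cs$q1 <= cs$median && cs$median <= cs$q3)
})

test_that("triplet sweep has the expected shape and is order-invariant", {
  m <- sweep_triplets(k1 = c(-10, 10), k2 = 0, k3 = c(0, 1),
                      n_reps = 2, window = 30, stim_duration = 25, seed = 3)
  expect_equal(nrow(m), 2 * 1 * 2 * 2)
  expect_true(all(m$mean_hpd_duration_s >= 0))
  # reversing the axis order must not change any per-triplet result
  m2 <- sweep_triplets(k1 = c(10, -10), k2 = 0, k3 = c(1, 0),
                       n_reps = 2, window = 30, stim_duration = 25, seed = 3)
  key <- function(d) d[order(d$k1, d$k3, d$rep),
                       c("k1", "k2", "k3", "rep", "mean_hpd_duration_s")]
  expect_equal(key(m), key(m2), ignore_attr = TRUE)
})

test_that("mean discharge duration is non-increasing in dendritic-interneuron depolarization", {
  # scored over the stimulated 50 s so that discharges recurring after the
  # epoch do not add k3-independent noise
  m <- sweep_triplets(k1 = 0, k2 = 0, k3 = c(0, 5, 10, 20, 30),
                      n_reps = 8, window = 50, stim_duration = 50, seed = 17)
  agg <- tapply(m$mean_hpd_duration_s, m$k3, mean)
  agg <- agg[order(as.numeric(names(agg)))]
  expect_true(all(diff(agg) <= 0.25))   # non-increasing up to replicate noise
  expect_lt(agg[length(agg)], 0.5 * agg[1])
})

test_that("a null protocol leaves all conditions indistinguishable", {
  prot <- build_protocol("protocol1", amplitude = 1e-9, t0 = 480)
  pr <- run_protocol(prot, triplet_preset("suppressive"), seed = 19)
  w <- pr$windows
  expect_equal(sum(w$condition != "baseline"), nrow(prot))
  st <- compare_conditions(
    w$relative_duration[w$condition != "baseline"],
    w$relative_duration[w$condition == "baseline"])
  expect_gt(st$p_value, 0.05)
})

test_that("suppressive stimulation lowers discharge duration during epochs only for its polarity", {
  prot <- build_protocol("protocol1", t0 = 480)
  pr <- run_protocol(prot, triplet_preset("suppressive"), seed = 23)
  w <- pr$windows
  # sub-session 1 carries the suppressive orientation, sub-session 2 the
  # inverted one
  supp <- w$relative_duration[w$condition == "stim"]
  inv <- w$relative_duration[w$condition == "stim_inverted"]
  base <- w$relative_duration[w$condition == "baseline"]
  expect_lt(median(supp), median(base))
  expect_gt(median(inv), median(supp))
})

test_that("protocol runs are reproducible under a master seed", {
  prot <- build_protocol("protocol2", t0 = 0)
  a <- run_protocol(prot, triplet_preset("suppressive"), window = 300,
                    seed = 29)
  b <- run_protocol(prot, triplet_preset("suppressive"), window = 300,
                    seed = 29)
  expect_identical(a$windows, b$windows)
  expect_equal(sum(a$windows$condition != "baseline"), 11)
})
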