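test_that("compute_work integrates constant, zero, and ramp forces", {
  # constant 100 kJ/mol/nm over 1 nm in 10 uniform steps
  x <- seq(0, 1, length.out = 11)
  pf <- force_profile(seq_along(x), rep(100, 11), x)
  expect_equal(compute_work(pf)$w_pull, 100)
  expect_equal(compute_work(pf, units = "kcal/mol")$w_pull, 100 / 4.184)

  pf0 <- force_profile(1:5, rep(0, 5), seq(0, 1, length.out = 5))
  expect_equal(compute_work(pf0)$w_pull, 0)
  expect_equal(compute_work(pf0)$f_max, 0)

  # F = c x, c = 50 kJ/mol/nm^2, x: 0 -> 2 nm in 1e4 steps -> c d^2 / 2
  x <- seq(0, 2, length.out = 1e4 + 1)
  pf <- force_profile(seq_along(x), 50 * x, x)
  expect_equal(compute_work(pf)$w_pull, 100, tolerance = 1e-3)
  expect_equal(compute_work(pf, method = "trapezoid")$w_pull, 100,
               tolerance = 1e-6)
  expect_equal(compute_work(pf)$f_max, 100)
})

test_that("work is additive over contiguous profile segments", {
  set.seed(3)
  t <- seq(0.01, 5, by = 0.01)
  f <- 40 + cumsum(rnorm(length(t)))
  x <- cumsum(abs(rnorm(length(t), 0.001, 0.002)))
  whole <- force_profile(t, f, x)
  cut <- 240
  a <- force_profile(t[1:cut], f[1:cut], x[1:cut])
  # the second segment keeps the last point of the first as its origin
  b <- force_profile(t[cut:length(t)], f[cut:length(t)], x[cut:length(t)])
  expect_equal(compute_work(whole)$w_pull,
               compute_work(a)$w_pull + compute_work(b)$w_pull,
               tolerance = 1e-10)
})

test_that("pearson matches the textbook formula and handles exact lines", {
  x <- 1:10
  expect_equal(pearson(x, 2 * x + 1)$r, 1)
  expect_equal(pearson(x, -x)$r, -1)
  expect_equal(pearson(x, -x)$r_squared, 1)

  set.seed(8)
  a <- rnorm(6)
  b <- rnorm(6)
  got <- pearson(a, b)
  # independent product-moment formula
  r_ref <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(got$r, r_ref, tolerance = 1e-12)
  expect_equal(got$r_squared, r_ref^2, tolerance = 1e-12)
  expect_equal(got$n, 6)
  expect_error(pearson(rep(1, 5), 1:5), "zero variance")
})

test_that("pearson is invariant under positive affine maps and flips sign
           under negative scaling", {
  set.seed(12)
  a <- rnorm(20)
  b <- a + rnorm(20, sd = 0.5)
  r0 <- pearson(a, b)$r
  expect_equal(pearson(3 * a + 7, b)$r, r0, tolerance = 1e-12)
  expect_equal(pearson(a, -2 * b + 1)$r, -r0, tolerance = 1e-12)
})

test_that("affinity_table stores ln(IC50) in mol/L", {
  tab <- affinity_table(c("l1", "l2"), c(1e-6, 5e-8))
  expect_equal(tab$ln_ic50, log(c(1e-6, 5e-8)))
  expect_error(affinity_table("x", -1))
})

test_that("success_rate counts exited trajectories", {
  mk <- function(s) structure(list(status = s), class = "path_result")
  expect_equal(success_rate(replicate(20, mk("exited"), FALSE)), 100)
  expect_equal(success_rate(replicate(5, mk("stuck"), FALSE)), 0)
  expect_equal(success_rate(list(mk("exited"), mk("exited"), mk("exited"),
                                 mk("stuck"), mk("max_intervals"))), 60)
})

test_that("pathway_percentage reproduces the published worked example", {
  counts <- c(PW1 = 11, PW2 = 31, PW3 = 9, PW4 = 2, PW5 = 7)
  pp <- pathway_percentage(counts)
  expect_equal(pp$percent, 100 * counts / 60, ignore_attr = TRUE)
  # the least-populated pathway: 2/60 = 3.33% which rounds to 3%
  least <- pp[which.min(pp$count), ]
  expect_equal(least$percent, 10 / 3, tolerance = 1e-12)
  expect_equal(least$percent_rounded, 3)
  expect_equal(pathway_percentage(c(A = 31, B = 29))$percent[1], 51.67,
               tolerance = 1e-3)
  expect_equal(pathway_percentage(c(only = 4))$percent, 100)
  expect_error(pathway_percentage(c(a = 0, b = 0)), "positive")
})

test_that("gate classification follows first-gate-entered semantics", {
  gates <- data.frame(label = c("A", "B"),
                      x = c(0, 2), y = c(0, 0), z = c(2, 0),
                      radius = c(0.4, 0.4))
  up <- fake_path(cbind(0, 0, seq(0, 2.5, by = 0.25)))
  right <- fake_path(cbind(seq(0, 2.5, by = 0.25), 0, 0))
  nowhere <- fake_path(cbind(0, seq(0, 2.5, by = 0.25), 0))
  expect_equal(classify_pathways(list(up, right, nowhere), gates,
                                 site_radius = 0.5),
               c("A", "B", "unassigned"))
  bad <- data.frame(label = c("A", "B"), x = c(0, 0.1), y = 0, z = 0,
                    radius = c(0.4, 0.4))
  expect_error(classify_pathways(list(up), bad, site_radius = 0.5),
               "disjoint")
})

test_that("gate-free fallback clusters exit directions by angle", {
  bundle <- function(base, jitter, n = 4)
    lapply(seq_len(n), function(i) {
      d <- depull:::unit_vec(base + jitter * c(sin(i), cos(i), 0.1 * i))
      fake_path(rbind(c(0, 0, 0), t(d * 2)))
    })
  paths <- c(bundle(c(0, 0, 1), 0.08), bundle(c(1, 0, 0), 0.08))
  labs <- classify_pathways(paths, gates = NULL, site_radius = 0.5)
  expect_equal(length(unique(labs)), 2)
  expect_equal(length(unique(labs[1:4])), 1)
  expect_equal(length(unique(labs[5:8])), 1)
})

test_that("bootstrap populations: degenerate and symmetric cases", {
  one <- bootstrap_populations(rep("A", 8), 500, seed = 1)
  expect_equal(one$mean_percent, 100)
  expect_equal(one$sd_percent, 0)

  two <- bootstrap_populations(c("A", "B"), 4000, seed = 2)
  expect_lt(max(abs(two$mean_percent - 50)), 3 * 100 * 0.5 / sqrt(4000))
})

test_that("bootstrap means converge to sample proportions with more
           resamples", {
  labels <- rep(c("A", "B", "C"), c(11, 31, 18))
  small <- bootstrap_populations(labels, 20000, seed = 3)
  big <- bootstrap_populations(labels, 200000, seed = 4)
  props <- 100 * c(11, 31, 18) / 60
  expect_lt(max(abs(small$mean_percent - props)), 0.5)
  expect_lt(max(abs(big$mean_percent - props)),
            max(abs(small$mean_percent - props)) + 0.05)
  expect_equal(sum(small$mean_percent), 100, tolerance = 1e-6)
})

test_that("secondary peaks are detected on two-peak traces and not on
           single-peak traces", {
  t <- seq(0.02, 60, by = 0.02)
  one <- 30 * exp(-(t - 18)^2 / 40)
  two <- one + 26 * exp(-(t - 45)^2 / 30)
  x <- cumsum(rep(0.003, length(t)))
  expect_false(has_secondary_peak(force_profile(t, one, x)))
  expect_true(has_secondary_peak(force_profile(t, two, x)))
})

test_that("summarize_work flags noisy ensembles", {
  mk <- function(w) {
    t <- 1:50
    structure(list(status = "exited",
                   profile = force_profile(t, rep(w, 50),
                                           seq(0, 1, length.out = 50))),
              class = "path_result")
  }
  quiet <- summarize_work(list(mk(10), mk(10.2), mk(9.9)))
  expect_equal(quiet$n, 3)
  expect_warning(summarize_work(list(mk(5), mk(15), mk(30))), "10%")
})
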