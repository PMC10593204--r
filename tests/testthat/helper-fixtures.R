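# Shared fixtures: nominal plants, a noise-free participant, tf comparison.

poly_mul_ <- heartpace:::poly_mul

nominal_p1 <- function() first_order_plant(28.57, 70.56)
nominal_p2 <- function() second_order_plant(24.70, 18.60, 37.95)

quiet_truth <- function(hr_rest = 70, age = 30, seed = 11) {
  list(k2 = 24.70, tau21 = 18.60, tau22 = 37.95, hr_rest = hr_rest, age = age,
       dist_sd = 0, dist_cutoff_hz = 0.05, noise_sd = 0, seed = seed)
}

expect_tf_equal <- function(a, b, tol = 1e-9) {
  a <- tf_minreal(a); b <- tf_minreal(b)
  expect_equal(length(a$num), length(b$num))
  expect_equal(length(a$den), length(b$den))
  scale <- max(abs(c(a$num, a$den, b$num, b$den)))
  expect_lt(max(abs(a$num - b$num)), tol * scale)
  expect_lt(max(abs(a$den - b$den)), tol * scale)
}

# Random stable strictly proper plant: distinct negative real poles spread
# over about two decades, positive DC gain.
random_stable_plant <- function(order) {
  poles <- -exp(runif(order, log(1e-3), log(1)))
  den <- 1
  for (p in poles) den <- heartpace:::poly_mul(den, c(1, -p))
  nb <- sample.int(order, 1) - 1L   # numerator degree < order
  num <- c(runif(1, 0.1, 5), if (nb > 0) runif(nb, -1, 1) * 0.1)
  tf(rev(num), den)   # constant term first -> reversed to descending
}
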