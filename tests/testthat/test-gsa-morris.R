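test_that("linear models give exact elementary effects with zero spread", {
  mp <- morris_plan(data.frame(name = c("a", "b", "c"),
                               min = c(0, 0, 0), max = c(1, 1, 1)),
                    p = 4, r = 30, seed = 13)
  f <- function(x) 3 * x[["a"]] - 2 * x[["b"]] + 0 * x[["c"]]
  res <- morris_screen(f, mp)
  res <- res[order(res$parameter), ]
  expect_equal(res$mu_star, c(3, 2, 0), tolerance = 1e-10)
  expect_equal(res$mu, c(3, -2, 0), tolerance = 1e-10)
  expect_lt(max(res$sigma), 1e-10)
  expect_equal(select_driver(morris_screen(f, mp)), "a")

  fc <- function(x) 42
  resc <- morris_screen(fc, mp)
  expect_equal(resc$mu_star, c(0, 0, 0))
})

test_that("mu* bounds |mu| and rankings survive parameter rescaling", {
  mp <- morris_plan(data.frame(name = c("a", "b"), min = c(0, 0), max = c(1, 1)),
                    p = 4, r = 100, seed = 3)
  f <- function(x) x[["a"]] * x[["b"]] + 2 * x[["a"]]
  res <- morris_screen(f, mp)
  expect_true(all(res$mu_star >= abs(res$mu) - 1e-12))
  expect_true(all(res$sigma >= 0))
  # same model expressed on a rescaled box: unit-box elementary effects and
  # hence the ranking must be unchanged
  mp2 <- morris_plan(data.frame(name = c("a", "b"),
                                min = c(0, 0), max = c(10, 100)),
                     p = 4, r = 100, seed = 3)
  f2 <- function(x) (x[["a"]] / 10) * (x[["b"]] / 100) + 2 * (x[["a"]] / 10)
  res2 <- morris_screen(f2, mp2)
  expect_equal(res$mu_star, res2$mu_star, tolerance = 1e-10)
  expect_equal(res$parameter, res2$parameter)
  # determinism
  expect_identical(morris_screen(f, mp), morris_screen(f, mp))
})

test_that("sampled estimates match exhaustive trajectory enumeration for x1*x2", {
  # brute-force oracle at p = 4 (Delta = 2/3, base levels {0, 1/3}): enumerate
  # every (base point, direction, order) trajectory and average |EE| exactly
  delta <- 2 / 3
  bases <- expand.grid(x1 = c(0, 1 / 3), x2 = c(0, 1 / 3),
                       d1 = c(-1, 1), d2 = c(-1, 1), first = c(1, 2))
  ee1 <- ee2 <- numeric(nrow(bases))
  for (i in seq_len(nrow(bases))) {
    b <- bases[i, ]
    x <- c(b$x1, b$x2)
    d <- c(b$d1, b$d2)
    x <- ifelse(d < 0, x + delta, x)        # shift down-steps onto the grid
    ord <- if (b$first == 1) c(1, 2) else c(2, 1)
    f <- function(z) z[1] * z[2]
    for (j in ord) {
      x2 <- x; x2[j] <- x[j] + d[j] * delta
      ee <- (f(x2) - f(x)) / (d[j] * delta)
      if (j == 1) ee1[i] <- ee else ee2[i] <- ee
      x <- x2
    }
  }
  oracle_mu_star <- c(mean(abs(ee1)), mean(abs(ee2)))

  mp <- morris_plan(data.frame(name = c("x1", "x2"), min = c(0, 0),
                               max = c(1, 1)), p = 4, r = 500, seed = 99)
  res <- morris_screen(function(x) x[["x1"]] * x[["x2"]], mp)
  res <- res[order(res$parameter), ]
  # Monte-Carlo error at r = 500 is ~ sd/sqrt(500) ~ 0.015
  expect_lt(max(abs(res$mu_star - oracle_mu_star)), 0.06)
})

test_that("tie-breaking prefers larger sigma then lexicographic order", {
  tie <- structure(data.frame(parameter = c("a", "b"), mu = c(1, 1),
                              mu_star = c(1, 1), sigma = c(0.1, 0.5),
                              rank = c(1, 2)),
                   class = c("morris_result", "data.frame"))
  expect_equal(select_driver(tie), "b")
  tie2 <- tie; tie2$sigma <- c(0.5, 0.5)
  expect_equal(select_driver(tie2), "a")
})

test_that("surface pH dominates the dissolution screening", {
  # screen the in vitro forward model over documented formulation-parameter
  # ranges; the output is the fraction dissolved at 30 min in the medium
  ranges <- data.frame(
    name = c("surface_pH", "S0_scalar", "h_max_um", "solubility_factor"),
    min = c(5.0, 0.5, 10, 0.5),
    max = c(7.0, 2.0, 50, 2.0))
  prot_screen <- dissolution_protocol(list(protocol_stage("MB7", 6.5, 900, 1)))
  f <- function(x) {
    d <- fix_drug
    d$S0 <- d$S0 * x[["S0_scalar"]] * x[["solubility_factor"]]
    sim <- quiet_sim(d, fix_psd5, prot_screen, x[["surface_pH"]],
                     h_max_um = x[["h_max_um"]], times_h = 0.5)
    sim$f_dissolved_pct[1]
  }
  res <- morris_screen(f, morris_plan(ranges, p = 4, r = 20, seed = 17))
  expect_equal(select_driver(res), "surface_pH")
})
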