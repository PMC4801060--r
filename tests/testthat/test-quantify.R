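# Read-rate model and Bayesian posteriors: GC correction, ZTNB dispersion,
# stack flagging, positional bootstrap, and discretized PSI/dPSI inference.

# ---- GC correction ----------------------------------------------------

test_that("disabled GC correction is the identity", {
  cts <- make_counts(junction_counts_row("e1", "chr1", "+", 200, 500, c(2, 3)))
  expect_identical(gc_correct(cts, enable = FALSE), cts)
  expect_identical(gc_correct(cts), cts)  # no gc values present
})

test_that("equal GC across junctions leaves counts unchanged", {
  cts <- make_counts(
    junction_counts_row("e1", "chr1", "+", 200, 500, c(10, 12)),
    junction_counts_row("e1", "chr1", "+", 700, 900, c(4, 6))
  )
  cts$gc <- 0.5
  out <- gc_correct(cts, enable = TRUE)
  expect_equal(out$count, cts$count)
  cts$gc <- 1.5
  expect_error(gc_correct(cts, enable = TRUE), "outside")
})

test_that("correction shrinks a simulated monotone GC trend", {
  sim <- simulate_genes(120, prop_differential = 0, seed = 21)
  cts <- simulate_counts(sim$truth, coverage = 60, gc_bias = 3, seed = 21)
  totals <- function(x) x %>%
    dplyr::group_by(donor_end, acceptor_start) %>%
    dplyr::summarise(total = sum(count), gc = dplyr::first(gc),
                     .groups = "drop")
  slope <- function(t) unname(coef(lm(total ~ gc, data = t))[2])
  before <- slope(totals(cts))
  after <- slope(totals(gc_correct(cts, enable = TRUE)))
  expect_gt(abs(before), 0)
  expect_lt(abs(after), 0.5 * abs(before))
})

# ---- ZTNB dispersion --------------------------------------------------

sim_nb_counts <- function(n_junctions, positions, mu, size, seed) {
  withr::local_seed(seed)
  dplyr::bind_rows(lapply(seq_len(n_junctions), function(j) {
    junction_counts_row("e1", "chr1", "+", j * 1000, j * 1000 + 300,
                        rnbinom(positions, mu = mu, size = size))
  })) %>% as_junction_counts()
}

test_that("the ZTNB dispersion is recovered from NB simulations", {
  cts <- sim_nb_counts(1000, 40, mu = 20, size = 5, seed = 31)
  r <- fit_dispersion(cts, seed = 1)
  expect_gt(r, 5 * 0.8)
  expect_lt(r, 5 * 1.2)
  # deterministic given the seed
  expect_identical(unclass(r), unclass(fit_dispersion(cts, seed = 1)))
})

test_that("Poisson-like data drives the dispersion to the cap", {
  withr::local_seed(32)
  cts <- dplyr::bind_rows(lapply(seq_len(300), function(j) {
    junction_counts_row("e1", "chr1", "+", j * 1000, j * 1000 + 300,
                        rpois(40, 20))
  })) %>% as_junction_counts()
  r <- fit_dispersion(cts, r_cap = 1e4)
  expect_gte(r, 1e3)
})

test_that("degenerate all-equal counts return the floor with a warning", {
  cts <- make_counts(
    junction_counts_row("e1", "chr1", "+", 200, 500, rep(1, 12)))
  expect_warning(r <- fit_dispersion(cts, min_reads = 5), "floor")
  expect_equal(as.numeric(r), 1e-2)
})

# ---- stack flagging ---------------------------------------------------

test_that("an extreme single-position spike is flagged, others are not", {
  cts <- make_counts(
    junction_counts_row("e1", "chr1", "+", 200, 500, c(3, 4, 3, 5000)))
  out <- flag_stacks(cts, r = 5, threshold = 1e-7)
  expect_equal(out$stack, c(FALSE, FALSE, FALSE, TRUE))
  # oracle: direct NB tail with mean of the other non-zero positions
  p <- pnbinom(5000 - 1, size = 5, mu = mean(c(3, 4, 3)), lower.tail = FALSE)
  expect_lte(p, 1e-7)
  p_ok <- pnbinom(4 - 1, size = 5, mu = mean(c(3, 3, 5000)), lower.tail = FALSE)
  expect_gt(p_ok, 1e-7)
})

test_that("homogeneous NB data yields (almost) no flags", {
  cts <- sim_nb_counts(500, 40, mu = 20, size = 5, seed = 33)  # 2e4 positions
  out <- flag_stacks(cts, r = 5, threshold = 1e-7)
  expect_lte(sum(out$stack), 1)
})

test_that("threshold 1 flags every testable non-zero position", {
  cts <- make_counts(
    junction_counts_row("e1", "chr1", "+", 200, 500, c(3, 4, 3)),
    junction_counts_row("e1", "chr1", "+", 700, 900, c(7))  # single position
  )
  out <- flag_stacks(cts, r = 5, threshold = 1)
  expect_true(all(out$stack[out$donor_end == 200]))
  expect_false(any(out$stack[out$donor_end == 700]))  # untestable, retained
})

# ---- bootstrap --------------------------------------------------------

test_that("bootstrap rates have the exact support and mean of resampling", {
  cts <- make_counts(junction_counts_row("e1", "chr1", "+", 200, 500,
                                         c(2, 2, 1)))
  boot <- bootstrap_rates(cts, M = 4000, seed = 5)
  mu <- boot$mu[[1]]
  expect_equal(boot$W, 3)
  expect_true(all(mu >= 3 & mu <= 6))
  # brute-force enumeration of all 27 resamples gives E[mu] = 5
  draws <- expand.grid(c(2, 2, 1), c(2, 2, 1), c(2, 2, 1))
  expect_equal(mean(3 * rowMeans(draws)), 5)
  expect_lt(abs(mean(mu) - 5), 0.1)
})

test_that("a single relevant position has zero resampling variance", {
  cts <- make_counts(junction_counts_row("e1", "chr1", "+", 200, 500, c(7)))
  boot <- bootstrap_rates(cts, M = 50, seed = 5)
  expect_true(all(boot$mu[[1]] == 7))
})

test_that("bootstrap samples are seed-deterministic and order-independent", {
  cts <- make_counts(
    junction_counts_row("e1", "chr1", "+", 200, 500, c(2, 5, 1)),
    junction_counts_row("e1", "chr1", "+", 700, 900, c(4, 4))
  )
  b1 <- bootstrap_rates(cts, M = 20, seed = 9)
  b2 <- bootstrap_rates(cts, M = 20, seed = 9)
  expect_identical(b1$mu, b2$mu)
  # reversing input row order must not change any junction's stream
  b3 <- bootstrap_rates(as_junction_counts(cts[rev(seq_len(nrow(cts))), ]),
                        M = 20, seed = 9)
  expect_identical(b1$mu, b3$mu)
  expect_false(identical(b1$mu, bootstrap_rates(cts, M = 20, seed = 10)$mu))
})

# ---- PSI posterior ----------------------------------------------------

test_that("with no reads the posterior is the discretized Jeffreys prior", {
  post <- psi_posterior(matrix(0, nrow = 2, ncol = 1), prior_config())
  expect_true(all(post$low_confidence))
  expect_equal(post$psi, c(0.5, 0.5))
  jeffreys <- diff(pbeta(seq(0, 1, length.out = 41), 0.5, 0.5))
  expect_equal(post$mass[[1]], jeffreys, tolerance = 1e-12)
  expect_equal(sum(post$mass[[1]]), 1, tolerance = 1e-9)
})

test_that("M = 1 deterministic rates give the closed-form Beta mean", {
  post <- psi_posterior(matrix(c(30, 10), ncol = 1), prior_config())
  expect_equal(post$psi[1], 30.5 / 41, tolerance = 1e-12)
  expect_equal(post$psi[2], 10.5 / 41, tolerance = 1e-12)
  # discretized expectation agrees within one bin width
  e_disc <- sum(post$mass[[1]] * ((1:40) - 0.5) / 40)
  expect_lt(abs(e_disc - 30.5 / 41), 1 / 40)
})

test_that("the J-junction prior is Beta(eta/J, eta(J-1)/J)", {
  post <- psi_posterior(matrix(0, nrow = 3, ncol = 1), prior_config(eta = 1))
  expect_equal(post$psi, rep(1 / 3, 3), tolerance = 1e-12)
  expected <- diff(pbeta(seq(0, 1, length.out = 41), 1 / 3, 2 / 3))
  expect_equal(post$mass[[2]], expected, tolerance = 1e-12)
})

test_that("PSI posteriors normalize and junction means sum to one", {
  withr::local_seed(41)
  for (J in c(2, 3, 5)) {
    mu <- matrix(rpois(J * 30, 15), nrow = J)
    post <- psi_posterior(mu, prior_config())
    for (m in post$mass) expect_equal(sum(m), 1, tolerance = 1e-9)
    expect_equal(sum(post$psi), 1, tolerance = 1e-6)
  }
})

test_that("the grid bin width is exactly 1/V", {
  for (V in c(10, 40, 100)) {
    post <- psi_posterior(matrix(c(5, 5), ncol = 1), prior_config(V = V))
    expect_length(post$mass[[1]], V)
  }
  centers <- lsvtools:::.bin_centers(40)
  expect_equal(unique(round(diff(centers), 12)), 1 / 40)
})

# ---- dPSI prior and posterior ----------------------------------------

test_that("a slab-only mixture reduces the joint prior to independence", {
  pr <- uniform_dpsi_prior(prior_config())
  joint <- dpsi_prior(pr)
  p0 <- diff(pbeta(seq(0, 1, length.out = 41), 0.5, 0.5))
  expect_equal(joint, outer(p0, p0), tolerance = 1e-9)
})

test_that("a spike-only mixture concentrates mass near the diagonal", {
  pr <- prior_config(mixture = data.frame(weight = 1, alpha = 1500,
                                          beta = 1500))
  joint <- dpsi_prior(pr)
  expect_equal(sum(joint), 1, tolerance = 1e-9)
  d <- outer(lsvtools:::.bin_centers(40), lsvtools:::.bin_centers(40), "-")
  expect_gt(sum(joint[abs(d) < 0.05]), 0.95)
})

test_that("the default mixture upweights small dPSI over the uniform slab", {
  near0 <- function(joint) {
    d <- outer(lsvtools:::.bin_centers(40), lsvtools:::.bin_centers(40), "-")
    sum(joint[abs(d) < 0.05])
  }
  expect_gt(near0(dpsi_prior(prior_config())),
            near0(dpsi_prior(uniform_dpsi_prior(prior_config()))))
  bad <- data.frame(weight = c(0.5, 0.4), alpha = c(1, 1), beta = c(1, 1))
  expect_error(prior_config(mixture = bad), "sum to 1")
})

test_that("identical counts give a centred dPSI posterior", {
  mu <- matrix(c(20, 20), ncol = 1)
  post <- dpsi_posterior(mu, mu, prior_config())
  expect_equal(post$dpsi, c(0, 0), tolerance = 1e-9)
  expect_lt(prob_changing(post$mass[[1]], 0.2), 0.05)
  for (m in post$mass) expect_equal(sum(m), 1, tolerance = 1e-9)
})

test_that("with a uniform prior E[dPSI] matches the closed-form difference", {
  pr <- uniform_dpsi_prior(prior_config())
  post <- dpsi_posterior(matrix(c(30, 10), ncol = 1),
                         matrix(c(10, 30), ncol = 1), pr)
  expect_equal(post$dpsi[1], 30.5 / 41 - 10.5 / 41, tolerance = 1e-3)
  expect_equal(post$psi_t[1], 30.5 / 41, tolerance = 1e-12)
})

test_that("swapping conditions mirrors the dPSI posterior", {
  a <- matrix(c(25, 8), ncol = 1); b <- matrix(c(12, 30), ncol = 1)
  p1 <- dpsi_posterior(a, b, prior_config())
  p2 <- dpsi_posterior(b, a, prior_config())
  expect_equal(p1$dpsi, -p2$dpsi, tolerance = 1e-9)
  expect_equal(p1$mass[[1]], rev(p2$mass[[1]]), tolerance = 1e-9)
})

test_that("prob_changing is monotonically non-increasing in the threshold", {
  post <- dpsi_posterior(matrix(c(30, 10), ncol = 1),
                         matrix(c(10, 30), ncol = 1), prior_config())
  cs <- seq(0, 0.9, by = 0.05)
  ps <- vapply(cs, function(c) prob_changing(post$mass[[1]], c), numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("discretized posteriors match fine-grid integration within TV 1e-3", {
  prior <- prior_config()
  # marginal PSI, binary and 3-junction
  for (mu in list(c(30, 10), c(20, 5, 15))) {
    J <- length(mu)
    post <- psi_posterior(matrix(mu, ncol = 1), prior)
    for (j in seq_len(J)) {
      a <- 1 / J + mu[j]; b <- (J - 1) / J + sum(mu) - mu[j]
      expect_lt(tv_dist(post$mass[[j]], fine_psi_oracle(a, b)), 1e-3)
    }
  }
  # joint dPSI, binary and 3-junction
  cases <- list(list(t = c(30, 10), tp = c(10, 30)),
                list(t = c(20, 5, 15), tp = c(5, 20, 15)))
  for (cs in cases) {
    post <- dpsi_posterior(matrix(cs$t, ncol = 1), matrix(cs$tp, ncol = 1),
                           prior)
    for (j in seq_along(cs$t)) {
      orc <- fine_dpsi_oracle(cs$t, cs$tp, prior, j = j)
      expect_lt(tv_dist(post$mass[[j]], orc), 1e-3)
    }
  }
})

test_that("the spike-containing prior never inflates |E[dPSI]|", {
  prior <- prior_config()
  slab <- uniform_dpsi_prior(prior)
  cases <- list(c(30, 10), c(12, 9), c(5, 45), c(22, 20))
  for (mu_t in cases) {
    mu_tp <- rev(mu_t)
    reg <- dpsi_posterior(matrix(mu_t, ncol = 1), matrix(mu_tp, ncol = 1),
                          prior)
    uni <- dpsi_posterior(matrix(mu_t, ncol = 1), matrix(mu_tp, ncol = 1),
                          slab)
    expect_lte(abs(reg$dpsi[1]), abs(uni$dpsi[1]) + 1e-9)
  }
})

# ---- replicates -------------------------------------------------------

test_that("two identical replicates equal one replicate with doubled rates", {
  m <- matrix(c(14, 6, 15, 5), nrow = 2)
  ref <- matrix(c(8, 12, 7, 13), nrow = 2)
  a <- combine_replicates(list(m, m), list(ref), prior_config())
  b <- combine_replicates(list(2 * m), list(ref), prior_config())
  expect_equal(a$dpsi, b$dpsi, tolerance = 1e-12)
  expect_equal(a$mass, b$mass, tolerance = 1e-12)
})

test_that("single-replicate groups reduce to the plain dPSI posterior", {
  m <- matrix(c(14, 6), ncol = 1); ref <- matrix(c(8, 12), ncol = 1)
  a <- combine_replicates(list(m), list(ref), prior_config())
  b <- dpsi_posterior(m, ref, prior_config())
  expect_equal(a$mass, b$mass, tolerance = 1e-12)
})

test_that("replicates with no evidence are dropped with a message", {
  m <- matrix(c(14, 6), ncol = 1); z <- matrix(c(0, 0), ncol = 1)
  ref <- matrix(c(8, 12), ncol = 1)
  expect_message(a <- combine_replicates(list(m, z), list(ref),
                                         prior_config()), "dropped")
  b <- combine_replicates(list(m), list(ref), prior_config())
  expect_equal(a$mass, b$mass, tolerance = 1e-12)
})
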