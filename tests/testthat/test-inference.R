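test_that("posterior naive weight follows the mixture arithmetic", {
  s <- rand_seq(40)
  # hand evaluation with a two-bin prior: bins centered at 0.25 and 0.75
  dens <- c(1.6, 0.4)
  m <- indel_model(mu_prior(0.3, dens, bin_width = 0.5), 0.02, 0.02,
                   geometric_length_distribution(2, 4),
                   geometric_length_distribution(2, 4))
  p <- compute_posterior(s, s, m, method = "grid")
  L0 <- forward_sum(s, s, 0, m, log = FALSE)
  L1 <- forward_sum(s, s, 0.25, m, log = FALSE)
  L2 <- forward_sum(s, s, 0.75, m, log = FALSE)
  denom <- 0.3 * L0 + 0.7 * (1.6 * L1 + 0.4 * L2) * 0.5
  expect_equal(p$f_s, 0.3 * L0 / denom, tolerance = 1e-12)
  expect_equal(p$loglik, log(denom), tolerance = 1e-12)
  # posterior density on the two bins, Bayes by hand
  expect_equal(p$density, c(1.6 * L1, 0.4 * L2) /
                 ((1.6 * L1 + 0.4 * L2) * 0.5), tolerance = 1e-12)
  # naive prior weight 0 forces posterior naive weight 0
  m0 <- indel_model(mu_prior(0, dens, bin_width = 0.5), 0.02, 0.02,
                    geometric_length_distribution(2, 4),
                    geometric_length_distribution(2, 4))
  expect_identical(compute_posterior(s, s, m0, method = "grid")$f_s, 0)
})

test_that("unmutated reads raise the posterior naive weight above the prior", {
  m <- validation_model(f = 0.1)
  s <- rand_seq(300)
  p <- compute_posterior(s, s, m, method = "grid")
  expect_gt(p$f_s, 0.1)
})

test_that("node-interpolated posterior agrees with the exact grid", {
  set.seed(31)
  ts <- synthetic_templates()
  m <- validation_model()
  # smooth realistic prior instead of the flat default
  sp <- shifted_gamma_spec()
  d <- shmindel:::shifted_gamma_density(sp, m$prior$mids)
  m <- indel_model(mu_prior(0.1, d / (sum(d) * 5e-4)), 0.025, 0.025,
                   geometric_length_distribution(15, 30),
                   geometric_length_distribution(15, 30))
  rep <- generate_repertoire(ts, m, n = 6, seed = 32, f = 0.2)
  for (i in seq_along(rep$reads)) {
    tseq <- ts$seqs[[rep$template_id[i]]]
    center <- max(rep$mu[i], 0.01)
    exact <- compute_posterior(rep$reads[[i]], tseq, m, method = "grid")
    approx <- compute_posterior(rep$reads[[i]], tseq, m, center = center,
                                spread = max(sqrt(center / 300), 0.008),
                                n_nodes = 25)
    expect_lt(abs(approx$f_s - exact$f_s), 0.02)
    expect_lt(abs(approx$loglik - exact$loglik), 0.05)
  }
})

test_that("EM prior update is the posterior average", {
  mk <- function(f_s, dens) structure(list(f_s = f_s, density = dens),
                                      class = "sequence_posterior")
  nb <- 100
  d1 <- rep(1, nb); d2 <- c(rep(2, nb / 2), rep(0, nb / 2))
  # two sequences with known weights: hand-computed weighted average
  p <- em_update_prior(list(mk(0.2, d1), mk(0.6, d2)))
  expect_equal(p$f, 0.4)
  expect_equal(p$density, (0.8 * d1 + 0.4 * d2) / 1.2, tolerance = 1e-12)
  # single sequence: prior equals its posterior
  p1 <- em_update_prior(list(mk(0.5, d2)))
  expect_equal(p1$density, d2)
  expect_equal(p1$f, 0.5)
  # all-naive degenerate case keeps the previous density
  prev <- mu_prior(0.5, d1, 1 / nb)
  expect_warning(p2 <- em_update_prior(list(mk(1, d1 * 0)), prev = prev),
                 "naive")
  expect_equal(p2$density, d1)
})

test_that("Monte-Carlo rate samples follow the posterior mixture", {
  mk <- function(f_s, dens) structure(list(f_s = f_s, density = dens),
                                      class = "sequence_posterior")
  nb <- 200
  # degenerate cases
  expect_identical(draw_mu_samples(list(mk(1, rep(1, nb))))[1, 1], 0)
  point <- rep(0, nb); point[60] <- nb
  set.seed(33)
  expect_equal(draw_mu_samples(list(mk(0, point)))[1, 1], (60 - 0.5) / nb,
               tolerance = 1 / nb)
  # KS test against the piecewise-constant CDF
  dens <- dgamma((seq_len(nb) - 0.5) / nb, shape = 3, rate = 20)
  dens <- dens / (sum(dens) / nb)
  draws <- draw_mu_samples(list(mk(0, dens)), n_mc = 2e4)[1, ]
  cdf <- function(q) {
    vapply(q, function(x) {
      full <- floor(x * nb)
      sum(dens[seq_len(full)]) / nb + dens[full + 1] * (x - full / nb)
    }, 0.0)
  }
  expect_gt(suppressWarnings(stats::ks.test(draws, cdf))$p.value, 0.01)
})

test_that("simplex projection is exact and idempotent", {
  expect_equal(project_simplex(c(0.25, 0.75)), c(0.25, 0.75))
  expect_equal(project_simplex(c(1.2, -0.2)), c(1, 0))
  set.seed(34)
  for (k in 1:20) {
    x <- rnorm(15)
    px <- project_simplex(x)
    expect_equal(sum(px), 1)
    expect_true(all(px >= 0))
    expect_equal(project_simplex(px), px)
  }
  expect_equal(clip_rates(c(-0.1, 0.2)), c(0, 0.2))
})

test_that("momentum schedule and projection behave as specified", {
  cfg <- optimizer_config(T = 100, alpha0 = 0.05)
  phi <- c(0.02, 0.03, c(0.6, 0.4), c(0.5, 0.5))
  # zero gradient and no history leaves phi unchanged
  expect_equal(momentum_step(phi, phi, phi * 0, 5, cfg, 2), phi)
  # learning rate at t = T is alpha0 * exp(-2)
  g <- c(1, 0, 0, 0, 0, 0)
  out <- momentum_step(phi, phi, g, 100, cfg, 2)
  expect_equal(out[1] - phi[1], 0.05 * exp(-2) * max(phi[1], cfg$scale_floor))
  # negative rates are clipped at zero
  out2 <- momentum_step(phi, phi, c(-1e6, 0, 0, 0, 0, 0), 1, cfg, 2)
  expect_gte(out2[1], 0)
})

test_that("momentum ascent maximizes a concave toy objective", {
  # maximize -(b - 0.3)^2 over the beta_del slot
  cfg <- optimizer_config(T = 300, alpha0 = 0.4, scale_floor = 0.05)
  phi <- c(0.9, 0.1, 1, 1)
  prev <- phi
  for (t in 1:300) {
    g <- c(-2 * (phi[1] - 0.3), 0, 0, 0)
    nxt <- momentum_step(phi, prev, g, t, cfg, 1)
    prev <- phi
    phi <- nxt
  }
  expect_lt(abs(phi[1] - 0.3), 1e-3)
})

test_that("numerical gradient matches refined finite differences", {
  set.seed(35)
  ts <- synthetic_templates()
  m <- validation_model()
  rep <- generate_repertoire(ts, m, n = 3, seed = 36, f = 0)
  t_stars <- unname(ts$seqs[rep$template_id])
  mu <- pmax(rep$mu, 0.02)
  g <- numerical_gradient(m, rep$reads, t_stars, mu, epsilon = 1e-4)
  # centered difference with a 10x smaller step as the refinement oracle
  for (idx in c(1, 2)) {
    eps <- 1e-5
    shift <- function(h) {
      phi <- shmindel:::pack_phi(m)
      phi[idx] <- phi[idx] + h
      m2 <- shmindel:::unpack_phi(phi, 30, 30, m$prior)
      sum(vapply(seq_along(rep$reads), function(i)
        forward_sum(rep$reads[[i]], t_stars[[i]], mu[i], m2), 0.0))
    }
    cd <- (shift(eps) - shift(-eps)) / (2 * eps)
    # forward difference carries O(epsilon) truncation error
    expect_lt(abs(g[idx] - cd), 5e-2 * max(abs(cd), 1))
  }
  # a component that cannot matter has zero gradient: insertion-free data
  # under an insertion-free model leave the whole P_ins block flat
  gen0 <- indel_model(mu_prior(0, rep(1, 2000)), 0.025, 0,
                      m$len_del, m$len_ins)
  rep0 <- generate_repertoire(ts, gen0, n = 3, seed = 360, f = 0)
  g0 <- numerical_gradient(gen0, rep0$reads,
                           unname(ts$seqs[rep0$template_id]),
                           pmax(rep0$mu, 0.02), epsilon = 1e-4)
  expect_true(all(abs(g0[33:62]) < 1e-6))  # P_ins block with beta_ins = 0
})

test_that("gradient pushes beta_ins up when data carry extra insertions", {
  set.seed(37)
  ts <- synthetic_templates()
  gen <- indel_model(mu_prior(0, rep(1, 2000)), 0.02, 0.08,
                     geometric_length_distribution(15, 30),
                     geometric_length_distribution(15, 30))
  rep <- generate_repertoire(ts, gen, n = 40, seed = 38, f = 0)
  # model expects fewer insertions than the generator produced
  low <- indel_model(mu_prior(0, rep(1, 2000)), 0.02, 0.02,
                     geometric_length_distribution(15, 30),
                     geometric_length_distribution(15, 30))
  g <- numerical_gradient(low, rep$reads, unname(ts$seqs[rep$template_id]),
                          pmax(rep$mu, 0.02))
  expect_gt(g[2], 0)
})

test_that("EM with frozen phi never decreases the data log-likelihood", {
  set.seed(39)
  ts <- template_set(c(t1 = rand_seq(60), t2 = rand_seq(60)))
  gen <- indel_model(mu_prior(0.3, rep(1, 2000)), 0.025, 0.025,
                     geometric_length_distribution(5, 8),
                     geometric_length_distribution(5, 8))
  rep <- generate_repertoire(ts, gen, n = 25, seed = 40, f = 0.3)
  # coarse prior bins keep the exact-grid E step cheap
  nb <- 50
  model <- indel_model(mu_prior(0.5, rep(1, nb), bin_width = 1 / nb),
                       0.025, 0.025,
                       geometric_length_distribution(5, 8),
                       geometric_length_distribution(5, 8))
  ll <- numeric(5)
  for (it in 1:5) {
    posts <- lapply(seq_along(rep$reads), function(i)
      compute_posterior(rep$reads[[i]], ts$seqs[[rep$template_id[i]]],
                        model, method = "grid"))
    ll[it] <- sum(vapply(posts, `[[`, 0.0, "loglik"))
    model$prior <- em_update_prior(posts, prev = model$prior)
  }
  expect_true(all(diff(ll) >= -1e-9))
  expect_gt(ll[5], ll[1])
})

test_that("fit recovers a pure point-mutation model", {
  set.seed(41)
  ts <- synthetic_templates()
  gen <- indel_model(mu_prior(0.5, rep(1, 2000)), 0, 0)
  rep <- generate_repertoire(ts, gen, n = 120, seed = 42, f = 0.5)
  fit <- fit_indel_model(rep$reads, ts,
                         config = optimizer_config(T = 12, seed = 43))
  expect_lt(abs(fit$model$prior$f - 0.5), 0.08)
  expect_lt(fit$model$beta_del, 0.01)
  expect_lt(fit$model$beta_ins, 0.01)
  expect_identical(sort(unique(fit$trajectory$iter)),
                   seq_len(nrow(fit$trajectory)))
})
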