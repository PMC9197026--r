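#' Optimizer configuration for model fitting
#'
#' Constants for the EM + projected momentum gradient-ascent fit. The
#' learning-rate and inertia schedules are `alpha_t = alpha0 * exp(-2 t / T)`
#' and `omega_t = omega0 * t / (t + 3)`.
#'
#' @param T maximum number of iterations.
#' @param alpha0 base learning rate (scaled per component by parameter
#'   magnitude, see [momentum_step()]).
#' @param epsilon finite-difference step for the numerical gradient.
#' @param n_mc Monte-Carlo samples per sequence per iteration.
#' @param convergence_tol relative change of the data log-likelihood over a
#'   10-iteration window below which the fit stops early.
#' @param omega0 inertia prefactor.
#' @param scale_floor lower bound on the per-component magnitude scale.
#' @param step_clip maximum step per component, as a multiple of its scale.
#' @param pruning_threshold passage-probability threshold for the alignment
#'   mask.
#' @param mask_mu_floor smallest mutation rate used when building a read's
#'   pruning mask (keeps plausible indel cells for unmutated reads).
#' @param seed optional RNG seed for the Monte-Carlo draws.
#' @export
optimizer_config <- function(T = 150, alpha0 = 0.05, epsilon = 1e-4,
                             n_mc = 1, convergence_tol = 1e-6, omega0 = 1,
                             scale_floor = 0.005, step_clip = 0.25,
                             pruning_threshold = 1e-5, mask_mu_floor = 0.02,
                             seed = NULL) {
  stopifnot(T >= 1, epsilon > 0, n_mc >= 1)
  structure(list(T = T, alpha0 = alpha0, epsilon = epsilon, n_mc = n_mc,
                 convergence_tol = convergence_tol, omega0 = omega0,
                 scale_floor = scale_floor, step_clip = step_clip,
                 pruning_threshold = pruning_threshold,
                 mask_mu_floor = mask_mu_floor, seed = seed),
            class = "optimizer_config")
}

# node-interpolated (or exact-grid) posterior over mu for one read.
# si/ti are integer-encoded read and selected template.
posterior_core <- function(si, ti, model, mask = NULL, center = 0.05,
                           spread = 0.02, k = 15,
                           method = c("nodes", "grid")) {
  method <- match.arg(method)
  prior <- model$prior
  mids <- prior$mids
  bw <- prior$bin_width
  ll0 <- .cpp_loglik_mu(si, ti, 0, model$beta_del, model$beta_ins,
                        model$len_del$probs, model$len_ins$probs, mask)
  nodes <- NULL
  if (method == "grid") {
    llgrid <- .cpp_loglik_mu(si, ti, mids, model$beta_del, model$beta_ins,
                             model$len_del$probs, model$len_ins$probs, mask)
  } else {
    z <- seq(-4, 4, length.out = k)
    nodes <- center + spread * z
    nodes <- sort(unique(pmin(pmax(nodes, mids[1]), 1 - bw / 2)))
    nodes <- unique(c(nodes, 1))
    lln <- .cpp_loglik_mu(si, ti, nodes, model$beta_del, model$beta_ins,
                          model$len_del$probs, model$len_ins$probs, mask)
    fin <- is.finite(lln)
    if (sum(fin) < 2)
      stop("degenerate sequence: likelihood vanishes at all posterior nodes")
    sp <- splinefun(nodes[fin], lln[fin], method = "natural")
    llgrid <- pmin(sp(mids), max(lln[fin]))
  }
  w <- llgrid + log(prior$density) + log(bw)
  log_exp <- logsumexp(w[prior$density > 0])
  log_num <- log(prior$f) + ll0
  loglik <- logsumexp(c(log_num, log(1 - prior$f) + log_exp))
  f_s <- if (is.finite(loglik)) exp(log_num - loglik) else 1
  dens <- numeric(length(mids))
  post_max <- center
  sdv <- spread
  if (is.finite(log_exp)) {
    d <- exp(w - max(w[is.finite(w)]))
    d[!is.finite(d)] <- 0
    dens <- d / (sum(d) * bw)
    post_max <- mids[which.max(dens)]
    m1 <- sum(dens * mids) * bw
    m2 <- sum(dens * mids^2) * bw
    sdv <- sqrt(max(m2 - m1^2, 0))
  }
  structure(list(f_s = f_s, nodes = nodes, density = dens,
                 log_naive = ll0, loglik = loglik, post_max = post_max,
                 spread = min(max(sdv, 0.002), 0.2)),
            class = "sequence_posterior")
}

#' Posterior distribution of the mutation rate for one read
#'
#' Computes the per-sequence posterior over the maturation age mu: the
#' posterior naive weight `f_s` and the posterior density of the
#' experienced component on the prior's binning. By default the alignment
#' likelihood is evaluated at 15-25 nodes placed around `center` with
#' spacing `spread` (plus mandatory nodes at mu = 0 and 1) and interpolated
#' with a natural cubic spline; `method = "grid"` evaluates every prior bin
#' exactly instead.
#'
#' @param s read (character string).
#' @param t_star selected template (character string).
#' @param model an [indel_model()].
#' @param mask optional pruning mask.
#' @param center,spread node-placement center and scale (typically the
#'   previous posterior maximum and its inverse-curvature width; on a first
#'   pass, the deterministic SHM-rate estimate).
#' @param n_nodes number of nodes (15 for lightly mutated reads, 25 for
#'   heavily mutated ones).
#' @param method `"nodes"` (interpolated, default) or `"grid"` (exact).
#' @return object of class `sequence_posterior` with fields `f_s`,
#'   `density` (on the prior bins), `log_naive`, `loglik` (marginal),
#'   `post_max` and `spread`.
#' @export
compute_posterior <- function(s, t_star, model, mask = NULL, center = 0.05,
                              spread = 0.02, n_nodes = 15,
                              method = c("nodes", "grid")) {
  posterior_core(seq_to_int(s), seq_to_int(t_star), model, mask, center,
                 spread, n_nodes, match.arg(method))
}

#' EM update of the mutation-rate prior
#'
#' The new naive fraction is the repertoire average of the posterior naive
#' weights; the new smooth density is the weighted average of the
#' per-sequence posterior densities with weights `1 - f_s`, renormalized on
#' the prior bins.
#'
#' @param posteriors list of [compute_posterior()] results.
#' @param prev previous [mu_prior()] kept (with a warning) when every
#'   sequence is posterior-certainly naive.
#' @return a [mu_prior()].
#' @export
em_update_prior <- function(posteriors, prev = NULL) {
  stopifnot(length(posteriors) >= 1)
  f_s <- vapply(posteriors, `[[`, 0.0, "f_s")
  f_new <- mean(f_s)
  wts <- 1 - f_s
  if (sum(wts) <= 0) {
    warning("all sequences posterior-naive; keeping previous density")
    dens <- if (!is.null(prev)) prev$density else
      rep(0, length(posteriors[[1]]$density))
    return(mu_prior(f_new, dens,
                    if (!is.null(prev)) prev$bin_width else 5e-4))
  }
  dens <- Reduce(`+`, Map(function(p, w) w * p$density, posteriors, wts)) /
    sum(wts)
  bw <- 1 / length(dens)
  tot <- sum(dens) * bw
  if (tot > 0) dens <- dens / tot
  mu_prior(f_new, dens, bw)
}

#' Draw Monte-Carlo mutation-rate samples from posteriors
#'
#' Inverse-CDF sampling from each sequence's posterior mixture: with
#' probability `f_s` the sample is exactly 0, otherwise a bin is drawn from
#' the posterior density and the value jittered uniformly within the bin.
#'
#' @param posteriors list of [compute_posterior()] results.
#' @param n_mc samples per sequence.
#' @return matrix with one row per sequence and `n_mc` columns.
#' @export
draw_mu_samples <- function(posteriors, n_mc = 1) {
  bw <- 1 / length(posteriors[[1]]$density)
  mids <- (seq_along(posteriors[[1]]$density) - 0.5) * bw
  out <- matrix(0, nrow = length(posteriors), ncol = n_mc)
  for (i in seq_along(posteriors)) {
    p <- posteriors[[i]]
    for (n in seq_len(n_mc)) {
      if (runif(1) < p$f_s || sum(p$density) == 0) next
      bin <- sample.int(length(mids), 1L, prob = p$density)
      out[i, n] <- min(max(mids[bin] + (runif(1) - 0.5) * bw, 0), 1)
    }
  }
  out
}

#' Euclidean projection onto the probability simplex
#'
#' Sorting-based projection: finds the threshold tau such that
#' `pmax(x - tau, 0)` sums to one. Idempotent; a valid distribution is
#' returned unchanged.
#'
#' @param x numeric vector.
#' @export
project_simplex <- function(x) {
  u <- sort(x, decreasing = TRUE)
  css <- cumsum(u)
  j <- seq_along(u)
  rho <- max(j[u + (1 - css) / j > 0])
  tau <- (1 - css[rho]) / rho
  pmax(x + tau, 0)
}

#' Clip rescaled rates at zero
#' @param beta numeric vector of rates.
#' @export
clip_rates <- function(beta) pmax(beta, 0)

#' Numerical gradient of the data log-likelihood over phi
#'
#' Forward finite differences per component of
#' `phi = (beta_del, beta_ins, P_del(1..theta), P_ins(1..theta))`, of the
#' summed log-likelihood at fixed per-read mutation-rate samples, using the
#' pruned likelihood. Components listed as inadmissible for a read (event
#' lengths its pruning mask cannot realize) contribute an exact zero and
#' are skipped.
#'
#' @param model an [indel_model()] providing phi.
#' @param reads character vector of reads.
#' @param t_stars character vector of the selected template sequence for
#'   each read.
#' @param mu_samples per-read mutation-rate samples (vector, or matrix with
#'   one column per MC sample).
#' @param masks optional list of pruning masks (one per read).
#' @param epsilon finite-difference step.
#' @param admissible optional list per read with integer vectors `del` and
#'   `ins` of admissible event lengths; `NULL` means all components.
#' @return gradient vector over phi (summed over reads and samples), with a
#'   `components` attribute naming the entries.
#' @export
numerical_gradient <- function(model, reads, t_stars, mu_samples,
                               masks = NULL, epsilon = 1e-4,
                               admissible = NULL) {
  phi <- pack_phi(model)
  Td <- model$len_del$theta_max
  Ti <- model$len_ins$theta_max
  mu_samples <- as.matrix(mu_samples)
  grad <- numeric(length(phi))
  for (i in seq_along(reads)) {
    si <- seq_to_int(reads[[i]])
    ti <- seq_to_int(t_stars[[i]])
    comp <- if (is.null(admissible)) list(del = seq_len(Td), ins = seq_len(Ti))
      else admissible[[i]]
    idx <- c(1L, 2L, 2L + comp$del, 2L + Td + comp$ins)
    for (n in seq_len(ncol(mu_samples))) {
      mu <- mu_samples[i, n]
      if (mu == 0) next  # log-likelihood is identically 0 in phi at mu = 0
      phis <- matrix(phi, nrow = length(idx) + 1L, ncol = length(phi),
                     byrow = TRUE)
      for (r in seq_along(idx)) phis[r + 1L, idx[r]] <-
          phis[r + 1L, idx[r]] + epsilon
      ll <- .cpp_loglik_phi_batch(si, ti, mu, phis, Td,
                                  if (is.null(masks)) NULL else masks[[i]])
      if (any(!is.finite(ll)))
        stop("non-finite log-likelihood in gradient for read ", i,
             " (component ", paste(idx[!is.finite(ll[-1])], collapse = ","),
             ")")
      grad[idx] <- grad[idx] + (ll[-1] - ll[1]) / epsilon
    }
  }
  attr(grad, "components") <- c("beta_del", "beta_ins",
                                paste0("p_del_", seq_len(Td)),
                                paste0("p_ins_", seq_len(Ti)))
  grad
}

#' Projected momentum gradient-ascent step
#'
#' `phi_{t+1} = P(phi_t + alpha_t * grad + omega_t * (phi_t - phi_{t-1}))`
#' with `alpha_t = alpha0 exp(-2t/T)` and `omega_t = omega0 t/(t+3)`. The
#' learning rate for the two rescaled rates is scaled by the component's
#' magnitude (floored at `scale_floor`); each length-distribution block
#' shares a single uniform scale (one over its support size), so that the
#' projected update has the correct fixed points on the simplex. The total
#' step per component is clipped at `step_clip` times its scale. The
#' projection P clips the rescaled
#' rates at zero and projects each length distribution onto the probability
#' simplex.
#'
#' @param phi_t,phi_prev current and previous packed phi vectors.
#' @param gradient gradient over phi (per-sequence average recommended).
#' @param t iteration number (>= 1).
#' @param config an [optimizer_config()].
#' @param theta_del support size of the deletion-length block of phi.
#' @return the updated packed phi vector.
#' @export
momentum_step <- function(phi_t, phi_prev, gradient, t, config, theta_del) {
  alpha_t <- config$alpha0 * exp(-2 * t / config$T)
  omega_t <- config$omega0 * t / (t + 3)
  Td_ <- theta_del
  Ti_ <- length(phi_t) - 2L - Td_
  # rates get a magnitude-proportional rate; each simplex block shares one
  # uniform scale so that a constant gradient (the fixed point of the
  # projected update) maps to the identity after projection
  scale <- c(pmax(abs(phi_t[1:2]), config$scale_floor),
             rep(1 / Td_, Td_), rep(1 / Ti_, Ti_))
  step <- alpha_t * scale * gradient + omega_t * (phi_t - phi_prev)
  lim <- config$step_clip * scale
  step <- sign(step) * pmin(abs(step), lim)
  raw <- phi_t + step
  Td <- theta_del
  Ti <- length(phi_t) - 2L - Td
  out <- raw
  out[1:2] <- clip_rates(raw[1:2])
  if (sum(out[1:2]) > 1) out[1:2] <- out[1:2] / sum(out[1:2])
  out[3:(2 + Td)] <- project_simplex(raw[3:(2 + Td)])
  out[(3 + Td):(2 + Td + Ti)] <- project_simplex(raw[(3 + Td):(2 + Td + Ti)])
  out
}

#' Fit the SHM-indel model by maximum likelihood
#'
#' Full inference loop: deterministic annotation selects one template per
#' read and provides the initial parameter guess; a single unpruned
#' forward/backward pass per read builds its pruning mask; then each
#' iteration recomputes the per-read mutation-rate posteriors
#' (node-interpolated), applies the closed-form EM update to the prior,
#' draws one Monte-Carlo rate per read, estimates the phi gradient by
#' finite differences on the pruned likelihood, and takes a projected
#' momentum step.
#'
#' @param reads named character vector of reads.
#' @param templates a [template_set()].
#' @param init optional initial [indel_model()]; by default built from the
#'   deterministic annotation statistics.
#' @param config an [optimizer_config()].
#' @param penalties aligner penalties for template selection and
#'   initialization.
#' @param theta_max support of the fitted length distributions (ignored
#'   when `init` is given).
#' @param verbose print per-iteration progress.
#' @return object of class `shmindel_fit`: `model` (fitted [indel_model()]),
#'   `trajectory` (data.frame of iteration, log-likelihood, f, betas),
#'   `per_read` (read id, template, posterior naive weight, posterior mode),
#'   `converged`, `annotation` (the deterministic [annotate()] result) and
#'   `init` (the initial model).
#' @export
fit_indel_model <- function(reads, templates, init = NULL,
                            config = optimizer_config(),
                            penalties = derive_penalties(),
                            theta_max = 30, verbose = FALSE) {
  if (length(reads) == 0L) stop("reads must be nonempty")
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(names(reads))) names(reads) <- sprintf("read_%05d",
                                                     seq_along(reads))
  ann <- annotate(reads, templates, penalties)
  det <- deterministic_estimates(ann, theta_max = theta_max)
  model <- if (is.null(init)) det$model else validate_indel_model(init)
  init_model <- model
  Td <- model$len_del$theta_max
  Ti <- model$len_ins$theta_max
  N <- length(reads)
  pr <- ann$per_read

  si <- lapply(reads, seq_to_int)
  ti <- lapply(pr$template_id, function(id) seq_to_int(templates$seqs[[id]]))
  mu_hat <- pmin(pmax(pr$shm_rate, 0), 0.9)

  masks <- vector("list", N)
  adm <- vector("list", N)
  for (i in seq_len(N)) {
    mu0 <- max(mu_hat[i], config$mask_mu_floor)
    post <- passage_posterior(reads[[i]],
                              templates$seqs[[pr$template_id[i]]], mu0, model)
    masks[[i]] <- build_pruning_mask(post, config$pruning_threshold)
    a <- .cpp_admissible_lengths(masks[[i]], Td, Ti)
    adm[[i]] <- list(del = which(a$del), ins = which(a$ins))
  }

  center <- pmax(mu_hat, 0.002)
  spread <- pmax(sqrt(center * (1 - center) / nchar(reads)), 0.004)
  k_nodes <- ifelse(pr$n_point < 5, 15L, 25L)

  phi <- pack_phi(model)
  phi_prev <- phi
  traj <- vector("list", config$T)
  ll_hist <- rep(NA_real_, config$T)
  converged <- FALSE
  f_s <- numeric(N)

  for (t in seq_len(config$T)) {
    dens_acc <- numeric(length(model$prior$density))
    wt_acc <- 0
    ll_tot <- 0
    mu_samp <- matrix(0, N, config$n_mc)
    bw <- model$prior$bin_width
    mids <- model$prior$mids
    for (i in seq_len(N)) {
      p <- posterior_core(si[[i]], ti[[i]], model, masks[[i]], center[i],
                          spread[i], k_nodes[i], "nodes")
      f_s[i] <- p$f_s
      ll_tot <- ll_tot + p$loglik
      dens_acc <- dens_acc + (1 - p$f_s) * p$density
      wt_acc <- wt_acc + (1 - p$f_s)
      center[i] <- p$post_max
      spread[i] <- p$spread
      for (n in seq_len(config$n_mc)) {
        if (runif(1) < p$f_s || sum(p$density) == 0) next
        bin <- sample.int(length(mids), 1L, prob = p$density)
        mu_samp[i, n] <- min(max(mids[bin] + (runif(1) - 0.5) * bw, 0), 1)
      }
    }
    f_new <- mean(f_s)
    if (wt_acc > 0) {
      dens_new <- dens_acc / wt_acc
      dens_new <- dens_new / (sum(dens_new) * bw)
    } else {
      dens_new <- model$prior$density
    }
    prior_new <- mu_prior(f_new, dens_new, bw)

    grad <- numeric(length(phi))
    for (i in seq_len(N)) {
      idx <- c(1L, 2L, 2L + adm[[i]]$del, 2L + Td + adm[[i]]$ins)
      for (n in seq_len(config$n_mc)) {
        mu <- mu_samp[i, n]
        if (mu == 0) next
        phis <- matrix(phi, nrow = length(idx) + 1L, ncol = length(phi),
                       byrow = TRUE)
        for (r in seq_along(idx)) phis[r + 1L, idx[r]] <-
            phis[r + 1L, idx[r]] + config$epsilon
        ll <- .cpp_loglik_phi_batch(si[[i]], ti[[i]], mu, phis, Td,
                                    masks[[i]])
        grad[idx] <- grad[idx] + (ll[-1] - ll[1]) / config$epsilon
      }
    }
    grad <- grad / (N * config$n_mc)

    phi_new <- momentum_step(phi, phi_prev, grad, t, config, Td)
    phi_new[1:2] <- pmax(phi_new[1:2], 1e-8)
    phi_prev <- phi
    phi <- phi_new
    model <- unpack_phi(phi, Td, Ti, prior_new)

    traj[[t]] <- data.frame(iter = t, loglik = ll_tot, f = f_new,
                            beta_del = phi[1], beta_ins = phi[2])
    ll_hist[t] <- ll_tot
    if (verbose)
      message(sprintf("iter %3d  loglik %.2f  f %.4f  bdel %.4f  bins %.4f",
                      t, ll_tot, f_new, phi[1], phi[2]))
    if (t > 15 &&
        abs(ll_hist[t] - ll_hist[t - 10]) <
        config$convergence_tol * abs(ll_hist[t])) {
      converged <- TRUE
      break
    }
  }

  structure(list(model = model,
                 trajectory = do.call(rbind, traj[!vapply(traj, is.null,
                                                          TRUE)]),
                 per_read = data.frame(read_id = names(reads),
                                       template_id = pr$template_id,
                                       f_s = f_s, mu_map = center,
                                       stringsAsFactors = FALSE),
                 converged = converged, annotation = ann,
                 init = init_model),
            class = "shmindel_fit")
}

#' Evaluate reads under a fixed model
#'
#' Evaluation mode: selects a template per read, builds a pruning mask, and
#' returns the marginal log-likelihood and posterior naive weight of every
#' read under the given model (no parameter updates).
#'
#' @param reads named character vector of reads.
#' @param templates a [template_set()].
#' @param model an [indel_model()].
#' @param penalties aligner penalties for template selection.
#' @param pruning_threshold passage-probability threshold.
#' @param mask_mu_floor smallest rate used for mask construction.
#' @return data.frame with `read_id`, `template_id`, `loglik`, `f_s`,
#'   `mu_map`.
#' @export
evaluate_repertoire <- function(reads, templates, model,
                                penalties = derive_penalties(),
                                pruning_threshold = 1e-5,
                                mask_mu_floor = 0.02) {
  if (is.null(names(reads))) names(reads) <- sprintf("read_%05d",
                                                     seq_along(reads))
  ann <- annotate(reads, templates, penalties)
  pr <- ann$per_read
  out <- vector("list", length(reads))
  for (i in seq_along(reads)) {
    tseq <- templates$seqs[[pr$template_id[i]]]
    mu0 <- max(min(pr$shm_rate[i], 0.9), mask_mu_floor)
    mask <- build_pruning_mask(passage_posterior(reads[[i]], tseq, mu0,
                                                 model),
                               pruning_threshold)
    p <- compute_posterior(reads[[i]], tseq, model, mask,
                           center = max(pr$shm_rate[i], 0.002),
                           spread = max(sqrt(mu0 * (1 - mu0) /
                                               nchar(reads[[i]])), 0.004),
                           n_nodes = if (pr$n_point[i] < 5) 15 else 25)
    out[[i]] <- data.frame(read_id = names(reads)[i],
                           template_id = pr$template_id[i],
                           loglik = p$loglik, f_s = p$f_s,
                           mu_map = p$post_max, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
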