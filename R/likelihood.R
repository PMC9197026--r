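# emission tables for a given mu under a model (linear space)
emission_tables <- function(mu, model) {
  stay <- 1 - mu * model$beta_del - mu * model$beta_ins
  list(gdel = mu * model$beta_del * model$len_del$probs,
       gins = mu * model$beta_ins * model$len_ins$probs *
         0.25^seq_along(model$len_ins$probs),
       pm = stay * (1 - mu), pmm = stay * mu)
}

#' Sum-over-scenarios alignment likelihood
#'
#' Computes `S(s, t | mu; phi)`: the sum over all global alignment scenarios
#' between read `s` and template `t` of their probabilities under the
#' generative model, by the forward recursion. A diagonal step contributes
#' the match/mismatch probability, a gap of `l` template bases contributes
#' `gamma_del(l)`, a gap of `l` read bases contributes `gamma_ins(l)`;
#' single events are limited to the model's maximum lengths, but abutting
#' events are distinct scenarios and are included in the sum. With a pruning
#' `mask`, disallowed cells contribute exactly zero.
#'
#' @param s,t read and template (character strings).
#' @param mu per-base-pair point-mutation rate.
#' @param model an [indel_model()].
#' @param mask optional logical matrix of admissible cells, dimensions
#'   `(nchar(s)+1) x (nchar(t)+1)`.
#' @param log if `TRUE` (default) return the log-likelihood.
#' @return the (log-)likelihood; `-Inf` (or 0) when no admissible scenario
#'   has positive probability.
#' @export
forward_sum <- function(s, t, mu, model, mask = NULL, log = TRUE) {
  if (mu < 0 || mu > 1) stop("mu must lie in [0, 1]")
  ll <- .cpp_loglik_mu(seq_to_int(s), seq_to_int(t), mu, model$beta_del,
                       model$beta_ins, model$len_del$probs,
                       model$len_ins$probs, mask)
  if (log) ll else exp(ll)
}

#' Full forward matrix in log space
#'
#' Matrix of prefix likelihoods `S(s_0:i, t_0:j)`; entry `[1, 1]` is the
#' empty-prefix boundary (log 0.0 = 1) and the bottom-right entry is the
#' total `log S(s, t | mu)`.
#'
#' @inheritParams forward_sum
#' @export
forward_matrix <- function(s, t, mu, model, mask = NULL) {
  em <- emission_tables(mu, model)
  .cpp_forward_logmat(seq_to_int(s), seq_to_int(t), em$gdel, em$gins,
                      em$pm, em$pmm, mask)
}

#' Suffix (backward) likelihood matrix
#'
#' Entry `[i+1, j+1]` holds `log S(s_{i+1:Ls}, t_{j+1:Lt})`, computed by the
#' forward recursion on the reversed sequences. The entry at `[1, 1]` equals
#' the total likelihood, and the bottom-right boundary (empty suffix) is 0.
#'
#' @inheritParams forward_sum
#' @export
backward_matrix <- function(s, t, mu, model, mask = NULL) {
  rev_chars <- function(x) paste(rev(strsplit(x, "", fixed = TRUE)[[1]]),
                                 collapse = "")
  rmask <- if (!is.null(mask))
    mask[rev(seq_len(nrow(mask))), rev(seq_len(ncol(mask))), drop = FALSE]
  m <- forward_matrix(rev_chars(s), rev_chars(t), mu, model, rmask)
  m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m))), drop = FALSE]
}

#' Posterior probability that the alignment passes through each cell
#'
#' For every pair of positions (i, j), the relative likelihood that the true
#' alignment scenario passes through read position i and template position
#' j: `Shat_ij = S(s_1:i, t_1:j) * S(s_i+1:Ls, t_j+1:Lt) / S(s, t)`.
#'
#' @inheritParams forward_sum
#' @return list with `shat` (matrix of passage probabilities in \[0, 1\])
#'   and `loglik` (total log-likelihood).
#' @export
passage_posterior <- function(s, t, mu, model) {
  fwd <- forward_matrix(s, t, mu, model)
  bwd <- backward_matrix(s, t, mu, model)
  total <- fwd[nrow(fwd), ncol(fwd)]
  if (!is.finite(total))
    stop("degenerate alignment: S(s, t) = 0 for this mu and model")
  shat <- exp(fwd + bwd - total)
  list(shat = shat, loglik = total)
}

#' Build a pruning mask from a passage posterior
#'
#' Admits cell (i, j) iff its passage probability is at least `threshold`.
#' The mask, computed once at an initial parameter guess, is reused for all
#' subsequent likelihood evaluations of the sequence.
#'
#' @param posterior a [passage_posterior()] result.
#' @param threshold pruning threshold (default 1e-5); must lie in (0, 1\].
#' @return logical matrix; errors if the final cell would be pruned away.
#' @export
build_pruning_mask <- function(posterior, threshold = 1e-5) {
  if (threshold <= 0 || threshold > 1)
    stop("pruning threshold must lie in (0, 1]")
  mask <- posterior$shat >= threshold
  mask[1, 1] <- TRUE
  if (!mask[nrow(mask), ncol(mask)])
    stop("pruning too aggressive: final cell excluded")
  mask
}

#' Select the closest template by deterministic alignment score
#'
#' The probabilistic likelihood keeps only the single best template per
#' read, chosen by the best-scoring affine-gap alignment (ties broken by
#' template order).
#'
#' @param s read (character string).
#' @param templates a [template_set()].
#' @param penalties a [derive_penalties()] object.
#' @return the selected template id.
#' @export
select_template <- function(s, templates, penalties = derive_penalties()) {
  scores <- vapply(templates$seqs, function(t) nw_align(s, t, penalties)$score,
                   0.0)
  names(templates$seqs)[which.max(scores)]
}

#' Marginal sequence likelihood under the full model
#'
#' Integrates the alignment likelihood over the mutation-rate prior:
#' `L(s) = f * S(s, t* | 0) + (1 - f) * sum_bins Ptilde(mu) S(s, t* | mu) *
#' dmu`, a midpoint-rule quadrature over the binned prior. Exact per-bin
#' evaluation; used directly in tests and small problems, while the fitter
#' uses the node-interpolated approximation of the same quantity.
#'
#' @param s read (character string).
#' @param t_star selected template (character string).
#' @param model an [indel_model()].
#' @param mask optional pruning mask.
#' @return list with `loglik` (log marginal likelihood), `log_naive`
#'   (log S at mu = 0) and `log_exp` (log of the experienced-part integral).
#' @export
sequence_likelihood <- function(s, t_star, model, mask = NULL) {
  prior <- model$prior
  si <- seq_to_int(s); ti <- seq_to_int(t_star)
  ll0 <- .cpp_loglik_mu(si, ti, 0, model$beta_del, model$beta_ins,
                        model$len_del$probs, model$len_ins$probs, mask)
  supp <- prior$density > 0
  log_exp <- -Inf
  if (any(supp)) {
    llmu <- .cpp_loglik_mu(si, ti, prior$mids[supp], model$beta_del,
                           model$beta_ins, model$len_del$probs,
                           model$len_ins$probs, mask)
    log_exp <- logsumexp(llmu + log(prior$density[supp]) +
                           log(prior$bin_width))
  }
  loglik <- logsumexp(c(log(prior$f) + ll0, log(1 - prior$f) + log_exp))
  list(loglik = loglik, log_naive = ll0, log_exp = log_exp)
}

logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
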