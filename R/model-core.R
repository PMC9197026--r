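#' @useDynLib shmindel, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats approx dgamma pgamma optimize qgamma rbinom rgamma runif
#'   setNames splinefun coef lm cor.test chisq.test density
#' @importFrom utils head tail write.table read.delim
"_PACKAGE"

NUCLEOTIDES <- c("A", "C", "G", "T")

# integer encoding used by the C++ dynamic programming (0..3)
seq_to_int <- function(x) {
  codes <- match(strsplit(toupper(x), "", fixed = TRUE)[[1]], NUCLEOTIDES) - 1L
  if (anyNA(codes)) stop("sequence contains characters outside {A,C,G,T}")
  codes
}

int_to_seq <- function(codes) paste(NUCLEOTIDES[codes + 1L], collapse = "")

#' Nucleotide sequence with identifier
#'
#' Light container for a single read or germline template: an identifier and
#' an A/C/G/T string. Most package functions accept plain named character
#' vectors; this constructor mainly validates the alphabet.
#'
#' @param id sequence identifier.
#' @param seq character string over the alphabet A, C, G, T.
#' @return an object of class `nucleotide_sequence` with fields `id`, `seq`
#'   and `L` (length in base pairs).
#' @export
nucleotide_sequence <- function(id, seq) {
  seq <- toupper(seq)
  if (nchar(seq) < 1L) stop("sequence must contain at least one base")
  seq_to_int(seq)  # alphabet check
  structure(list(id = as.character(id), seq = seq, L = nchar(seq)),
            class = "nucleotide_sequence")
}

#' Set of germline V templates with a prior
#'
#' @param templates named character vector of template sequences (names are
#'   template ids), or a list of [nucleotide_sequence()] objects.
#' @param prior per-template probabilities; default uniform.
#' @return an object of class `template_set` with fields `seqs` (named
#'   character vector), `prior` and `n`.
#' @export
template_set <- function(templates, prior = NULL) {
  if (is.list(templates))
    templates <- setNames(vapply(templates, `[[`, "", "seq"),
                          vapply(templates, `[[`, "", "id"))
  if (length(templates) == 0L) stop("template set must not be empty")
  if (is.null(names(templates)) || anyDuplicated(names(templates)))
    stop("templates must have unique names")
  lapply(templates, seq_to_int)  # alphabet check
  if (is.null(prior)) prior <- rep(1 / length(templates), length(templates))
  if (length(prior) != length(templates) || any(prior < 0) ||
      abs(sum(prior) - 1) > 1e-9)
    stop("template prior must be a probability vector over the templates")
  structure(list(seqs = templates, prior = prior, n = length(templates)),
            class = "template_set")
}

#' Indel event-length distribution
#'
#' Probabilities of single-event lengths 1..theta_max base pairs. Events
#' longer than `theta_max` have probability zero by construction.
#'
#' @param probs non-negative vector indexed by length 1..theta_max; must sum
#'   to 1 (within 1e-9).
#' @return object of class `length_distribution`.
#' @export
length_distribution <- function(probs) {
  if (any(probs < 0)) stop("length probabilities must be non-negative")
  if (abs(sum(probs) - 1) > 1e-9) stop("length probabilities must sum to 1")
  structure(list(probs = as.numeric(probs), theta_max = length(probs)),
            class = "length_distribution")
}

#' Truncated geometric event-length distribution
#'
#' Exponentially decaying length law `P(l) proportional to exp(-l / scale)`
#' for `l = 1..theta_max`, renormalized. This is the law used throughout for
#' indel event lengths.
#'
#' @param scale characteristic length in base pairs.
#' @param theta_max maximum single-event length in base pairs.
#' @export
geometric_length_distribution <- function(scale = 15, theta_max = 30) {
  if (scale <= 0) stop("scale must be positive")
  p <- exp(-(1:theta_max) / scale)
  length_distribution(p / sum(p))
}

#' Prior over per-sequence mutation rates
#'
#' Mixture of a point mass at mu = 0 (naive sequences, weight `f`) and a
#' smooth density over (0, 1] stored on a uniform binning of the unit
#' interval.
#'
#' @param f naive fraction in \[0, 1\].
#' @param density density values at the bin midpoints; must integrate to 1
#'   (within 1e-6). A scalar 0 with `f = 1` is allowed.
#' @param bin_width width of the uniform bins (default 0.0005).
#' @return object of class `mu_prior` with fields `f`, `density`,
#'   `bin_width` and `mids` (bin midpoints).
#' @export
mu_prior <- function(f, density, bin_width = 5e-4) {
  if (f < 0 || f > 1) stop("naive fraction f must lie in [0, 1]")
  nbin <- round(1 / bin_width)
  if (length(density) == 1L && f == 1) density <- rep(0, nbin)
  if (length(density) != nbin)
    stop("density must have one value per bin of [0, 1]")
  if (any(density < 0)) stop("density must be non-negative")
  tot <- sum(density) * bin_width
  if (f < 1 && abs(tot - 1) > 1e-6) stop("density must integrate to 1")
  structure(list(f = f, density = as.numeric(density), bin_width = bin_width,
                 mids = (seq_len(nbin) - 0.5) * bin_width),
            class = "mu_prior")
}

#' Full SHM-indel model
#'
#' The parameter set theta = (P(mu), beta_del, beta_ins, P_del, P_ins): a
#' prior over per-sequence point-mutation rates, the rescaled deletion and
#' insertion rates (ratios of indel-event rate to point-mutation rate per
#' base pair), and the two event-length distributions.
#'
#' @param prior a [mu_prior()].
#' @param beta_del,beta_ins non-negative rescaled indel rates.
#' @param len_del,len_ins [length_distribution()] objects for deletion and
#'   insertion event lengths.
#' @return object of class `indel_model`.
#' @export
indel_model <- function(prior, beta_del, beta_ins,
                        len_del = geometric_length_distribution(),
                        len_ins = geometric_length_distribution()) {
  model <- structure(list(prior = prior, beta_del = beta_del,
                          beta_ins = beta_ins, len_del = len_del,
                          len_ins = len_ins),
                     class = "indel_model")
  validate_indel_model(model)
  model
}

#' Validate an SHM-indel model
#'
#' Checks all component invariants, and that for every mu in \[0, 1\] the
#' per-position probabilities stay in \[0, 1\]: this requires
#' `beta_del + beta_ins <= 1` so that `1 - mu*(beta_del + beta_ins)` cannot
#' go negative.
#'
#' @param model an [indel_model()].
#' @return the model, invisibly; errors on violation.
#' @export
validate_indel_model <- function(model) {
  stopifnot(inherits(model, "indel_model"))
  if (model$beta_del < 0 || model$beta_ins < 0)
    stop("rescaled indel rates must be non-negative")
  if (model$beta_del + model$beta_ins > 1)
    stop("beta_del + beta_ins must not exceed 1 (per-position probabilities ",
         "would leave [0, 1] at large mu)")
  if (!inherits(model$prior, "mu_prior")) stop("prior must be a mu_prior")
  if (!inherits(model$len_del, "length_distribution") ||
      !inherits(model$len_ins, "length_distribution"))
    stop("len_del and len_ins must be length_distribution objects")
  invisible(model)
}

#' Elementary deletion-event probability
#'
#' Probability that a deletion event of exactly `ell` template base pairs
#' starts at a given position: `mu * beta_del * P_del(ell)`, zero beyond the
#' maximum event length.
#'
#' @param ell event length in base pairs (vectorized).
#' @param mu per-base-pair point-mutation rate in \[0, 1\].
#' @param model an [indel_model()].
#' @export
gamma_del <- function(ell, mu, model) {
  check_rate_args(ell, mu)
  p <- ifelse(ell <= model$len_del$theta_max, model$len_del$probs[ell], 0)
  unname(mu * model$beta_del * ifelse(is.na(p), 0, p))
}

#' Elementary insertion-event probability
#'
#' Probability that an insertion of exactly `ell` specific base pairs occurs
#' at a given position: `mu * beta_ins * P_ins(ell) * (1/4)^ell`, the last
#' factor being the probability of the particular inserted bases under the
#' uniform-insertion assumption.
#'
#' @inheritParams gamma_del
#' @export
gamma_ins <- function(ell, mu, model) {
  check_rate_args(ell, mu)
  p <- ifelse(ell <= model$len_ins$theta_max, model$len_ins$probs[ell], 0)
  unname(mu * model$beta_ins * ifelse(is.na(p), 0, p) * 0.25^ell)
}

#' Match/mismatch emission probability
#'
#' Probability of observing read base `a` aligned to template base `b`:
#' `(1 - mu*beta_del - mu*beta_ins) * ((1 - mu)` if `a == b`, else `mu)`.
#' The mismatch term carries weight `mu` for any of the three alternative
#' bases (no mu/3 split), matching the log-odds penalty `ln(mu)` of the
#' deterministic aligner.
#'
#' @param a,b nucleotides in A, C, G, T.
#' @inheritParams gamma_del
#' @export
match_prob <- function(a, b, mu, model) {
  if (any(mu < 0 | mu > 1)) stop("mu must lie in [0, 1]")
  if (!all(c(a, b) %in% NUCLEOTIDES)) stop("bases must be one of A, C, G, T")
  stay <- 1 - mu * model$beta_del - mu * model$beta_ins
  out <- stay * ifelse(a == b, 1 - mu, mu)
  if (any(out < 0 | out > 1))
    stop("match probability left [0, 1]; invalid model for this mu")
  out
}

check_rate_args <- function(ell, mu) {
  if (any(ell < 1)) stop("event length must be at least 1")
  if (any(mu < 0 | mu > 1)) stop("mu must lie in [0, 1]")
  invisible(NULL)
}

# packed phi vector used by the optimizer: (beta_del, beta_ins, P_del, P_ins)
pack_phi <- function(model) {
  c(model$beta_del, model$beta_ins, model$len_del$probs, model$len_ins$probs)
}

unpack_phi <- function(phi, theta_del, theta_ins, prior) {
  indel_model(prior = prior, beta_del = phi[1], beta_ins = phi[2],
              len_del = length_distribution(phi[3:(2 + theta_del)]),
              len_ins = length_distribution(phi[(3 + theta_del):
                                                  (2 + theta_del + theta_ins)]))
}
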