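#' Shifted-Gamma specification for experienced-cell mutation rates
#'
#' Experienced (non-naive) sequences carry a per-base-pair point-mutation
#' rate mu drawn from a Gamma distribution parameterized by the mode and
#' standard deviation of its unshifted form, then shifted left by `shift`
#' with negative draws discarded. With the defaults (mode 0.07, sd 0.04,
#' shift 0.02) the resulting density has nonzero weight at infinitesimally
#' small rates and a mode of 0.05.
#'
#' @param mode mode of the unshifted Gamma, (alpha - 1) / beta.
#' @param sd standard deviation of the unshifted Gamma, sqrt(alpha) / beta.
#' @param shift amount subtracted after sampling (mu0).
#' @return object of class `shifted_gamma_spec` with derived `alpha`, `beta`.
#' @export
shifted_gamma_spec <- function(mode = 0.07, sd = 0.04, shift = 0.02) {
  if (sd <= 0) stop("sd must be positive")
  if (mode <= 0) stop("mode must be positive")
  # (alpha-1)/beta = mode, sqrt(alpha)/beta = sd  =>  with x = sqrt(alpha):
  # (x^2 - 1)/x = mode/sd  =>  x^2 - (mode/sd) x - 1 = 0
  r <- mode / sd
  x <- (r + sqrt(r^2 + 4)) / 2
  alpha <- x^2
  beta <- x / sd
  structure(list(mode = mode, sd = sd, shift = shift,
                 alpha = alpha, beta = beta),
            class = "shifted_gamma_spec")
}

#' Mode of the shifted-Gamma mutation-rate density
#'
#' Analytic mode of the experienced-cell rate distribution: the unshifted
#' Gamma mode minus the shift (the truncation at zero does not move the
#' mode as long as it is positive).
#'
#' @param spec a [shifted_gamma_spec()].
#' @export
shifted_gamma_mode <- function(spec) {
  (spec$alpha - 1) / spec$beta - spec$shift
}

# density of the shifted, negative-rejected Gamma on a grid (for priors)
shifted_gamma_density <- function(spec, mu) {
  d <- dgamma(mu + spec$shift, shape = spec$alpha, rate = spec$beta)
  z <- 1 - pgamma(spec$shift, shape = spec$alpha, rate = spec$beta)
  d / z
}

#' Sample per-sequence mutation rates
#'
#' Draws maturation ages from the naive/experienced mixture: with
#' probability `f` a sequence is naive (mu exactly 0); otherwise mu is drawn
#' from the shifted Gamma of `spec`, redrawing negative values.
#'
#' @param n number of rates to draw.
#' @param f naive fraction.
#' @param spec a [shifted_gamma_spec()].
#' @return numeric vector of length `n`.
#' @export
sample_mu <- function(n, f = 0.1, spec = shifted_gamma_spec()) {
  if (n < 1) stop("n must be at least 1")
  naive <- runif(n) < f
  mu <- numeric(n)
  todo <- which(!naive)
  while (length(todo)) {
    draw <- rgamma(length(todo), shape = spec$alpha, rate = spec$beta) -
      spec$shift
    ok <- draw >= 0
    mu[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  pmin(mu, 1)
}

#' Apply a mutation scenario to its template
#'
#' Reconstructs the read implied by a scenario: deletions remove template
#' spans, insertions add bases immediately before their template position,
#' point mutations substitute single template bases. Overlapping deletions
#' delete the union of their spans.
#'
#' @param template template sequence (character string).
#' @param events data.frame with columns `kind` ("point"/"del"/"ins"),
#'   `position` (0-based template position), `length`, `inserted_seq`.
#' @return the reconstructed read (character string).
#' @export
apply_scenario <- function(template, events) {
  L <- nchar(template)
  bases <- strsplit(template, "", fixed = TRUE)[[1]]
  deleted <- rep(FALSE, L)
  inserts <- vector("list", L + 1L)
  if (nrow(events)) {
    for (k in seq_len(nrow(events))) {
      ev <- events[k, ]
      p <- ev$position
      if (ev$kind == "del") {
        span <- seq.int(p + 1L, min(p + ev$length, L))
        deleted[span] <- TRUE
      } else if (ev$kind == "ins") {
        inserts[[p + 1L]] <- paste0(ev$inserted_seq, inserts[[p + 1L]] %||% "")
      } else {
        bases[p + 1L] <- ev$inserted_seq
      }
    }
  }
  out <- character(0)
  for (j in seq_len(L)) {
    if (!is.null(inserts[[j]])) out <- c(out, inserts[[j]])
    if (!deleted[j]) out <- c(out, bases[j])
  }
  if (!is.null(inserts[[L + 1L]])) out <- c(out, inserts[[L + 1L]])
  paste(out, collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_events <- function() {
  data.frame(kind = character(0), position = integer(0), length = integer(0),
             inserted_seq = character(0), stringsAsFactors = FALSE)
}

#' Mutate a template according to the generative SHM-indel model
#'
#' At every template position an independent draw decides between starting a
#' deletion event (probability `mu * beta_del`), starting an insertion event
#' (`mu * beta_ins`), a point mutation (`(1 - mu*beta_del - mu*beta_ins) *
#' mu`, substituting one of the three alternative bases uniformly), or no
#' event. Event lengths follow the model's length distributions; inserted
#' bases are uniform over A/C/G/T; a deletion overrunning the template end
#' is truncated there. Events are resolved right-to-left: an event whose
#' start lies inside an already-deleted stretch is discarded.
#'
#' @param template template sequence (character string).
#' @param mu per-base-pair point-mutation rate.
#' @param model an [indel_model()] (only `beta_del`, `beta_ins`, `len_del`,
#'   `len_ins` are used).
#' @return list with `read` (character string) and `events` (data.frame as
#'   in [apply_scenario()]); applying the events to the template reproduces
#'   the read exactly.
#' @export
mutate_sequence <- function(template, mu, model) {
  if (mu < 0 || mu > 1) stop("mu must lie in [0, 1]")
  L <- nchar(template)
  if (L < 1) stop("template must be nonempty")
  if (mu == 0)
    return(list(read = template, events = empty_events()))
  p_del <- mu * model$beta_del
  p_ins <- mu * model$beta_ins
  p_pt <- (1 - p_del - p_ins) * mu
  u <- runif(L)
  kind <- rep(NA_character_, L)
  kind[u < p_del] <- "del"
  kind[u >= p_del & u < p_del + p_ins] <- "ins"
  kind[u >= p_del + p_ins & u < p_del + p_ins + p_pt] <- "point"
  idx <- which(!is.na(kind))
  if (!length(idx))
    return(list(read = template, events = empty_events()))
  tpl <- strsplit(template, "", fixed = TRUE)[[1]]
  events <- list()
  del_spans <- matrix(numeric(0), ncol = 2)
  inside_deleted <- function(p) {
    nrow(del_spans) > 0 && any(p >= del_spans[, 1] & p < del_spans[, 2])
  }
  for (p in rev(idx) - 1L) {  # 0-based positions, right to left
    k <- kind[p + 1L]
    if (inside_deleted(p)) next
    if (k == "del") {
      len <- sample.int(model$len_del$theta_max, 1L,
                        prob = model$len_del$probs)
      len <- min(len, L - p)
      del_spans <- rbind(del_spans, c(p, p + len))
      events[[length(events) + 1L]] <-
        data.frame(kind = "del", position = p, length = len,
                   inserted_seq = "", stringsAsFactors = FALSE)
    } else if (k == "ins") {
      len <- sample.int(model$len_ins$theta_max, 1L,
                        prob = model$len_ins$probs)
      ins <- paste(sample(NUCLEOTIDES, len, replace = TRUE), collapse = "")
      events[[length(events) + 1L]] <-
        data.frame(kind = "ins", position = p, length = len,
                   inserted_seq = ins, stringsAsFactors = FALSE)
    } else {
      alt <- sample(setdiff(NUCLEOTIDES, tpl[p + 1L]), 1L)
      events[[length(events) + 1L]] <-
        data.frame(kind = "point", position = p, length = 1L,
                   inserted_seq = alt, stringsAsFactors = FALSE)
    }
  }
  events <- do.call(rbind, events)
  events <- events[order(events$position), , drop = FALSE]
  rownames(events) <- NULL
  list(read = apply_scenario(template, events), events = events)
}

#' Generate a synthetic repertoire with ground truth
#'
#' Draws a template for each read from the template prior, a maturation age
#' from the naive/experienced mixture, and mutates the template under the
#' generative model. Deterministic under `seed`.
#'
#' @param templates a [template_set()].
#' @param model an [indel_model()]; its prior supplies the naive fraction
#'   `f` when `spec` sampling is used.
#' @param n number of reads (>= 1).
#' @param seed RNG seed for the repertoire.
#' @param f naive fraction (defaults to the model prior's `f`).
#' @param spec [shifted_gamma_spec()] for experienced-cell rates.
#' @return list of class `synthetic_repertoire`: `reads` (named character
#'   vector), `truth` (data.frame of events with a `read_id` column), `mu`
#'   (true per-read rates), `template_id` (per-read template), `seed`.
#' @export
generate_repertoire <- function(templates, model, n, seed = 1L,
                                f = model$prior$f,
                                spec = shifted_gamma_spec()) {
  if (n < 1) stop("n must be at least 1")
  stopifnot(inherits(templates, "template_set"))
  set.seed(seed)
  tid <- sample(names(templates$seqs), n, replace = TRUE,
                prob = templates$prior)
  mu <- sample_mu(n, f = f, spec = spec)
  reads <- character(n)
  truth <- vector("list", n)
  ids <- sprintf("read_%05d", seq_len(n))
  for (i in seq_len(n)) {
    sim <- mutate_sequence(templates$seqs[[tid[i]]], mu[i], model)
    reads[i] <- sim$read
    if (nrow(sim$events)) {
      sim$events$read_id <- ids[i]
      truth[[i]] <- sim$events
    }
  }
  truth <- if (any(!vapply(truth, is.null, TRUE)))
    do.call(rbind, truth[!vapply(truth, is.null, TRUE)]) else {
      ev <- empty_events(); ev$read_id <- character(0); ev
    }
  rownames(truth) <- NULL
  structure(list(reads = setNames(reads, ids), truth = truth, mu = mu,
                 template_id = setNames(tid, ids), seed = seed),
            class = "synthetic_repertoire")
}

#' Write a synthetic repertoire to disk
#'
#' Reads as FASTA, ground-truth events as TSV (one row per event), and the
#' generating seed in a header comment of the TSV.
#'
#' @param rep a repertoire from [generate_repertoire()].
#' @param prefix output path prefix; writes `<prefix>.fasta` and
#'   `<prefix>_truth.tsv`.
#' @export
write_repertoire <- function(rep, prefix) {
  write_fasta(rep$reads, paste0(prefix, ".fasta"))
  tsv <- paste0(prefix, "_truth.tsv")
  con <- file(tsv, "w")
  writeLines(sprintf("# seed=%d", rep$seed), con)
  write.table(rep$truth[, c("read_id", "kind", "position", "length",
                            "inserted_seq")],
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(prefix)
}
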