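#' Derive log-odds alignment penalties from rates
#'
#' Converts an average point-mutation rate, a per-base-pair indel rate and a
#' geometric indel length scale into the natural-log-odds penalties of the
#' affine-gap aligner. The gap-open penalty includes the first extension
#' step; insertion penalties carry an extra `-ln 4` per base for the choice
#' of the inserted nucleotide. With the defaults this reproduces the
#' familiar values: match -0.05, mismatch -3.0, deletion open -7.7, extend
#' -0.1, insertion open -9.1, extend -1.5.
#'
#' @param point_rate average point-mutation rate per base pair, in (0, 1).
#' @param indel_rate indel-event rate per base pair, in (0, 1).
#' @param length_scale characteristic (exponential) indel length in bp.
#' @return object of class `penalty_set` with fields `match`, `mismatch`,
#'   `del_open`, `del_extend`, `ins_open`, `ins_extend`.
#' @export
derive_penalties <- function(point_rate = 0.05, indel_rate = 5e-4,
                             length_scale = 10) {
  if (point_rate <= 0 || point_rate >= 1 || indel_rate <= 0 || indel_rate >= 1)
    stop("rates must lie strictly inside (0, 1)")
  if (length_scale <= 0) stop("length_scale must be positive")
  del_extend <- -1 / length_scale
  structure(list(match = log(1 - point_rate),
                 mismatch = log(point_rate),
                 del_open = log(indel_rate) + del_extend,
                 del_extend = del_extend,
                 ins_open = log(indel_rate) + del_extend - log(4),
                 ins_extend = del_extend - log(4)),
            class = "penalty_set")
}

#' Best-scoring affine-gap global alignment
#'
#' Standard Needleman-Wunsch with a three-state affine gap recursion,
#' returning the single maximum-score alignment and its event decomposition.
#' Ties are broken deterministically: diagonal over deletion over insertion,
#' and among equal-score gap placements the gap is placed leftmost (5').
#' Terminal gaps are scored like internal gaps (true global alignment).
#'
#' @param s read sequence (character string).
#' @param t template sequence (character string).
#' @param penalties a [derive_penalties()] object.
#' @return list with `score`, `events` (data.frame with columns `kind`,
#'   `position` = 0-based template position, `read_position`, `length`,
#'   `inserted_seq`) and `n_aligned` (number of aligned match/mismatch
#'   columns).
#' @export
nw_align <- function(s, t, penalties) {
  res <- .cpp_nw_align(seq_to_int(s), seq_to_int(t), penalties$match,
                       penalties$mismatch, penalties$del_open,
                       penalties$del_extend, penalties$ins_open,
                       penalties$ins_extend)
  kinds <- c("point", "del", "ins")
  ev <- data.frame(kind = kinds[res$kind + 1L],
                   position = res$tpos,
                   read_position = res$rpos,
                   length = res$len,
                   inserted_seq = character(length(res$kind)),
                   stringsAsFactors = FALSE)
  grab <- ev$kind != "del"
  if (any(grab))
    ev$inserted_seq[grab] <- substring(s, ev$read_position[grab] + 1L,
                                       ev$read_position[grab] + ev$length[grab])
  list(score = res$score, events = ev, n_aligned = res$n_aligned)
}

#' Annotate reads against a template set
#'
#' Aligns every read to every template with [nw_align()] and keeps, for each
#' read, the best-scoring template (ties broken by template order). This is
#' the deterministic baseline annotation whose event lists feed the summary
#' statistics and initialize the probabilistic inference.
#'
#' @param reads named character vector of reads.
#' @param templates a [template_set()].
#' @param penalties a [derive_penalties()] object.
#' @return object of class `annotation_set`: `events` (data.frame of all
#'   events, with `read_id` and `template_id` columns) and `per_read`
#'   (data.frame with `read_id`, `template_id`, `score`, `n_point`, `n_del`,
#'   `n_ins`, `n_aligned`, `shm_rate`).
#' @export
annotate <- function(reads, templates, penalties = derive_penalties()) {
  stopifnot(inherits(templates, "template_set"))
  if (is.null(names(reads))) names(reads) <- sprintf("read_%05d",
                                                     seq_along(reads))
  tmpl_int <- lapply(templates$seqs, seq_to_int)
  events <- vector("list", length(reads))
  per <- vector("list", length(reads))
  for (i in seq_along(reads)) {
    si <- seq_to_int(reads[[i]])
    best <- NULL
    best_score <- -Inf
    best_tid <- NA_character_
    for (tid in names(tmpl_int)) {
      res <- .cpp_nw_align(si, tmpl_int[[tid]], penalties$match,
                           penalties$mismatch, penalties$del_open,
                           penalties$del_extend, penalties$ins_open,
                           penalties$ins_extend)
      if (res$score > best_score) {
        best_score <- res$score
        best <- res
        best_tid <- tid
      }
    }
    kinds <- c("point", "del", "ins")
    ev <- data.frame(kind = kinds[best$kind + 1L], position = best$tpos,
                     read_position = best$rpos, length = best$len,
                     inserted_seq = character(length(best$kind)), stringsAsFactors = FALSE)
    if (nrow(ev)) {
      grab <- ev$kind != "del"
      if (any(grab))
        ev$inserted_seq[grab] <-
          substring(reads[[i]], ev$read_position[grab] + 1L,
                    ev$read_position[grab] + ev$length[grab])
      ev$read_id <- names(reads)[i]
      ev$template_id <- best_tid
      events[[i]] <- ev
    }
    n_point <- sum(ev$kind == "point")
    per[[i]] <- data.frame(read_id = names(reads)[i], template_id = best_tid,
                           score = best$score, n_point = n_point,
                           n_del = sum(ev$kind == "del"),
                           n_ins = sum(ev$kind == "ins"),
                           n_aligned = best$n_aligned,
                           shm_rate = n_point / best$n_aligned,
                           stringsAsFactors = FALSE)
  }
  keep <- !vapply(events, is.null, TRUE)
  events <- if (any(keep)) do.call(rbind, events[keep]) else {
    ev <- empty_events()
    ev$read_position <- integer(0); ev$read_id <- character(0)
    ev$template_id <- character(0); ev
  }
  rownames(events) <- NULL
  structure(list(events = events, per_read = do.call(rbind, per)),
            class = "annotation_set")
}

#' Deterministic parameter estimates from an annotation
#'
#' Turns best-scoring alignments into the plug-in parameter estimates used
#' both as a baseline and to initialize the probabilistic fit: the naive
#' fraction is the fraction of event-free reads, rescaled indel rates are
#' ratios of pooled event counts to pooled point-mutation counts, length
#' distributions are (pseudocounted) event-length histograms, and the
#' mutation-rate density is a smoothed histogram of per-read SHM rates of
#' mutated reads.
#'
#' @param ann an [annotate()] result.
#' @param theta_max support of the estimated length distributions.
#' @param bin_width prior bin width.
#' @param pseudocount added to each length bin before normalization.
#' @return list with `f`, `beta_del`, `beta_ins`, `len_del`, `len_ins`,
#'   `prior` ([mu_prior()]) and `model` (an assembled [indel_model()]).
#' @export
deterministic_estimates <- function(ann, theta_max = 30, bin_width = 5e-4,
                                    pseudocount = 0.5) {
  pr <- ann$per_read
  naive <- pr$n_point + pr$n_del + pr$n_ins == 0
  f <- mean(naive)
  n_point <- sum(pr$n_point)
  beta_del <- sum(pr$n_del) / max(n_point, 1)
  beta_ins <- sum(pr$n_ins) / max(n_point, 1)
  hist_of <- function(kind) {
    lens <- ann$events$length[ann$events$kind == kind]
    lens <- lens[lens <= theta_max]
    h <- tabulate(lens, nbins = theta_max) + pseudocount
    length_distribution(h / sum(h))
  }
  nbin <- round(1 / bin_width)
  mids <- (seq_len(nbin) - 0.5) * bin_width
  rates <- pr$shm_rate[!naive]
  if (length(rates) >= 2) {
    dens <- density(rates, bw = 0.005, from = mids[1], to = mids[nbin],
                    n = nbin)$y
    dens[dens < 0] <- 0
  } else {
    dens <- rep(1, nbin)
  }
  dens <- dens / (sum(dens) * bin_width)
  prior <- mu_prior(f, dens, bin_width)
  model <- indel_model(prior, beta_del = min(beta_del, 0.45),
                       beta_ins = min(beta_ins, 0.45),
                       len_del = hist_of("del"), len_ins = hist_of("ins"))
  list(f = f, beta_del = beta_del, beta_ins = beta_ins,
       len_del = model$len_del, len_ins = model$len_ins,
       prior = prior, model = model)
}
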