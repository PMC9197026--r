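# helpers shared by the summary statistics: annotations are either an
# `annotation_set` from annotate() or a ground-truth event table from
# generate_repertoire() (plus the read ids it covers).

events_of <- function(annotations) {
  if (inherits(annotations, "annotation_set")) annotations$events
  else annotations
}

per_read_counts <- function(annotations, read_ids = NULL) {
  ev <- events_of(annotations)
  if (is.null(read_ids)) {
    if (inherits(annotations, "annotation_set"))
      read_ids <- annotations$per_read$read_id
    else read_ids <- unique(ev$read_id)
  }
  count <- function(kind)
    vapply(read_ids,
           function(id) sum(ev$read_id == id & ev$kind == kind), 0L)
  data.frame(read_id = read_ids, n_point = count("point"),
             n_del = count("del"), n_ins = count("ins"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Distribution of the number of indels per read
#'
#' Empirical fraction of reads carrying exactly n indel events, separately
#' for deletions, insertions and both types cumulated, together with the
#' maximum-likelihood Poisson mean for comparison (the generative model
#' with a variable mutation rate is super-Poissonian: variance exceeds the
#' mean).
#'
#' @param annotations an [annotate()] result or ground-truth event table.
#' @param read_ids read ids covered (required for event tables so that
#'   event-free reads enter the zero class).
#' @return list with `counts` (data.frame n, p_del, p_ins, p_all) and
#'   `poisson_mean` (named vector of fitted means).
#' @export
indel_count_distribution <- function(annotations, read_ids = NULL) {
  pc <- per_read_counts(annotations, read_ids)
  if (nrow(pc) == 0L) stop("no reads to summarize")
  all_counts <- pc$n_del + pc$n_ins
  nmax <- max(all_counts, 0)
  p_of <- function(x) vapply(0:nmax, function(k) mean(x == k), 0.0)
  list(counts = data.frame(n = 0:nmax, p_del = p_of(pc$n_del),
                           p_ins = p_of(pc$n_ins), p_all = p_of(all_counts)),
       poisson_mean = c(del = mean(pc$n_del), ins = mean(pc$n_ins),
                        all = mean(all_counts)),
       variance = c(del = var_pop(pc$n_del), ins = var_pop(pc$n_ins),
                    all = var_pop(all_counts)))
}

var_pop <- function(x) mean((x - mean(x))^2)

#' Mean SHM load conditioned on the number of indels
#'
#' Groups reads by their number of indel events and reports the mean and
#' standard deviation of the per-read SHM point-mutation rate in each
#' group. Under a mixture of maturation ages this profile increases with n;
#' under a single fixed rate it is flat.
#'
#' @param annotations an [annotate()] result (needs per-read SHM rates), or
#'   a ground-truth event table with `shm_rates` supplied.
#' @param shm_rates named per-read SHM rates (required for event tables).
#' @return data.frame with `n_indels`, `mean_shm`, `sd_shm`, `n_reads`.
#' @export
shm_conditional_on_indels <- function(annotations, shm_rates = NULL) {
  if (inherits(annotations, "annotation_set")) {
    pr <- annotations$per_read
    shm <- setNames(pr$shm_rate, pr$read_id)
    pc <- per_read_counts(annotations)
  } else {
    if (is.null(shm_rates)) stop("shm_rates required for event tables")
    shm <- shm_rates
    pc <- per_read_counts(annotations, names(shm_rates))
  }
  n_ind <- pc$n_del + pc$n_ins
  groups <- sort(unique(n_ind))
  out <- lapply(groups, function(g) {
    r <- shm[pc$read_id[n_ind == g]]
    data.frame(n_indels = g, mean_shm = mean(r),
               sd_shm = if (length(r) > 1) stats::sd(r) else NA_real_,
               n_reads = length(r))
  })
  do.call(rbind, out)
}

overlap_fraction <- function(segment, flank) {
  a <- strsplit(segment, "", fixed = TRUE)[[1]]
  b <- strsplit(flank, "", fixed = TRUE)[[1]]
  mean(a == b)
}

#' Overlap of inserted segments with their flanking regions
#'
#' For every insertion, the fraction of positions at which the inserted
#' segment matches the same-length region immediately 5' or 3' of it along
#' the read; the larger of the two is reported with its side. High overlap
#' is the signature of duplication (polymerase slippage); the generative
#' model's uniform-random insertions show only the chance-level overlap. A
#' randomized control replaces each insert with uniform random bases.
#'
#' @param annotations an [annotate()] result or ground-truth event table
#'   with `read_position` available (annotation events carry it; for
#'   ground-truth tables insertions are located via their reconstructed
#'   read positions, so pass annotation events where possible).
#' @param reads named character vector of reads.
#' @param control if `TRUE`, also compute the randomized control.
#' @return data.frame with one row per scorable insertion: `read_id`,
#'   `length`, `overlap`, `side`, and `control` overlap when requested;
#'   events with incomplete flanks are skipped (attribute `n_skipped`).
#' @export
insertion_flank_overlap <- function(annotations, reads, control = TRUE) {
  ev <- events_of(annotations)
  ev <- ev[ev$kind == "ins", , drop = FALSE]
  if (is.null(ev$read_position))
    stop("insertion events must carry read positions")
  out <- list()
  skipped <- 0L
  for (k in seq_len(nrow(ev))) {
    e <- ev[k, ]
    read <- reads[[e$read_id]]
    L <- nchar(read)
    start <- e$read_position + 1L  # 1-based first inserted base
    end <- start + e$length - 1L
    if (start - e$length < 1L || end + e$length > L) {
      skipped <- skipped + 1L
      next
    }
    ins <- substring(read, start, end)
    fl5 <- substring(read, start - e$length, start - 1L)
    fl3 <- substring(read, end + 1L, end + e$length)
    o5 <- overlap_fraction(ins, fl5)
    o3 <- overlap_fraction(ins, fl3)
    row <- data.frame(read_id = e$read_id, length = e$length,
                      overlap = max(o5, o3),
                      side = if (o5 >= o3) "5p" else "3p",
                      stringsAsFactors = FALSE)
    if (control) {
      rnd <- paste(sample(NUCLEOTIDES, e$length, replace = TRUE),
                   collapse = "")
      row$control <- max(overlap_fraction(rnd, fl5),
                         overlap_fraction(rnd, fl3))
    }
    out[[length(out) + 1L]] <- row
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(read_id = character(0), length = integer(0),
               overlap = numeric(0), side = character(0))
  attr(res, "n_skipped") <- skipped
  res
}

#' Overlap of deleted segments with their flanking regions
#'
#' Same contract as [insertion_flank_overlap()], but the deleted bases and
#' both flanks are taken from the template.
#'
#' @param annotations an [annotate()] result or ground-truth event table
#'   (template positions suffice).
#' @param templates a [template_set()].
#' @param template_ids per-read template assignment for ground-truth
#'   tables; annotation events carry their own.
#' @param control if `TRUE`, also compute the randomized control.
#' @export
deletion_flank_overlap <- function(annotations, templates,
                                   template_ids = NULL, control = TRUE) {
  ev <- events_of(annotations)
  ev <- ev[ev$kind == "del", , drop = FALSE]
  if (is.null(ev$template_id)) {
    if (is.null(template_ids)) stop("template_ids required")
    ev$template_id <- template_ids[ev$read_id]
  }
  out <- list()
  skipped <- 0L
  for (k in seq_len(nrow(ev))) {
    e <- ev[k, ]
    tpl <- templates$seqs[[e$template_id]]
    L <- nchar(tpl)
    start <- e$position + 1L
    end <- start + e$length - 1L
    if (start - e$length < 1L || end + e$length > L) {
      skipped <- skipped + 1L
      next
    }
    del <- substring(tpl, start, end)
    fl5 <- substring(tpl, start - e$length, start - 1L)
    fl3 <- substring(tpl, end + 1L, end + e$length)
    o5 <- overlap_fraction(del, fl5)
    o3 <- overlap_fraction(del, fl3)
    row <- data.frame(read_id = e$read_id, length = e$length,
                      overlap = max(o5, o3),
                      side = if (o5 >= o3) "5p" else "3p",
                      stringsAsFactors = FALSE)
    if (control) {
      rnd <- paste(sample(NUCLEOTIDES, e$length, replace = TRUE),
                   collapse = "")
      row$control <- max(overlap_fraction(rnd, fl5),
                         overlap_fraction(rnd, fl3))
    }
    out[[length(out) + 1L]] <- row
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(read_id = character(0), length = integer(0),
               overlap = numeric(0), side = character(0))
  attr(res, "n_skipped") <- skipped
  res
}

#' Distances between deletion pairs along the same read
#'
#' Restricted to reads hosting exactly two deletion events and no
#' insertions, the number of template base pairs between the end of the
#' first deletion and the start of the second. Deterministic best-scoring
#' annotation depletes short distances (nearby events get merged into one
#' long deletion), which the comparison against ground truth exposes.
#'
#' @param annotations an [annotate()] result or ground-truth event table.
#' @return integer vector of distances (one per qualifying read).
#' @export
deletion_pair_distances <- function(annotations) {
  ev <- events_of(annotations)
  pc <- per_read_counts(annotations, unique(ev$read_id))
  keep <- pc$read_id[pc$n_del == 2L & pc$n_ins == 0L]
  dist <- integer(0)
  for (id in keep) {
    d <- ev[ev$read_id == id & ev$kind == "del", , drop = FALSE]
    d <- d[order(d$position), ]
    dist <- c(dist, d$position[2] - (d$position[1] + d$length[1]))
  }
  dist
}

#' Positional mutation profiles with coverage masking
#'
#' Per-template-position rates of point mutations, deletion starts and
#' insertion starts in template-local (0-based) coordinates, normalized by
#' positional coverage, masked where fewer than `min_coverage_frac` of the
#' template's reads cover the position, plus Pearson correlations between
#' the three profiles. Since global alignments cover the whole template,
#' coverage here is the number of reads assigned to the template.
#'
#' @param annotations an [annotate()] result or ground-truth event table.
#' @param templates a [template_set()].
#' @param template_ids per-read template assignment (required for
#'   ground-truth tables).
#' @param min_coverage_frac masking threshold (default 0.02).
#' @param position_map optional function mapping (template_id, 0-based
#'   position) to a common numbering; identity by default.
#' @return list with `profiles` (data.frame template_id, position, rate per
#'   kind, coverage, masked) and `correlations` (data.frame pair, r, p).
#' @export
positional_profiles <- function(annotations, templates, template_ids = NULL,
                                min_coverage_frac = 0.02,
                                position_map = NULL) {
  ev <- events_of(annotations)
  if (is.null(ev$template_id)) {
    if (is.null(template_ids)) stop("template_ids required")
    ev$template_id <- template_ids[ev$read_id]
    reads_per_tpl <- table(template_ids)
  } else {
    reads_per_tpl <- table(setNames(
      events_of(annotations)$template_id[!duplicated(ev$read_id)],
      NULL))
    if (inherits(annotations, "annotation_set"))
      reads_per_tpl <- table(annotations$per_read$template_id)
  }
  total_reads <- sum(reads_per_tpl)
  out <- list()
  for (tid in names(templates$seqs)) {
    L <- nchar(templates$seqs[[tid]])
    cov <- if (tid %in% names(reads_per_tpl)) reads_per_tpl[[tid]] else 0L
    rate_of <- function(kind) {
      sel <- ev$template_id == tid & ev$kind == kind
      counts <- tabulate(ev$position[sel] + 1L, nbins = L)
      if (cov > 0) counts / cov else rep(NA_real_, L)
    }
    pos <- 0:(L - 1L)
    if (!is.null(position_map)) pos <- position_map(tid, pos)
    out[[tid]] <- data.frame(template_id = tid, position = pos,
                             point = rate_of("point"), del = rate_of("del"),
                             ins = rate_of("ins"), coverage = cov,
                             masked = cov < min_coverage_frac * total_reads,
                             stringsAsFactors = FALSE)
  }
  prof <- do.call(rbind, out)
  rownames(prof) <- NULL
  kept <- prof[!prof$masked, , drop = FALSE]
  if (nrow(kept) == 0L) stop("all positions masked; no profile to report")
  pairs <- list(c("point", "del"), c("point", "ins"), c("del", "ins"))
  cors <- do.call(rbind, lapply(pairs, function(p) {
    ct <- suppressWarnings(cor.test(kept[[p[1]]], kept[[p[2]]]))
    data.frame(pair = paste(p, collapse = "-"), r = unname(ct$estimate),
               p_value = ct$p.value, stringsAsFactors = FALSE)
  }))
  list(profiles = prof, correlations = cors)
}

#' Indel / point-mutation co-localization against a reshuffled null
#'
#' For each indel, the distance (in template base pairs) to the nearest
#' point mutation on the same read, binned; the null distribution is
#' obtained by reshuffling the indel-to-read assignment among reads carrying
#' the same template and recomputing. The reported ratio is empirical /
#' null per distance bin; under the generative model (independent
#' placement) it is about 1 everywhere.
#'
#' @param annotations an [annotate()] result or ground-truth event table.
#' @param template_ids per-read template assignment (required for
#'   ground-truth tables).
#' @param n_perm number of reshuffles for the null.
#' @param max_dist largest distance bin.
#' @return data.frame with `distance`, `observed`, `null`, `ratio`;
#'   templates with fewer than two indel-bearing reads are excluded (ids in
#'   attribute `excluded_templates`).
#' @export
colocalization_null <- function(annotations, template_ids = NULL,
                                n_perm = 20, max_dist = 30) {
  ev <- events_of(annotations)
  if (is.null(ev$template_id)) {
    if (is.null(template_ids)) stop("template_ids required")
    ev$template_id <- template_ids[ev$read_id]
  }
  indels <- ev[ev$kind != "point", , drop = FALSE]
  points <- ev[ev$kind == "point", , drop = FALSE]
  dist_one <- function(ipos, iread) {
    pp <- points$position[points$read_id == iread]
    if (!length(pp)) return(NA_integer_)
    min(abs(pp - ipos))
  }
  observed <- mapply(dist_one, indels$position, indels$read_id)
  excluded <- character(0)
  null_all <- integer(0)
  for (tid in unique(indels$template_id)) {
    sub <- indels[indels$template_id == tid, , drop = FALSE]
    pool <- unique(ev$read_id[ev$template_id == tid])
    if (length(pool) < 2L) {
      excluded <- c(excluded, tid)
      next
    }
    for (p in seq_len(n_perm)) {
      newids <- sample(pool, nrow(sub), replace = TRUE)
      null_all <- c(null_all,
                    mapply(dist_one, sub$position, newids))
    }
  }
  breaks <- c(0:max_dist, Inf)
  bin <- function(x) {
    x <- x[!is.na(x)]
    h <- tabulate(findInterval(x, breaks), nbins = length(breaks) - 1L)
    h / max(sum(h), 1)
  }
  obs_h <- bin(observed)
  null_h <- bin(null_all)
  data.frame(distance = 0:max_dist, observed = obs_h, null = null_h,
             ratio = ifelse(null_h > 0, obs_h / null_h, NA_real_))
}

#' Filter reads by aligned V-segment coverage
#'
#' Drops reads whose alignment covers fewer than `min_coverage` template
#' base pairs. With global alignments the covered span is the template
#' length minus deleted bases.
#'
#' @param annotations an [annotate()] result.
#' @param templates a [template_set()].
#' @param min_coverage minimum covered base pairs (default 200).
#' @return the filtered `annotation_set`; dropped read ids in attribute
#'   `dropped`.
#' @export
quality_filter <- function(annotations, templates, min_coverage = 200) {
  stopifnot(inherits(annotations, "annotation_set"))
  pr <- annotations$per_read
  tlen <- vapply(templates$seqs[pr$template_id], nchar, 0L)
  del_bp <- vapply(pr$read_id, function(id) {
    ev <- annotations$events
    sum(ev$length[ev$read_id == id & ev$kind == "del"])
  }, 0)
  covered <- tlen - del_bp
  keep <- covered >= min_coverage
  out <- structure(list(events = annotations$events[
    annotations$events$read_id %in% pr$read_id[keep], , drop = FALSE],
    per_read = pr[keep, , drop = FALSE]),
    class = "annotation_set")
  attr(out, "dropped") <- pr$read_id[!keep]
  out
}

#' Characteristic length of an event-length distribution
#'
#' Fits the exponential decay `P(l) ~ exp(-l / scale)` by mass-weighted
#' least squares of `log P(l)` on `l` over the support where the
#' distribution carries appreciable mass, and returns `scale` (the inverse
#' decay slope) in base pairs.
#'
#' @param probs probability vector indexed by length 1..theta_max (or a
#'   [length_distribution()]).
#' @param min_prob bins below this probability are excluded from the fit.
#' @export
length_scale_fit <- function(probs, min_prob = 1e-4) {
  if (inherits(probs, "length_distribution")) probs <- probs$probs
  keep <- probs > min_prob
  if (sum(keep) < 3) stop("too few occupied length bins to fit a scale")
  l <- seq_along(probs)[keep]
  fit <- lm(log(probs[keep]) ~ l, weights = probs[keep])
  -1 / unname(coef(fit)[2])
}
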