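#' Read sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()]. Records containing
#' characters outside A/C/G/T (e.g. `N`) are skipped with a warning;
#' duplicated ids are deduplicated with numeric suffixes.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L) stop("FASTA file contains no records: ", path)
  seqs <- as.character(x)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad)) {
    warning(sum(bad), " record(s) with non-ACGT characters skipped")
    seqs <- seqs[!bad]
  }
  if (length(seqs) == 0L) stop("no usable records in ", path)
  if (anyDuplicated(names(seqs))) {
    warning("duplicated record ids deduplicated with suffixes")
    names(seqs) <- make.unique(names(seqs), sep = "_")
  }
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

MODEL_SCHEMA_VERSION <- "1.0"

#' Serialize an SHM-indel model to JSON
#'
#' The JSON document stores the naive fraction, the binned mutation-rate
#' density (bin edges implicit from `bin_width`), the rescaled indel rates
#' and the two length distributions at full double precision, so that a
#' write/read round trip is bit-exact.
#'
#' @param model an [indel_model()].
#' @param path output file.
#' @export
write_indel_model <- function(model, path) {
  validate_indel_model(model)
  # 17 significant digits guarantee an exact double round trip (jsonlite
  # caps its output short of that, so numbers are formatted here)
  num <- function(x) sprintf("%.17g", x)
  arr <- function(x) paste0("[", paste(num(x), collapse = ","), "]")
  doc <- c(sprintf('"version": "%s"', MODEL_SCHEMA_VERSION),
           sprintf('"naive_fraction": %s', num(model$prior$f)),
           sprintf('"bin_width": %s', num(model$prior$bin_width)),
           sprintf('"mu_density": %s', arr(model$prior$density)),
           sprintf('"beta_del": %s', num(model$beta_del)),
           sprintf('"beta_ins": %s', num(model$beta_ins)),
           sprintf('"p_del": %s', arr(model$len_del$probs)),
           sprintf('"p_ins": %s', arr(model$len_ins$probs)),
           sprintf('"theta_max": %d', model$len_del$theta_max))
  writeLines(paste0("{\n  ", paste(doc, collapse = ",\n  "), "\n}"), path)
  invisible(path)
}

#' Read an SHM-indel model from JSON
#'
#' @param path JSON file written by [write_indel_model()] (or hand-authored
#'   with the same schema). Missing `theta_max` is defaulted to 30 with a
#'   warning; schema violations raise an error naming the offending field.
#' @return an [indel_model()].
#' @export
read_indel_model <- function(path) {
  doc <- jsonlite::fromJSON(path)
  for (field in c("naive_fraction", "beta_del", "beta_ins", "p_del", "p_ins"))
    if (is.null(doc[[field]])) stop("model file is missing field '", field, "'")
  if (is.null(doc$theta_max)) {
    warning("model file has no 'theta_max'; defaulting to 30")
    doc$theta_max <- 30
  }
  if (doc$beta_del < 0) stop("invalid model field 'beta_del': must be >= 0")
  if (doc$beta_ins < 0) stop("invalid model field 'beta_ins': must be >= 0")
  if (is.null(doc$bin_width)) doc$bin_width <- 5e-4
  if (length(doc$p_del) != doc$theta_max || length(doc$p_ins) != doc$theta_max)
    stop("invalid model: length distributions must have theta_max entries")
  indel_model(prior = mu_prior(doc$naive_fraction, doc$mu_density,
                               doc$bin_width),
              beta_del = doc$beta_del, beta_ins = doc$beta_ins,
              len_del = length_distribution(doc$p_del),
              len_ins = length_distribution(doc$p_ins))
}
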