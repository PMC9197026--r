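# Brute-force scenario enumeration: explicit recursion over the last event of
# every alignment path (diagonal step, deletion of l template bases,
# insertion of l read bases), multiplying elementary probabilities. Serves as
# the independent oracle for the forward algorithm on tiny instances.
bf_scenario_sum <- function(s, t, mu, model) {
  si <- strsplit(s, "", fixed = TRUE)[[1]]
  ti <- strsplit(t, "", fixed = TRUE)[[1]]
  Td <- model$len_del$theta_max
  Ti <- model$len_ins$theta_max
  stay <- 1 - mu * model$beta_del - mu * model$beta_ins
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(1)
    tot <- 0
    if (i > 0 && j > 0)
      tot <- tot + rec(i - 1, j - 1) * stay *
        (if (si[i] == ti[j]) 1 - mu else mu)
    if (j > 0)
      for (l in seq_len(min(Td, j)))
        tot <- tot + rec(i, j - l) * mu * model$beta_del *
          model$len_del$probs[l]
    if (i > 0)
      for (l in seq_len(min(Ti, i)))
        tot <- tot + rec(i - l, j) * mu * model$beta_ins *
          model$len_ins$probs[l] * 0.25^l
    tot
  }
  rec(length(si), length(ti))
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# small model with short event support for enumeration tests
small_model <- function(beta_del = 0.1, beta_ins = 0.08, theta = 3,
                        f = 0.1) {
  indel_model(mu_prior(f, rep(1, 2000)), beta_del, beta_ins,
              geometric_length_distribution(2, theta),
              geometric_length_distribution(2, theta))
}

# the generative conditions used for synthetic-data validation
validation_model <- function(f = 0.1) {
  indel_model(mu_prior(f, rep(1, 2000)), 0.025, 0.025,
              geometric_length_distribution(15, 30),
              geometric_length_distribution(15, 30))
}

synthetic_templates <- function() {
  template_set(read_fasta(system.file("extdata",
                                      "synthetic_v_templates.fasta",
                                      package = "shmindel")))
}
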