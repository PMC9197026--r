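test_that("indel count distribution and Poisson fit", {
  set.seed(51)
  ts <- synthetic_templates()
  # indel-free repertoire: all mass at zero
  gen0 <- indel_model(mu_prior(0.2, rep(1, 2000)), 0, 0)
  rep0 <- generate_repertoire(ts, gen0, n = 40, seed = 52, f = 0.2)
  ann0 <- annotate(rep0$reads, ts)
  icd0 <- indel_count_distribution(ann0)
  expect_equal(icd0$counts$p_all[1], 1)
  expect_equal(unname(icd0$poisson_mean["all"]), 0)
  # Poisson-generated counts recover their mean (MLE = sample mean)
  counts <- stats::rpois(2e4, 0.3)
  ids <- sprintf("r%05d", seq_along(counts))
  ev <- do.call(rbind, lapply(which(counts > 0), function(i)
    data.frame(read_id = ids[i], kind = rep("del", counts[i]),
               position = 0L, length = 1L, inserted_seq = "")))
  icd <- indel_count_distribution(ev, read_ids = ids)
  expect_lt(abs(icd$poisson_mean[["del"]] - 0.3),
            3 * sqrt(0.3 / 2e4))
})

test_that("generative counts are super-Poissonian under a mu mixture", {
  set.seed(53)
  ts <- synthetic_templates()
  rep <- generate_repertoire(ts, validation_model(), n = 600, seed = 54)
  icd <- indel_count_distribution(rep$truth,
                                  read_ids = names(rep$reads))
  expect_gt(icd$variance[["all"]], icd$poisson_mean[["all"]])
})

test_that("SHM load grows with the number of indels under a rate mixture", {
  set.seed(55)
  ts <- synthetic_templates()
  rep <- generate_repertoire(ts, validation_model(), n = 800, seed = 56)
  shm <- setNames(vapply(seq_along(rep$reads), function(i)
    sum(rep$truth$read_id == names(rep$reads)[i] &
          rep$truth$kind == "point") / 300, 0.0), names(rep$reads))
  prof <- shm_conditional_on_indels(rep$truth, shm_rates = shm)
  lo <- prof$mean_shm[prof$n_indels == 0]
  hi <- prof$mean_shm[prof$n_indels == max(prof$n_indels[prof$n_reads >= 5])]
  expect_gt(hi, lo)
  # constant-rate model gives a flat profile (slope indistinguishable from 0)
  rep2 <- generate_repertoire(ts, validation_model(), n = 400, seed = 57,
                              f = 0, spec = shifted_gamma_spec(sd = 1e-3))
  shm2 <- setNames(vapply(seq_along(rep2$reads), function(i)
    sum(rep2$truth$read_id == names(rep2$reads)[i] &
          rep2$truth$kind == "point") / 300, 0.0), names(rep2$reads))
  prof2 <- shm_conditional_on_indels(rep2$truth, shm_rates = shm2)
  keep <- prof2$n_reads >= 10
  expect_lt(diff(range(prof2$mean_shm[keep])), 0.02)
})

test_that("flank overlap detects duplications and scores controls", {
  ts <- synthetic_templates()
  tpl <- ts$seqs[[1]]
  # build a read whose insertion duplicates its 5' flank exactly
  seg <- substring(tpl, 96, 100)
  read <- paste0(substring(tpl, 1, 100), seg, substring(tpl, 101))
  ev <- data.frame(read_id = "r1", kind = "ins", position = 100L,
                   read_position = 100L, length = 5L, inserted_seq = seg)
  ov <- insertion_flank_overlap(ev, c(r1 = read), control = FALSE)
  expect_equal(ov$overlap, 1)
  expect_identical(ov$side, "5p")
  # an insertion at the read boundary is skipped and counted
  ev2 <- data.frame(read_id = "r1", kind = "ins", position = 0L,
                    read_position = 1L, length = 5L,
                    inserted_seq = substring(read, 2, 6))
  ov2 <- insertion_flank_overlap(ev2, c(r1 = read), control = FALSE)
  expect_identical(nrow(ov2), 0L)
  expect_identical(attr(ov2, "n_skipped"), 1L)
  # uniform random inserts: mean max-of-two-flanks overlap above 0.25,
  # matching a Monte-Carlo oracle of the null
  set.seed(58)
  n <- 4000
  oracle <- mean(vapply(seq_len(n), function(k) {
    ins <- sample(4, 5, TRUE)
    max(mean(ins == sample(4, 5, TRUE)), mean(ins == sample(4, 5, TRUE)))
  }, 0.0))
  rep <- generate_repertoire(ts, validation_model(), n = 2500, seed = 59,
                             f = 0)
  tru <- rep$truth
  # restrict to reads whose only indel is one insertion of length 5: point
  # mutations do not shift read coordinates, so the read position equals
  # the template position
  n_indel <- table(tru$read_id[tru$kind != "point"])
  single <- names(n_indel)[n_indel == 1]
  tru <- tru[tru$kind == "ins" & tru$length == 5 &
               tru$read_id %in% single, , drop = FALSE]
  tru$read_position <- tru$position
  # confirm the located segments before trusting the overlap statistic
  ok <- vapply(seq_len(nrow(tru)), function(k)
    substring(rep$reads[[tru$read_id[k]]], tru$read_position[k] + 1,
              tru$read_position[k] + 5) == tru$inserted_seq[k], TRUE)
  expect_true(all(ok))
  ov3 <- insertion_flank_overlap(tru, rep$reads, control = FALSE)
  expect_gt(mean(ov3$overlap), 0.25)
  expect_lt(abs(mean(ov3$overlap) - oracle),
            2 * stats::sd(ov3$overlap) / sqrt(nrow(ov3)) + 0.02)
})

test_that("deletion flank overlap mirrors the insertion contract", {
  ts <- synthetic_templates()
  tpl <- ts$seqs[[2]]
  ev <- data.frame(read_id = "r1", kind = "del", position = 100L,
                   length = 4L, inserted_seq = "",
                   template_id = "synthV2")
  ov <- deletion_flank_overlap(ev, ts, control = TRUE)
  expect_identical(nrow(ov), 1L)
  manual5 <- mean(strsplit(substring(tpl, 101, 104), "")[[1]] ==
                    strsplit(substring(tpl, 97, 100), "")[[1]])
  manual3 <- mean(strsplit(substring(tpl, 101, 104), "")[[1]] ==
                    strsplit(substring(tpl, 105, 108), "")[[1]])
  expect_equal(ov$overlap, max(manual5, manual3))
  expect_true(ov$control >= 0 && ov$control <= 1)
})

test_that("inter-deletion distances use template coordinates", {
  ev <- data.frame(read_id = "r1", kind = c("del", "del"),
                   position = c(7L, 15L), length = c(3L, 2L),
                   inserted_seq = "")
  # first deletion ends at position 10, second starts at 15: 5 bp between
  expect_identical(deletion_pair_distances(ev), 5L)
  # reads with insertions or a different deletion count are excluded
  ev2 <- rbind(ev, data.frame(read_id = "r1", kind = "ins", position = 2L,
                              length = 1L, inserted_seq = "A"))
  expect_identical(length(deletion_pair_distances(ev2)), 0L)
})

test_that("positional profiles are flat for the uniform generator", {
  set.seed(60)
  ts1 <- template_set(c(v = rand_seq(300)))
  rep <- generate_repertoire(ts1, validation_model(), n = 1500, seed = 61,
                             f = 0)
  prof <- positional_profiles(rep$truth, ts1,
                              template_ids = rep$template_id)
  pts <- prof$profiles$point[!prof$profiles$masked]
  counts <- pts * 1500
  expect_gt(chisq.test(counts)$p.value, 0.001)
  # identical event lists correlate perfectly
  ev <- rep$truth
  ev2 <- ev
  ev2$kind[ev2$kind == "del"] <- "ins"
  ev2$kind[ev$kind == "ins"] <- "del"
  both <- rbind(ev, ev2)
  prof2 <- positional_profiles(both, ts1, template_ids = rep$template_id)
  r_di <- prof2$correlations$r[prof2$correlations$pair == "del-ins"]
  expect_equal(r_di, 1)
})

test_that("co-localization ratio is near 1 for independent placement", {
  set.seed(62)
  ts1 <- template_set(c(v = rand_seq(300)))
  rep <- generate_repertoire(ts1, validation_model(), n = 500, seed = 63,
                             f = 0)
  co <- colocalization_null(rep$truth, template_ids = rep$template_id,
                            n_perm = 20)
  # per-bin ratios are noisy; compare pooled short-distance mass instead
  near <- co$distance <= 5
  pooled <- sum(co$observed[near]) / sum(co$null[near])
  expect_lt(abs(pooled - 1), 0.3)
  # hand-built co-localized events inflate the short-distance ratio
  ids <- sprintf("r%03d", 1:60)
  ev <- do.call(rbind, lapply(ids, function(id) {
    p <- sample(20:280, 1)
    data.frame(read_id = id, kind = c("del", "point"),
               position = c(p, p + 1L), length = c(2L, 1L),
               inserted_seq = c("", "A"))
  }))
  co2 <- colocalization_null(ev, template_ids = setNames(rep("v", 60), ids),
                             n_perm = 10)
  expect_gt(co2$ratio[co2$distance == 1], 1.5)
})

test_that("coverage filter drops short-coverage reads only", {
  set.seed(64)
  ts <- synthetic_templates()
  rep <- generate_repertoire(ts, validation_model(), n = 60, seed = 65)
  ann <- annotate(rep$reads, ts)
  filt <- quality_filter(ann, ts, min_coverage = 200)
  expect_lte(length(attr(filt, "dropped")), 60)
  expect_true(all(!filt$per_read$read_id %in% attr(filt, "dropped")))
  # a read with a 150-bp deletion covers only 150 bp and is dropped
  tpl <- ts$seqs[[1]]
  short <- paste0(substring(tpl, 1, 75), substring(tpl, 226))
  ann2 <- annotate(c(ok = tpl, cut = short), ts)
  filt2 <- quality_filter(ann2, ts, min_coverage = 200)
  expect_identical(attr(filt2, "dropped"), "cut")
  expect_identical(filt2$per_read$read_id, "ok")
})
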