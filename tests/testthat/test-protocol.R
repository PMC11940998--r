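# Cohorts here use a short 200-point axis so each protocol run stays fast;
# the statistical structure (patients, replicates, effects) is unchanged.

make_balanced_input <- function(n1, n2, spp = 3, seed = 1) {
  generate_cohort(tiny_config(n1 = n1, n2 = n2, spp = spp, seed = seed))
}

test_that("bootstrap balancing equalizes patient counts and draws replicate spectra", {
  ds <- make_balanced_input(41, 103, spp = 3, seed = 2)
  bal <- sersclass:::with_seed(5, balance_classes(ds, protocol_config()))
  tab <- table(class_of_patients(bal))
  expect_equal(unname(tab), c(41L, 41L), ignore_attr = TRUE)

  ds2 <- make_balanced_input(11, 11, spp = 4, seed = 3)
  bal2 <- sersclass:::with_seed(6, balance_classes(ds2,
    protocol_config(spectra_per_patient_draw = 3)))
  counts <- table(bal2$meta$class_label)
  expect_equal(unname(counts), c(33L, 33L), ignore_attr = TRUE)

  # already balanced and draw >= replicates: patient set unchanged
  ds3 <- make_balanced_input(5, 5, spp = 2, seed = 4)
  bal3 <- sersclass:::with_seed(7, balance_classes(ds3,
    protocol_config(spectra_per_patient_draw = 2)))
  expect_setequal(unique(bal3$meta$patient_id), unique(ds3$meta$patient_id))

  # patients with too few replicates are drawn with replacement
  ds4 <- make_balanced_input(3, 3, spp = 2, seed = 5)
  bal4 <- sersclass:::with_seed(8, balance_classes(ds4,
    protocol_config(spectra_per_patient_draw = 4)))
  expect_equal(nrow(bal4$intensities), 6 * 4)
  expect_false(anyDuplicated(bal4$meta$spectrum_id) > 0)
})

test_that("patient-wise split hits the nearest feasible spectra count with disjoint patients", {
  ds <- make_balanced_input(11, 11, spp = 3, seed = 6)  # 22 patients x 3
  for (s in 1:5) {
    sp <- sersclass:::with_seed(s, patient_split(ds, 0.8))
    expect_length(intersect(unique(sp$train$meta$patient_id),
                            unique(sp$test$meta$patient_id)), 0)
    expect_true(nrow(sp$train$intensities) %in% c(51, 54))
    for (side in sp)
      expect_equal(length(unique(side$meta$class_label)), 2)
  }
  # fraction 0.5 with 2 equal patients per class: 1 patient each side
  ds2 <- make_balanced_input(2, 2, spp = 3, seed = 7)
  sp2 <- sersclass:::with_seed(1, patient_split(ds2, 0.5))
  for (side in sp2)
    expect_equal(unname(table(class_of_patients(side))), c(1L, 1L),
                 ignore_attr = TRUE)
  expect_error(patient_split(make_balanced_input(1, 5), 0.8), "2 patients")
})

test_that("the protocol emits exactly P x T folds with no patient leakage", {
  ds <- preprocess_dataset(make_balanced_input(6, 8, seed = 8),
                           tiny_preprocess())
  for (pt in list(c(1, 1), c(2, 3))) {
    res <- run_protocol(ds, protocol_config(P = pt[1], T_rep = pt[2],
                                            K = 5, max_lv = 6, seed = 42))
    expect_length(res$folds, pt[1] * pt[2])
    for (f in res$folds) {
      expect_length(intersect(f$train_patient_ids, f$test_patient_ids), 0)
      expect_gte(f$n_lv_used, 1)
    }
  }
})

test_that("protocol runs are reproducible from the seed", {
  ds <- preprocess_dataset(make_balanced_input(6, 8, seed = 9),
                           tiny_preprocess())
  cfg <- protocol_config(P = 2, T_rep = 2, K = 5, max_lv = 5, seed = 77)
  r1 <- run_protocol(ds, cfg)
  r2 <- run_protocol(ds, cfg)
  expect_identical(summary(r1)$table, summary(r2)$table)
  expect_identical(summary(r1)$mean_vip, summary(r2)$mean_vip)
  r3 <- run_protocol(ds, protocol_config(P = 2, T_rep = 2, K = 5,
                                         max_lv = 5, seed = 78))
  # a different seed draws different balanced subsets / splits
  expect_false(identical(lapply(r1$folds, `[[`, "train_patient_ids"),
                         lapply(r3$folds, `[[`, "train_patient_ids")))
})

test_that("aggregation reduces fold metrics to mean/min/max and averages VIPs", {
  ds <- preprocess_dataset(make_balanced_input(6, 8, seed = 10),
                           tiny_preprocess())
  res <- run_protocol(ds, protocol_config(P = 3, T_rep = 1, K = 4,
                                          max_lv = 4, seed = 5))
  s <- aggregate_folds(res)
  expect_equal(s$n_folds, 3)
  expect_true(all(s$table$min <= s$table$mean + 1e-12))
  expect_true(all(s$table$mean <= s$table$max + 1e-12))
  # independent reduction from the stored folds
  acc <- vapply(res$folds, function(f) f$test_metrics$accuracy, numeric(1))
  row <- s$table[s$table$set == "test" & s$table$metric == "accuracy", ]
  expect_equal(row$mean, mean(acc))
  expect_equal(row$min, min(acc))
  expect_equal(row$max, max(acc))
  vips <- sapply(res$folds, `[[`, "vip")
  expect_equal(s$mean_vip, rowMeans(vips))
  # single fold degenerates to mean = min = max
  one <- aggregate_folds(run_protocol(ds, protocol_config(
    P = 1, T_rep = 1, K = 4, max_lv = 4, seed = 6)))
  expect_equal(one$table$mean, one$table$min)
  expect_equal(one$table$mean, one$table$max)
  expect_error(aggregate_folds(list()), "no folds")
})

test_that("band report ranks planted bands first and handles flat profiles", {
  # plant effects only at the two headline bands so the recovery target
  # is unambiguous on the short test axis
  peaks <- neutral_peaks(default_peak_library())
  centers <- vapply(peaks, `[[`, numeric(1), "center")
  peaks[[which(centers == 638)]]$group_effect <- c(case = 0.8, ref = 1)
  peaks[[which(centers == 1051)]]$group_effect <- c(case = 1.2, ref = 1)
  cfg <- synthetic_config(classes = tiny_classes(8, 10),
                          axis = wavenumber_axis(517, 1913, 200),
                          peaks = peaks, seed = 11)
  ds <- preprocess_dataset(generate_cohort(cfg), tiny_preprocess())
  res <- run_protocol(ds, protocol_config(P = 2, T_rep = 2, K = 5,
                                          max_lv = 6, seed = 13))
  s <- aggregate_folds(res)
  rep_tab <- vip_band_report(s, default_peak_library())
  top2 <- rep_tab$band[rep_tab$rank <= 2]
  expect_setequal(top2, c(638, 1051))

  flat <- s
  flat$mean_vip <- rep(1, length(flat$mean_vip))
  ft <- vip_band_report(flat)
  expect_true(all(ft$mean_vip == 1))
  # window 0 is an exact nearest-grid lookup
  z <- vip_band_report(s, window_cm1 = 0)
  ax <- as.numeric(s$axis)
  j <- which.min(abs(ax - 638))
  expect_equal(z$mean_vip[z$band == 638], s$mean_vip[j])
})

test_that("class labels with no signal yield chance-level folds (small null run)", {
  ds <- preprocess_dataset(
    null_cohort(tiny_config(n1 = 8, n2 = 8, seed = 12)),
    tiny_preprocess())
  res <- run_protocol(ds, protocol_config(P = 3, T_rep = 3, K = 5,
                                          max_lv = 5, seed = 21))
  s <- aggregate_folds(res)
  acc <- s$table$mean[s$table$set == "test" & s$table$metric == "accuracy"]
  expect_gt(acc, 0.25)
  expect_lt(acc, 0.75)
})
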