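test_that("metrics match direct formula substitution and degenerate rules", {
  r <- compute_metrics(c(TP = 10, TN = 10, FP = 0, FN = 0))
  expect_equal(c(r$Sn, r$Sp, r$AC, r$MCC), c(100, 100, 100, 1))

  r0 <- compute_metrics(c(TP = 0, TN = 10, FP = 0, FN = 10))
  expect_equal(r0$Sn, 0)
  expect_equal(r0$MCC, 0)     # zero denominator factor -> 0

  r2 <- compute_metrics(c(TP = 5, TN = 8, FP = 2, FN = 1))
  expect_equal(r2$Sn, 100 * 5 / 6)
  expect_equal(r2$Sp, 100 * 8 / 10)
  expect_equal(r2$AC, 100 * 13 / 16)
  expect_equal(r2$MCC, (5 * 8 - 2 * 1) / sqrt(7 * 6 * 10 * 9))

  expect_error(compute_metrics(c(TP = 0, TN = 0, FP = 0, FN = 0)), "zero")
  expect_error(compute_metrics(c(TP = -1, TN = 1, FP = 0, FN = 0)),
               "non-negative")

  set.seed(99)
  for (i in 1:200) {
    q <- sample(0:40, 4, replace = TRUE)
    if (sum(q) == 0) q[1] <- 1
    r <- compute_metrics(c(TP = q[1], TN = q[2], FP = q[3], FN = q[4]))
    tp <- q[1]; tn <- q[2]; fp <- q[3]; fn <- q[4]
    if (tp + fn > 0) expect_equal(r$Sn, 100 * tp / (tp + fn))
    if (tn + fp > 0) expect_equal(r$Sp, 100 * tn / (tn + fp))
    expect_equal(r$AC, 100 * (tp + tn) / sum(q))
    expect_true(r$MCC >= -1 - 1e-12 && r$MCC <= 1 + 1e-12)
    expect_true(r$AC >= 0 && r$AC <= 100)
  }
})

fast_config <- function(seed = 1L) {
  pipeline_config(selector = selector_config(k = 2, B = 3, P = 2, delta = 0),
                  qbc = 2L, n_trees = 30L, seed = seed)
}

test_that("leave-one-protein-out pools every site exactly once", {
  synth <- generate_dataset(synthetic_spec(n_proteins = 3L, seed = 14L))
  ds <- encode_synthetic(synth)
  rep <- jackknife_lopo(ds, fast_config())
  counts <- rep$counts
  expect_equal(counts$TP + counts$TN + counts$FP + counts$FN, nrow(ds$meta))
  expect_equal(rep$protocol, "jackknife_LOPO")
})

test_that("jackknife on an easy planted task beats the majority baseline", {
  accs <- vapply(1:3, function(s) {
    synth <- generate_dataset(synthetic_spec(n_proteins = 8L, seed = 500 + s))
    ds <- encode_synthetic(synth)
    jackknife_lopo(ds, fast_config(seed = s))$AC
  }, numeric(1))
  base <- 100 * 0.65
  expect_gt(mean(accs), base)
})

test_that("k-fold folds group by protein, stratify, and are seed-stable", {
  synth <- generate_dataset(synthetic_spec(n_proteins = 4L, seed = 18L))
  ds <- encode_synthetic(synth)
  r1 <- kfold(ds, k = 2, seed = 5, config = fast_config())
  r2 <- kfold(ds, k = 2, seed = 5, config = fast_config())
  expect_equal(r1$counts, r2$counts)
  expect_error(kfold(ds, k = 9, seed = 1, config = fast_config()),
               "exceeds the number of proteins")
  expect_error(kfold(ds, k = 1, seed = 1, config = fast_config()), "k must be")

  # balanced construction: equal posts per protein deal out evenly
  meta <- data.frame(protein_id = rep(sprintf("q%d", 1:4), each = 4),
                     position = rep(seq(3, 12, 3), 4),
                     label = rep(c(1L, 0L, 0L, 0L), 4))
  feats <- matrix(rnorm(16 * 3), 16, 3,
                  dimnames = list(NULL, c("a", "b", "c")))
  dummy <- structure(list(features = feats, meta = meta), class = "ubi_dataset")
  ids <- unique(meta$protein_id)
  npos <- vapply(ids, function(p) sum(meta$label[meta$protein_id == p]),
                 numeric(1))
  set.seed(5)
  ord <- order(-npos, sample.int(4))
  fold <- integer(4); fold[ord] <- rep_len(1:2, 4)
  pos_per_fold <- vapply(1:2, function(u) sum(npos[fold == u]), numeric(1))
  expect_lte(abs(diff(pos_per_fold)), 1)
})

test_that("select-once selection warns about cross-fold leakage", {
  synth <- generate_dataset(synthetic_spec(n_proteins = 3L, seed = 23L))
  ds <- encode_synthetic(synth)
  cfg <- fast_config()
  cfg$select_once <- TRUE
  expect_warning(jackknife_lopo(ds, cfg), "leak")
})

test_that("independent test equals pooled confusion metrics and flags overlap", {
  synth <- generate_dataset(synthetic_spec(n_proteins = 8L, seed = 19L))
  ds <- encode_synthetic(synth)
  sp <- split_by_protein(ds, 0.25, seed = 2)
  dm <- discretize(sp$train, B = 3)
  subs <- generate_subsets(dm, selector_config(k = 3, P = 3, B = 3))
  model <- train_ensemble(sp$train, subsets = subs,
                          spec = ensemble_spec(n_trees = 50, seed = 9))
  rep <- independent_test(model, sp$test)
  pr <- predict(model, sp$test)
  manual <- compute_metrics(ubisite:::confusion_from_predictions(
    sp$test$meta$label, pr$labels), protocol = "independent")
  expect_equal(rep[c("Sn", "Sp", "AC", "MCC")],
               manual[c("Sn", "Sp", "AC", "MCC")])
  expect_warning(independent_test(model, sp$train), "shares")
  expect_error(independent_test(model, subset_dataset(sp$test, integer(0))),
               "empty")
})

test_that("feature provenance counts slots per family and per site", {
  reg <- feature_registry()
  pssm_ids <- reg$id[reg$family == "PSSM"][1:12]
  prov <- feature_provenance(list(pssm_ids), reg)
  expect_equal(prov$family$count[prov$family$family == "PSSM"], 12L)
  expect_equal(sum(prov$family$count), 12L)

  mixed <- list(c("AAC_comp_A", "DIS_s11", "PSSM_s01_A"),
                c("DIS_s11", "FAC_s02_f1"))
  prov2 <- feature_provenance(mixed, reg)
  expect_equal(sum(prov2$family$count), 5L)          # multiset over subsets
  expect_equal(sum(prov2$site$count), 4L)            # AAC carries no site
  expect_equal(prov2$site$count[prov2$site$site == 11], 2L)
  expect_error(feature_provenance(list(), reg), "nonempty")
  expect_error(feature_provenance(list("nope"), reg), "not in registry")
})
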