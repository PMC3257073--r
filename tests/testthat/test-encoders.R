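test_that("composition features: hand-counted example and normalization", {
  w <- make_window(paste0(strrep("A", 10), "K", strrep("A", 10)))
  aac <- encode_aac(w)
  expect_length(aac$values, 86L)
  expect_equal(unname(aac$values["AAC_comp_A"]), 20 / 21)
  expect_equal(unname(aac$values["AAC_comp_K"]), 1 / 21)
  expect_equal(sum(aac$values[1:20]), 1)
  expect_equal(sum(aac$values[21:86]), 1)   # dipeptide block normalized

  # unmerged intermediate representation: 20 + 11^2 = 141 entries
  raw <- encode_aac(w, merge_dipeptides = FALSE)
  expect_length(raw$values, 141L)
  expect_length(grep("^AAC_odp_", raw$names), 121L)
})

test_that("merged dipeptides: 66 unordered categories, X pairs skipped", {
  expect_length(grep("^AAC_dp_", feature_registry()$id), 66L)
  # (g,h) and (h,g) merge: a reversed window has identical merged counts
  w1 <- make_window("AKKAX")
  w2 <- make_window("XAKKA")
  a1 <- encode_aac(w1)$values
  a2 <- encode_aac(w2)$values
  expect_equal(unname(a1[grep("^AAC_dp_", names(a1))]),
               unname(a2[grep("^AAC_dp_", names(a2))]))
  # pairs touching X are not counted: AK|X|KA leaves 2 pairs, both A:K
  w3 <- make_window("AKXKA")
  dp3 <- encode_aac(w3)$values
  expect_equal(unname(dp3["AAC_dp_g01g08"]), 1)
})

test_that("composition is order-free but dipeptides are not", {
  w1 <- make_window("ADKLR", center = 3L)
  w2 <- make_window("DAKLR", center = 3L)  # two flanking residues swapped
  a1 <- encode_aac(w1)$values
  a2 <- encode_aac(w2)$values
  expect_equal(a1[1:20], a2[1:20])
  w3 <- make_window("ALKDR", center = 3L)  # swap across the center: D<->L
  a3 <- encode_aac(w3)$values
  expect_equal(a1[1:20], a3[1:20])
  expect_false(isTRUE(all.equal(a1[21:86], a3[21:86])))
})

test_that("PSSM encoding slices the normalized matrix with zero padding", {
  set.seed(2)
  raw <- matrix(sample(-5:7, 30 * 20, replace = TRUE), 30, 20)
  colnames(raw) <- amino_acids()
  pssm <- structure(list(protein_id = "p", raw = raw,
                         normalized = ubisite:::normalize_pssm(raw),
                         column_order = amino_acids()),
                    class = "ubi_pssm")
  win <- make_window("K", protein_id = "p", center = 15L, w = 1L)
  one <- encode_pssm(win, pssm, w = 1L)
  expect_equal(unname(one$values), unname(pssm$normalized[15, ]))

  win21 <- make_window(strrep("A", 21), protein_id = "p", center = 15L, w = 21L)
  v <- encode_pssm(win21, pssm)
  expect_length(v$values, 420L)
  # oracle: direct matrix indexing on interior sites
  expect_equal(unname(v$values),
               as.vector(t(pssm$normalized[5:25, ])))

  # center at position 1: the 10 upstream rows are zero blocks
  win_edge <- make_window(strrep("A", 21), protein_id = "p", center = 1L, w = 21L)
  ve <- encode_pssm(win_edge, pssm)
  expect_equal(unname(ve$values[1:200]), rep(0, 200))
  expect_error(encode_pssm(win21, NULL), "no PSSM")
})

test_that("factor encoding covers the 20 flanking sites and ignores the center", {
  w_all_x <- make_window(paste0(strrep("X", 10), "K", strrep("X", 10)))
  f <- encode_factors(w_all_x)
  expect_length(f$values, 100L)
  expect_true(all(f$values == 0))

  # windows differing only at the center give identical factor blocks
  w1 <- make_window(paste0(strrep("A", 10), "K", strrep("A", 10)))
  w2 <- make_window(paste0(strrep("A", 10), "R", strrep("A", 10)))
  expect_equal(encode_factors(w1)$values, encode_factors(w2)$values)

  # values come straight from the Atchley table
  expect_equal(unname(encode_factors(w1)$values[1:5]),
               unname(atchley_factors()["A", ]))
})

test_that("disorder encoding pads edges with zeros", {
  track <- structure(list(protein_id = "p", scores = rep(0.7, 50)),
                     class = "ubi_disorder")
  win <- make_window(strrep("A", 21), protein_id = "p", center = 25L, w = 21L)
  d <- encode_disorder(win, track)
  expect_equal(unname(d$values), rep(0.7, 21))

  win_edge <- make_window(strrep("A", 21), protein_id = "p", center = 1L, w = 21L)
  de <- encode_disorder(win_edge, track)
  expect_equal(unname(de$values[1:10]), rep(0, 10))
  expect_equal(unname(de$values[11:21]), rep(0.7, 11))
  expect_error(encode_disorder(win, NULL), "no disorder")
})

test_that("full encoding has 627 aligned coordinates; family masks shrink it", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 627L)
  expect_equal(as.vector(table(reg$family)[c("AAC", "PSSM", "FACTOR", "DISORDER")]),
               c(86L, 420L, 100L, 21L))

  cfg_no_pssm <- encoder_config(families = c("AAC", "FACTOR", "DISORDER"))
  expect_equal(nrow(feature_registry(cfg_no_pssm)), 207L)

  # dimension bookkeeping for general odd w: 86 + 20w + 5(w-1) + w
  for (w in c(3L, 5L, 11L, 21L)) {
    expect_equal(nrow(feature_registry(encoder_config(w = w))),
                 86L + 20L * w + 5L * (w - 1L) + w)
  }
})

test_that("single-window and bulk encoders agree", {
  synth <- generate_dataset(synthetic_spec(n_proteins = 3L, seed = 9L))
  ds <- encode_synthetic(synth)
  providers <- list(pssm = function(id) synth$pssms[[id]],
                    disorder = function(id) synth$disorder[[id]])
  for (r in c(1L, 5L, nrow(ds$meta))) {
    p <- synth$proteins[synth$proteins$id == ds$meta$protein_id[r], ]
    win <- extract_window(p, ds$meta$position[r], 21L)
    v <- encode_all(win, providers)
    expect_equal(unname(v), unname(ds$features[r, ]), tolerance = 1e-12)
  }
})

test_that("registry alignment survives any family-enable mask", {
  synth <- generate_dataset(synthetic_spec(n_proteins = 3L, seed = 9L))
  cfg <- encoder_config(families = c("AAC", "DISORDER"))
  ds <- encode_dataset(synth$proteins, synth$annotations,
                       disorder = synth$disorder, config = cfg)
  expect_equal(colnames(ds$features), feature_registry(cfg)$id)
  expect_equal(ncol(ds$features), 86L + 21L)
})
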