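test_that("read_fasta parses records, uppercases and enforces the alphabet", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">p1", "MKKA"), fa)
  prot <- read_fasta(fa)
  expect_equal(prot$id, "p1")
  expect_equal(prot$length, 4L)

  writeLines(c(">p1", "mk", ">p2", "KKK"), fa)
  prot <- read_fasta(fa)
  expect_equal(nrow(prot), 2L)
  expect_equal(prot$sequence[1], "MK")

  writeLines(c(">good", "MKA", ">bad", "MBKA"), fa)
  expect_warning(prot <- read_fasta(fa), "non-standard")
  expect_equal(prot$id, "good")

  empty <- tempfile(fileext = ".fasta")
  file.create(empty)
  expect_error(read_fasta(empty))
  expect_error(read_fasta(tempfile()), "cannot read")
})

test_that("read_annotations validates lysines, skips bad rows, last wins on duplicates", {
  prot <- proteins("p1", "MKKA")
  path <- tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tposition\tlabel",
               "p1\t2\tpositive"), path)
  ann <- read_annotations(path, prot)
  expect_equal(ann$position, 2L)
  expect_equal(ann$label, 1L)

  writeLines(c("protein_id\tposition\tlabel",
               "p1\t1\tpositive",            # residue M, not K
               "p1\t2\tpositive"), path)
  expect_warning(ann <- read_annotations(path, prot), "not on a lysine")
  expect_equal(ann$position, 2L)

  writeLines(c("protein_id\tposition\tlabel",
               "p1\t2\tpositive",
               "p1\t2\tnegative"), path)
  expect_warning(ann <- read_annotations(path, prot), "duplicate")
  expect_equal(ann$label, 0L)   # last one wins

  writeLines(c("protein_id\tposition\tlabel",
               "ghost\t2\tpositive",
               "p1\t2\tpositive"), path)
  expect_warning(ann <- read_annotations(path, prot), "unknown")
  expect_equal(nrow(ann), 1L)
})

test_that("derive_negative_sites covers exactly the unannotated lysines", {
  prot <- proteins("p1", "MKKA")
  pos <- data.frame(protein_id = "p1", position = 2L, label = 1L)
  neg <- derive_negative_sites(prot, pos)
  expect_equal(neg$position, 3L)

  expect_equal(nrow(derive_negative_sites(proteins("p2", "MAAA"),
                                          pos[0, ])), 0L)

  prot3 <- proteins(c("a", "b", "c"), c("KK", "KK", "KK"))
  pos3 <- data.frame(protein_id = c("a", "b", "c"),
                     position = c(1L, 2L, 1L), label = 1L)
  neg3 <- derive_negative_sites(prot3, pos3)
  expect_equal(nrow(neg3), 3L)

  # partition property: positives and negatives tile the lysines exactly
  all_sites <- rbind(pos3[, c("protein_id", "position")],
                     neg3[, c("protein_id", "position")])
  expect_false(anyDuplicated(paste(all_sites$protein_id, all_sites$position)) > 0)
  expect_equal(nrow(all_sites), 6L)
})

test_that("extract_window pads with X and validates the center", {
  p <- proteins("p1", "AAAAKAAAA")
  w <- extract_window(p, 5L, 9L)
  expect_equal(w$residues, "AAAAKAAAA")

  p2 <- proteins("p2", "KA")
  w2 <- extract_window(p2, 1L, 5L)
  expect_equal(w2$residues, "XXKAX")

  p3 <- proteins("p3", paste(rep("K", 30), collapse = ""))
  w3 <- extract_window(p3, 15L, 21L)
  expect_equal(nchar(w3$residues), 21L)
  expect_equal(substr(w3$residues, 11, 11), "K")

  expect_error(extract_window(p, 1L, 9L), "not a lysine")
  expect_error(extract_window(p, 5L, 10L), "odd")
})

test_that("window extraction is total on every lysine of every protein", {
  synth <- generate_dataset(synthetic_spec(n_proteins = 4L, seed = 5L))
  for (i in seq_len(nrow(synth$proteins))) {
    p <- synth$proteins[i, ]
    for (pos in ubisite:::lysine_positions(p$sequence)) {
      w <- extract_window(p, pos, 21L)
      expect_equal(nchar(w$residues), 21L)
      expect_equal(substr(w$residues, 11, 11), "K")
    }
  }
})

test_that("PSSM parsing, min-max normalization and its degenerate rule", {
  # a 3-residue matrix whose raw entries span {-3, 0, 7}
  raw <- matrix(0, 3, 20)
  raw[1, 1] <- -3; raw[2, 5] <- 7
  colnames(raw) <- amino_acids()
  pssm <- structure(list(protein_id = "p1", raw = raw,
                         normalized = ubisite:::normalize_pssm(raw),
                         column_order = amino_acids()),
                    class = "ubi_pssm")
  path <- tempfile(fileext = ".pssm")
  ubisite:::write_pssm_ascii(pssm, "MKA", path)
  parsed <- read_pssm(path, sequence = "MKA")
  expect_equal(parsed$raw, raw)
  expect_equal(min(parsed$normalized), 0)
  expect_equal(max(parsed$normalized), 1)
  expect_equal(unname(parsed$normalized[1, 1]), 0)
  expect_equal(unname(parsed$normalized[2, 5]), 1)
  expect_equal(unname(parsed$normalized[3, 3]), 0.3)   # (0 - -3) / (7 - -3)

  expect_error(read_pssm(path, sequence = "MKAA"), "rows")

  # normalization is idempotent on an already-normalized matrix
  renorm <- ubisite:::normalize_pssm(parsed$normalized)
  expect_equal(renorm, parsed$normalized)

  expect_warning(const <- ubisite:::normalize_pssm(matrix(2, 4, 20)),
                 "constant")
  expect_true(all(const == 0.5))
})

test_that("protein-level split is reproducible and partitions the windows", {
  synth <- generate_dataset(synthetic_spec(n_proteins = 10L, seed = 11L))
  ds <- encode_synthetic(synth)
  sp1 <- split_by_protein(ds, 0.2, seed = 3L)
  sp2 <- split_by_protein(ds, 0.2, seed = 3L)
  expect_identical(sp1$test$meta, sp2$test$meta)
  expect_equal(length(unique(sp1$test$meta$protein_id)), 2L)
  expect_length(intersect(unique(sp1$train$meta$protein_id),
                          unique(sp1$test$meta$protein_id)), 0L)
  expect_equal(nrow(sp1$train$meta) + nrow(sp1$test$meta), nrow(ds$meta))
  expect_error(split_by_protein(ds, 1.2, 1L), "test_fraction")
})
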