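# Self-contained synthetic benchmark: random protein sequences with
# lysines at known positions, a plantable flanking motif that makes a
# minority of lysines "ubiquitylated", surrogate PSSMs carrying a
# class-conditional log-odds shift at the motif sites, and disorder tracks
# with a bump around positive sites. Ground truth lists the registry
# features planted directly on the class so selector recovery can be
# scored.

#' Specification of a synthetic benchmark dataset
#'
#' The defaults emulate the structure of the curated ubiquitylation
#' training data: ~60 proteins of 200-320 residues with ~860 lysine sites,
#' about 35% of them positive (imbalance ~1:1.9), window size 21. The
#' effective PSSM shift and disorder bump scale with `motif_strength`, so
#' strength 0 yields an exact null dataset (class-independent features).
#'
#' @param n_proteins Number of proteins.
#' @param length_range Min/max protein length (residues).
#' @param lysine_density Per-residue probability of a lysine.
#' @param positive_fraction Fraction of lysines labeled positive.
#' @param motif data.frame with columns `offset` (site offset from the
#'   central lysine, in -10..10 excluding 0) and `residue` (preferred
#'   letter); flanks of positive sites are rewritten to the preferred
#'   residue with probability `motif_strength`.
#' @param motif_strength Motif rewrite probability in [0,1]; also scales
#'   the PSSM shift and disorder bump.
#' @param pssm_shift Log-odds added (times `motif_strength`) at the motif
#'   cells of positive-site PSSM rows.
#' @param pssm_noise SD of the Gaussian noise on raw PSSM scores.
#' @param disorder_bump Peak disorder increment (times `motif_strength`)
#'   added with triangular decay within +/-3 residues of positive sites.
#' @param seed RNG seed; all randomness flows from it.
#' @return Object of class `ubi_synth_spec`.
#' @export
synthetic_spec <- function(n_proteins = 60L, length_range = c(200L, 320L),
                           lysine_density = 0.055, positive_fraction = 0.35,
                           motif = default_motif(), motif_strength = 0.9,
                           pssm_shift = 8, pssm_noise = 1,
                           disorder_bump = 0.4, seed = 101L) {
  stopifnot(n_proteins >= 2L, length_range[1] >= 30L,
            length_range[2] >= length_range[1],
            lysine_density > 0, lysine_density < 1,
            positive_fraction > 0, positive_fraction < 1,
            motif_strength >= 0, motif_strength <= 1,
            all(motif$offset != 0L), all(abs(motif$offset) <= 10L),
            all(motif$residue %in% setdiff(amino_acids(), "K")))
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 lysine_density = lysine_density,
                 positive_fraction = positive_fraction,
                 motif = motif, motif_strength = motif_strength,
                 pssm_shift = pssm_shift, pssm_noise = pssm_noise,
                 disorder_bump = disorder_bump, seed = as.integer(seed)),
            class = "ubi_synth_spec")
}

#' Default planted motif: five flanking sites with one preferred residue each
#' @return data.frame with columns offset, residue.
#' @export
default_motif <- function() {
  data.frame(offset = c(-2L, -1L, 1L, 2L, 3L),
             residue = c("E", "L", "D", "F", "R"),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic benchmark dataset
#'
#' Sequences are drawn from a uniform background over the 20 amino acids
#' with lysines placed at `lysine_density`; a random subset of lysines
#' becomes positive. Flanks of positive sites are rewritten from the motif
#' preferences (lysine positions are never overwritten, so the site set is
#' stable). Surrogate PSSMs are background log-odds plus the
#' class-conditional shift at motif cells plus Gaussian noise, rounded to
#' integers and min-max normalized with the standard rule. Disorder tracks
#' are smoothed uniform noise plus a triangular bump around positive sites.
#'
#' Ground truth (`$truth$informative_ids`) lists the primary planted
#' features: the PSSM cell of each motif site's preferred residue and the
#' center-site disorder feature. Residue-mediated echoes of the same signal
#' (factor/composition features of rewritten flanks, off-center disorder
#' sites) are excluded as redundant copies.
#'
#' @param spec [synthetic_spec()].
#' @return Object of class `ubi_synth_data`: proteins, annotations, pssms,
#'   disorder, truth, spec.
#' @export
generate_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "ubi_synth_spec"))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(spec$seed)
  aa <- amino_acids()
  non_k <- setdiff(aa, "K")
  n <- spec$n_proteins
  lens <- sample(spec$length_range[1]:spec$length_range[2], n, replace = TRUE)
  seqs <- vector("list", n)
  kpos_list <- vector("list", n)
  for (i in seq_len(n)) {
    L <- lens[i]
    ch <- sample(non_k, L, replace = TRUE)
    is_k <- runif(L) < spec$lysine_density
    ch[is_k] <- "K"
    seqs[[i]] <- ch
    kpos_list[[i]] <- which(is_k)
  }
  total_k <- sum(lengths(kpos_list))
  if (total_k < 2L) stop("infeasible spec: almost no lysines generated")
  site_tab <- data.frame(
    protein = rep(seq_len(n), lengths(kpos_list)),
    position = unlist(kpos_list)
  )
  n_pos <- max(1L, round(spec$positive_fraction * total_k))
  pos_rows <- sample(nrow(site_tab), n_pos)
  site_tab$label <- 0L
  site_tab$label[pos_rows] <- 1L

  # rewrite flanks of positive sites (never overwriting a lysine)
  strength <- spec$motif_strength
  for (r in which(site_tab$label == 1L)) {
    i <- site_tab$protein[r]; c0 <- site_tab$position[r]
    for (m in seq_len(nrow(spec$motif))) {
      p <- c0 + spec$motif$offset[m]
      if (p < 1L || p > lens[i]) next
      if (seqs[[i]][p] == "K") next
      if (runif(1) < strength) seqs[[i]][p] <- spec$motif$residue[m]
    }
  }

  pids <- sprintf("synthP%03d", seq_len(n))
  prot <- proteins(pids, vapply(seqs, paste, character(1), collapse = ""))
  ann <- data.frame(protein_id = pids[site_tab$protein],
                    position = site_tab$position,
                    label = site_tab$label, stringsAsFactors = FALSE)
  ann <- structure(ann, class = c("ubi_annotations", "data.frame"))

  shift <- spec$pssm_shift * strength
  bump <- spec$disorder_bump * strength
  col_of <- match(spec$motif$residue, aa)
  pssms <- vector("list", n); names(pssms) <- pids
  tracks <- vector("list", n); names(tracks) <- pids
  for (i in seq_len(n)) {
    L <- lens[i]
    raw <- matrix(rnorm(L * 20L, 0, 2), L, 20L)
    pos_centers <- site_tab$position[site_tab$protein == i & site_tab$label == 1L]
    for (c0 in pos_centers) {
      for (m in seq_len(nrow(spec$motif))) {
        p <- c0 + spec$motif$offset[m]
        if (p >= 1L && p <= L) raw[p, col_of[m]] <- raw[p, col_of[m]] + shift
      }
    }
    raw <- round(raw + rnorm(L * 20L, 0, spec$pssm_noise))
    colnames(raw) <- aa
    pssms[[i]] <- structure(
      list(protein_id = pids[i], raw = raw,
           normalized = normalize_pssm(raw), column_order = aa),
      class = "ubi_pssm")

    base <- as.numeric(stats::filter(runif(L + 4L), rep(1 / 5, 5L),
                                     sides = 2L))[3:(L + 2L)]
    track <- 0.05 + 0.5 * base
    for (c0 in pos_centers) {
      for (d in -3:3) {
        p <- c0 + d
        if (p >= 1L && p <= L) {
          track[p] <- track[p] + bump * (1 - abs(d) / 4)^2
        }
      }
    }
    tracks[[i]] <- structure(
      list(protein_id = pids[i], scores = pmin(1, pmax(0, track))),
      class = "ubi_disorder")
  }

  truth <- list(
    informative_ids = c(
      sprintf("PSSM_s%02d_%s", 11L + spec$motif$offset, spec$motif$residue),
      "DIS_s11"
    ),
    positive_sites = ann[ann$label == 1L, c("protein_id", "position")]
  )
  structure(list(proteins = prot, annotations = ann, pssms = pssms,
                 disorder = tracks, truth = truth, spec = spec),
            class = "ubi_synth_data")
}

#' Encode a synthetic dataset into a feature matrix
#' @param synth `ubi_synth_data`.
#' @param config [encoder_config()].
#' @return `ubi_dataset`.
#' @export
encode_synthetic <- function(synth, config = encoder_config()) {
  encode_dataset(synth$proteins, synth$annotations, synth$pssms,
                 synth$disorder, config)
}

#' Permute labels within proteins: a null control
#'
#' Labels are permuted across sites within each protein; features are
#' untouched. Class counts are preserved, and any genuine feature-label
#' association is destroyed, giving a negative control for the whole
#' pipeline.
#'
#' @param dataset `ubi_dataset`.
#' @param seed RNG seed.
#' @return `ubi_dataset` with permuted labels.
#' @export
make_null_permutation <- function(dataset, seed) {
  stopifnot(inherits(dataset, "ubi_dataset"), nrow(dataset$meta) > 0L)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  out <- dataset
  for (pid in unique(out$meta$protein_id)) {
    rows <- which(out$meta$protein_id == pid)
    out$meta$label[rows] <- sample(out$meta$label[rows])
  }
  out
}

#' Write a synthetic dataset in the on-disk input formats
#'
#' Emits exactly what the readers consume: `sequences.fasta`,
#' `annotations.tsv`, one `<id>.pssm` per protein in PSI-BLAST ASCII
#' layout, one `<id>.disorder.tsv` per protein, and `ground_truth.tsv`.
#'
#' @param synth `ubi_synth_data`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(synth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- Biostrings::AAStringSet(synth$proteins$sequence)
  names(fa) <- synth$proteins$id
  Biostrings::writeXStringSet(fa, file.path(dir, "sequences.fasta"))
  ann <- synth$annotations
  ann$label <- ifelse(ann$label == 1L, "positive", "negative")
  utils::write.table(ann, file.path(dir, "annotations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (pid in synth$proteins$id) {
    write_pssm_ascii(synth$pssms[[pid]],
                     synth$proteins$sequence[synth$proteins$id == pid],
                     file.path(dir, paste0(pid, ".pssm")))
    tr <- synth$disorder[[pid]]
    utils::write.table(
      data.frame(position = seq_along(tr$scores),
                 score = sprintf("%.4f", tr$scores)),
      file.path(dir, paste0(pid, ".disorder.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(
    data.frame(feature_id = synth$truth$informative_ids),
    file.path(dir, "ground_truth.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

# PSI-BLAST-style ASCII dump readable by read_pssm(). Uses the classic
# PSI-BLAST column order and appends a dummy percentage block.
write_pssm_ascii <- function(pssm, sequence, path) {
  psiblast_order <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                      "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  raw <- pssm$raw[, psiblast_order, drop = FALSE]
  res <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("Last position-specific scoring matrix computed", ""), con)
  writeLines(paste0("            ",
                    paste(sprintf("%3s", psiblast_order), collapse = ""),
                    "   ",
                    paste(sprintf("%3s", psiblast_order), collapse = "")), con)
  for (i in seq_len(nrow(raw))) {
    writeLines(paste0(sprintf("%5d %s  ", i, res[i]),
                      paste(sprintf("%3d", raw[i, ]), collapse = ""),
                      "   ",
                      paste(sprintf("%3d", rep(0L, 20L)), collapse = ""),
                      sprintf("  %5.2f %5.2f", 0, 0)), con)
  }
  invisible(path)
}

#' Read a synthetic dataset back from disk
#' @param dir Directory written by [write_synthetic()].
#' @return List with proteins, annotations, pssms, disorder tracks and the
#'   ground-truth feature ids.
#' @export
read_synthetic <- function(dir) {
  prot <- read_fasta(file.path(dir, "sequences.fasta"))
  ann <- read_annotations(file.path(dir, "annotations.tsv"), prot)
  pssms <- lapply(seq_len(nrow(prot)), function(i) {
    read_pssm(file.path(dir, paste0(prot$id[i], ".pssm")),
              sequence = prot$sequence[i])
  })
  names(pssms) <- prot$id
  tracks <- lapply(seq_len(nrow(prot)), function(i) {
    read_disorder(file.path(dir, paste0(prot$id[i], ".disorder.tsv")),
                  protein_id = prot$id[i], length = prot$length[i])
  })
  names(tracks) <- prot$id
  gt_path <- file.path(dir, "ground_truth.tsv")
  truth <- if (file.exists(gt_path)) {
    list(informative_ids = utils::read.delim(gt_path,
                                             stringsAsFactors = FALSE)$feature_id)
  } else NULL
  list(proteins = prot, annotations = ann, pssms = pssms, disorder = tracks,
       truth = truth)
}
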