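# Feature encoders: grouped amino-acid composition, PSSM window slices,
# Atchley factors and disorder scores, plus the bulk dataset builder.
#
# Conventions shared by every encoder: padded positions hold 'X', which is
# inert — it contributes nothing to composition counts (denominators use
# non-'X' residues only), maps to the zero factor vector, to a zero PSSM
# row and to disorder score 0.

window_chars <- function(window) strsplit(window$residues, "", fixed = TRUE)[[1L]]

#' Grouped amino-acid composition of a window
#'
#' 20 single-residue composition features (count / number of non-'X'
#' residues) followed by 66 merged dipeptide features: residues are mapped
#' to the 11 physicochemical groups, the w-1 adjacent ordered group pairs
#' are counted (pairs touching 'X' are skipped), ordered pairs (g,h) and
#' (h,g) are merged into one unordered category and counts are normalized
#' by the number of counted pairs. The unmerged intermediate representation
#' (20 + 11^2 = 141 entries) is available with `merge_dipeptides = FALSE`.
#'
#' @param window `ubi_window`.
#' @param scheme [group_scheme()].
#' @param merge_dipeptides Merge ordered group pairs into the 66 unordered
#'   categories (default TRUE, giving 86 values).
#' @return List with `values` (named numeric) and `names`.
#' @export
encode_aac <- function(window, scheme = group_scheme(), merge_dipeptides = TRUE) {
  ch <- window_chars(window)
  if (!length(ch)) stop("empty window")
  aa <- amino_acids()
  n_real <- sum(ch != "X")
  comp <- if (n_real > 0) {
    vapply(aa, function(a) sum(ch == a), numeric(1)) / n_real
  } else {
    stats::setNames(numeric(20), aa)
  }
  names(comp) <- paste0("AAC_comp_", aa)
  gidx <- scheme_index(scheme)[ch]
  a <- gidx[-length(gidx)]
  b <- gidx[-1L]
  keep <- a > 0L & b > 0L
  a <- a[keep]; b <- b[keep]
  gnames <- names(scheme)
  if (merge_dipeptides) {
    lo <- pmin(a, b); hi <- pmax(a, b)
    pair <- which(upper.tri(diag(11), diag = TRUE), arr.ind = TRUE)
    pair <- pair[order(pair[, "row"], pair[, "col"]), , drop = FALSE]
    cat_id <- paste0("AAC_dp_", gnames[pair[, "row"]], gnames[pair[, "col"]])
    counts <- stats::setNames(numeric(66), cat_id)
    if (length(lo)) {
      obs <- table(paste0("AAC_dp_", gnames[lo], gnames[hi]))
      counts[names(obs)] <- as.numeric(obs)
      counts <- counts / length(lo)
    }
  } else {
    cat_id <- paste0("AAC_odp_", rep(gnames, each = 11L), rep(gnames, 11L))
    counts <- stats::setNames(numeric(121), cat_id)
    if (length(a)) {
      obs <- table(paste0("AAC_odp_", gnames[a], gnames[b]))
      counts[names(obs)] <- as.numeric(obs)
      counts <- counts / length(a)
    }
  }
  values <- c(comp, counts)
  list(values = values, names = names(values))
}

#' PSSM window features
#'
#' Concatenates the w normalized 20-dimensional PSSM rows covering the
#' window (site 1 first, amino-acid columns in alphabetical order within a
#' site). Rows falling outside the protein contribute 20 zeros. Length is
#' w * 20 (420 at the default w = 21).
#'
#' @param window `ubi_window`.
#' @param pssm `ubi_pssm` for the window's protein.
#' @param w Window size (defaults to the window's own).
#' @return List with `values` and `names`.
#' @export
encode_pssm <- function(window, pssm, w = window$w) {
  if (is.null(pssm)) stop("no PSSM available for protein ", window$protein_id)
  w <- as.integer(w)
  norm <- pssm$normalized
  L <- nrow(norm)
  if (window$center < 1L || window$center > L) stop("window center outside PSSM")
  half <- (w - 1L) %/% 2L
  rows <- window$center + seq.int(-half, half)
  block <- matrix(0, nrow = w, ncol = 20L)
  inside <- rows >= 1L & rows <= L
  block[inside, ] <- norm[rows[inside], , drop = FALSE]
  values <- as.vector(t(block))
  nm <- sprintf("PSSM_s%02d_%s", rep(seq_len(w), each = 20L),
                rep(amino_acids(), w))
  list(values = stats::setNames(values, nm), names = nm)
}

#' Atchley-factor features of the flanking sites
#'
#' For each of the w-1 non-center window sites, in window order, emits the
#' five factor values of that site's residue ('X' maps to zeros). The
#' invariant central lysine is excluded, giving 5 * (w-1) values (100 at
#' w = 21).
#'
#' @param window `ubi_window`.
#' @param table Factor table, see [atchley_factors()].
#' @return List with `values` and `names`.
#' @export
encode_factors <- function(window, table = atchley_factors()) {
  ch <- window_chars(window)
  w <- window$w
  center <- (w + 1L) %/% 2L
  sites <- setdiff(seq_len(w), center)
  if (!length(sites)) return(list(values = numeric(0), names = character(0)))
  vals <- table[ch[sites], , drop = FALSE]
  values <- as.vector(t(vals))
  nm <- sprintf("FAC_s%02d_f%d", rep(sites, each = 5L), rep(1:5, length(sites)))
  list(values = stats::setNames(values, nm), names = nm)
}

#' Disorder-score features of a window
#'
#' One score per window site in window order; padded sites score 0.
#'
#' @param window `ubi_window`.
#' @param track `ubi_disorder` covering the window's protein.
#' @return List with `values` and `names`.
#' @export
encode_disorder <- function(window, track) {
  if (is.null(track)) stop("no disorder track for protein ", window$protein_id)
  w <- window$w
  half <- (w - 1L) %/% 2L
  pos <- window$center + seq.int(-half, half)
  values <- numeric(w)
  inside <- pos >= 1L & pos <= length(track$scores)
  values[inside] <- track$scores[pos[inside]]
  nm <- sprintf("DIS_s%02d", seq_len(w))
  list(values = stats::setNames(values, nm), names = nm)
}

#' Encode one window into the full feature vector
#'
#' Concatenates the enabled families in the fixed order AAC, PSSM, FACTOR,
#' DISORDER, aligned to [feature_registry()]. At the defaults the result
#' has 627 coordinates.
#'
#' @param window `ubi_window`.
#' @param providers List with functions or objects supplying per-protein
#'   tracks: `pssm` (a `ubi_pssm`, or `function(protein_id)` returning one)
#'   and `disorder` (likewise). Only consulted for enabled families.
#' @param config [encoder_config()].
#' @return Named numeric vector aligned to the registry ids.
#' @export
encode_all <- function(window, providers = list(), config = encoder_config()) {
  stopifnot(inherits(window, "ubi_window"))
  if (window$w != config$w) stop("window size does not match encoder config")
  get_provider <- function(name) {
    p <- providers[[name]]
    if (is.function(p)) p(window$protein_id) else p
  }
  parts <- list()
  if ("AAC" %in% config$families) {
    parts$AAC <- encode_aac(window, config$scheme)$values
  }
  if ("PSSM" %in% config$families) {
    parts$PSSM <- encode_pssm(window, get_provider("pssm"), config$w)$values
  }
  if ("FACTOR" %in% config$families) {
    parts$FACTOR <- encode_factors(window)$values
  }
  if ("DISORDER" %in% config$families) {
    parts$DISORDER <- encode_disorder(window, get_provider("disorder"))$values
  }
  values <- unlist(unname(parts))
  reg <- feature_registry(config)
  stopifnot(identical(names(values), reg$id))
  values
}

#' Build an encoded dataset from proteins, annotations and tracks
#'
#' Extracts the w-residue window of every annotated site and encodes all
#' enabled feature families. PSSMs and disorder tracks are supplied as
#' named lists keyed by protein id; they are required only when the
#' corresponding family is enabled.
#'
#' @param proteins `ubi_proteins`.
#' @param annotations `ubi_annotations` (positives and negatives).
#' @param pssms Named list of `ubi_pssm`.
#' @param disorder Named list of `ubi_disorder`.
#' @param config [encoder_config()].
#' @return Object of class `ubi_dataset`: list with `features` (n x d
#'   numeric matrix, columns = registry ids), `meta` (data.frame
#'   protein_id, position, label), `registry`, `config`.
#' @export
encode_dataset <- function(proteins, annotations, pssms = NULL, disorder = NULL,
                           config = encoder_config()) {
  stopifnot(nrow(annotations) > 0L)
  reg <- feature_registry(config)
  w <- config$w
  half <- (w - 1L) %/% 2L
  need_pssm <- "PSSM" %in% config$families
  need_dis <- "DISORDER" %in% config$families
  blocks <- vector("list", nrow(proteins))
  metas <- vector("list", nrow(proteins))
  for (i in seq_len(nrow(proteins))) {
    pid <- proteins$id[i]
    ann <- annotations[annotations$protein_id == pid, , drop = FALSE]
    if (!nrow(ann)) next
    seqs <- proteins$sequence[i]
    L <- proteins$length[i]
    if (need_pssm && is.null(pssms[[pid]])) stop("missing PSSM for protein ", pid)
    if (need_dis && is.null(disorder[[pid]])) {
      stop("missing disorder track for protein ", pid)
    }
    padded <- paste0(strrep("X", half), seqs, strrep("X", half))
    res_mat <- t(vapply(ann$position, function(p) {
      strsplit(substr(padded, p, p + w - 1L), "", fixed = TRUE)[[1L]]
    }, character(w)))
    if (any(res_mat[, half + 1L] != "K")) stop("non-lysine center in ", pid)
    fam <- list()
    if ("AAC" %in% config$families) {
      fam$AAC <- encode_aac_matrix(res_mat, config$scheme)
    }
    if (need_pssm) {
      fam$PSSM <- encode_pssm_matrix(ann$position, pssms[[pid]]$normalized, w)
    }
    if ("FACTOR" %in% config$families) {
      fam$FACTOR <- encode_factor_matrix(res_mat)
    }
    if (need_dis) {
      fam$DISORDER <- encode_disorder_matrix(ann$position,
                                             disorder[[pid]]$scores, w)
    }
    blocks[[i]] <- do.call(cbind, unname(fam))
    metas[[i]] <- data.frame(protein_id = pid, position = ann$position,
                             label = ann$label, stringsAsFactors = FALSE)
  }
  keep <- !vapply(blocks, is.null, logical(1))
  features <- do.call(rbind, blocks[keep])
  meta <- do.call(rbind, metas[keep])
  rownames(meta) <- NULL
  colnames(features) <- reg$id
  structure(list(features = features, meta = meta, registry = reg,
                 config = config),
            class = "ubi_dataset")
}

# ---- vectorized per-protein family encoders (rows = windows) -------------

encode_aac_matrix <- function(res_mat, scheme) {
  n <- nrow(res_mat); w <- ncol(res_mat)
  aa <- amino_acids()
  n_real <- rowSums(res_mat != "X")
  comp <- matrix(0, n, 20L)
  for (j in seq_len(20L)) comp[, j] <- rowSums(res_mat == aa[j])
  comp <- comp / pmax(n_real, 1L)
  gidx <- matrix(scheme_index(scheme)[res_mat], n, w)
  counts <- matrix(0, n, 66L)
  npairs <- numeric(n)
  for (j in seq_len(w - 1L)) {
    a <- gidx[, j]; b <- gidx[, j + 1L]
    ok <- a > 0L & b > 0L
    if (!any(ok)) next
    lo <- pmin(a, b)[ok]; hi <- pmax(a, b)[ok]
    # registry order is row-major over the upper triangle: (1,1)..(1,11),(2,2)..
    cat <- (lo - 1L) * 12L - lo * (lo - 1L) / 2L + (hi - lo + 1L)
    ii <- cbind(which(ok), cat)
    counts[ii] <- counts[ii] + 1
    npairs[ok] <- npairs[ok] + 1
  }
  counts <- counts / pmax(npairs, 1)
  cbind(comp, counts)
}

encode_pssm_matrix <- function(centers, norm, w) {
  half <- (w - 1L) %/% 2L
  L <- nrow(norm)
  padded <- rbind(matrix(0, half, 20L), norm, matrix(0, half, 20L))
  out <- matrix(0, length(centers), w * 20L)
  for (i in seq_along(centers)) {
    block <- padded[centers[i] + seq_len(w) - 1L, , drop = FALSE]
    out[i, ] <- as.vector(t(block))
  }
  out
}

encode_factor_matrix <- function(res_mat) {
  w <- ncol(res_mat)
  center <- (w + 1L) %/% 2L
  sites <- setdiff(seq_len(w), center)
  if (!length(sites)) return(matrix(0, nrow(res_mat), 0L))
  tab <- atchley_factors()
  n <- nrow(res_mat)
  out <- matrix(0, n, 5L * length(sites))
  for (s in seq_along(sites)) {
    out[, (s - 1L) * 5L + 1:5] <- tab[res_mat[, sites[s]], , drop = FALSE]
  }
  out
}

encode_disorder_matrix <- function(centers, scores, w) {
  half <- (w - 1L) %/% 2L
  padded <- c(numeric(half), scores, numeric(half))
  t(vapply(centers, function(p) padded[p + seq_len(w) - 1L], numeric(w)))
}

#' Subset an encoded dataset by row
#' @param dataset `ubi_dataset`.
#' @param rows Logical or integer row selector.
#' @return `ubi_dataset` with the selected windows.
#' @export
subset_dataset <- function(dataset, rows) {
  out <- dataset
  out$features <- dataset$features[rows, , drop = FALSE]
  out$meta <- dataset$meta[rows, , drop = FALSE]
  rownames(out$meta) <- NULL
  out
}

#' Write an encoded dataset as TSV
#'
#' One row per window: protein_id, position, label, then one column per
#' registry feature id.
#'
#' @param dataset `ubi_dataset`.
#' @param path Output file.
#' @export
write_dataset_tsv <- function(dataset, path) {
  df <- cbind(dataset$meta, as.data.frame(dataset$features))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an encoded dataset written by [write_dataset_tsv()]
#' @param path TSV file.
#' @param config Encoder configuration the dataset was built with.
#' @return `ubi_dataset`.
#' @export
read_dataset_tsv <- function(path, config = encoder_config()) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  reg <- feature_registry(config)
  if (!all(reg$id %in% names(df))) stop("dataset columns do not match registry")
  structure(list(
    features = as.matrix(df[, reg$id, drop = FALSE]),
    meta = df[, c("protein_id", "position", "label")],
    registry = reg, config = config
  ), class = "ubi_dataset")
}
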