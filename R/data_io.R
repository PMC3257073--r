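# Readers for the input formats (FASTA, annotation TSV, PSI-BLAST ASCII
# PSSM, per-protein disorder TSV), window extraction and protein-level
# splitting. All user-facing coordinates are 1-based inclusive.

#' Read protein sequences from FASTA
#'
#' Sequences are upper-cased; records containing letters outside the 20
#' standard amino acids plus 'X' are skipped with a warning.
#'
#' @param path FASTA file.
#' @return `data.frame` (class `ubi_proteins`) with columns id, sequence,
#'   length; one row per accepted record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("no sequences in ", path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  ok <- !grepl(sprintf("[^%s]", paste(aa_alphabet(), collapse = "")), seqs)
  if (any(!ok)) {
    warning("skipping ", sum(!ok), " record(s) with non-standard letters: ",
            paste(ids[!ok], collapse = ", "))
  }
  if (!any(ok)) stop("no valid sequences in ", path)
  if (anyDuplicated(ids[ok])) stop("duplicate sequence ids in ", path)
  proteins(ids[ok], seqs[ok])
}

#' Construct a protein table from ids and sequences
#' @param id Character vector of protein ids.
#' @param sequence Character vector of sequences (20 amino acids plus 'X').
#' @return `ubi_proteins` data.frame.
#' @export
proteins <- function(id, sequence) {
  stopifnot(length(id) == length(sequence), !anyDuplicated(id))
  sequence <- toupper(sequence)
  bad <- grepl(sprintf("[^%s]", paste(aa_alphabet(), collapse = "")), sequence)
  if (any(bad)) stop("invalid residue letters in: ", paste(id[bad], collapse = ", "))
  if (any(nchar(sequence) < 1L)) stop("empty sequence")
  structure(
    data.frame(id = as.character(id), sequence = sequence,
               length = nchar(sequence), stringsAsFactors = FALSE),
    class = c("ubi_proteins", "data.frame")
  )
}

#' Read a site-annotation table
#'
#' Tab-separated with columns protein_id, position (1-based), label
#' ("positive"/"negative"; 1/0 accepted). Rows referring to unknown
#' proteins, to out-of-range positions, or to residues that are not lysine
#' are rejected with a warning. Duplicate (protein, position) rows: the last
#' one wins, with a warning.
#'
#' @param path TSV file with a header.
#' @param proteins `ubi_proteins` table used for validation.
#' @return `data.frame` (class `ubi_annotations`) with columns protein_id,
#'   position, label (integer 0/1).
#' @export
read_annotations <- function(path, proteins) {
  if (!file.exists(path)) stop("cannot read annotation file: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "position", "label")
  if (!all(need %in% names(tab))) {
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  }
  lab <- tolower(as.character(tab$label))
  lab_int <- ifelse(lab %in% c("positive", "1", "pos", "true"), 1L,
                    ifelse(lab %in% c("negative", "0", "neg", "false"), 0L,
                           NA_integer_))
  pos <- suppressWarnings(as.integer(tab$position))
  ann <- data.frame(protein_id = as.character(tab$protein_id),
                    position = pos, label = lab_int,
                    stringsAsFactors = FALSE)
  malformed <- is.na(ann$position) | is.na(ann$label)
  if (any(malformed)) {
    warning("skipping ", sum(malformed), " malformed annotation row(s)")
    ann <- ann[!malformed, , drop = FALSE]
  }
  validate_annotations(ann, proteins)
}

validate_annotations <- function(ann, proteins) {
  known <- ann$protein_id %in% proteins$id
  if (any(!known)) {
    warning("skipping ", sum(!known), " annotation(s) for unknown proteins: ",
            paste(unique(ann$protein_id[!known]), collapse = ", "))
    ann <- ann[known, , drop = FALSE]
  }
  idx <- match(ann$protein_id, proteins$id)
  in_range <- ann$position >= 1L & ann$position <= proteins$length[idx]
  res <- rep(NA_character_, nrow(ann))
  res[in_range] <- substr(proteins$sequence[idx[in_range]],
                          ann$position[in_range], ann$position[in_range])
  is_k <- !is.na(res) & res == "K"
  if (any(!is_k)) {
    bad <- ann[!is_k, , drop = FALSE]
    warning("rejecting ", nrow(bad), " annotation(s) not on a lysine: ",
            paste(sprintf("%s:%d", bad$protein_id, bad$position), collapse = ", "))
    ann <- ann[is_k, , drop = FALSE]
  }
  key <- paste(ann$protein_id, ann$position)
  if (anyDuplicated(key)) {
    warning("duplicate annotations for ",
            paste(unique(key[duplicated(key)]), collapse = ", "),
            "; keeping the last occurrence")
    ann <- ann[!duplicated(key, fromLast = TRUE), , drop = FALSE]
  }
  rownames(ann) <- NULL
  structure(ann, class = c("ubi_annotations", "data.frame"))
}

#' Derive negative sites from unannotated lysines
#'
#' Every lysine of every protein that is not listed as a positive site
#' becomes a negative annotation, following the convention that
#' unannotated lysines are treated as non-ubiquitylation sites.
#'
#' @param proteins `ubi_proteins` table.
#' @param positives Annotations of the positive sites (`ubi_annotations` or
#'   data.frame with protein_id, position).
#' @return `ubi_annotations` of the negatives.
#' @export
derive_negative_sites <- function(proteins, positives) {
  out <- lapply(seq_len(nrow(proteins)), function(i) {
    kpos <- lysine_positions(proteins$sequence[i])
    pk <- positives$position[positives$protein_id == proteins$id[i]]
    neg <- setdiff(kpos, pk)
    if (!length(neg)) return(NULL)
    data.frame(protein_id = proteins$id[i], position = neg, label = 0L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(protein_id = character(), position = integer(),
                      label = integer(), stringsAsFactors = FALSE)
  }
  structure(out, class = c("ubi_annotations", "data.frame"))
}

lysine_positions <- function(sequence) {
  m <- gregexpr("K", sequence, fixed = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m)
}

#' Extract a lysine-centered peptide window
#'
#' Positions overhanging the sequence ends are padded with 'X'. The center
#' residue must be a lysine.
#'
#' @param protein One-row `ubi_proteins` slice or list with `id`, `sequence`.
#' @param position 1-based lysine position.
#' @param w Odd window size (default 21: 10 up + site + 10 down).
#' @return List of class `ubi_window`: protein_id, center, w, residues,
#'   site_index (= (w+1)/2), label (NA here).
#' @export
extract_window <- function(protein, position, w = 21L) {
  w <- as.integer(w)
  if (w < 1L || w %% 2L == 0L) stop("window size w must be odd")
  seqs <- protein$sequence
  stopifnot(length(seqs) == 1L)
  L <- nchar(seqs)
  position <- as.integer(position)
  if (position < 1L || position > L) stop("position out of range")
  if (substr(seqs, position, position) != "K") {
    stop("window center at ", protein$id, ":", position, " is not a lysine")
  }
  half <- (w - 1L) %/% 2L
  padded <- paste0(strrep("X", half), seqs, strrep("X", half))
  residues <- substr(padded, position, position + w - 1L)
  structure(list(protein_id = protein$id, center = position, w = w,
                 residues = residues, site_index = half + 1L,
                 label = NA_integer_),
            class = "ubi_window")
}

# Normalize a raw PSSM over the whole per-protein matrix:
# (value - min) / (max - min); a constant matrix maps to all 0.5.
normalize_pssm <- function(raw) {
  rng <- range(raw)
  if (rng[1] == rng[2]) {
    warning("constant PSSM matrix; normalized values set to 0.5")
    return(matrix(0.5, nrow(raw), ncol(raw), dimnames = dimnames(raw)))
  }
  (raw - rng[1]) / (rng[2] - rng[1])
}

#' Read a PSI-BLAST ASCII position-specific scoring matrix
#'
#' Parses the standard PSI-BLAST ASCII dump (header line with the 20-letter
#' column order, one row per residue whose first 20 numeric columns are the
#' log-odds scores; the trailing percentage block is ignored). Scores are
#' min-max normalized to [0,1] over the whole matrix and columns are
#' reordered to the alphabetical amino-acid order.
#'
#' @param path `.pssm` file; the protein id is the file name without
#'   extension unless `protein_id` is given.
#' @param sequence Optional protein sequence to cross-check the row count.
#' @param protein_id Optional explicit id.
#' @return List of class `ubi_pssm`: protein_id, raw (L x 20 integer matrix,
#'   alphabetical columns), normalized (same shape, in [0,1]), column_order
#'   (letters as found in the file).
#' @export
read_pssm <- function(path, sequence = NULL, protein_id = NULL) {
  if (!file.exists(path)) stop("cannot read PSSM file: ", path)
  lines <- readLines(path, warn = FALSE)
  header_i <- which(vapply(lines, function(l) {
    toks <- strsplit(trimws(l), "\\s+")[[1L]]
    length(toks) >= 20L && all(toks[1:20] %in% amino_acids())
  }, logical(1L)))[1L]
  if (is.na(header_i)) stop("no PSSM header line (20 amino-acid columns) in ", path)
  col_order <- strsplit(trimws(lines[header_i]), "\\s+")[[1L]][1:20]
  data_lines <- lines[-seq_len(header_i)]
  data_lines <- data_lines[grepl("^\\s*\\d+\\s+[A-Z]", data_lines)]
  if (!length(data_lines)) stop("no PSSM rows in ", path)
  rows <- lapply(data_lines, function(l) {
    toks <- strsplit(trimws(l), "\\s+")[[1L]]
    vals <- suppressWarnings(as.numeric(toks[3:22]))
    if (anyNA(vals)) stop("malformed PSSM row in ", path, ": ", l)
    list(res = toks[2L], vals = vals)
  })
  raw <- do.call(rbind, lapply(rows, `[[`, "vals"))
  colnames(raw) <- col_order
  raw <- raw[, amino_acids(), drop = FALSE]
  if (!is.null(sequence) && nrow(raw) != nchar(sequence)) {
    stop("PSSM has ", nrow(raw), " rows but sequence has ", nchar(sequence),
         " residues (", path, ")")
  }
  if (is.null(protein_id)) {
    protein_id <- tools::file_path_sans_ext(basename(path))
  }
  structure(list(protein_id = protein_id, raw = raw,
                 normalized = normalize_pssm(raw), column_order = col_order),
            class = "ubi_pssm")
}

#' Read a per-protein disorder track
#'
#' Tab-separated file with columns position, score; scores are clamped to
#' [0,1].
#'
#' @param path TSV file.
#' @param protein_id Optional id (default: file name without extension).
#' @param length Optional expected protein length for validation.
#' @return List of class `ubi_disorder`: protein_id, scores.
#' @export
read_disorder <- function(path, protein_id = NULL, length = NULL) {
  if (!file.exists(path)) stop("cannot read disorder file: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("position", "score") %in% names(tab))) {
    stop("disorder table must have columns position, score")
  }
  tab <- tab[order(tab$position), , drop = FALSE]
  if (!identical(as.integer(tab$position), seq_len(nrow(tab)))) {
    stop("disorder positions must be 1..L without gaps (", path, ")")
  }
  if (!is.null(length) && nrow(tab) != length) {
    stop("disorder track length ", nrow(tab), " != protein length ", length)
  }
  if (is.null(protein_id)) {
    protein_id <- sub("\\.disorder$", "",
                      tools::file_path_sans_ext(basename(path)))
  }
  structure(list(protein_id = protein_id,
                 scores = pmin(1, pmax(0, as.numeric(tab$score)))),
            class = "ubi_disorder")
}

#' Split an encoded dataset at the protein level
#'
#' All windows of one protein fall on the same side; reproducible for a
#' fixed seed.
#'
#' @param dataset `ubi_dataset` (see [encode_dataset()]).
#' @param test_fraction Fraction of proteins assigned to the test side.
#' @param seed Integer RNG seed.
#' @return List with elements `train` and `test`, both `ubi_dataset`.
#' @export
split_by_protein <- function(dataset, test_fraction, seed) {
  stopifnot(inherits(dataset, "ubi_dataset"))
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must be in (0, 1)")
  }
  ids <- unique(dataset$meta$protein_id)
  if (length(ids) < 2L) stop("need at least 2 proteins to split")
  n_test <- max(1L, round(test_fraction * length(ids)))
  if (n_test >= length(ids)) n_test <- length(ids) - 1L
  test_ids <- local({
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(seed)
    sample(ids, n_test)
  })
  list(train = subset_dataset(dataset, !dataset$meta$protein_id %in% test_ids),
       test  = subset_dataset(dataset, dataset$meta$protein_id %in% test_ids))
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
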