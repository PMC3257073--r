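# Amino-acid alphabet, the 11-group reduction, the Atchley factor table and
# the feature registry shared by every encoder.

#' The 20 standard amino acids, alphabetical one-letter codes
#' @return Character vector of length 20.
#' @export
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# 'X' is the padding/unknown letter; inert in every encoder.
aa_alphabet <- function() c(amino_acids(), "X")

#' Default 11-group physicochemical clustering of the amino acids
#'
#' Groups by shared physicochemical/structural character: the four special
#' residues A, G, P, C on their own, hydroxyl (S,T), amide (N,Q), acidic
#' (D,E), basic (K,R), H alone, aliphatic hydrophobic (I,L,M,V) and aromatic
#' (F,W,Y). Any alternative scheme with 11 disjoint exhaustive groups can be
#' passed wherever a `scheme` argument is accepted.
#'
#' @param groups Optional list of character vectors replacing the default.
#' @return Object of class `ubi_scheme`: a named list of 11 character vectors.
#' @export
group_scheme <- function(groups = NULL) {
  if (is.null(groups)) {
    groups <- list(
      g01 = "A", g02 = "G", g03 = "P", g04 = "C",
      g05 = c("S", "T"), g06 = c("N", "Q"), g07 = c("D", "E"),
      g08 = c("K", "R"), g09 = "H", g10 = c("I", "L", "M", "V"),
      g11 = c("F", "W", "Y")
    )
  }
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- sprintf("g%02d", seq_along(groups))
  }
  all_aa <- sort(unlist(groups, use.names = FALSE))
  if (length(groups) != 11L) {
    stop("a group scheme must have exactly 11 groups, got ", length(groups))
  }
  if (!identical(all_aa, amino_acids())) {
    stop("group scheme must partition the 20 amino acids (disjoint, exhaustive)")
  }
  structure(groups, class = "ubi_scheme")
}

# residue letter -> group index (1..11), X and unknown -> 0L
scheme_index <- function(scheme) {
  idx <- integer(length(aa_alphabet()))
  names(idx) <- aa_alphabet()
  for (g in seq_along(scheme)) idx[scheme[[g]]] <- g
  idx
}

#' Atchley amino-acid factor table
#'
#' The five multivariate numeric indices per residue summarizing
#' electrostatic charge (f1), codon diversity (f2), molecular volume (f3),
#' secondary-structure propensity (f4) and polarity (f5), bundled as a
#' plain-text table. 'X' maps to the zero vector.
#'
#' @return 21 x 5 numeric matrix, rownames = amino acids plus "X".
#' @export
atchley_factors <- function() {
  cache <- get0(".atchley_cache", envir = .ubi_cache)
  if (!is.null(cache)) return(cache)
  path <- system.file("extdata", "atchley_factors.tsv", package = "ubisite",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, c("f1", "f2", "f3", "f4", "f5")])
  rownames(m) <- tab$aa
  m <- m[amino_acids(), , drop = FALSE]
  m <- rbind(m, X = rep(0, 5))
  assign(".atchley_cache", m, envir = .ubi_cache)
  m
}

.ubi_cache <- new.env(parent = emptyenv())

#' Encoder configuration
#'
#' @param w Odd window size (number of residues in a lysine-centered window).
#' @param scheme 11-group amino-acid clustering, see [group_scheme()].
#' @param families Feature families to encode, a subset of
#'   `c("AAC","PSSM","FACTOR","DISORDER")`, kept in this canonical order.
#' @return Object of class `ubi_encoder_config`.
#' @export
encoder_config <- function(w = 21L, scheme = group_scheme(),
                           families = c("AAC", "PSSM", "FACTOR", "DISORDER")) {
  w <- as.integer(w)
  if (w < 1L || w %% 2L == 0L) stop("window size w must be a positive odd integer")
  families <- match.arg(families, several.ok = TRUE)
  families <- intersect(c("AAC", "PSSM", "FACTOR", "DISORDER"), families)
  structure(list(w = w, scheme = scheme, families = families),
            class = "ubi_encoder_config")
}

#' Feature registry: names, families and window sites of every coordinate
#'
#' Builds the ordered feature descriptor table for a configuration. At the
#' defaults (w = 21, all four families) the registry has 627 rows: 86
#' composition features (20 single-residue + 66 merged group dipeptides),
#' 20*21 = 420 PSSM features, 5*20 = 100 factor features for the 20
#' non-center sites, and 21 disorder features. `site` is the 1-based window
#' site (center = (w+1)/2); composition features carry no site (NA).
#'
#' @param config An [encoder_config()].
#' @return `data.frame` with columns id, family, site, detail;
#'   class `ubi_registry`.
#' @export
feature_registry <- function(config = encoder_config()) {
  w <- config$w
  aa <- amino_acids()
  gnames <- names(config$scheme)
  rows <- list()
  if ("AAC" %in% config$families) {
    comp <- data.frame(id = paste0("AAC_comp_", aa), family = "AAC",
                       site = NA_integer_, detail = aa,
                       stringsAsFactors = FALSE)
    pair <- which(upper.tri(diag(11), diag = TRUE), arr.ind = TRUE)
    pair <- pair[order(pair[, "row"], pair[, "col"]), , drop = FALSE]
    dp <- data.frame(
      id = paste0("AAC_dp_", gnames[pair[, "row"]], gnames[pair[, "col"]]),
      family = "AAC", site = NA_integer_,
      detail = paste0(gnames[pair[, "row"]], ":", gnames[pair[, "col"]]),
      stringsAsFactors = FALSE
    )
    rows <- c(rows, list(comp, dp))
  }
  if ("PSSM" %in% config$families) {
    rows <- c(rows, list(data.frame(
      id = sprintf("PSSM_s%02d_%s", rep(seq_len(w), each = 20L), rep(aa, w)),
      family = "PSSM", site = rep(seq_len(w), each = 20L), detail = rep(aa, w),
      stringsAsFactors = FALSE
    )))
  }
  if ("FACTOR" %in% config$families) {
    sites <- setdiff(seq_len(w), (w + 1L) %/% 2L)
    if (length(sites)) {
      rows <- c(rows, list(data.frame(
        id = sprintf("FAC_s%02d_f%d", rep(sites, each = 5L), rep(1:5, length(sites))),
        family = "FACTOR", site = rep(sites, each = 5L),
        detail = sprintf("f%d", rep(1:5, length(sites))),
        stringsAsFactors = FALSE
      )))
    }
  }
  if ("DISORDER" %in% config$families) {
    rows <- c(rows, list(data.frame(
      id = sprintf("DIS_s%02d", seq_len(w)), family = "DISORDER",
      site = seq_len(w), detail = "disorder", stringsAsFactors = FALSE
    )))
  }
  reg <- do.call(rbind, rows)
  rownames(reg) <- NULL
  stopifnot(!anyDuplicated(reg$id))
  class(reg) <- c("ubi_registry", "data.frame")
  reg
}

# FNV-1a 32-bit hash over the ordered feature ids; used to detect
# registry/model mismatches. 32-bit arithmetic is kept exact in doubles by
# splitting the multiplication into 16-bit halves.
registry_fingerprint <- function(ids) {
  if (inherits(ids, "ubi_registry")) ids <- ids$id
  bytes <- utf8ToInt(paste(ids, collapse = "\x1f"))
  h <- 2166136261
  for (b in bytes) {
    h <- xor32(h, b)
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("fnv1a:%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

xor32 <- function(a, b) {
  # bitwXor on doubles representing uint32
  hi_a <- a %/% 65536; lo_a <- a %% 65536
  hi_b <- b %/% 65536; lo_b <- b %% 65536
  bitwXor(as.integer(hi_a), as.integer(hi_b)) * 65536 +
    bitwXor(as.integer(lo_a), as.integer(lo_b))
}
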