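# Greedy forward feature selection on normalized conditional mutual
# information (FSNCMI), run from multiple starting points of the marginal
# MI ranking, plus the mRMR baseline.
#
# Selection criterion for a candidate f against the selected set FS and
# class C:  J'(f) = min over fs in FS of I(f;C|fs) / H(f,C).
# The min replaces conditioning on the full FS (high-dimensional joint
# estimates are unreliable); the H(f,C) normalization removes the bias of
# plain CMI toward features with many distinct values.

#' Selector configuration
#'
#' @param k Maximum subset size (default 12, the size at which successive
#'   criterion values flatten on the original ubiquitylation data).
#' @param delta Stopping threshold: selection stops when the criterion of
#'   the next greedy pick differs from the previous accepted value by less
#'   than `delta` (default 0.015).
#' @param B Number of equal-frequency bins for discretization (default 5).
#' @param P Number of subsets / starting points (default 10).
#' @param epsilon Zero tolerance for the J(f)=0 pruning rule (default 1e-12).
#' @return Object of class `ubi_selector_config`.
#' @export
selector_config <- function(k = 12L, delta = 0.015, B = 5L, P = 10L,
                            epsilon = 1e-12) {
  stopifnot(k >= 1L, delta >= 0, B >= 2L, P >= 1L, epsilon >= 0)
  structure(list(k = as.integer(k), delta = delta, B = as.integer(B),
                 P = as.integer(P), epsilon = epsilon),
            class = "ubi_selector_config")
}

#' Normalized conditional mutual information criterion
#'
#' J'(f) = min over fs in FS of I(f;C|fs) / H(f,C); returns 0 when
#' H(f,C) = 0 (a constant feature and constant class carry no information).
#'
#' @param f Candidate feature codes (non-negative integers).
#' @param FS Selected features: a list of code vectors, or a matrix with
#'   one column per selected feature.
#' @param C Class codes aligned to `f`.
#' @return The criterion value (dimensionless, >= 0 up to tolerance).
#' @export
criterion_J <- function(f, FS, C) {
  if (is.matrix(FS)) FS <- lapply(seq_len(ncol(FS)), function(j) FS[, j])
  if (!length(FS)) stop("FS must be nonempty; seed the subset first")
  hfc <- joint_entropy(f, C)
  if (hfc == 0) return(0)
  min(vapply(FS, function(fs) conditional_mutual_information(f, C, fs),
             numeric(1))) / hfc
}

# internal fast path: conditional MI of every feature in `cand` (columns of
# codes) with class cc given a fixed conditioning feature zc.
cmi_with_class_given <- function(codes, cand, cc, zc, B) {
  nz <- max(zc) + 1L
  nc <- max(cc) + 1L
  hz <- ent_from_counts(tabulate(zc + 1L, nz))
  hcz <- ent_from_counts(tabulate(cc * nz + zc + 1L, nc * nz))
  cz <- (cc * nz + zc)   # combined (class, z) code, < nc*nz
  vapply(cand, function(j) {
    fc <- codes[, j]
    nf <- max(fc) + 1L
    hfz <- ent_from_counts(tabulate(fc * nz + zc + 1L, nf * nz))
    hfcz <- ent_from_counts(tabulate(fc * (nc * nz) + cz + 1L, nf * nc * nz))
    hfz + hcz - hz - hfcz
  }, numeric(1))
}

mi_with <- function(codes, cols, y) {
  ny <- max(y) + 1L
  hy <- ent_from_counts(tabulate(y + 1L, ny))
  vapply(cols, function(j) {
    x <- codes[, j]
    nx <- max(x) + 1L
    hx <- ent_from_counts(tabulate(x + 1L, nx))
    hxy <- ent_from_counts(tabulate(x * ny + y + 1L, nx * ny))
    hx + hy - hxy
  }, numeric(1))
}

# MI ranking shared by all starting points; ties broken by smaller index.
mi_ranking <- function(dm) {
  mi <- mi_with(dm$codes, seq_len(ncol(dm$codes)), dm$class)
  list(mi = mi, order = order(-mi, seq_along(mi)))
}

#' FSNCMI feature selection from one starting point
#'
#' Features are ranked by mutual information with the class (descending,
#' ties to the smaller registry index). The subset is seeded with the
#' feature of rank `t` (0-based). Then, iteratively: candidates whose
#' criterion is <= epsilon are pruned permanently (they duplicate
#' already-selected information); the candidate with the largest J' is
#' appended. Selection stops when k features are selected, when the
#' criterion of the next pick differs from the previous accepted value by
#' less than delta (that pick is rejected), or when the candidate pool is
#' exhausted.
#'
#' The trajectory records the seed's normalized marginal MI, I(f;C)/H(f,C),
#' followed by the J' value of each greedy pick; the delta rule is applied
#' between successive greedy picks only (the seed value is not an Eq-J'
#' quantity, so the first greedy pick is always accepted).
#'
#' @param dm `ubi_discretized` (see [discretize()]).
#' @param t 0-based starting rank in the MI ordering.
#' @param config [selector_config()].
#' @param ranking Optional precomputed [mi_ranking] (internal reuse).
#' @return Object of class `ubi_subset`: list with `ids`, `idx`, `t`,
#'   `trajectory`, `stop_reason` in {"k_reached","threshold","exhausted"}.
#' @export
fsncmi_select <- function(dm, t = 0L, config = selector_config(),
                          ranking = NULL) {
  stopifnot(inherits(dm, "ubi_discretized"))
  d <- ncol(dm$codes)
  t <- as.integer(t)
  if (t < 0L || t >= d) stop("starting rank t out of range [0, ", d - 1L, "]")
  if (is.null(ranking)) ranking <- mi_ranking(dm)
  cc <- dm$class
  seed <- ranking$order[t + 1L]
  hfc <- vapply(seq_len(d), function(j) joint_entropy(dm$codes[, j], cc),
                numeric(1))
  fs <- seed
  traj <- if (hfc[seed] > 0) ranking$mi[seed] / hfc[seed] else 0
  cand <- setdiff(seq_len(d), seed)
  # running J'(f) = min over selected fs of I(f;C|fs)/H(f,C)
  jp <- cmi_with_class_given(dm$codes, cand, cc, dm$codes[, seed], dm$B)
  jp <- ifelse(hfc[cand] > 0, jp / hfc[cand], 0)
  reason <- NULL
  n_greedy <- 0L
  while (is.null(reason)) {
    if (length(fs) >= config$k) { reason <- "k_reached"; break }
    keep <- jp > config$epsilon
    cand <- cand[keep]; jp <- jp[keep]
    if (!length(cand)) { reason <- "exhausted"; break }
    best <- which.max(jp)          # ties: which.max takes the first, and
    best_idx <- cand[best]         # cand is in ascending registry order
    if (n_greedy >= 1L && abs(traj[length(traj)] - jp[best]) < config$delta) {
      reason <- "threshold"; break
    }
    fs <- c(fs, best_idx)
    traj <- c(traj, jp[best])
    n_greedy <- n_greedy + 1L
    cand <- cand[-best]; jp <- jp[-best]
    if (length(cand)) {
      upd <- cmi_with_class_given(dm$codes, cand, cc, dm$codes[, best_idx], dm$B)
      upd <- ifelse(hfc[cand] > 0, upd / hfc[cand], 0)
      jp <- pmin(jp, upd)
    }
  }
  new_subset(dm, fs, t, traj, reason)
}

new_subset <- function(dm, idx, t, traj, reason) {
  ids <- if (!is.null(dm$ids)) dm$ids[idx] else as.character(idx)
  structure(list(ids = ids, idx = idx, t = t, trajectory = traj,
                 stop_reason = reason),
            class = "ubi_subset")
}

#' Generate multiple feature subsets from consecutive starting points
#'
#' Subset p (p = 0..P-1) is produced by [fsncmi_select()] started from rank
#' p of the marginal MI ordering. Subsets may overlap; the procedure is
#' deterministic.
#'
#' @param dm `ubi_discretized`.
#' @param config [selector_config()]; `config$P` subsets are produced.
#' @return List of `ubi_subset`.
#' @export
generate_subsets <- function(dm, config = selector_config()) {
  d <- ncol(dm$codes)
  if (config$P > d) stop("P = ", config$P, " exceeds the number of features ", d)
  ranking <- mi_ranking(dm)
  lapply(seq_len(config$P) - 1L, function(t) {
    fsncmi_select(dm, t, config, ranking = ranking)
  })
}

#' mRMR baseline selection
#'
#' Greedy maximum-relevance minimum-redundancy: seed with the feature of
#' maximal MI with the class; then repeatedly add the feature maximizing
#' I(f;C) - mean over selected fs of I(f;fs). Ties break to the smaller
#' registry index.
#'
#' @param dm `ubi_discretized`.
#' @param k Number of features to select.
#' @return `ubi_subset` whose trajectory holds the mRMR scores.
#' @export
mrmr_select <- function(dm, k = 12L) {
  stopifnot(inherits(dm, "ubi_discretized"))
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  d <- ncol(dm$codes)
  mi <- mi_with(dm$codes, seq_len(d), dm$class)
  seed <- order(-mi, seq_len(d))[1L]
  fs <- seed
  traj <- mi[seed]
  cand <- setdiff(seq_len(d), seed)
  redsum <- mi_with(dm$codes, cand, dm$codes[, seed])
  while (length(fs) < k && length(cand)) {
    score <- mi[cand] - redsum / length(fs)
    best_pos <- order(-score, seq_along(cand))[1L]  # cand ascends in registry order
    best_idx <- cand[best_pos]
    fs <- c(fs, best_idx)
    traj <- c(traj, score[best_pos])
    cand <- cand[-best_pos]
    redsum <- redsum[-best_pos]
    if (length(cand)) {
      redsum <- redsum + mi_with(dm$codes, cand, dm$codes[, best_idx])
    }
  }
  new_subset(dm, fs, 0L, traj,
             if (length(fs) >= k) "k_reached" else "exhausted")
}

#' Serialize subsets as a TSV table
#'
#' One row per (subset, rank): subset index, starting rank t, within-subset
#' rank, feature id, criterion value and stopping reason.
#'
#' @param subsets List of `ubi_subset` (or a single one).
#' @param path Output TSV file.
#' @export
write_subsets_tsv <- function(subsets, path) {
  if (inherits(subsets, "ubi_subset")) subsets <- list(subsets)
  rows <- do.call(rbind, lapply(seq_along(subsets), function(p) {
    s <- subsets[[p]]
    data.frame(subset = p, t = s$t, rank = seq_along(s$ids),
               feature_id = s$ids, criterion = s$trajectory,
               stop_reason = s$stop_reason, stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
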