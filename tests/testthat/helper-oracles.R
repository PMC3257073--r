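# Independent brute-force oracles: direct frequency tables and explicit
# summation over cells, kept deliberately separate from the package's
# estimator code paths.

oracle_entropy <- function(x) {
  p <- as.numeric(table(x)) / length(x)
  -sum(p * log2(p))
}

oracle_joint_entropy <- function(x, y) {
  p <- as.numeric(table(paste(x, y))) / length(x)
  -sum(p * log2(p))
}

oracle_mi <- function(x, y) {
  n <- length(x)
  total <- 0
  for (xv in unique(x)) {
    for (yv in unique(y)) {
      pxy <- sum(x == xv & y == yv) / n
      if (pxy == 0) next
      px <- sum(x == xv) / n
      py <- sum(y == yv) / n
      total <- total + pxy * log2(pxy / (px * py))
    }
  }
  total
}

# I(X;Y|Z) by direct summation of p(x,y,z) log2 [p(z) p(x,y,z) / (p(x,z) p(y,z))]
oracle_cmi <- function(x, y, z) {
  n <- length(x)
  total <- 0
  for (xv in unique(x)) {
    for (yv in unique(y)) {
      for (zv in unique(z)) {
        pxyz <- sum(x == xv & y == yv & z == zv) / n
        if (pxyz == 0) next
        pz <- sum(z == zv) / n
        pxz <- sum(x == xv & z == zv) / n
        pyz <- sum(y == yv & z == zv) / n
        total <- total + pxyz * log2(pz * pxyz / (pxz * pyz))
      }
    }
  }
  total
}

# Naive re-implementation of the forward selector: full recomputation of
# the criterion (min over the selected set) at every step, oracle
# estimators throughout.
oracle_fsncmi <- function(codes, class, t, k, delta = 0.015, epsilon = 1e-12) {
  d <- ncol(codes)
  mi <- vapply(seq_len(d), function(j) oracle_mi(codes[, j], class), numeric(1))
  ord <- order(-mi, seq_len(d))
  seed <- ord[t + 1L]
  hfc <- vapply(seq_len(d), function(j) {
    oracle_joint_entropy(codes[, j], class)
  }, numeric(1))
  fs <- seed
  traj <- if (hfc[seed] > 0) mi[seed] / hfc[seed] else 0
  cand <- setdiff(seq_len(d), seed)
  n_greedy <- 0L
  reason <- NULL
  while (is.null(reason)) {
    if (length(fs) >= k) { reason <- "k_reached"; break }
    jp <- vapply(cand, function(f) {
      if (hfc[f] == 0) return(0)
      min(vapply(fs, function(s) {
        oracle_cmi(codes[, f], class, codes[, s])
      }, numeric(1))) / hfc[f]
    }, numeric(1))
    keep <- jp > epsilon
    cand <- cand[keep]; jp <- jp[keep]
    if (!length(cand)) { reason <- "exhausted"; break }
    best <- which.max(jp)
    if (n_greedy >= 1L && abs(traj[length(traj)] - jp[best]) < delta) {
      reason <- "threshold"; break
    }
    fs <- c(fs, cand[best]); traj <- c(traj, jp[best])
    n_greedy <- n_greedy + 1L
    cand <- cand[-best]
  }
  list(idx = fs, trajectory = traj, stop_reason = reason)
}

oracle_mrmr <- function(codes, class, k) {
  d <- ncol(codes)
  mi <- vapply(seq_len(d), function(j) oracle_mi(codes[, j], class), numeric(1))
  fs <- order(-mi, seq_len(d))[1L]
  cand <- setdiff(seq_len(d), fs)
  while (length(fs) < k && length(cand)) {
    score <- vapply(cand, function(f) {
      mi[f] - mean(vapply(fs, function(s) {
        oracle_mi(codes[, f], codes[, s])
      }, numeric(1)))
    }, numeric(1))
    best <- order(-score, seq_along(cand))[1L]
    fs <- c(fs, cand[best])
    cand <- cand[-best]
  }
  fs
}

# Small random coded matrix + binary class for estimator checks.
random_coded_matrix <- function(n, d, levels = 3L) {
  codes <- matrix(sample.int(levels, n * d, replace = TRUE) - 1L, n, d)
  colnames(codes) <- sprintf("f%02d", seq_len(d))
  list(codes = codes, class = sample(0:1, n, replace = TRUE))
}

as_dm <- function(codes, class, B = 5L) {
  structure(list(codes = codes, class = as.integer(class), B = as.integer(B),
                 ids = colnames(codes)),
            class = "ubi_discretized")
}

# Hand-built window object for encoder unit tests.
make_window <- function(residues, protein_id = "p", center = 1L,
                        w = nchar(residues)) {
  structure(list(protein_id = protein_id, center = as.integer(center),
                 w = as.integer(w), residues = residues,
                 site_index = (as.integer(w) + 1L) %/% 2L,
                 label = NA_integer_),
            class = "ubi_window")
}

# Tiny trainable dataset: two informative continuous features + noise,
# grouped into proteins, for ensemble/evaluation tests.
make_toy_dataset <- function(n_proteins = 6L, sites_per_protein = 10L,
                             d_noise = 4L, seed = 1L, separation = 3) {
  set.seed(seed)
  n <- n_proteins * sites_per_protein
  label <- rbinom(n, 1L, 0.4)
  f1 <- rnorm(n) + separation * label
  f2 <- rnorm(n) - separation * label
  noise <- matrix(rnorm(n * d_noise), n, d_noise)
  features <- cbind(f1, f2, noise)
  colnames(features) <- c("sig1", "sig2", sprintf("noise%d", seq_len(d_noise)))
  meta <- data.frame(
    protein_id = rep(sprintf("tp%02d", seq_len(n_proteins)),
                     each = sites_per_protein),
    position = rep(seq_len(sites_per_protein) * 3L, n_proteins),
    label = label, stringsAsFactors = FALSE)
  structure(list(features = features, meta = meta, registry = NULL,
                 config = NULL),
            class = "ubi_dataset")
}
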