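# Plug-in information-theoretic estimators on discretized (integer-coded)
# variables. All quantities are in bits (log base 2). Estimates use the
# empirical joint frequencies directly; no bias correction is applied, so
# MI and CMI are >= 0 only up to floating tolerance.

check_codes <- function(x, name = "codes") {
  if (anyNA(x)) stop(name, " contain NA")
  x <- as.integer(x)
  if (length(x) && min(x) < 0L) stop(name, " must be non-negative integers")
  x
}

ent_from_counts <- function(counts) {
  n <- sum(counts)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

#' Shannon entropy of a coded variable (bits)
#' @param x Non-negative integer code vector.
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(x) {
  x <- check_codes(x, "x")
  if (!length(x)) stop("empty vector")
  ent_from_counts(tabulate(x + 1L, max(x) + 1L))
}

#' Joint entropy H(X,Y) of two coded variables (bits)
#' @param x,y Aligned non-negative integer code vectors.
#' @return Joint entropy in bits.
#' @export
joint_entropy <- function(x, y) {
  x <- check_codes(x, "x"); y <- check_codes(y, "y")
  if (length(x) != length(y)) stop("length mismatch between x and y")
  if (!length(x)) stop("empty vectors")
  ny <- max(y) + 1L
  ent_from_counts(tabulate(x * ny + y + 1L, (max(x) + 1L) * ny))
}

#' Mutual information I(X;Y) (bits)
#'
#' Plug-in estimate from the empirical joint frequency table,
#' I(X;Y) = sum_xy p(x,y) log2 p(x,y) / (p(x) p(y)).
#'
#' @param x,y Aligned non-negative integer code vectors.
#' @return Mutual information in bits (>= 0 up to floating tolerance).
#' @export
mutual_information <- function(x, y) {
  x <- check_codes(x, "x"); y <- check_codes(y, "y")
  if (length(x) != length(y)) stop("length mismatch between x and y")
  if (!length(x)) stop("empty vectors")
  hx <- ent_from_counts(tabulate(x + 1L, max(x) + 1L))
  hy <- ent_from_counts(tabulate(y + 1L, max(y) + 1L))
  hx + hy - joint_entropy(x, y)
}

#' Conditional mutual information I(X;Y|Z) (bits)
#'
#' Plug-in estimate via the entropy identity
#' I(X;Y|Z) = H(X,Z) + H(Y,Z) - H(Z) - H(X,Y,Z), equivalently
#' H(Y|Z) - H(Y|X,Z): the reduction in uncertainty about Y due to X once Z
#' is known.
#'
#' @param x,y,z Aligned non-negative integer code vectors.
#' @return Conditional mutual information in bits.
#' @export
conditional_mutual_information <- function(x, y, z) {
  x <- check_codes(x, "x"); y <- check_codes(y, "y"); z <- check_codes(z, "z")
  n <- length(x)
  if (length(y) != n || length(z) != n) stop("length mismatch among x, y, z")
  if (!n) stop("empty vectors")
  nx <- max(x) + 1L; ny <- max(y) + 1L; nz <- max(z) + 1L
  hz <- ent_from_counts(tabulate(z + 1L, nz))
  hxz <- ent_from_counts(tabulate(x * nz + z + 1L, nx * nz))
  hyz <- ent_from_counts(tabulate(y * nz + z + 1L, ny * nz))
  hxyz <- ent_from_counts(tabulate((x * ny + y) * nz + z + 1L, nx * ny * nz))
  hxz + hyz - hz - hxyz
}

#' Equal-frequency discretization of a feature matrix
#'
#' Bins each feature into at most B equal-frequency bins using its sample
#' quantiles (ties can merge bins; constant features map to a single bin).
#' Deterministic given the input. The result carries the class labels and
#' is the input of every selector.
#'
#' @param features Numeric matrix (windows x features) with column names,
#'   or a `ubi_dataset` (then `labels` is taken from its meta).
#' @param labels Binary class labels (0/1), aligned to rows.
#' @param B Maximum number of bins per feature (default 5).
#' @return Object of class `ubi_discretized`: list with `codes` (integer
#'   matrix, 0-based), `class` (integer 0/1), `B`, `ids`.
#' @export
discretize <- function(features, labels = NULL, B = 5L) {
  if (inherits(features, "ubi_dataset")) {
    if (is.null(labels)) labels <- features$meta$label
    features <- features$features
  }
  B <- as.integer(B)
  if (B < 2L) stop("B must be >= 2")
  if (is.null(dim(features)) || nrow(features) == 0L || ncol(features) == 0L) {
    stop("empty feature matrix")
  }
  labels <- as.integer(labels)
  if (length(labels) != nrow(features)) stop("labels not aligned to rows")
  codes <- matrix(0L, nrow(features), ncol(features))
  probs <- seq_len(B - 1L) / B
  for (j in seq_len(ncol(features))) {
    x <- features[, j]
    brk <- unique(stats::quantile(x, probs = probs, names = FALSE, type = 7))
    brk <- brk[brk > min(x)]           # avoid an empty lowest bin
    codes[, j] <- findInterval(x, brk)  # bin b = [brk_b, brk_{b+1})
  }
  structure(list(codes = codes, class = labels, B = B,
                 ids = colnames(features)),
            class = "ubi_discretized")
}
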