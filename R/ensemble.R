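# Majority-voting ensemble of random forests, one base classifier per
# selected feature subset. Base learners are Breiman random forests via
# the randomForest package; member p is trained only on the columns of
# subset p, with a per-member seed derived deterministically from the
# master seed.

#' Ensemble training specification
#'
#' @param n_trees Trees per random forest (default 500).
#' @param mtry Features tried per split; default `floor(sqrt(d))` of each
#'   member's subset size (NULL).
#' @param seed Master seed; per-member seeds are derived from it.
#' @return Object of class `ubi_ensemble_spec`.
#' @export
ensemble_spec <- function(n_trees = 500L, mtry = NULL, seed = 1L) {
  stopifnot(n_trees >= 1L)
  structure(list(n_trees = as.integer(n_trees), mtry = mtry,
                 seed = as.integer(seed)),
            class = "ubi_ensemble_spec")
}

subset_ids <- function(s) if (inherits(s, "ubi_subset")) s$ids else as.character(s)

#' Train a majority-voting random-forest ensemble
#'
#' One random forest per feature subset; member p sees only the columns of
#' subset p. Training is deterministic given the master seed.
#'
#' @param features Numeric matrix (windows x features), columns named by
#'   registry ids, or a `ubi_dataset`.
#' @param labels Binary labels (0/1); taken from the dataset when omitted.
#' @param subsets List of `ubi_subset` (or character vectors of ids).
#' @param spec [ensemble_spec()].
#' @return Object of class `ubi_ensemble`: members, subsets, qbc,
#'   fingerprint, per-member out-of-bag error (diagnostic only), spec,
#'   train_proteins (when a dataset was given).
#' @export
train_ensemble <- function(features, labels = NULL, subsets,
                           spec = ensemble_spec()) {
  train_proteins <- NULL
  if (inherits(features, "ubi_dataset")) {
    if (is.null(labels)) labels <- features$meta$label
    train_proteins <- unique(features$meta$protein_id)
    features <- features$features
  }
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(features), all(labels %in% 0:1))
  if (inherits(subsets, "ubi_subset")) subsets <- list(subsets)
  ids_list <- lapply(subsets, subset_ids)
  unknown <- setdiff(unique(unlist(ids_list)), colnames(features))
  if (length(unknown)) {
    stop("subset references unknown feature id(s): ",
         paste(unknown, collapse = ", "))
  }
  y <- factor(labels, levels = c(0L, 1L))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(spec$seed)
  member_seeds <- sample.int(.Machine$integer.max, length(ids_list))
  members <- vector("list", length(ids_list))
  oob <- numeric(length(ids_list))
  for (p in seq_along(ids_list)) {
    x <- features[, ids_list[[p]], drop = FALSE]
    mtry <- if (is.null(spec$mtry)) max(1L, floor(sqrt(ncol(x)))) else spec$mtry
    set.seed(member_seeds[p])
    rf <- randomForest::randomForest(x = x, y = y, ntree = spec$n_trees,
                                     mtry = mtry)
    members[[p]] <- rf
    oob[p] <- rf$err.rate[spec$n_trees, "OOB"]
  }
  structure(list(members = members, subsets = ids_list,
                 qbc = length(members),
                 fingerprint = registry_fingerprint(colnames(features)),
                 oob = oob, spec = spec, member_seeds = member_seeds,
                 train_proteins = train_proteins,
                 format_version = 1L),
            class = "ubi_ensemble")
}

#' Predict with a majority-voting ensemble
#'
#' Each member votes on its own feature subset; `vote_fraction` is the
#' share of members voting positive and the label is positive iff the
#' fraction is >= 0.5 (an even split counts as positive, which favors
#' sensitivity on the minority class).
#'
#' @param object `ubi_ensemble`.
#' @param features Feature matrix aligned to the training registry, or a
#'   `ubi_dataset`.
#' @param q Use only the first q members (default: all).
#' @param ... Unused.
#' @return List with `labels` (integer 0/1) and `vote_fraction`.
#' @export
predict.ubi_ensemble <- function(object, features, q = NULL, ...) {
  if (inherits(features, "ubi_dataset")) features <- features$features
  if (!identical(registry_fingerprint(colnames(features)), object$fingerprint)) {
    stop("feature registry does not match the one the model was trained on")
  }
  if (is.null(q)) q <- object$qbc
  q <- as.integer(q)
  stopifnot(q >= 1L, q <= object$qbc)
  votes <- vapply(seq_len(q), function(p) {
    x <- features[, object$subsets[[p]], drop = FALSE]
    as.integer(as.character(stats::predict(object$members[[p]], x,
                                           type = "response")))
  }, integer(nrow(features)))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1L)
  vote_fraction <- rowMeans(votes)
  list(labels = as.integer(vote_fraction >= 0.5),
       vote_fraction = vote_fraction)
}

#' Performance as a function of the number of base classifiers
#'
#' Trains members for all subsets once, then evaluates the nested
#' ensembles that use the first q members for each q in `q_values`.
#'
#' @param features,labels,subsets,spec As in [train_ensemble()].
#' @param q_values Integer vector of ensemble sizes (subset of
#'   1..length(subsets)).
#' @param eval_fn Function(model, q) returning a `ubi_metrics` report, e.g.
#'   a closure around [independent_test()] for a held-out dataset.
#' @return `data.frame` with columns Qbc, Sn, Sp, AC, MCC.
#' @export
sweep_qbc <- function(features, labels = NULL, subsets, q_values, eval_fn,
                      spec = ensemble_spec()) {
  q_values <- as.integer(q_values)
  if (!length(q_values)) stop("q_values must be nonempty")
  if (any(q_values < 1L | q_values > length(subsets))) {
    stop("q_values must lie in 1..", length(subsets))
  }
  model <- train_ensemble(features, labels, subsets, spec)
  rows <- lapply(q_values, function(q) {
    rep <- eval_fn(model, q)
    data.frame(Qbc = q, Sn = rep$Sn, Sp = rep$Sp, AC = rep$AC, MCC = rep$MCC)
  })
  do.call(rbind, rows)
}

#' Save / load an ensemble model
#'
#' The archive bundles the members, subsets, registry fingerprint and
#' training metadata; a round-trip preserves predictions exactly.
#'
#' @param model `ubi_ensemble`.
#' @param path File path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ubi_ensemble"))
  saveRDS(list(format = "ubisite_ensemble", version = 1L, model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @param registry Optional `ubi_registry` (or character ids): when given,
#'   a fingerprint mismatch is rejected at load time.
#' @return `load_model`: the `ubi_ensemble`.
#' @export
load_model <- function(path, registry = NULL) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("cannot read model archive ", path, ": ", conditionMessage(e))
  })
  if (!is.list(obj) || !identical(obj$format, "ubisite_ensemble")) {
    stop("file ", path, " is not a ubisite ensemble archive")
  }
  if (!identical(obj$version, 1L)) {
    stop("unsupported model archive version: ", obj$version)
  }
  model <- obj$model
  if (!inherits(model, "ubi_ensemble")) stop("corrupt model archive: ", path)
  if (!is.null(registry) &&
      !identical(registry_fingerprint(registry), model$fingerprint)) {
    stop("model was trained under a different feature registry")
  }
  model
}
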