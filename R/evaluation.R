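# Evaluation protocols (leave-one-protein-out jackknife, protein-grouped
# stratified k-fold, independent test) with the four imbalance-aware
# metrics, and provenance analysis of selected subsets.

#' Confusion counts
#' @param TP,TN,FP,FN Non-negative integers.
#' @return Object of class `ubi_confusion`.
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  counts <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  if (sum(counts) == 0) stop("all confusion counts are zero")
  structure(as.list(counts), class = "ubi_confusion")
}

confusion_from_predictions <- function(truth, predicted) {
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  confusion_counts(TP = sum(truth == 1L & predicted == 1L),
                   TN = sum(truth == 0L & predicted == 0L),
                   FP = sum(truth == 0L & predicted == 1L),
                   FN = sum(truth == 1L & predicted == 0L))
}

#' Sensitivity, specificity, accuracy and MCC from confusion counts
#'
#' Sn = TP/(TP+FN), Sp = TN/(TN+FP), AC = (TP+TN)/total (all reported as
#' percentages) and the Matthews correlation coefficient
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#' Degenerate cases: when any factor of the MCC denominator is zero, MCC is
#' 0; when the Sn (or Sp) denominator is zero the metric is NA.
#'
#' @param counts `ubi_confusion`, or a named vector/list with TP, TN, FP, FN.
#' @param protocol Label stored in the report.
#' @return Object of class `ubi_metrics`: Sn, Sp, AC (percent), MCC,
#'   counts, protocol.
#' @export
compute_metrics <- function(counts, protocol = "custom") {
  if (!inherits(counts, "ubi_confusion")) {
    counts <- confusion_counts(counts[["TP"]], counts[["TN"]],
                               counts[["FP"]], counts[["FN"]])
  }
  tp <- as.numeric(counts$TP); tn <- as.numeric(counts$TN)
  fp <- as.numeric(counts$FP); fn <- as.numeric(counts$FN)
  total <- tp + tn + fp + fn
  sn <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  ac <- 100 * (tp + tn) / total
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / sqrt(denom) else 0
  structure(list(Sn = sn, Sp = sp, AC = ac, MCC = mcc, counts = counts,
                 protocol = protocol),
            class = "ubi_metrics")
}

#' @export
print.ubi_metrics <- function(x, ...) {
  cat(sprintf("ubisite metrics [%s]\n", x$protocol))
  cat(sprintf("  Sn = %.2f%%  Sp = %.2f%%  AC = %.2f%%  MCC = %.3f\n",
              x$Sn, x$Sp, x$AC, x$MCC))
  cat(sprintf("  counts: TP=%d TN=%d FP=%d FN=%d\n",
              x$counts$TP, x$counts$TN, x$counts$FP, x$counts$FN))
  invisible(x)
}

#' Pipeline configuration for cross-validated evaluation
#'
#' @param selector [selector_config()] used inside each training fold.
#' @param qbc Number of base classifiers (default 10).
#' @param n_trees Trees per base classifier.
#' @param seed Master seed for fold seeds and member seeds.
#' @param select_once If TRUE, feature subsets are selected ONCE on the full
#'   dataset before the fold loop (select-then-validate). This replicates
#'   the original protocol but leaks feature-selection information across
#'   folds; a warning is emitted. Default FALSE: selection re-runs inside
#'   every training fold.
#' @param site_level If TRUE, jackknife leaves out single sites instead of
#'   whole proteins (comparison mode only).
#' @return Object of class `ubi_pipeline_config`.
#' @export
pipeline_config <- function(selector = selector_config(), qbc = 10L,
                            n_trees = 500L, seed = 1L, select_once = FALSE,
                            site_level = FALSE) {
  structure(list(selector = selector, qbc = as.integer(qbc),
                 n_trees = as.integer(n_trees), seed = as.integer(seed),
                 select_once = isTRUE(select_once),
                 site_level = isTRUE(site_level)),
            class = "ubi_pipeline_config")
}

# Shared fold loop: trains the pipeline on each training side and pools
# held-out predictions. `fold` is an integer fold id per window. Returns a
# report per requested ensemble size.
evaluate_folds <- function(dataset, fold, config, protocol,
                           q_values = config$qbc) {
  stopifnot(inherits(dataset, "ubi_dataset"))
  q_values <- sort(unique(as.integer(q_values)))
  sel_cfg <- config$selector
  sel_cfg$P <- max(sel_cfg$P, max(q_values))
  subsets_global <- NULL
  if (config$select_once) {
    warning("select_once: feature subsets selected on the full dataset ",
            "before cross-validation; feature-selection information leaks ",
            "across folds")
    dm <- discretize(dataset$features, dataset$meta$label, sel_cfg$B)
    subsets_global <- generate_subsets(dm, sel_cfg)
  }
  n <- nrow(dataset$features)
  pred <- matrix(NA_integer_, n, length(q_values))
  for (u in sort(unique(fold))) {
    test_rows <- which(fold == u)
    train_rows <- which(fold != u)
    tr_feat <- dataset$features[train_rows, , drop = FALSE]
    tr_lab <- dataset$meta$label[train_rows]
    subsets <- subsets_global
    if (is.null(subsets)) {
      dm <- discretize(tr_feat, tr_lab, sel_cfg$B)
      subsets <- generate_subsets(dm, sel_cfg)
    }
    model <- train_ensemble(tr_feat, tr_lab, subsets[seq_len(max(q_values))],
                            ensemble_spec(n_trees = config$n_trees,
                                          seed = config$seed + u))
    for (qi in seq_along(q_values)) {
      pr <- predict(model, dataset$features[test_rows, , drop = FALSE],
                    q = q_values[qi])
      pred[test_rows, qi] <- pr$labels
    }
  }
  reports <- lapply(seq_along(q_values), function(qi) {
    compute_metrics(confusion_from_predictions(dataset$meta$label, pred[, qi]),
                    protocol = protocol)
  })
  names(reports) <- paste0("qbc", q_values)
  if (length(reports) == 1L) reports[[1L]] else reports
}

#' Leave-one-protein-out jackknife evaluation
#'
#' Each protein in turn is held out and its sites are predicted by a
#' pipeline (discretization, subset selection, ensemble training) fitted on
#' the remaining proteins; pooled predictions give one metric report. With
#' `config$site_level = TRUE` single sites are left out instead. Proteins
#' contributing no windows are skipped with a warning.
#'
#' @param dataset `ubi_dataset`.
#' @param config [pipeline_config()].
#' @param q_values Optional vector of ensemble sizes to evaluate from the
#'   same fold models (default: `config$qbc` only).
#' @return `ubi_metrics`, or a named list of them when several `q_values`
#'   are requested.
#' @export
jackknife_lopo <- function(dataset, config = pipeline_config(),
                           q_values = config$qbc) {
  ids <- unique(dataset$meta$protein_id)
  if (length(ids) < 2L) stop("jackknife needs at least 2 proteins")
  if (config$site_level) {
    fold <- seq_len(nrow(dataset$meta))
  } else {
    fold <- match(dataset$meta$protein_id, ids)
  }
  evaluate_folds(dataset, fold, config, "jackknife_LOPO", q_values)
}

#' Protein-grouped stratified k-fold cross-validation
#'
#' Proteins (never single windows) are assigned to k folds; the assignment
#' balances positive-site counts across folds by dealing proteins, sorted
#' by their number of positive sites with a seeded random tie-break, round
#' robin onto the folds.
#'
#' @param dataset `ubi_dataset`.
#' @param k Number of folds (>= 2, at most the number of proteins).
#' @param seed Seed for the fold assignment.
#' @param config [pipeline_config()].
#' @param q_values As in [jackknife_lopo()].
#' @return `ubi_metrics`, or a named list for several `q_values`.
#' @export
kfold <- function(dataset, k = 5L, seed = 1L, config = pipeline_config(),
                  q_values = config$qbc) {
  k <- as.integer(k)
  ids <- unique(dataset$meta$protein_id)
  if (k < 2L) stop("k must be >= 2")
  if (k > length(ids)) stop("k = ", k, " exceeds the number of proteins")
  npos <- vapply(ids, function(p) {
    sum(dataset$meta$label[dataset$meta$protein_id == p])
  }, numeric(1))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  ord <- order(-npos, sample.int(length(ids)))
  fold_of_protein <- integer(length(ids))
  fold_of_protein[ord] <- rep_len(seq_len(k), length(ids))
  fold <- fold_of_protein[match(dataset$meta$protein_id, ids)]
  evaluate_folds(dataset, fold, config, "kfold", q_values)
}

#' Independent-test evaluation of a trained model
#'
#' Single-pass prediction on a dataset disjoint (by protein id) from the
#' training proteins; an overlap triggers a warning, not an error.
#'
#' @param model `ubi_ensemble`.
#' @param dataset `ubi_dataset`.
#' @param q Optional number of members to use.
#' @return `ubi_metrics` with protocol "independent".
#' @export
independent_test <- function(model, dataset, q = NULL) {
  stopifnot(inherits(model, "ubi_ensemble"), inherits(dataset, "ubi_dataset"))
  if (nrow(dataset$meta) == 0L) stop("empty dataset")
  if (!is.null(model$train_proteins)) {
    overlap <- intersect(model$train_proteins, unique(dataset$meta$protein_id))
    if (length(overlap)) {
      warning("test set shares ", length(overlap),
              " protein(s) with the training set: ",
              paste(utils::head(overlap, 5L), collapse = ", "))
    }
  }
  pr <- predict(model, dataset, q = q)
  compute_metrics(confusion_from_predictions(dataset$meta$label, pr$labels),
                  protocol = "independent")
}

#' Provenance of selected features: family and window-site counts
#'
#' Counts, as a multiset over all subsets, how many selected feature slots
#' fall in each family (AAC, PSSM, FACTOR, DISORDER) and, for the
#' site-bearing families, at each window site 1..w (composition features
#' carry no site and are excluded from the site table).
#'
#' @param subsets List of `ubi_subset` (or id vectors).
#' @param registry `ubi_registry`.
#' @return List with `family` (data.frame family, count) and `site`
#'   (data.frame site, count).
#' @export
feature_provenance <- function(subsets, registry) {
  if (inherits(subsets, "ubi_subset")) subsets <- list(subsets)
  if (!length(subsets)) stop("subsets must be nonempty")
  ids <- unlist(lapply(subsets, subset_ids))
  ri <- match(ids, registry$id)
  if (anyNA(ri)) stop("subset feature id not in registry")
  fams <- c("AAC", "PSSM", "FACTOR", "DISORDER")
  fam_count <- vapply(fams, function(f) sum(registry$family[ri] == f),
                      numeric(1))
  w <- max(registry$site, na.rm = TRUE)
  sites <- registry$site[ri]
  site_count <- vapply(seq_len(w), function(s) {
    sum(!is.na(sites) & sites == s)
  }, numeric(1))
  list(family = data.frame(family = fams, count = as.integer(fam_count),
                           stringsAsFactors = FALSE),
       site = data.frame(site = seq_len(w), count = as.integer(site_count)))
}
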