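#' Sample matched null regions for classification
#'
#' Draws one random region per DSB with the same chromosome and length,
#' uniformly placed and rejection-resampled until it overlaps nothing in
#' \code{exclude} (normally the full DSB catalog, so null regions are genuine
#' non-DSB regions with matched chromosome and length distributions).
#'
#' @param dsbs \code{GRanges}
#' @param genome a \code{\link{genome}}; defaults to the genome bound to
#'   \code{dsbs}
#' @param exclude \code{GRanges} that null regions must not touch
#' @param seed integer seed
#' @param max_attempts rejection cap per region (default 1000)
#' @return \code{GRanges} of null regions, parallel to \code{dsbs}
#' @export
sample_matched_nulls <- function(dsbs, genome = NULL, exclude = dsbs,
                                 seed = 1L, max_attempts = 1000L) {
  genome <- if (is.null(genome)) genome_of(dsbs) else as_genome(genome)
  chroms <- as.character(GenomeInfoDb::seqnames(dsbs))
  w <- GenomicRanges::width(dsbs)
  L <- as.numeric(genome[chroms])
  if (any(is.na(L) | w > L)) stop("DSB intervals incompatible with genome")
  idx <- overlap_index(exclude, genome)
  start0 <- with_seed(seed, {
    s <- draw_starts(L, w)
    for (attempt in seq_len(max_attempts)) {
      qs <- idx$offset[chroms] + s
      clash <- overlapping_any(idx, qs, qs + w)
      if (!any(clash)) break
      s[clash] <- draw_starts(L[clash], w[clash])
    }
    if (any(clash <- overlapping_any(idx, idx$offset[chroms] + s,
                                     idx$offset[chroms] + s + w))) {
      i <- which(clash)[1]
      stop(sprintf(
        "no exclusion-free placement found for region %d (%s, %d bp) in %d attempts",
        i, chroms[i], w[i], max_attempts))
    }
    s
  })
  out <- GenomicRanges::GRanges(chroms,
                                IRanges::IRanges(start = start0 + 1, width = w),
                                seqinfo = genome_seqinfo(genome))
  S4Vectors::metadata(out)$label <- "matched_null"
  out
}

overlapping_any <- function(idx, qs, qe) {
  n <- length(idx$rs)
  if (n == 0L) return(rep(FALSE, length(qs)))
  i <- findInterval(qs, idx$rs)
  (i >= 1L & idx$re[pmax(i, 1L)] > qs) | (i < n & idx$rs[pmin(i + 1L, n)] < qe)
}

#' Build the region-by-feature matrix for classification
#'
#' Rows are the real DSB regions followed by the matched null regions, with a
#' \code{label} factor (\code{real} / \code{null}). In \code{signal} mode each
#' column is the mean signal of one track over the region
#' (\code{\link{mean_signal_over_region}}); in \code{distance} mode each
#' column is the edge-to-edge distance in bp to the nearest interval of one
#' feature set (\code{\link{nearest_gap}}), with regions on chromosomes
#' lacking the feature encoded as the chromosome length (a genome-scale
#' sentinel preserving "far" ordering without missing values). \code{sum}
#' mode is signal summed (mean times region length) rather than averaged.
#'
#' @param real,null \code{GRanges}
#' @param tracks named list of signal-track \code{GRanges} (signal/sum mode)
#' @param feature_sets named list of \code{GRanges} (distance mode)
#' @param mode \code{"signal"}, \code{"distance"} or \code{"sum"}
#' @return data.frame with a \code{label} column and one numeric column per
#'   feature; attribute \code{mode} records the variant
#' @export
build_feature_matrix <- function(real, null, tracks = NULL, feature_sets = NULL,
                                 mode = c("signal", "distance", "sum")) {
  mode <- match.arg(mode)
  regions <- c(GenomicRanges::granges(real), GenomicRanges::granges(null))
  label <- factor(rep(c("real", "null"), c(length(real), length(null))),
                  levels = c("null", "real"))
  cols <- if (mode == "distance") feature_sets else tracks
  if (is.null(cols) || is.null(names(cols)) || any(names(cols) == "") ||
      anyDuplicated(names(cols)))
    stop("feature columns must be a uniquely named list")
  vals <- lapply(cols, function(x) {
    if (mode == "distance") {
      d <- nearest_gap(regions, x)
      sentinel <- as.numeric(genome_of(regions)[
        as.character(GenomeInfoDb::seqnames(regions))])
      ifelse(is.na(d), sentinel, as.numeric(d))
    } else {
      m <- mean_signal_over_region(x, regions, uncovered_as_zero = TRUE)
      if (mode == "sum") m * GenomicRanges::width(regions) else m
    }
  })
  out <- data.frame(label = label, vals, check.names = FALSE)
  attr(out, "mode") <- mode
  out
}

#' Train and evaluate a random-forest DSB classifier
#'
#' Fits a random forest (default 700 trees, default \code{mtry} for
#' classification) to distinguish real DSB regions from matched nulls, and
#' evaluates on the out-of-bag predictions: AUROC, area under the
#' precision-recall curve for the \code{real} class, per-class error rates,
#' and both permutation (mean decrease in accuracy) and impurity (mean
#' decrease in Gini) variable importance.
#'
#' @param matrix data.frame from \code{\link{build_feature_matrix}}
#' @param n_trees number of trees (default 700)
#' @param seed integer seed; results are deterministic given the seed
#' @param holdout optional fraction in (0, 1): evaluate on a stratified
#'   held-out split instead of out-of-bag votes
#' @return a \code{classifier_report} with \code{auroc}, \code{pr_auc},
#'   \code{class_errors}, \code{importance} (two-column matrix), \code{n_trees},
#'   \code{seed}
#' @export
train_evaluate <- function(matrix, n_trees = 700L, seed = 1L, holdout = NULL) {
  if (!"label" %in% names(matrix)) stop("matrix needs a 'label' column")
  y <- factor(matrix$label, levels = c("null", "real"))
  if (nlevels(droplevels(y)) < 2) stop("both classes must be present")
  if (min(table(y)) < 10) stop("need at least 10 rows per class")
  x <- matrix[setdiff(names(matrix), "label")]

  with_seed(seed, {
    if (is.null(holdout)) {
      fit <- randomForest::randomForest(x = x, y = y, ntree = n_trees,
                                        importance = TRUE)
      votes <- fit$votes[, "real"]
      truth <- y
      err <- fit$confusion[, "class.error"]
      pred <- fit$predicted
    } else {
      test <- unlist(lapply(split(seq_along(y), y), function(i)
        sample(i, max(1, round(length(i) * holdout)))))
      fit <- randomForest::randomForest(x = x[-test, , drop = FALSE],
                                        y = y[-test], ntree = n_trees,
                                        importance = TRUE)
      votes <- stats::predict(fit, x[test, , drop = FALSE], type = "prob")[, "real"]
      truth <- y[test]
      pred <- stats::predict(fit, x[test, , drop = FALSE])
      err <- vapply(levels(y), function(l)
        mean(pred[truth == l] != l), numeric(1))
    }
    auroc <- as.numeric(pROC::auc(pROC::roc(
      response = truth, predictor = votes, levels = c("null", "real"),
      direction = "<", quiet = TRUE)))
    structure(list(
      auroc = auroc,
      pr_auc = pr_auc(truth == "real", votes),
      class_errors = stats::setNames(as.numeric(err), levels(y)),
      importance = fit$importance[, c("MeanDecreaseAccuracy", "MeanDecreaseGini"),
                                  drop = FALSE],
      n_trees = as.integer(n_trees),
      seed = seed,
      mode = attr(matrix, "mode") %||% "signal",
      oob = is.null(holdout)),
      class = "classifier_report")
  })
}

# Area under the precision-recall curve by step integration over score
# thresholds (precision interpolated at each recall step).
pr_auc <- function(positive, score) {
  o <- order(score, decreasing = TRUE)
  positive <- positive[o]
  tp <- cumsum(positive)
  fp <- cumsum(!positive)
  # collapse tied scores to the last index of each tie group
  last <- cumsum(rle(score[o])$lengths)
  tp <- tp[last]; fp <- fp[last]
  recall <- tp / sum(positive)
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("Random-forest DSB classifier (%s mode, %d trees, %s)\n",
              x$mode, x$n_trees, if (x$oob) "out-of-bag" else "held-out"))
  cat(sprintf("  AUROC %.3f, PR-AUC %.3f\n", x$auroc, x$pr_auc))
  cat(sprintf("  class errors: null %.3f, real %.3f\n",
              x$class_errors["null"], x$class_errors["real"]))
  top <- rownames(x$importance)[order(-x$importance[, "MeanDecreaseAccuracy"])]
  cat("  importance (MeanDecreaseAccuracy ranking): ",
      paste(top, collapse = " > "), "\n", sep = "")
  invisible(x)
}

#' Write/read a feature matrix as TSV
#' @param matrix data.frame from \code{\link{build_feature_matrix}}
#' @param path output path
#' @export
write_feature_matrix <- function(matrix, path) {
  df <- cbind(mode = attr(matrix, "mode") %||% "signal", matrix)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  mode <- df$mode[1]
  df <- df[setdiff(names(df), "mode")]
  df$label <- factor(df$label, levels = c("null", "real"))
  attr(df, "mode") <- mode
  df
}
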