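#' Linear-discriminant classification of reaction vectors by EC class
#'
#' Reaction-feature vectors of the same enzyme class should lie close
#' together in latent space; this is checked by classifying the vectors into
#' EC classes (numbers truncated to `digitLevel` dotted fields) with linear
#' discriminant analysis. Classes with fewer than two members are excluded.
#' Accuracy is cross-validated by default (`folds >= 2`); `folds = 1` gives
#' resubstitution accuracy for comparison.
#'
#' @param db a [ReactionFeatureDB-class].
#' @param digitLevel EC truncation level, 1-3.
#' @param part which latent part of the stored vectors to use. DBs built
#'   with part `"combined"` can be evaluated as `"tree"`, `"graph"` or
#'   `"combined"`; DBs built on a single part only as that part.
#' @param folds number of stratified CV folds (default 5).
#' @param seed integer seed for fold assignment.
#' @return list of class `"ECClassificationReport"` with elements
#'   `digitLevel`, `part`, `confusion` (square count matrix, rows = truth),
#'   `accuracy`, `classes` (per-class counts), `nExcluded`.
#' @export
classifyEC <- function(db, digitLevel = 2L, part = db@part, folds = 5L,
                       seed = 1L) {
  X <- partColumns(db, part)
  y <- ecPrefix(db@ec, digitLevel)
  counts <- table(y)
  keepCls <- names(counts)[counts > 1L]
  if (length(keepCls) < 2L)
    stop("class-error: fewer than 2 EC classes with more than one member",
         call. = FALSE)
  sel <- y %in% keepCls
  X <- X[sel, , drop = FALSE]
  y <- factor(y[sel], levels = sort(keepCls))
  # drop coordinates without variance so the discriminant fit is defined
  keepCol <- apply(X, 2L, stats::var) > 1e-12
  X <- X[, keepCol, drop = FALSE]
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  if (folds <= 1L) {
    fit <- suppressWarnings(MASS::lda(X, grouping = y, tol = 1e-10))
    pred[] <- stats::predict(fit, X)$class
  } else {
    fold <- stratifiedFolds(as.integer(y), folds, seed)
    for (r in seq_len(folds)) {
      tr <- fold != r
      fit <- suppressWarnings(MASS::lda(X[tr, , drop = FALSE],
                                        grouping = droplevels(y[tr]),
                                        tol = 1e-10))
      pred[!tr] <- as.character(stats::predict(fit, X[!tr, , drop = FALSE])$class)
    }
  }
  cm <- table(truth = y, predicted = pred)
  cm <- unclass(cm)[, levels(y), drop = FALSE]  # square, fixed order
  structure(list(digitLevel = as.integer(digitLevel), part = part,
                 confusion = cm,
                 accuracy = sum(diag(cm)) / sum(cm),
                 classes = as.integer(table(y)),
                 classNames = levels(y),
                 nExcluded = as.integer(sum(!sel))),
            class = "ECClassificationReport")
}

partColumns <- function(db, part) {
  if (part == db@part) return(db@vectors)
  if (db@part != "combined")
    stopParam(sprintf("DB stores the %s part only; cannot extract %s",
                      db@part, part))
  switch(part,
         tree = db@vectors[, seq_len(db@treeDim), drop = FALSE],
         graph = db@vectors[, db@treeDim + seq_len(db@graphDim), drop = FALSE],
         stopParam("part must be tree, graph or combined"))
}

#' Aggregate a confusion matrix to a coarser EC digit level
#'
#' Entries of the coarser matrix are the sums of the corresponding
#' finer-level entries; e.g. classification at 3-digit classes can be
#' reported as a 2-digit confusion matrix.
#'
#' @param confusion square count matrix with dotted-EC row/column names.
#' @param digits target truncation level (< the matrix's level).
#' @return square count matrix over the truncated classes.
#' @export
aggregateConfusion <- function(confusion, digits = 2L) {
  rTo <- ecPrefix(rownames(confusion), digits)
  cTo <- ecPrefix(colnames(confusion), digits)
  cls <- sort(unique(c(rTo, cTo)))
  out <- matrix(0, length(cls), length(cls), dimnames = list(cls, cls))
  for (i in seq_len(nrow(confusion)))
    for (j in seq_len(ncol(confusion)))
      out[rTo[i], cTo[j]] <- out[rTo[i], cTo[j]] + confusion[i, j]
  out
}

#' Compare latent parts by EC classification accuracy
#'
#' Runs [classifyEC()] with identical fold splits for the tree, graph and
#' combined parts of a combined-part DB, to ask which representation carries
#' the enzyme-class signal.
#'
#' @inheritParams classifyEC
#' @return data.frame with columns `part`, `accuracy`, `nClasses`, plus
#'   attribute `"reports"` holding the three full reports.
#' @export
compareParts <- function(db, digitLevel = 2L, folds = 5L, seed = 1L) {
  if (db@part != "combined")
    stopParam("compareParts needs a DB built with part = 'combined'")
  parts <- c("tree", "graph", "combined")
  reports <- lapply(parts, function(p)
    classifyEC(db, digitLevel, part = p, folds = folds, seed = seed))
  out <- data.frame(part = parts,
                    accuracy = vapply(reports, `[[`, numeric(1), "accuracy"),
                    nClasses = vapply(reports, function(r)
                      length(r$classNames), integer(1)))
  attr(out, "reports") <- stats::setNames(reports, parts)
  out
}

#' @export
print.ECClassificationReport <- function(x, ...) {
  cat("EC classification (", x$part, " part, ", x$digitLevel, "-digit classes)\n",
      "  classes: ", length(x$classNames),
      "  evaluated: ", sum(x$confusion),
      "  excluded (singleton classes): ", x$nExcluded, "\n",
      "  accuracy: ", format(x$accuracy, digits = 4), "\n", sep = "")
  invisible(x)
}
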