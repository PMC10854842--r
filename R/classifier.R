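# Linear discriminant analysis of fecal alkane profiles, written out in
# full: pooled within-class covariance, whitened between-class eigenproblem,
# and Gaussian discriminant scores for prediction. Scaling convention:
# discriminant scores have unit pooled within-class variance; sign fixed so
# the first nonzero coefficient of each direction is positive.

#' Fit a linear discriminant model
#'
#' @param x Numeric matrix, animals x markers (column names = marker
#'   labels).
#' @param labels Class (diet) label per row; >= 2 classes with >= 2 animals
#'   each.
#' @param priors Named prior probabilities per class (must sum to 1);
#'   default: observed class frequencies.
#' @param ridge Optional ridge term `ridge * I` added to the pooled
#'   covariance (default 0; use a small positive value when the pooled
#'   covariance is singular).
#' @return An object of class `lda_model`: `classes`, `class_means`
#'   (class x marker), `pooled_cov`, `scaling` (marker x discriminant),
#'   `priors`, `n`.
#' @examples
#' x <- matrix(c(1, 2, 3, 7, 8, 9), ncol = 1, dimnames = list(NULL, "C29"))
#' lda_fit(x, rep(c("a", "b"), each = 3))$scaling
#' @export
lda_fit <- function(x, labels, priors = NULL, ridge = 0) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  labels <- as.character(labels)
  if (nrow(x) != length(labels))
    stop_validation("lda_fit: nrow(x) != length(labels)")
  if (any(!is.finite(x)))
    stop_validation("lda_fit: features must be finite")
  classes <- unique(labels)
  g <- length(classes)
  if (g < 2) stop_validation("lda_fit: need at least 2 classes")
  counts <- table(factor(labels, levels = classes))
  if (any(counts < 2))
    stop_validation("lda_fit: every class needs at least 2 animals")
  n <- nrow(x); p <- ncol(x)
  if (n <= p + g - 1)
    warning(sprintf("lda_fit: only %d animals for %d markers and %d classes",
                    n, p, g))
  if (is.null(priors)) {
    priors <- as.numeric(counts) / n
    names(priors) <- classes
  } else {
    if (is.null(names(priors)) || !setequal(names(priors), classes))
      stop_validation("lda_fit: priors must be named by class")
    priors <- priors[classes]
    if (abs(sum(priors) - 1) > 1e-9)
      stop_validation("lda_fit: priors must sum to 1")
  }

  means <- do.call(rbind, lapply(classes, function(k)
    colMeans(x[labels == k, , drop = FALSE])))
  dimnames(means) <- list(classes, colnames(x))

  W <- matrix(0, p, p)
  for (k in classes) {
    xc <- sweep(x[labels == k, , drop = FALSE], 2, means[k, ])
    W <- W + crossprod(xc)
  }
  W <- W / (n - g) + diag(ridge, p)

  L <- tryCatch(t(chol(W)), error = function(e)
    stop_numerical("lda_fit: pooled covariance is singular; consider ridge > 0"))

  grand <- colSums(means * as.numeric(counts)) / n
  B <- matrix(0, p, p)
  for (k in classes) {
    d <- means[k, ] - grand
    B <- B + counts[[k]] * tcrossprod(d)
  }
  B <- B / (n - g)

  Bw <- forwardsolve(L, t(forwardsolve(L, B)))
  Bw <- (Bw + t(Bw)) / 2
  eg <- eigen(Bw, symmetric = TRUE)
  if (eg$values[1] <= sqrt(.Machine$double.eps))
    stop_numerical("lda_fit: identical class means; discriminant undefined")
  n_ld <- min(g - 1, sum(eg$values > sqrt(.Machine$double.eps) * eg$values[1]))
  V <- eg$vectors[, seq_len(n_ld), drop = FALSE]
  scaling <- backsolve(t(L), V)   # a = L'^{-1} v  =>  a' W a = I
  for (j in seq_len(ncol(scaling))) {
    nz <- which(abs(scaling[, j]) > 0)[1]
    if (!is.na(nz) && scaling[nz, j] < 0) scaling[, j] <- -scaling[, j]
  }
  dimnames(scaling) <- list(colnames(x), paste0("LD", seq_len(n_ld)))

  structure(list(classes = classes, class_means = means, pooled_cov = W,
                 scaling = scaling, priors = priors, n = n),
            class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model> %d classes (%s), %d animals\n",
              length(x$classes), paste(x$classes, collapse = ", "), x$n))
  cat("  discriminant coefficients:\n")
  print(signif(x$scaling, 4))
  invisible(x)
}

#' Predict diet classes from fecal profiles
#'
#' Assigns each row the class maximizing the Gaussian discriminant score
#' with pooled covariance,
#' \eqn{\delta_k(x) = x^\top W^{-1}\mu_k - \tfrac12 \mu_k^\top W^{-1}\mu_k
#' + \log \pi_k}. Ties are broken toward the first class in model order
#' (with a warning).
#'
#' @param model An [lda_fit()] model.
#' @param x Numeric matrix with the model's marker columns.
#' @return Character vector of predicted class labels.
#' @export
lda_predict <- function(model, x) {
  x <- as.matrix(x)
  p <- ncol(model$class_means)
  if (ncol(x) != p)
    stop_validation(sprintf("lda_predict: model has %d markers, data has %d",
                            p, ncol(x)))
  if (!is.null(colnames(x)) && !is.null(colnames(model$class_means)) &&
      !identical(colnames(x), colnames(model$class_means)))
    stop_validation("lda_predict: feature columns do not match model markers")
  Winv_mu <- solve(model$pooled_cov, t(model$class_means))  # p x g
  scores <- x %*% Winv_mu
  offset <- -0.5 * colSums(t(model$class_means) * Winv_mu) +
    log(model$priors[model$classes])
  scores <- sweep(scores, 2, offset, "+")
  idx <- apply(scores, 1, function(s) {
    best <- which(s >= max(s) - 1e-12)
    if (length(best) > 1)
      warning("lda_predict: tied discriminant scores; assigning first class")
    best[1]
  })
  model$classes[idx]
}

#' Confusion matrix of true vs predicted classes
#'
#' @param truth,predicted Class label vectors of equal length.
#' @param classes Class ordering (default: order of appearance in `truth`).
#' @return Integer matrix, rows = true class, columns = predicted class.
#' @export
confusion_matrix <- function(truth, predicted, classes = unique(truth)) {
  table(factor(truth, levels = classes),
        factor(predicted, levels = classes))
}

#' Per-marker discriminant report
#'
#' Fits one LDA on all markers together and one per single marker, and
#' tabulates each model's first-discriminant coefficients and its confusion
#' matrix — by default training-set resubstitution (each animal classified
#' by the model fitted on all animals); leave-one-out is available behind
#' `method = "loo"`. A degenerate single-marker fit (e.g. a marker constant
#' across all animals) is recorded as an error for that row; other rows are
#' unaffected.
#'
#' @param x Numeric matrix, animals x markers.
#' @param labels Class label per row.
#' @param method `"resubstitution"` (default) or `"loo"`.
#' @param priors Passed to [lda_fit()].
#' @return List of class `marker_report`, one element per model (`"all"`
#'   first, then each marker) with fields `model`, `markers`, `ld1`
#'   (coefficients, `NULL` on error), `confusion` and `error` (message or
#'   `NULL`).
#' @export
per_marker_report <- function(x, labels, method = c("resubstitution", "loo"),
                              priors = NULL) {
  method <- match.arg(method)
  x <- as.matrix(x)
  classes <- unique(as.character(labels))
  models <- c(list(all = colnames(x)),
              setNames(as.list(colnames(x)), colnames(x)))
  out <- lapply(names(models), function(nm) {
    cols <- models[[nm]]
    xm <- x[, cols, drop = FALSE]
    res <- tryCatch({
      pred <- if (method == "resubstitution") {
        fit <- lda_fit(xm, labels, priors = priors)
        lda_predict(fit, xm)
      } else {
        fit <- lda_fit(xm, labels, priors = priors)
        vapply(seq_len(nrow(xm)), function(i) {
          f <- lda_fit(xm[-i, , drop = FALSE], labels[-i], priors = priors)
          lda_predict(f, xm[i, , drop = FALSE])
        }, character(1))
      }
      list(model = nm, markers = cols, ld1 = fit$scaling[, 1],
           confusion = confusion_matrix(labels, pred, classes),
           error = NULL)
    }, alkdiet_error = function(e)
      list(model = nm, markers = cols, ld1 = NULL, confusion = NULL,
           error = conditionMessage(e)))
    res
  })
  names(out) <- names(models)
  structure(out, class = "marker_report")
}

#' @export
print.marker_report <- function(x, ...) {
  for (row in x) {
    cat(sprintf("== model %s ==\n", row$model))
    if (!is.null(row$error)) {
      cat("  degenerate fit:", row$error, "\n")
    } else {
      cat("  LD1:", paste(sprintf("%s %.3g", names(row$ld1), row$ld1),
                          collapse = ", "), "\n")
      print(row$confusion)
    }
  }
  invisible(x)
}

#' Write a per-marker discriminant report to CSV
#'
#' One row per (model, true class): LD1 coefficients (hyphen-joined, in
#' marker order) and the predicted-class counts.
#'
#' @param report A [per_marker_report()] result.
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
write_classify <- function(report, path) {
  rows <- list()
  for (row in report) {
    if (!is.null(row$error)) {
      rows[[length(rows) + 1L]] <-
        data.frame(model = row$model, ld1 = "", true_class = NA,
                   error = row$error, stringsAsFactors = FALSE)
      next
    }
    cm <- row$confusion
    for (k in rownames(cm)) {
      r <- data.frame(model = row$model,
                      ld1 = paste(signif(row$ld1, 6), collapse = "-"),
                      true_class = k, error = "", stringsAsFactors = FALSE)
      for (j in colnames(cm)) r[[paste0("pred_", j)]] <- cm[k, j]
      rows[[length(rows) + 1L]] <- r
    }
  }
  all_cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (cl in setdiff(all_cols, names(r))) r[[cl]] <- NA
    r[all_cols]
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fecal-concentration feature matrix for classification
#'
#' @param animals List of [animal_record()] objects.
#' @param markers Marker set (default: the first animal's).
#' @return List with `x` (matrix animals x markers) and `labels` (diet ids).
#' @export
fecal_features <- function(animals, markers = NULL) {
  if (length(animals) == 0) stop_validation("no animals")
  if (is.null(markers)) markers <- names(animals[[1]]$fecal_conc)
  markers <- validate_markers(markers)
  x <- t(vapply(animals, function(a) a$fecal_conc[markers],
                numeric(length(markers))))
  colnames(x) <- markers
  list(x = x, labels = vapply(animals, function(a) a$diet_id, ""))
}
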