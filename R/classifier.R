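#' Fit a calibrated linear ACP classifier
#'
#' Fits a linear soft-margin support-vector machine on z-standardized
#' composition features and calibrates its decision values to [0, 1] with a
#' logistic map fitted on the training decision values. By default the
#' feature set is restricted to Bonferroni-selected discriminative features
#' (see [select_features()]); set `select = FALSE` to use all 420.
#'
#' @param table Labelled feature table from [featurize_set()].
#' @param cost Soft-margin regularization constant C.
#' @param seed Integer seed recorded in the model and used for any stochastic
#'   step; the fit itself is deterministic given the data.
#' @param threshold Decision threshold on the calibrated score; a peptide is
#'   labelled ACP iff score > threshold (strict).
#' @param select Restrict to Bonferroni-selected features.
#' @param alpha Selection level when `select = TRUE`.
#' @param features Explicit feature ids to use (overrides `select`).
#' @param var_equal Passed to [select_features()].
#' @return An object of class `acp_model`: feature ids, standardization
#'   means/sds, weight vector, bias, calibration slope/intercept, threshold
#'   and training metadata.
#' @seealso [predict.acp_model()], [cross_validate()], [save_model()]
#' @export
acp_fit <- function(table, cost = 1, seed = 1L, threshold = 0.5,
                    select = TRUE, alpha = 0.05, features = NULL,
                    var_equal = FALSE) {
  if (!"label" %in% names(table)) stop("table must have a label column")
  lab <- factor(as.character(table$label), levels = c("ACP", "nonACP"))
  if (any(table(lab) < 2L))
    stop("need at least 2 rows per class to train")
  explicit <- !is.null(features)
  if (!explicit) {
    features <- if (select) {
      sel <- select_features(table, alpha = alpha, var_equal = var_equal)
      ids <- sel$feature_id[sel$selected]
      if (!length(ids))
        stop("no features selected at alpha = ", alpha,
             "; use select = FALSE or supply features")
      ids
    } else setdiff(names(table), "label")
  }
  x <- as.matrix(table[, features, drop = FALSE])
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  if (any(sdv == 0)) {
    if (explicit)
      stop("constant feature(s) after selection: ",
           paste(features[sdv == 0], collapse = ", "))
    # automatically derived feature sets just shed unusable columns
    keep <- sdv > 0
    features <- features[keep]
    x <- x[, keep, drop = FALSE]
    mu <- mu[keep]; sdv <- sdv[keep]
    if (!length(features)) stop("no non-constant features to train on")
  }
  z <- scale(x, center = mu, scale = sdv)
  fit <- .with_seed(seed,
    e1071::svm(x = z, y = lab, kernel = "linear", cost = cost,
               scale = FALSE, probability = FALSE))
  w <- drop(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  # e1071 orients the decision value so the first factor level (ACP) is
  # positive; keep that orientation explicit.
  if (fit$labels[1L] != 1L) { w <- -w; b <- -b }
  d <- drop(z %*% w) + b
  y01 <- as.integer(lab == "ACP")
  cal <- suppressWarnings(
    stats::glm(y01 ~ d, family = stats::binomial())$coefficients)
  if (!is.finite(cal[2L]) || cal[2L] <= 0) cal <- c(0, 1)
  structure(list(
    version = "acp_model/1",
    feature_ids = features,
    center = stats::setNames(as.numeric(mu), features),
    scale = stats::setNames(as.numeric(sdv), features),
    weights = stats::setNames(as.numeric(w), features),
    bias = as.numeric(b),
    calibration = c(intercept = unname(cal[1L]), slope = unname(cal[2L])),
    threshold = threshold,
    meta = list(n_acp = sum(lab == "ACP"), n_nonacp = sum(lab == "nonACP"),
                cost = cost, seed = as.integer(seed),
                n_support = nrow(fit$SV))
  ), class = "acp_model")
}

.model_decision <- function(model, x) {
  x <- x[, model$feature_ids, drop = FALSE]
  z <- sweep(sweep(x, 2L, model$center), 2L, model$scale, "/")
  drop(z %*% model$weights) + model$bias
}

#' Calibrated ACP score of peptides under a fitted model
#'
#' The score is `plogis(intercept + slope * decision)`, a strictly monotone
#' transform of the linear decision value, in [0, 1].
#'
#' @param model An `acp_model`.
#' @param peptides Character vector of peptides (or an unlabelled feature
#'   table / matrix with the model's feature columns).
#' @return Numeric scores in [0, 1].
#' @export
acp_score <- function(model, peptides) {
  stopifnot(inherits(model, "acp_model"))
  x <- if (is.character(peptides)) .composition_matrix(peptides)
  else as.matrix(peptides[, setdiff(colnames(peptides), "label"),
                          drop = FALSE])
  missing <- setdiff(model$feature_ids, colnames(x))
  if (length(missing))
    stop("input lacks model feature(s): ", paste(missing, collapse = ", "))
  d <- .model_decision(model, x)
  stats::plogis(model$calibration["intercept"] +
                  model$calibration["slope"] * d)
}

#' Hard ACP/nonACP label under a fitted model
#'
#' Label is ACP iff score strictly exceeds the model threshold; a score
#' exactly at the threshold is nonACP.
#'
#' @inheritParams acp_score
#' @return Character vector of `"ACP"` / `"nonACP"`.
#' @export
predict_label <- function(model, peptides) {
  ifelse(acp_score(model, peptides) > model$threshold, "ACP", "nonACP")
}

#' @param object An `acp_model`.
#' @param newdata Peptide character vector or feature table/matrix.
#' @param type `"score"` (calibrated, default), `"label"`, or `"decision"`
#'   (raw linear decision value).
#' @param ... Unused.
#' @rdname acp_fit
#' @export
predict.acp_model <- function(object, newdata,
                              type = c("score", "label", "decision"), ...) {
  type <- match.arg(type)
  switch(type,
         score = unname(acp_score(object, newdata)),
         label = unname(predict_label(object, newdata)),
         decision = {
           x <- if (is.character(newdata)) .composition_matrix(newdata)
           else as.matrix(newdata[, setdiff(colnames(newdata), "label"),
                                  drop = FALSE])
           unname(.model_decision(object, x))
         })
}

#' @param object,x An `acp_model`.
#' @rdname acp_fit
#' @export
coef.acp_model <- function(object, ...) {
  c(object$weights, bias = object$bias)
}

#' @rdname acp_fit
#' @export
print.acp_model <- function(x, ...) {
  cat("Linear ACP classifier (", x$version, ")\n", sep = "")
  cat("  features:  ", length(x$feature_ids), "of 420 composition features\n")
  cat("  training:  ", x$meta$n_acp, "ACP vs", x$meta$n_nonacp,
      "nonACP peptides (cost", x$meta$cost, ", seed", x$meta$seed, ")\n")
  cat("  threshold: ", x$threshold, "(score > threshold => ACP)\n")
  invisible(x)
}

#' @rdname acp_fit
#' @export
summary.acp_model <- function(object, ...) {
  w <- sort(abs(object$weights), decreasing = TRUE)
  print(object)
  cat("  support vectors:", object$meta$n_support, "\n")
  cat("  calibration: score = plogis(",
      signif(object$calibration["intercept"], 4), " + ",
      signif(object$calibration["slope"], 4), " * decision)\n", sep = "")
  cat("  top |weight| features:",
      paste(names(w)[seq_len(min(5L, length(w)))], collapse = ", "), "\n")
  invisible(object)
}

#' Save / load a fitted model as checksummed structured text
#'
#' The model is serialized as versioned key-value text (numbers written with
#' full 17-significant-digit precision, so a round trip preserves scores
#' bit-exactly) prefixed by an md5 checksum line; [load_model()] verifies
#' the checksum and the version before reconstructing the model.
#'
#' @param model An `acp_model`.
#' @param path File path.
#' @return `save_model()` returns `path` invisibly; `load_model()` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "acp_model"))
  num <- function(x) paste(sprintf("%.17g", x), collapse = "\t")
  payload <- c(
    paste0("version\t", model$version),
    paste0("feature_ids\t", paste(model$feature_ids, collapse = "\t")),
    paste0("center\t", num(model$center)),
    paste0("scale\t", num(model$scale)),
    paste0("weights\t", num(model$weights)),
    paste0("bias\t", num(model$bias)),
    paste0("calibration\t", num(model$calibration)),
    paste0("threshold\t", num(model$threshold)),
    paste0("meta\t", jsonlite::toJSON(model$meta, auto_unbox = TRUE)))
  tmp <- tempfile(); on.exit(unlink(tmp))
  writeLines(payload, tmp)
  chk <- unname(tools::md5sum(tmp))
  writeLines(c(paste0("#acp_model md5:", chk), payload), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L || !startsWith(lines[1L], "#acp_model md5:"))
    stop("not an acp_model file: ", path)
  chk <- sub("^#acp_model md5:", "", lines[1L])
  tmp <- tempfile(); on.exit(unlink(tmp))
  writeLines(lines[-1L], tmp)
  if (!identical(unname(tools::md5sum(tmp)), chk))
    stop("model file checksum mismatch (corrupted?): ", path)
  parts <- strsplit(lines[-1L], "\t", fixed = TRUE)
  obj <- stats::setNames(lapply(parts, `[`, -1L),
                         vapply(parts, `[`, character(1), 1L))
  if (!identical(obj$version, "acp_model/1"))
    stop("unsupported model version '", obj$version,
         "' (this package reads acp_model/1)")
  ids <- obj$feature_ids
  model <- list(
    version = obj$version,
    feature_ids = ids,
    center = stats::setNames(as.numeric(obj$center), ids),
    scale = stats::setNames(as.numeric(obj$scale), ids),
    weights = stats::setNames(as.numeric(obj$weights), ids),
    bias = as.numeric(obj$bias),
    calibration = c(intercept = as.numeric(obj$calibration[1L]),
                    slope = as.numeric(obj$calibration[2L])),
    threshold = as.numeric(obj$threshold),
    meta = jsonlite::fromJSON(obj$meta))
  class(model) <- "acp_model"
  model
}

#' Stratified k-fold cross-validation of the classifier
#'
#' @inheritParams acp_fit
#' @param k Number of folds (>= 2, at most the smaller class size).
#' @param ... Passed on to [acp_fit()].
#' @return List with `folds` (per-fold accuracy, sensitivity, specificity),
#'   `mean` (their means) and `pooled` (metrics over pooled predictions).
#' @export
cross_validate <- function(table, k = 5L, seed = 1L, ...) {
  if (!.is_count(k, 2L)) stop("k must be an integer >= 2")
  lab <- factor(as.character(table$label), levels = c("ACP", "nonACP"))
  if (any(table(lab) < k))
    stop("k = ", k, " exceeds the size of a class")
  fold <- integer(nrow(table))
  .with_seed(seed, for (lv in levels(lab)) {
    idx <- which(lab == lv)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  })
  pred <- character(nrow(table))
  rows <- lapply(seq_len(k), function(f) {
    train <- table[fold != f, , drop = FALSE]
    test <- table[fold == f, , drop = FALSE]
    m <- acp_fit(train, seed = seed, ...)
    p <- predict(m, test, type = "label")
    pred[fold == f] <<- p
    truth <- as.character(test$label)
    c(accuracy = mean(p == truth),
      sensitivity = mean(p[truth == "ACP"] == "ACP"),
      specificity = mean(p[truth == "nonACP"] == "nonACP"))
  })
  folds <- do.call(rbind, rows)
  truth <- as.character(lab)
  pooled <- c(accuracy = mean(pred == truth),
              sensitivity = mean(pred[truth == "ACP"] == "ACP"),
              specificity = mean(pred[truth == "nonACP"] == "nonACP"))
  list(folds = data.frame(fold = seq_len(k), folds),
       mean = colMeans(folds), pooled = pooled,
       assignment = fold)
}
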