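#' Perceptron / training specification
#'
#' A single-layer (no hidden units) feed-forward perceptron with logistic
#' output units, one-hot targets and cross-entropy loss, trained by resilient
#' propagation (Rprop without weight-backtracking): each weight keeps its own
#' step size, grown by `eta_plus` while the loss gradient keeps its sign and
#' shrunk by `eta_minus` when the sign flips; only the gradient sign enters
#' the update. Training is deterministic given `seed`.
#'
#' @param n_outputs number of output nodes (groups).
#' @param eta_plus,eta_minus step-size growth / shrink factors,
#'   `0 < eta_minus < 1 < eta_plus`.
#' @param delta0,delta_min,delta_max initial / minimum / maximum step size.
#' @param max_epochs training epoch cap.
#' @param convergence_tol stop when the loss change per epoch falls below this.
#' @param seed RNG seed for weight initialization.
#' @return A list of class `perceptron_spec`.
#' @export
perceptron_spec <- function(n_outputs = 2, eta_plus = 1.2, eta_minus = 0.5,
                            delta0 = 0.1, delta_min = 1e-6, delta_max = 50,
                            max_epochs = 1000, convergence_tol = 1e-6,
                            seed = 1L) {
  stopifnot(eta_minus > 0, eta_minus < 1, eta_plus > 1, n_outputs >= 2,
            delta_min > 0, delta_min <= delta0, delta0 <= delta_max,
            max_epochs >= 1)
  structure(list(n_outputs = n_outputs, eta_plus = eta_plus,
                 eta_minus = eta_minus, delta0 = delta0,
                 delta_min = delta_min, delta_max = delta_max,
                 max_epochs = max_epochs, convergence_tol = convergence_tol,
                 seed = as.integer(seed)),
            class = "perceptron_spec")
}

#' Standardize feature matrices by a training reference
#'
#' Columns are centred and scaled by the *reference* (training) subset's mean
#' and SD, so held-out rows never contribute to the statistics. Columns with
#' zero or undefined reference variance are dropped from both matrices;
#' missing values are imputed by the reference column mean before scaling,
#' with the imputation count logged.
#'
#' @param reference numeric matrix/data frame used to fit the transformation.
#' @param newdata optional matrix/data frame transformed with the reference
#'   statistics.
#' @return A list: `reference` and `newdata` (standardized matrices),
#'   `dropped` (names of removed columns), `n_imputed`, `center`, `scale`.
#' @export
standardize_features <- function(reference, newdata = NULL) {
  ref <- as.matrix(reference)
  if (!is.numeric(ref)) abort("features must be numeric.")
  if (nrow(ref) < 1L) abort("reference subset is empty.")
  ctr <- colMeans(ref, na.rm = TRUE)
  scl <- apply(ref, 2L, stats::sd, na.rm = TRUE)
  keep <- is.finite(ctr) & is.finite(scl) & scl > 0
  dropped <- colnames(ref)[!keep]
  n_imp <- 0L
  transform <- function(m) {
    m <- as.matrix(m)[, keep, drop = FALSE]
    for (j in seq_len(ncol(m))) {
      na <- is.na(m[, j])
      if (any(na)) {
        n_imp <<- n_imp + sum(na)
        m[na, j] <- ctr[keep][j]
      }
    }
    sweep(sweep(m, 2L, ctr[keep]), 2L, scl[keep], "/")
  }
  out_ref <- transform(ref)
  out_new <- if (!is.null(newdata)) transform(newdata) else NULL
  list(reference = out_ref, newdata = out_new, dropped = dropped,
       n_imputed = n_imp, center = ctr[keep], scale = scl[keep])
}

one_hot <- function(labels) {
  f <- factor(labels)
  t(vapply(f, function(x) as.numeric(levels(f) == x), numeric(nlevels(f))))
}

#' Train the single-layer Rprop perceptron
#'
#' @param x numeric feature matrix (samples x features), already standardized.
#' @param labels group labels (coerced to factor); one output node per level.
#' @param spec a [perceptron_spec()]; `n_outputs` is taken from the labels.
#' @return An object of class `mea_perceptron`: weights `W` (features x
#'   groups), bias `b`, `levels`, `loss` trace, `epochs`, `converged`.
#' @export
train_perceptron <- function(x, labels, spec = perceptron_spec()) {
  x <- as.matrix(x)
  f <- factor(labels)
  if (nlevels(f) < 2L) abort("need at least two groups.")
  # empty levels are tolerated (they can arise in cross-validation folds):
  # their one-hot columns are all-zero and the node learns to stay off
  if (sum(table(f) >= 1L) < 2L) abort("need samples from at least two groups.")
  tgt <- one_hot(f)
  p <- ncol(x); k <- nlevels(f)
  theta <- with_seed(spec$seed,
                     matrix(runif((p + 1L) * k, -0.1, 0.1), p + 1L, k))
  delta <- matrix(spec$delta0, p + 1L, k)
  g_prev <- matrix(0, p + 1L, k)
  xb <- cbind(1, x)
  loss_trace <- numeric(0)
  loss_prev <- Inf
  converged <- FALSE
  eps <- 1e-12
  for (epoch in seq_len(spec$max_epochs)) {
    a <- xb %*% theta
    prob <- plogis(a)
    loss <- -sum(tgt * log(pmax(prob, eps)) +
                   (1 - tgt) * log(pmax(1 - prob, eps)))
    if (!is.finite(loss)) abort("training loss became non-finite.")
    loss_trace <- c(loss_trace, loss)
    g <- crossprod(xb, prob - tgt)
    s <- g * g_prev
    delta <- pmin(pmax(
      delta * ifelse(s > 0, spec$eta_plus, ifelse(s < 0, spec$eta_minus, 1)),
      spec$delta_min), spec$delta_max)
    theta <- theta - sign(g) * delta
    g_prev <- g
    if (abs(loss_prev - loss) < spec$convergence_tol) {
      converged <- TRUE
      break
    }
    loss_prev <- loss
  }
  structure(list(W = theta[-1L, , drop = FALSE], b = theta[1L, ],
                 levels = levels(f), loss = loss_trace,
                 epochs = length(loss_trace), converged = converged,
                 spec = spec),
            class = "mea_perceptron")
}

#' @export
print.mea_perceptron <- function(x, ...) {
  cat(sprintf(
    "<mea_perceptron> %d inputs -> %d outputs; %d epoch(s), %sconverged, final loss %.4g\n",
    nrow(x$W), ncol(x$W), x$epochs, if (x$converged) "" else "not ",
    tail(x$loss, 1)))
  invisible(x)
}

#' @param object an `mea_perceptron`.
#' @param newdata numeric matrix of standardized features.
#' @param type `"class"` for predicted labels, `"prob"` for logistic outputs.
#' @param ... unused.
#' @rdname train_perceptron
#' @export
predict.mea_perceptron <- function(object, newdata, type = c("class", "prob"),
                                   ...) {
  type <- match.arg(type)
  a <- cbind(1, as.matrix(newdata)) %*% rbind(object$b, object$W)
  prob <- plogis(a)
  colnames(prob) <- object$levels
  if (type == "prob") return(prob)
  factor(object$levels[max.col(prob, ties.method = "first")],
         levels = object$levels)
}

#' Chi-squared test of a recognition (confusion) matrix
#'
#' Goodness-of-fit of the observed confusion counts against the chance
#' expectation. By default chance is uniform over predicted classes within
#' each true-group row (e.g. 50% everywhere for two groups);
#' `expectation = "proportional"` uses predicted-class proportions equal to
#' the group sizes. The statistic sums `(O - E)^2 / E` over all cells with
#' `df = rows * (cols - 1)`.
#'
#' @param confusion integer matrix of counts, true group x predicted group.
#' @param expectation `"uniform"` or `"proportional"`.
#' @return A list: `statistic`, `df`, `p_value`, `expected`.
#' @export
chi_square_recognition <- function(confusion,
                                   expectation = c("uniform", "proportional")) {
  expectation <- match.arg(expectation)
  m <- as.matrix(confusion)
  rs <- rowSums(m)
  if (any(rs == 0)) abort("a true group has zero counts; expected count 0.")
  probs <- if (expectation == "uniform") {
    rep(1 / ncol(m), ncol(m))
  } else {
    cs <- rs / sum(rs)
    if (any(cs == 0)) abort("zero expected count under proportional chance.")
    cs
  }
  expd <- outer(rs, probs)
  stat <- sum((m - expd)^2 / expd)
  df <- nrow(m) * (ncol(m) - 1L)
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE), expected = expd)
}

#' Cross-validated pattern recognition of activity phenotypes
#'
#' Leave-one-out by default (or k-fold via `folds`): inside every fold the
#' standardization is re-fit on the training samples only, a fresh perceptron
#' is trained, and the held-out samples are predicted. The accumulated
#' confusion matrix is row-normalized into per-group recognition percentages
#' and tested against chance with [chi_square_recognition()].
#'
#' @param features numeric feature data (samples x features): a matrix, or a
#'   tibble from [assemble_cohort_features()] (metadata columns `network_id`,
#'   `group`, `div` are dropped automatically).
#' @param labels group label per sample; at least two samples per group.
#' @param spec a [perceptron_spec()].
#' @param folds number of folds; `NULL` (default) means leave-one-out.
#' @return An object of class `mea_cv`: `confusion` (counts),
#'   `recognition_pct` (rows sum to 100), `chi2_stat`, `chi2_df`, `chi2_p`,
#'   `folds`, `n`, `levels`.
#' @export
cross_validate <- function(features, labels, spec = perceptron_spec(),
                           folds = NULL) {
  x <- features
  if (is.data.frame(x)) {
    x <- dplyr::select(x, -dplyr::any_of(c("network_id", "group", "div")))
    x <- as.matrix(x)
  }
  f <- factor(labels)
  if (nrow(x) != length(f)) abort("features and labels disagree in length.")
  tab <- table(f)
  if (any(tab < 2L)) {
    warn(sprintf("group(s) with a single sample: %s",
                 paste(names(tab)[tab < 2L], collapse = ", ")))
  }
  n <- nrow(x)
  fold_id <- if (is.null(folds)) {
    seq_len(n)
  } else {
    # deterministic, label-balanced fold assignment
    id <- integer(n)
    for (lv in levels(f)) {
      idx <- which(f == lv)
      id[idx] <- rep_len(seq_len(folds), length(idx))
    }
    id
  }
  k <- nlevels(f)
  confusion <- matrix(0L, k, k, dimnames = list(true = levels(f),
                                                predicted = levels(f)))
  for (fd in sort(unique(fold_id))) {
    test <- fold_id == fd
    st <- standardize_features(x[!test, , drop = FALSE],
                               x[test, , drop = FALSE])
    fit <- train_perceptron(
      st$reference, f[!test],
      spec = perceptron_spec(n_outputs = k, eta_plus = spec$eta_plus,
                             eta_minus = spec$eta_minus, delta0 = spec$delta0,
                             delta_min = spec$delta_min,
                             delta_max = spec$delta_max,
                             max_epochs = spec$max_epochs,
                             convergence_tol = spec$convergence_tol,
                             seed = derive_seed(spec$seed, fd))
    )
    pred <- predict(fit, st$newdata)
    ti <- as.integer(f[test])
    pi <- as.integer(pred)
    for (j in seq_along(ti)) {
      confusion[ti[j], pi[j]] <- confusion[ti[j], pi[j]] + 1L
    }
  }
  chi <- chi_square_recognition(confusion)
  structure(list(
    confusion = confusion,
    recognition_pct = 100 * confusion / rowSums(confusion),
    chi2_stat = chi$statistic, chi2_df = chi$df, chi2_p = chi$p_value,
    folds = if (is.null(folds)) "leave-one-out" else sprintf("%d-fold", folds),
    n = n, levels = levels(f)
  ), class = "mea_cv")
}

#' @export
print.mea_cv <- function(x, ...) {
  cat(sprintf("<mea_cv> %s cross-validation, n = %d\n", x$folds, x$n))
  print(round(x$recognition_pct, 1))
  cat(sprintf("chi-squared = %.3f (df %d), p = %.4g\n",
              x$chi2_stat, x$chi2_df, x$chi2_p))
  invisible(x)
}

#' Tidy a cross-validation result
#'
#' @param x an `mea_cv` object.
#' @param ... unused.
#' @return One row per confusion cell: `true`, `predicted`, `n`,
#'   `recognition_pct`.
#' @method tidy mea_cv
#' @export
tidy.mea_cv <- function(x, ...) {
  tidyr::expand_grid(true = x$levels, predicted = x$levels) %>%
    mutate(
      n = purrr::map2_int(.data$true, .data$predicted,
                          function(a, b) x$confusion[a, b]),
      recognition_pct = purrr::map2_dbl(.data$true, .data$predicted,
                                        function(a, b) x$recognition_pct[a, b])
    )
}

#' Glance at a cross-validation result
#'
#' @inheritParams tidy.mea_cv
#' @return One-row tibble: `n`, `accuracy`, `chi2_stat`, `chi2_df`, `chi2_p`,
#'   `folds`.
#' @method glance mea_cv
#' @export
glance.mea_cv <- function(x, ...) {
  tibble(n = x$n,
         accuracy = sum(diag(x$confusion)) / sum(x$confusion),
         chi2_stat = x$chi2_stat, chi2_df = x$chi2_df, chi2_p = x$chi2_p,
         folds = x$folds)
}

#' Export a recognition table
#'
#' One row per true group with predicted-percentage columns and the
#' chi-squared p-value, as delimiter-separated text.
#'
#' @param result an `mea_cv` object.
#' @param path output path.
#' @return The written tibble, invisibly.
#' @export
write_recognition_table <- function(result, path) {
  out <- as_tibble(as.data.frame(result$recognition_pct)) %>%
    mutate(group = result$levels, .before = 1) %>%
    mutate(n = as.integer(rowSums(result$confusion)),
           chi2_p = result$chi2_p)
  names(out)[2:(1 + length(result$levels))] <-
    paste0("pct_recognized_as_", result$levels)
  readr::write_csv(out, path)
  invisible(out)
}
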