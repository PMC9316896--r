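#' Fit a PLS calibration model (NIPALS)
#'
#' Fits a univariate-response partial least squares regression by the
#' NIPALS latent-variable recursion on mean-centered predictors and
#' response: for each component, the weight vector is iterated to
#' convergence (relative change < 1e-10, at most 500 iterations), scores
#' and loadings are extracted and the predictor block and response are
#' deflated. The regression vector is
#' \eqn{b = W (P'W)^{-1} q} in original (centered) channel space, so the
#' model predicts the mean response for the mean training spectrum by
#' construction.
#'
#' @param cal A \code{calibration_set} from
#'   \code{\link{build_calibration_set}}.
#' @param n_components Number of latent variables, between 1 and
#'   \code{min(nrow - 1, ncol)}.
#' @return An object of class \code{pls_model}: preprocessing record,
#'   channel wavenumbers, centering vectors, weights/loadings, regression
#'   vector, training response range and an (initially unset) calibration
#'   floor.
#' @seealso \code{\link{predict.pls_model}},
#'   \code{\link{choose_components_cv}}, \code{\link{write_pls_model}}
#' @export
fit_pls <- function(cal, n_components) {
  X <- cal$X
  y <- cal$y
  n <- nrow(X); p <- ncol(X)
  max_comp <- min(n - 1L, p)
  if (n_components < 1 || n_components > max_comp) {
    stop_ftir("ftir_degenerate_data",
              sprintf("n_components must be in 1..%d for %d x %d data",
                      max_comp, n, p))
  }
  if (stats::var(y) == 0) {
    stop_ftir("ftir_degenerate_data", "responses are all equal")
  }
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean)
  if (all(abs(Xc) < 1e-14)) {
    stop_ftir("ftir_degenerate_data", "predictor block has zero variance")
  }
  yc <- y - y_mean
  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  Q <- numeric(n_components)
  Tm <- matrix(0, n, n_components)
  for (a in seq_len(n_components)) {
    w <- crossprod(Xc, yc)[, 1]
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) {
      stop_ftir("ftir_pls_convergence",
                sprintf("component %d: residual predictor-response covariance is zero", a))
    }
    w <- w / nw
    # NIPALS inner iteration (immediate for a univariate response, but run
    # to the stated tolerance for uniformity)
    for (it in seq_len(500)) {
      tvec <- Xc %*% w
      q <- sum(yc * tvec) / sum(tvec^2)
      u <- yc * q
      w_new <- crossprod(Xc, u)[, 1]
      w_new <- w_new / sqrt(sum(w_new^2))
      delta <- sqrt(sum((w_new - w)^2)) / sqrt(sum(w^2))
      w <- w_new
      if (delta < 1e-10) break
      if (it == 500) {
        stop_ftir("ftir_pls_convergence",
                  sprintf("component %d failed to converge in 500 iterations", a))
      }
    }
    tvec <- (Xc %*% w)[, 1]
    tt <- sum(tvec^2)
    pvec <- crossprod(Xc, tvec)[, 1] / tt
    q <- sum(yc * tvec) / tt
    Xc <- Xc - tcrossprod(tvec, pvec)
    yc <- yc - tvec * q
    W[, a] <- w; P[, a] <- pvec; Q[a] <- q; Tm[, a] <- tvec
  }
  b <- W %*% solve(crossprod(P, W), Q)
  structure(
    list(
      prep = cal$prep,
      wavenumber = cal$wavenumber,
      window = cal$window,
      n_components = as.integer(n_components),
      x_mean = x_mean,
      y_mean = y_mean,
      weights = W,
      loadings = P,
      q = Q,
      coefficients = b[, 1],
      training_range = range(cal$y),
      calibration_floor = NA_real_
    ),
    class = "pls_model"
  )
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf(
    "<pls_model> %d component(s), %d channels, trained on %.3g-%.3g ug/cm^2%s\n",
    x$n_components, length(x$coefficients),
    x$training_range[1], x$training_range[2],
    if (is.na(x$calibration_floor)) "" else
      sprintf(", calibration floor %.3g ug/cm^2", x$calibration_floor)
  ))
  invisible(x)
}

#' Predict surface residue from a spectrum
#'
#' Applies the model's recorded preprocessing (window restriction, baseline
#' correction), centers with the training means, and projects onto the
#' regression vector. The result carries two quality flags:
#' \code{extrapolated} when the prediction falls outside the training
#' response range, and \code{below_floor} when it falls below the
#' calibration floor (the LOQ; see
#' \code{\link{apply_calibration_floor}}). The numeric value is always
#' returned.
#'
#' @param object A \code{pls_model}.
#' @param spectrum An \code{\link{ftir_spectrum}} (or list of them).
#' @param ... Unused.
#' @return A data.frame with columns \code{density} (ug/cm^2),
#'   \code{extrapolated} and \code{below_floor}.
#' @export
predict.pls_model <- function(object, spectrum, ...) {
  spectra <- if (inherits(spectrum, "ftir_spectrum")) list(spectrum) else spectrum
  out <- vapply(spectra, function(sp) {
    ch <- preprocess_channels(sp, object$prep)
    if (length(ch$absorbance) != length(object$coefficients)) {
      stop_ftir("ftir_window_coverage",
                "spectrum channel grid does not match the trained model")
    }
    sum((ch$absorbance - object$x_mean) * object$coefficients) + object$y_mean
  }, numeric(1))
  data.frame(
    density = out,
    extrapolated = out < object$training_range[1] | out > object$training_range[2],
    below_floor = !is.na(object$calibration_floor) & out < object$calibration_floor
  )
}

#' Choose the PLS component count by cross-validation
#'
#' Contiguous-block cross-validation grouped by calibration level: all
#' replicates of a level stay in one fold, so replicate structure never
#' leaks between training and validation. Returns the smallest component
#' count whose cross-validated RMSE is within 5% of the global minimum
#' (parsimony rule).
#'
#' @param cal A \code{calibration_set}.
#' @param max_components Largest component count to consider.
#' @param folds Number of folds (>= 2, <= number of distinct levels).
#' @param seed Integer seed (fold assignment of levels is deterministic
#'   given the seed).
#' @return A list with \code{n_components}, \code{rmse} (per candidate
#'   count) and \code{folds}.
#' @export
choose_components_cv <- function(cal, max_components, folds = 5, seed = NULL) {
  y <- cal$y
  lev <- sort(unique(y))
  if (folds < 2) stop_ftir("ftir_degenerate_data", "folds must be >= 2")
  if (length(lev) < folds) {
    stop_ftir("ftir_degenerate_data",
              sprintf("%d distinct levels cannot fill %d folds", length(lev), folds))
  }
  # contiguous blocks of levels -> folds (deterministic); seed only breaks
  # ties in block boundaries when levels do not divide evenly
  fold_of_level <- with_seed(seed, {
    sizes <- rep(length(lev) %/% folds, folds)
    extra <- length(lev) %% folds
    if (extra > 0) {
      bump <- sample.int(folds, extra)
      sizes[bump] <- sizes[bump] + 1L
    }
    rep(seq_len(folds), times = sizes)
  })
  fold <- fold_of_level[match(y, lev)]
  max_fold_train <- min(vapply(seq_len(folds), function(f) sum(fold != f), integer(1)))
  cap <- min(max_components, max_fold_train - 1L, ncol(cal$X))
  if (cap < 1) stop_ftir("ftir_degenerate_data", "too few samples for cross-validation")
  sse <- numeric(cap)
  for (f in seq_len(folds)) {
    tr <- fold != f
    sub <- structure(
      list(X = cal$X[tr, , drop = FALSE], y = y[tr],
           wavenumber = cal$wavenumber, window = cal$window, prep = cal$prep),
      class = "calibration_set"
    )
    Xv <- cal$X[!tr, , drop = FALSE]
    yv <- y[!tr]
    for (a in seq_len(cap)) {
      m <- tryCatch(fit_pls(sub, a), ftirclean_error = function(e) NULL)
      if (is.null(m)) {
        # the fold's data rank is exhausted: larger counts are not
        # estimable on this split and drop out of the comparison
        sse[a:cap] <- sse[a:cap] + Inf
        break
      }
      pred <- sweep(Xv, 2, m$x_mean) %*% m$coefficients + m$y_mean
      sse[a] <- sse[a] + sum((pred[, 1] - yv)^2)
    }
  }
  rmse <- sqrt(sse / length(y))
  best <- min(rmse)
  n_comp <- which(rmse <= 1.05 * best)[1]
  list(n_components = as.integer(n_comp), rmse = rmse, folds = folds)
}

#' Serialize a PLS model to JSON
#'
#' Writes every field of the fitted model (windows, centering vectors,
#' weights, loadings, regression vector, training range, calibration
#' floor) as a self-describing JSON document at full double precision, so
#' \code{\link{read_pls_model}} reproduces the model losslessly.
#'
#' @param model A \code{pls_model}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_pls_model <- function(model, path) {
  doc <- list(
    format = "ftirclean-pls-model",
    version = 1L,
    windows = model$prep$windows$windows,
    baseline = model$prep$baseline,
    centering = model$prep$centering,
    wavenumber = model$wavenumber,
    window = model$window,
    n_components = model$n_components,
    x_mean = model$x_mean,
    y_mean = model$y_mean,
    weights = model$weights,
    loadings = model$loadings,
    q = model$q,
    coefficients = model$coefficients,
    training_range = model$training_range,
    calibration_floor = model$calibration_floor
  )
  writeLines(
    jsonlite::toJSON(doc, digits = NA, auto_unbox = TRUE, na = "null",
                     matrix = "columnmajor"),
    path
  )
  invisible(path)
}

#' Read a serialized PLS model
#'
#' @param path Path written by \code{\link{write_pls_model}}.
#' @return A \code{pls_model}.
#' @export
read_pls_model <- function(path) {
  doc <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                            simplifyMatrix = TRUE)
  if (is.null(doc$format) || doc$format != "ftirclean-pls-model") {
    stop_ftir("ftir_parse_error", sprintf("%s: not a ftirclean PLS model", path))
  }
  windows <- if (is.matrix(doc$windows)) {
    lapply(seq_len(nrow(doc$windows)), function(i) doc$windows[i, ])
  } else if (is.list(doc$windows)) {
    doc$windows
  } else {
    list(doc$windows)
  }
  p <- length(doc$coefficients)
  as_mat <- function(m) {
    m <- as.matrix(m)
    if (nrow(m) != p) m <- t(m)
    m
  }
  structure(
    list(
      prep = preprocess_spec(spectral_windows(windows),
                             baseline = doc$baseline,
                             centering = doc$centering),
      wavenumber = as.numeric(doc$wavenumber),
      window = as.integer(doc$window),
      n_components = as.integer(doc$n_components),
      x_mean = as.numeric(doc$x_mean),
      y_mean = as.numeric(doc$y_mean),
      weights = as_mat(doc$weights),
      loadings = as_mat(doc$loadings),
      q = as.numeric(doc$q),
      coefficients = as.numeric(doc$coefficients),
      training_range = as.numeric(doc$training_range),
      calibration_floor = if (is.null(doc$calibration_floor)) NA_real_ else
        as.numeric(doc$calibration_floor)
    ),
    class = "pls_model"
  )
}
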