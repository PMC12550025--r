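#' Fit a surrogate predictor on latent + condition features
#'
#' Used during fine-tuning for catalytic endpoints other than percent
#' yield (binding energies, activation free-energy differences, ...). The
#' surrogate regresses the target on the concatenated latent-mean and
#' condition features with a tree ensemble, optionally averaging an
#' ensemble of independently seeded fits.
#'
#' @param features numeric matrix (`n x p`), typically
#'   `cbind(latent_mean, condition)`.
#' @param targets numeric vector of length `n` (at least 10).
#' @param model_kind `"random_forest"` or `"gradient_boosting"`.
#' @param n_models ensemble size; predictions are averaged over members.
#' @param seed integer seed.
#' @return an object of class `catvae_surrogate`.
#' @export
fit_surrogate <- function(features, targets,
                          model_kind = c("random_forest", "gradient_boosting"),
                          n_models = 1L, seed = 1L) {
  model_kind <- match.arg(model_kind)
  features <- as.matrix(features)
  if (nrow(features) < 10L) stop("surrogate fitting needs at least 10 samples")
  stopifnot(nrow(features) == length(targets), n_models >= 1L)
  colnames(features) <- paste0("f", seq_len(ncol(features)))
  fits <- lapply(seq_len(n_models), function(k) {
    .fit_one_surrogate(features, targets, model_kind, seed + k - 1L)
  })
  structure(list(kind = model_kind, fits = fits, p = ncol(features)),
            class = "catvae_surrogate")
}

.fit_one_surrogate <- function(features, targets, kind, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  if (kind == "random_forest") {
    randomForest::randomForest(x = features, y = targets, ntree = 300)
  } else {
    dtrain <- xgboost::xgb.DMatrix(features, label = targets)
    xgboost::xgb.train(params = list(max_depth = 5, eta = 0.1,
                                     objective = "reg:squarederror"),
                       data = dtrain, nrounds = 300, verbose = 0)
  }
}

#' Predict from a fitted surrogate
#' @param surrogate a `catvae_surrogate`.
#' @param features feature matrix with the same columns as at fitting.
#' @return numeric predictions (ensemble mean).
#' @export
surrogate_predict <- function(surrogate, features) {
  features <- as.matrix(features)
  stopifnot(ncol(features) == surrogate$p)
  colnames(features) <- paste0("f", seq_len(ncol(features)))
  preds <- lapply(surrogate$fits, function(f) {
    as.numeric(stats::predict(f, features))
  })
  Reduce(`+`, preds) / length(preds)
}
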