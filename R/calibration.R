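#' The ten regressor families used for personalized calibration
#'
#' Four linear families (ordinary, ridge, lasso, elastic-net), linear and
#' RBF-kernel support vector regression, a decision tree, a random forest,
#' gradient boosting, and cubic polynomial regression.
#' @export
REGRESSOR_FAMILIES <- c("LR", "RR", "LaR", "ER", "SVR_linear",
                        "DT", "RF", "GB", "PR", "SVR_RBF")

default_hyperparams <- function(family) {
  switch(family,
    LR = list(),
    RR = list(penalty = 1.0),
    LaR = list(penalty = 0.01),
    ER = list(penalty = 0.01, mixing = 0.5),
    SVR_linear = list(cost = 10, epsilon = 0.1),
    DT = list(max_depth = 6, cp = 1e-4),
    RF = list(num_trees = 200, min_node_size = 1),
    GB = list(nrounds = 200, eta = 0.1, max_depth = 3),
    PR = list(degree = 3),
    SVR_RBF = list(cost = 10, epsilon = 0.1, gamma = NULL),
    stop("unknown regressor family: ", family, call. = FALSE)
  )
}

#' Specify a calibration regressor
#'
#' @param family One of [REGRESSOR_FAMILIES].
#' @param hyperparams Named list overriding the family's documented
#'   defaults (regularization penalties 1.0 / 0.01 / 0.01 with elastic-net
#'   mixing 0.5, expressed per observation; SVR cost 10 with RBF gamma
#'   `1/var(x)`; tree depth 6; 200 trees/boosting stages with learning rate
#'   0.1; polynomial degree 3).
#' @param seed Integer seed for stochastic fitters (RF, GB).
#' @return A `regressor_spec` object.
#' @examples
#' regressor_spec("RF", seed = 7)
#' @export
regressor_spec <- function(family, hyperparams = list(), seed = 1L) {
  family <- match.arg(family, REGRESSOR_FAMILIES)
  hp <- utils::modifyList(default_hyperparams(family), hyperparams)
  structure(list(family = family, hyperparams = hp, seed = as.integer(seed)),
            class = "regressor_spec")
}

#' Construct a calibration dataset for one stratum
#'
#' Frame-level univariate pairs of SDK-estimated and reference shoulder
#' angles from a single stratum (one subject x exercise x distance x arm);
#' personalized calibration never pools strata.
#'
#' @param x SDK-derived alpha samples (degrees).
#' @param y Reference (mocap-derived) alpha samples (degrees), matched to
#'   `x`.
#' @param meta Named list carrying `subject_id`, `exercise`, `distance`,
#'   `arm` (optional but recommended).
#' @return A `calibration_dataset`.
#' @export
calibration_dataset <- function(x, y, meta = list()) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (anyNA(x) || anyNA(y)) stop("calibration data must be complete", call. = FALSE)
  structure(list(x = x, y = y, meta = meta), class = "calibration_dataset")
}

stratum_label <- function(meta) {
  paste(meta$subject_id %||% "?", meta$exercise %||% "?",
        meta$distance %||% "?", meta$arm %||% "", sep = "/")
}

#' Shuffled train/test split of a calibration dataset
#'
#' Reproducible shuffled split; by convention 80% of the stratum's samples
#' train the regressor and the remaining 20% stay unseen for evaluation.
#'
#' @param dataset A [calibration_dataset()] with n >= 10.
#' @param train_frac Training fraction in (0, 1); default 0.8.
#' @param seed Integer seed controlling the shuffle.
#' @return A list with `train` and `test` calibration datasets (disjoint,
#'   union complete) and `split_seed`.
#' @export
split_shuffle <- function(dataset, train_frac = 0.8, seed = 1L) {
  stopifnot(inherits(dataset, "calibration_dataset"))
  n <- length(dataset$x)
  if (n < 10) {
    stop("stratum too small to calibrate (n = ", n, " < 10): ",
         stratum_label(dataset$meta), call. = FALSE)
  }
  if (!is.numeric(train_frac) || train_frac <= 0 || train_frac >= 1) {
    stop("`train_frac` must be strictly between 0 and 1", call. = FALSE)
  }
  n_train <- round(train_frac * n)
  n_train <- min(max(n_train, 1L), n - 1L)
  idx <- withr::with_seed(seed, sample.int(n))
  tr <- sort(idx[seq_len(n_train)])
  te <- sort(idx[-seq_len(n_train)])
  list(
    train = calibration_dataset(dataset$x[tr], dataset$y[tr], dataset$meta),
    test = calibration_dataset(dataset$x[te], dataset$y[te], dataset$meta),
    split_seed = as.integer(seed)
  )
}

#' Fit a calibration mapping
#'
#' Fits the specified regressor family to one stratum's training pairs,
#' producing a deterministic univariate mapping from SDK angles to
#' reference angles. Regularized linear families use penalties expressed
#' per observation on standardized inputs, so at the documented defaults
#' they reduce numerically to ordinary linear regression, mirroring how
#' weak regularization behaves on well-conditioned strata.
#'
#' @param spec A [regressor_spec()].
#' @param train A [calibration_dataset()].
#' @return A `calibrator` object supporting [predict()] on numeric vectors;
#'   carries `train_mae` / `train_rmse`.
#' @export
fit_calibrator <- function(spec, train) {
  stopifnot(inherits(spec, "regressor_spec"), inherits(train, "calibration_dataset"))
  x <- train$x
  y <- train$y
  if (length(x) == 0) stop("empty training set", call. = FALSE)
  if (var(x) == 0) {
    stop("degenerate stratum (constant x): ", stratum_label(train$meta),
         call. = FALSE)
  }
  hp <- spec$hyperparams
  df <- data.frame(x = x, y = y)
  # glmnet needs >= 2 columns; the zero column is inert
  xmat <- function(v) cbind(x = v, zero = 0)
  fitted <- switch(spec$family,
    LR = {
      m <- lm(y ~ x, data = df)
      list(model = m, fun = function(v) unname(predict(m, data.frame(x = v))))
    },
    PR = {
      m <- lm(y ~ poly(x, degree = hp$degree, raw = TRUE), data = df)
      list(model = m, fun = function(v) unname(predict(m, data.frame(x = v))))
    },
    RR = ,
    LaR = ,
    ER = {
      alpha <- switch(spec$family, RR = 0, LaR = 1, ER = hp$mixing)
      lam <- hp$penalty / length(x)
      m <- glmnet::glmnet(xmat(x), y, alpha = alpha, lambda = lam,
                          standardize = TRUE)
      list(model = m, fun = function(v) as.numeric(predict(m, xmat(v), s = lam)))
    },
    SVR_linear = {
      # scale = FALSE keeps cost/epsilon in degrees (x and y share units)
      m <- e1071::svm(y ~ x, data = df, kernel = "linear", cost = hp$cost,
                      epsilon = hp$epsilon, scale = FALSE)
      list(model = m, fun = function(v) unname(predict(m, data.frame(x = v))))
    },
    SVR_RBF = {
      gamma <- hp$gamma %||% (1 / var(x)) # scale-based default
      m <- e1071::svm(y ~ x, data = df, kernel = "radial", cost = hp$cost,
                      epsilon = hp$epsilon, gamma = gamma, scale = FALSE)
      list(model = m, fun = function(v) unname(predict(m, data.frame(x = v))))
    },
    DT = {
      m <- rpart::rpart(y ~ x, data = df,
                        control = rpart::rpart.control(
                          maxdepth = hp$max_depth, cp = hp$cp, xval = 0))
      list(model = m, fun = function(v) unname(predict(m, data.frame(x = v))))
    },
    RF = {
      m <- ranger::ranger(y ~ x, data = df, num.trees = hp$num_trees,
                          min.node.size = hp$min_node_size,
                          seed = spec$seed, num.threads = 1)
      list(model = m, fun = function(v) {
        predict(m, data.frame(x = v), num.threads = 1)$predictions
      })
    },
    GB = {
      m <- xgboost::xgboost(
        matrix(x, ncol = 1), y, nrounds = hp$nrounds,
        learning_rate = hp$eta, max_depth = hp$max_depth,
        objective = "reg:squarederror", nthreads = 1, verbosity = 0,
        seed = spec$seed
      )
      list(model = m, fun = function(v) predict(m, matrix(v, ncol = 1)))
    }
  )
  resid <- fitted$fun(x) - y
  structure(
    list(spec = spec, model = fitted$model, predict_fun = fitted$fun,
         train_mae = mean(abs(resid)), train_rmse = sqrt(mean(resid^2)),
         meta = train$meta),
    class = "calibrator"
  )
}

#' @export
predict.calibrator <- function(object, newdata, ...) {
  stopifnot(is.numeric(newdata))
  object$predict_fun(newdata)
}

#' @exportS3Method base::print
print.calibrator <- function(x, ...) {
  cat(sprintf("<calibrator> %s on %s: train MAE %.3f deg, RMSE %.3f deg\n",
              x$spec$family, stratum_label(x$meta), x$train_mae, x$train_rmse))
  invisible(x)
}

#' Evaluate a fitted calibrator on held-out data
#'
#' Test-set MAE/RMSE of the calibrated mapping, alongside the uncalibrated
#' baseline (identity mapping, i.e. using the SDK angle as-is) computed on
#' the same test samples.
#'
#' @param calibrator A fitted [fit_calibrator()] object.
#' @param test A [calibration_dataset()] disjoint from the training data.
#' @param split_seed Seed of the split that produced `test` (recorded for
#'   provenance).
#' @return A one-row tibble (`CalibrationResult`): family, stratum meta,
#'   train/test MAE and RMSE, baseline test MAE/RMSE, split seed.
#' @export
evaluate_calibration <- function(calibrator, test, split_seed = NA_integer_) {
  stopifnot(inherits(calibrator, "calibrator"),
            inherits(test, "calibration_dataset"))
  pred <- predict(calibrator, test$x)
  err <- pred - test$y
  base <- test$x - test$y
  meta <- calibrator$meta
  tibble(
    family = calibrator$spec$family,
    subject = meta$subject_id %||% NA_character_,
    exercise = meta$exercise %||% NA_character_,
    distance = meta$distance %||% NA_real_,
    arm = meta$arm %||% NA_character_,
    train_mae = calibrator$train_mae, train_rmse = calibrator$train_rmse,
    test_mae = mean(abs(err)), test_rmse = sqrt(mean(err^2)),
    baseline_test_mae = mean(abs(base)), baseline_test_rmse = sqrt(mean(base^2)),
    n_train = NA_integer_, n_test = length(test$x),
    split_seed = as.integer(split_seed)
  )
}

#' Compare the ten regressor families across calibration strata
#'
#' Runs the full personalized-calibration grid: for every stratum (one
#' subject x exercise x distance), one shuffled 80/20 split is drawn and
#' each regressor family is fitted on the training portion and evaluated on
#' the held-out portion, next to the uncalibrated baseline. Stochastic
#' fitters receive per-stratum seeds derived deterministically from the
#' global seed. A stratum whose fit fails is recorded and skipped, not
#' fatal.
#'
#' @param datasets A list of [calibration_dataset()] objects (one per
#'   stratum).
#' @param families Regressor families to include (default all ten).
#' @param train_frac Training fraction (default 0.8).
#' @param seed Global integer seed.
#' @return A `calibration_comparison`: list with `results` (stratum x
#'   family grid), `by_family` (mean +/- population sd across strata),
#'   `by_subject` (before/after per subject) and `failures`.
#' @export
run_model_comparison <- function(datasets, families = REGRESSOR_FAMILIES,
                                 train_frac = 0.8, seed = 1L) {
  stopifnot(length(datasets) >= 1)
  families <- match.arg(families, REGRESSOR_FAMILIES, several.ok = TRUE)
  rows <- list()
  failures <- list()
  for (ds in datasets) {
    label <- stratum_label(ds$meta)
    split_seed <- derive_seed(seed, "split", label)
    sp <- tryCatch(split_shuffle(ds, train_frac, seed = split_seed),
                   error = function(e) e)
    if (inherits(sp, "error")) {
      failures[[length(failures) + 1L]] <- tibble(stratum = label,
                                                  error = conditionMessage(sp))
      next
    }
    for (fam in families) {
      res <- tryCatch({
        spec <- regressor_spec(fam, seed = derive_seed(seed, "fit", label, fam))
        cal <- fit_calibrator(spec, sp$train)
        out <- evaluate_calibration(cal, sp$test, split_seed = sp$split_seed)
        out$n_train <- length(sp$train$x)
        out
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1L]] <- tibble(
          stratum = paste(label, fam), error = conditionMessage(res))
      } else {
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  results <- dplyr::bind_rows(rows)
  by_family <- results |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(
      test_mae_mean = mean(.data$test_mae), test_mae_sd = sd_pop(.data$test_mae),
      test_rmse_mean = mean(.data$test_rmse), test_rmse_sd = sd_pop(.data$test_rmse),
      baseline_mae_mean = mean(.data$baseline_test_mae),
      baseline_rmse_mean = mean(.data$baseline_test_rmse),
      n_strata = dplyr::n(), .groups = "drop"
    )
  by_subject <- results |>
    dplyr::group_by(.data$subject, .data$distance) |>
    dplyr::summarise(
      before_mae = mean(.data$baseline_test_mae),
      after_mae = min(.data$test_mae),
      before_rmse = mean(.data$baseline_test_rmse),
      after_rmse = min(.data$test_rmse),
      best_family = .data$family[which.min(.data$test_mae)],
      .groups = "drop"
    )
  structure(
    list(results = results, by_family = by_family, by_subject = by_subject,
         failures = dplyr::bind_rows(failures)),
    class = "calibration_comparison"
  )
}

#' @exportS3Method base::print
print.calibration_comparison <- function(x, ...) {
  cat(sprintf("<calibration_comparison> %d results over %d strata; %d failures\n",
              nrow(x$results), length(unique(paste(x$results$subject,
                                                   x$results$exercise,
                                                   x$results$distance))),
              nrow(x$failures)))
  print(x$by_family)
  invisible(x)
}
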