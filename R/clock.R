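#' Subset a beta matrix to probes mappable in all requested species
#'
#' Array probes are designed on sequence conserved across mammals, but
#' each probe aligns uniquely only to a subset of genomes. Clocks use
#' only probes mappable in every species they are trained on
#' (intersection semantics for multi-species clocks).
#'
#' @param beta Probes x samples beta matrix.
#' @param annotation Probe annotation with the `mappable_species` list
#'   column.
#' @param species Character vector of required species labels.
#' @return The row-subset beta matrix, probe order preserved.
#' @export
subset_mappable_probes <- function(beta, annotation, species) {
  idx <- match(rownames(beta), annotation$probe_id)
  if (anyNA(idx)) {
    stop("probes missing from annotation: ",
         paste(utils::head(rownames(beta)[is.na(idx)], 3L), collapse = ", "))
  }
  keep <- vapply(annotation$mappable_species[idx],
                 function(s) all(species %in% s), logical(1L))
  if (!any(keep)) {
    stop("no probes mappable in all of: ", paste(species, collapse = ", "))
  }
  beta[keep, , drop = FALSE]
}

#' Fit an elastic-net epigenetic clock
#'
#' Regresses transformed age on methylation betas with the elastic net
#' at mixing parameter `alpha = 0.5` (midpoint of ridge and lasso, not
#' tuned), via `glmnet::cv.glmnet`: the penalty is chosen from a
#' 100-value log-spaced grid spanning `lambda_max` down to
#' `1e-4 * lambda_max` by minimizing the mean 10-fold cross-validated
#' squared error (the CV-minimum rule; equal-error ties resolve to the
#' larger, sparser lambda). Fold assignment is a seeded uniform shuffle
#' cut into contiguous blocks, so fits are reproducible. Predictors are
#' standardized internally; coefficients are reported on the beta
#' scale. Probes with any missing value among the training samples are
#' dropped (count recorded), as are zero-variance probes.
#'
#' @param beta Probes x samples beta matrix.
#' @param samples Sample sheet covering `colnames(beta)`.
#' @param transform [age_transform()] defining the target scale.
#' @param n_folds Internal CV folds (default 10).
#' @param seed Integer seed for fold assignment.
#' @return An object of class `clock_model`: `intercept`,
#'   `coefficients` (named numeric, nonzero only), `transform`,
#'   `alpha`, `lambda`, and `training` metadata (species, tissues,
#'   sample count, probe universe, dropped-probe counts, seed).
#' @export
fit_clock <- function(beta, samples, transform = age_transform("identity"),
                      n_folds = 10L, seed = 1L) {
  validate_beta_matrix(beta)
  stopifnot(inherits(transform, "age_transform"))
  samples <- align_samples(beta, samples)
  n <- ncol(beta)
  if (n < n_folds) stop("fewer samples (", n, ") than CV folds (", n_folds, ")")

  has_na <- rowSums(is.na(beta)) > 0L
  n_dropped_na <- sum(has_na)
  if (n_dropped_na > 0L) {
    message("dropping ", n_dropped_na, " probe(s) with missing training values")
  }
  beta_fit <- beta[!has_na, , drop = FALSE]
  rv <- rowSums((beta_fit - rowMeans(beta_fit))^2)
  beta_fit <- beta_fit[rv > 0, , drop = FALSE]
  if (nrow(beta_fit) < 2L) stop("fewer than 2 usable probes")

  y <- transform_age(transform, samples$age_years, samples)
  if (stats::var(y) == 0) stop("all-constant target age")

  set.seed(as.integer(seed))
  perm <- sample.int(n)
  foldid <- integer(n)
  foldid[perm] <- rep(seq_len(n_folds), each = ceiling(n / n_folds),
                      length.out = n)

  cv <- glmnet::cv.glmnet(t(beta_fit), y, alpha = 0.5, foldid = foldid,
                          nlambda = 100, lambda.min.ratio = 1e-4,
                          standardize = TRUE, family = "gaussian",
                          thresh = 1e-5)
  co <- as.matrix(stats::coef(cv, s = "lambda.min"))[, 1L]
  nz <- co[-1L][co[-1L] != 0]

  structure(list(intercept = unname(co[1L]),
                 coefficients = nz,
                 transform = transform,
                 alpha = 0.5,
                 lambda = cv$lambda.min,
                 training = list(species = unique(samples$species),
                                 tissues = unique(samples$tissue),
                                 n_samples = n,
                                 probe_universe = rownames(beta_fit),
                                 n_dropped_missing = n_dropped_na,
                                 n_dropped_constant = sum(rv == 0),
                                 seed = as.integer(seed))),
            class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf("elastic-net clock (alpha = %.1f): %d nonzero CpGs of %d, lambda = %.4g\n",
              x$alpha, length(x$coefficients),
              length(x$training$probe_universe), x$lambda))
  cat("  target scale:", x$transform$kind, "| trained on",
      x$training$n_samples, "samples (",
      paste(x$training$species, collapse = ", "), ")\n")
  invisible(x)
}

#' Predict DNAm age with a fitted clock
#'
#' The linear predictor `intercept + sum_j coef_j * beta_ij` is
#' inverse-transformed to years with each sample's own species
#' constants, so one dual-species model yields ages on each species'
#' own time scale. A sample missing a beta for any model probe gets an
#' `NA` prediction (flagged); a model probe absent from the matrix is
#' an error.
#'
#' @param model A `clock_model`.
#' @param beta Probes x samples beta matrix covering the model probes.
#' @param samples Sample sheet covering `colnames(beta)` (supplies
#'   species constants for the inverse transform).
#' @return Named numeric vector of predicted ages in years; the
#'   transformed-scale predictions are attached as attribute
#'   `"transformed"`.
#' @export
predict_age <- function(model, beta, samples) {
  stopifnot(inherits(model, "clock_model"))
  probes <- names(model$coefficients)
  missing_probes <- setdiff(probes, rownames(beta))
  if (length(missing_probes) > 0L) {
    stop("model probes missing from matrix: ",
         paste(utils::head(missing_probes, 3L), collapse = ", "))
  }
  samples <- align_samples(beta, samples)
  sub <- beta[probes, , drop = FALSE]
  lin <- model$intercept + as.vector(crossprod(sub, model$coefficients))
  lin[colSums(is.na(sub)) > 0L] <- NA_real_
  names(lin) <- colnames(beta)
  years <- invert_age(model$transform, lin, samples)
  names(years) <- colnames(beta)
  attr(years, "transformed") <- lin
  years
}

#' Evaluate age predictions
#'
#' The two accuracy summaries of clock figures: the Pearson correlation
#' R between predicted and actual age, and the median absolute error
#' (median over samples of |predicted - actual|, in target units).
#' Incomplete pairs are dropped. Zero-variance predictions (a
#' degenerate fit) give `r = 0` with `degenerate = TRUE` rather than an
#' error, so pipelines keep running.
#'
#' @param predicted,actual Numeric vectors of equal length (>= 2
#'   complete pairs).
#' @return List with `pearson_r`, `median_abs_error`, `n`,
#'   `degenerate`.
#' @export
evaluate_predictions <- function(predicted, actual) {
  stopifnot(length(predicted) == length(actual))
  ok <- !is.na(predicted) & !is.na(actual)
  if (sum(ok) < 2L) stop("fewer than 2 complete prediction pairs")
  predicted <- predicted[ok]
  actual <- actual[ok]
  degenerate <- stats::sd(predicted) == 0 || stats::sd(actual) == 0
  r <- if (degenerate) 0 else stats::cor(predicted, actual)
  list(pearson_r = r,
       median_abs_error = stats::median(abs(predicted - actual)),
       n = sum(ok),
       degenerate = degenerate)
}

#' Leave-one-sample-out cross-validation of a clock
#'
#' For every sample, a full [fit_clock()] — including the internal
#' 10-fold penalty search with freshly drawn folds — is run on the
#' remaining `n - 1` samples and the held-out sample is predicted, so
#' no information from the held-out sample enters fitting. Accuracy is
#' summarized on the target's natural units: relative age for the
#' relative transform, years otherwise.
#'
#' @param beta Probes x samples beta matrix (n >= 10).
#' @param samples Sample sheet.
#' @param transform [age_transform()] for the target scale.
#' @param n_folds Internal CV folds per fit.
#' @param seed Base seed; iteration i uses `seed + i` for its fold
#'   draw.
#' @return List with `predictions` (data.frame `sample_id`, `actual`,
#'   `predicted`, in target units, plus `predicted_years`) and
#'   `evaluation` (see [evaluate_predictions()]).
#' @export
loocv_evaluate <- function(beta, samples, transform = age_transform("identity"),
                           n_folds = 10L, seed = 1L) {
  validate_beta_matrix(beta)
  samples <- align_samples(beta, samples)
  n <- ncol(beta)
  if (n < 10L) stop("LOOCV needs at least 10 samples")
  pred_t <- pred_y <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    fit <- fit_clock(beta[, -i, drop = FALSE], samples[-i, , drop = FALSE],
                     transform = transform, n_folds = n_folds,
                     seed = as.integer(seed) + i)
    if (length(fit$coefficients) == 0L) {
      # intercept-only model: constant prediction
      lin <- fit$intercept
    } else {
      pr <- predict_age(fit, beta[, i, drop = FALSE],
                        samples[i, , drop = FALSE])
      lin <- attr(pr, "transformed")
      pred_y[i] <- pr[[1L]]
    }
    pred_t[i] <- lin
    if (length(fit$coefficients) == 0L) {
      pred_y[i] <- invert_age(transform, lin, samples[i, , drop = FALSE])
    }
  }
  actual_t <- transform_age(transform, samples$age_years, samples)
  if (transform$kind == "relative") {
    actual <- actual_t
    predicted <- pred_t
  } else {
    actual <- samples$age_years
    predicted <- pred_y
  }
  list(predictions = data.frame(sample_id = samples$sample_id,
                                actual = actual, predicted = predicted,
                                predicted_years = pred_y,
                                stringsAsFactors = FALSE),
       evaluation = evaluate_predictions(predicted, actual))
}

#' Pool per-species datasets onto their shared probe universe
#'
#' Subsets each dataset to probes mappable in every species involved
#' (via [subset_mappable_probes()]), checks the universes agree, and
#' concatenates samples.
#'
#' @param datasets List of `list(beta = , samples = )` pairs.
#' @param annotation Probe annotation with `mappable_species`.
#' @return List with pooled `beta` and `samples`.
#' @export
pool_datasets <- function(datasets, annotation) {
  stopifnot(length(datasets) >= 1L)
  all_species <- unique(unlist(lapply(datasets,
                                      function(d) unique(d$samples$species))))
  subs <- lapply(datasets, function(d) {
    subset_mappable_probes(d$beta, annotation, all_species)
  })
  probes <- Reduce(intersect, lapply(subs, rownames))
  if (length(probes) == 0L) stop("probe universes are disjoint across datasets")
  beta <- do.call(cbind, lapply(subs, function(b) b[probes, , drop = FALSE]))
  samples <- do.call(rbind, lapply(datasets, function(d) {
    align_samples(d$beta, d$samples)
  }))
  rownames(samples) <- NULL
  validate_beta_matrix(beta)
  list(beta = beta, samples = samples)
}

#' Fit a dual-species epigenetic clock
#'
#' Samples from two (or more) species are pooled on the probes mappable
#' in all of them and a single elastic net is fitted as in
#' [fit_clock()]. In `"chronological"` mode the target is the piecewise
#' log-linear transform of age with each species' own maturity; in
#' `"relative"` mode it is relative age (age / maximum lifespan), the
#' scale on which species with ~29-fold lifespan differences become
#' comparable. With a single species the result equals the
#' corresponding [fit_clock()] call.
#'
#' @param datasets List of `list(beta = , samples = )`, typically one
#'   per species.
#' @param annotation Probe annotation with `mappable_species`.
#' @param mode `"chronological"` or `"relative"`.
#' @param k Offset (years) of the log-linear transform.
#' @param n_folds,seed As in [fit_clock()].
#' @return A `clock_model` fitted on the pooled data.
#' @export
fit_dual_species_clock <- function(datasets, annotation,
                                   mode = c("chronological", "relative"),
                                   k = 1, n_folds = 10L, seed = 1L) {
  mode <- match.arg(mode)
  pooled <- pool_datasets(datasets, annotation)
  transform <- if (mode == "chronological") {
    age_transform("loglinear", k = k)
  } else {
    age_transform("relative")
  }
  fit_clock(pooled$beta, pooled$samples, transform = transform,
            n_folds = n_folds, seed = seed)
}

#' Serialize a clock model to JSON text
#'
#' @param model A `clock_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clock_model <- function(model, path) {
  stopifnot(inherits(model, "clock_model"))
  obj <- list(intercept = model$intercept,
              coefficients = as.list(model$coefficients),
              transform = list(kind = model$transform$kind,
                               k = model$transform$k),
              alpha = model$alpha, lambda = model$lambda,
              training = model$training)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a clock model from JSON text
#'
#' @param path Path written by [write_clock_model()].
#' @return A `clock_model`.
#' @export
read_clock_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(intercept = obj$intercept,
                 coefficients = unlist(obj$coefficients),
                 transform = age_transform(obj$transform$kind,
                                           k = obj$transform$k),
                 alpha = obj$alpha, lambda = obj$lambda,
                 training = obj$training),
            class = "clock_model")
}
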