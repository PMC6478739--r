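## Transition potential modelling: balanced sampling, a single-hidden-layer
## back-propagation network over the driver stack, and Skill Measure
## validation.  One model per country per direction; each model has one
## transition and one persistence class (T = 1, P = 1), so a balanced test
## set has expected accuracy E(A) = 0.5 under chance.

#' Draw balanced training/testing samples
#'
#' Randomly selects equal-sized samples from the changed pixels and from the
#' pixels that were eligible to change but persisted, then splits each class
#' 50/50 into training and testing halves. With equal class sizes the prior
#' probability of change is 0.5 by construction.
#'
#' @param change a `change_grid` covering the calibration period.
#' @param eligible logical matrix: pixels eligible to change (for loss models,
#'   forest at both epochs; for gain models, non-forest at both epochs minus
#'   urban/water).
#' @param direction `"loss"` or `"gain"`.
#' @param n_per_class samples per class; clamped (with a warning recorded in
#'   the plan) to the smaller pool. Default `min(pools, 10000)`.
#' @param seed RNG seed for reproducible sampling.
#' @return a `sampling_plan` list: index vectors `train_changed`,
#'   `train_persist`, `test_changed`, `test_persist`, plus metadata.
#' @export
draw_samples <- function(change, eligible, direction = c("loss", "gain"),
                         n_per_class = NULL, seed = 1) {
  direction <- match.arg(direction)
  stopifnot_same_shape(change, eligible)
  code <- if (direction == "loss") CHANGE_LOSS else CHANGE_GAIN
  persist_code <- if (direction == "loss") CHANGE_FOREST_PERSIST else
    CHANGE_NONFOREST_PERSIST
  changed_pool <- which(!is.na(change) & change == code)
  persist_pool <- which(!is.na(change) & change == persist_code & eligible)
  pool_min <- min(length(changed_pool), length(persist_pool))
  if (pool_min < 2)
    stop("need at least 2 pixels in each of the changed and persistent pools")
  n_req <- if (is.null(n_per_class)) min(pool_min, 10000L) else n_per_class
  clamped <- n_req > pool_min
  if (clamped) {
    warning(sprintf("n_per_class reduced from %d to pool size %d", n_req, pool_min))
    n_req <- pool_min
  }
  n <- as.integer(n_req)
  with_seed(seed, {
    ch <- sample(changed_pool, n)
    pe <- sample(persist_pool, n)
  })
  n_train <- n %/% 2
  structure(list(
    direction = direction,
    train_changed = ch[seq_len(n_train)],
    test_changed = ch[(n_train + 1):n],
    train_persist = pe[seq_len(n_train)],
    test_persist = pe[(n_train + 1):n],
    n_per_class = n, clamped = clamped, seed = seed,
    eligible = which(eligible)
  ), class = "sampling_plan")
}

#' Skill Measure
#'
#' Chance-corrected accuracy of a transition model:
#' \deqn{SM = (A - E(A)) / (1 - E(A)), \quad E(A) = 1/(T+P)}
#' where `A` is the measured test accuracy, `T` the number of transitions in
#' the sub-model and `P` the number of persistence classes. SM is 1 for a
#' perfect prediction, 0 for chance-level accuracy and negative (down to -1
#' when T = P = 1) for worse than chance.
#'
#' @param A measured accuracy in \[0, 1\].
#' @param T number of transitions (>= 1).
#' @param P number of persistence classes (>= 1).
#' @return the Skill Measure.
#' @examples
#' skill_measure(0.78, 1, 1)  # 0.56
#' @export
skill_measure <- function(A, T = 1, P = 1) {
  if (T < 1 || P < 1) stop("T and P must each be >= 1")
  if (A < 0 || A > 1) stop("A must be in [0, 1]")
  E <- 1 / (T + P)
  if (1 - E == 0) stop("expected accuracy is 1 (T + P = 1); SM undefined")
  (A - E) / (1 - E)
}

#' Train a transition potential model
#'
#' Fits a single-hidden-layer feed-forward network (logistic activations,
#' back-propagation via [nnet::nnet()]) on the balanced training half of a
#' sampling plan, using the z-scored driver stack as predictors. Drivers with
#' zero variance over the eligible pixels are excluded with a warning. The
#' fitted model predicts a change probability for every eligible pixel (the
#' transition potential map); test-half accuracy and the Skill Measure are
#' recorded with T = 1 transition and P = 1 persistence class.
#'
#' @param plan a `sampling_plan` from [draw_samples()].
#' @param drivers a `driver_stack` from [build_driver_stack()].
#' @param hidden hidden-layer width; default `max(3, ceiling((k + 1) / 2))`
#'   for k retained drivers.
#' @param decay,maxit weight decay and iteration cap passed to the optimiser.
#' @param seed RNG seed for weight initialisation.
#' @return a `tpm_model`: list with the fitted net, `tpm` (probability grid,
#'   `NA` off the eligible set), `validation` (A, T, P, SM), scaling and
#'   architecture metadata. Has `print`, `summary` and `predict` methods.
#' @export
train_tpm <- function(plan, drivers, hidden = NULL, decay = 5e-4,
                      maxit = 200, seed = 1) {
  if (!inherits(plan, "sampling_plan")) stop("`plan` must come from draw_samples()")
  if (!inherits(drivers, "driver_stack")) stop("`drivers` must be a driver_stack")
  elig <- plan$eligible
  X_all <- vapply(drivers, function(g) as.vector(g)[elig],
                  numeric(length(elig)))
  mu <- colMeans(X_all)
  sd_ <- apply(X_all, 2, stats::sd)
  keep <- sd_ > 0
  if (!all(keep))
    warning("constant driver(s) excluded: ",
            paste(names(drivers)[!keep], collapse = ", "))
  if (!any(keep)) stop("all drivers are constant over the eligible pixels")
  scale_fun <- function(idx) {
    X <- vapply(drivers, function(g) as.vector(g)[idx], numeric(length(idx)))
    sweep(sweep(X[, keep, drop = FALSE], 2, mu[keep]), 2, sd_[keep], "/")
  }
  tr_idx <- c(plan$train_changed, plan$train_persist)
  te_idx <- c(plan$test_changed, plan$test_persist)
  y_tr <- rep(c(1L, 0L), c(length(plan$train_changed), length(plan$train_persist)))
  y_te <- rep(c(1L, 0L), c(length(plan$test_changed), length(plan$test_persist)))
  k <- sum(keep)
  size <- if (is.null(hidden)) max(3L, ceiling((k + 1) / 2)) else hidden
  fit <- with_seed(seed,
    nnet::nnet(scale_fun(tr_idx), y_tr, size = size, decay = decay,
               maxit = maxit, entropy = TRUE, trace = FALSE))
  p_te <- as.vector(stats::predict(fit, scale_fun(te_idx)))
  A <- mean((p_te > 0.5) == y_te)
  sm <- skill_measure(A, T = 1, P = 1)
  tpm <- matrix(NA_real_, nrow(drivers[[1]]), ncol(drivers[[1]]))
  tpm[elig] <- as.vector(stats::predict(fit, scale_fun(elig)))
  structure(list(
    fit = fit, tpm = tpm,
    validation = list(A = A, T = 1L, P = 1L, SM = sm),
    direction = plan$direction,
    drivers_used = names(drivers)[keep],
    scaling = list(mu = mu[keep], sd = sd_[keep]),
    architecture = list(hidden = size, decay = decay, maxit = maxit),
    seed = seed, n_per_class = plan$n_per_class,
    mean_test_potential = mean(p_te)
  ), class = "tpm_model")
}

#' @export
print.tpm_model <- function(x, ...) {
  cat(sprintf("<tpm_model (%s): MLP %d-%d-1, A = %.3f, SM = %.3f>\n",
              x$direction, length(x$drivers_used), x$architecture$hidden,
              x$validation$A, x$validation$SM))
  invisible(x)
}

#' @export
summary.tpm_model <- function(object, ...) {
  v <- object$validation
  cat("Transition potential model (", object$direction, ")\n", sep = "")
  cat("  architecture : ", length(object$drivers_used), " inputs, ",
      object$architecture$hidden, " hidden units, logistic output\n", sep = "")
  cat("  drivers      : ", paste(object$drivers_used, collapse = ", "), "\n", sep = "")
  cat("  samples      : ", object$n_per_class, " per class (50/50 split)\n", sep = "")
  cat(sprintf("  test accuracy: %.4f   E(A) = %.2f (T = %d, P = %d)\n",
              v$A, 1 / (v$T + v$P), v$T, v$P))
  cat(sprintf("  Skill Measure: %.4f\n", v$SM))
  invisible(object)
}

#' @export
#' @rdname train_tpm
#' @param object a `tpm_model`.
#' @param newdata optionally a `driver_stack` to predict on; defaults to the
#'   stored transition potential map.
#' @param eligible logical matrix of pixels to predict for `newdata`.
#' @param ... unused.
predict.tpm_model <- function(object, newdata = NULL, eligible = NULL, ...) {
  if (is.null(newdata)) return(object$tpm)
  idx <- if (is.null(eligible)) seq_along(as.vector(newdata[[1]])) else which(eligible)
  X <- vapply(newdata[object$drivers_used],
              function(g) as.vector(g)[idx], numeric(length(idx)))
  X <- sweep(sweep(X, 2, object$scaling$mu), 2, object$scaling$sd, "/")
  out <- matrix(NA_real_, nrow(newdata[[1]]), ncol(newdata[[1]]))
  out[idx] <- as.vector(stats::predict(object$fit, X))
  out
}

#' Export a model validation report
#'
#' Writes the validation block of a [train_tpm()] model (accuracy, T, P,
#' Skill Measure, seed, architecture) as JSON.
#'
#' @param model a `tpm_model`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_validation_report <- function(model, path) {
  rep_ <- c(model$validation,
            list(direction = model$direction, seed = model$seed,
                 architecture = model$architecture,
                 drivers = model$drivers_used))
  jsonlite::write_json(rep_, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
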