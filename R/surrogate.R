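#' Assemble the surrogate training table
#'
#' Builds one row per (conversion level, heating rate): features are the
#' isoconversional temperature `T`, heating rate `beta`, conversion
#' `alpha` and conversion rate `rate` (1/min); the target is the
#' isoconversional activation energy at that conversion. Z-score scalers
#' for the four features are computed here and stored as attributes so
#' training and prediction share them.
#'
#' @param profiles list of `conversion_profile`s covering the profile grid.
#' @param ea_profile an `ea_profile` providing the target `Ea(alpha)`.
#' @return a data frame of class `surrogate_table` with columns `T`,
#'   `beta`, `alpha`, `rate`, `Ea`, and attributes `center` / `scale`.
#' @export
assemble_training_table <- function(profiles, ea_profile) {
  stopifnot(inherits(ea_profile, "data.frame"))
  iso <- temperatures_at_conversion(profiles, sort(unique(ea_profile$alpha)))
  key <- match(iso$alpha, ea_profile$alpha)
  if (any(is.na(key)))
    stop("conversion grid mismatch between profiles and the Ea profile")
  out <- data.frame(T = iso$T, beta = iso$beta, alpha = iso$alpha,
                    rate = iso$rate, Ea = ea_profile$Ea_kJ_per_mol[key])
  feats <- c("T", "beta", "alpha", "rate")
  ctr <- vapply(out[feats], mean, 0)
  scl <- vapply(out[feats], stats::sd, 0)
  scl[scl == 0] <- 1
  structure(out, center = ctr, scale = scl,
            class = c("surrogate_table", "data.frame"))
}

.activations <- list(
  ## exp clamped well above the useful range so overflow cannot poison the
  ## optimizer; the gradient is zeroed where the clamp is active
  exponential = list(f = function(z) exp(pmin(z, 30)),
                     df = function(z, a) a * (z < 30)),
  tanh = list(f = function(z) tanh(z), df = function(z, a) 1 - a^2),
  logistic = list(f = function(z) 1 / (1 + exp(-z)),
                  df = function(z, a) a * (1 - a)))
.out_activations <- list(
  sine = list(f = function(z) sin(z), df = function(z) cos(z)),
  identity = list(f = function(z) z, df = function(z) rep(1, length(z))))

.scale_features <- function(x, ctr, scl) {
  sweep(sweep(as.matrix(x), 2, ctr, "-"), 2, scl, "/")
}

.r2 <- function(obs, pred) {
  sst <- sum((obs - mean(obs))^2)
  ssr <- sum((obs - pred)^2)
  if (sst == 0) return(if (ssr < 1e-16) 1 else 0)
  1 - ssr / sst
}

#' Train a feed-forward surrogate for the activation-energy surface
#'
#' A single-hidden-layer perceptron (default 4-10-1: four inputs, ten
#' hidden units, one output) trained by quasi-Newton (BFGS) minimization
#' of the sum of squared errors with analytic gradients. The default
#' activations are exponential (hidden) and sine (output); sine outputs
#' require the target to be scaled, so the target is min-max scaled to
#' `[-0.9, 0.9]` and the scaler stored. The data are split at random
#' (seeded) into training / test / validation sets and the coefficient of
#' determination is reported on each.
#'
#' @param table a `surrogate_table` with at least 20 rows.
#' @param hidden_units hidden-layer width (default 10).
#' @param hidden_activation `"exponential"`, `"tanh"` or `"logistic"`.
#' @param output_activation `"sine"` or `"identity"`.
#' @param split fractions for train/test/validation; must sum to 1.
#' @param seed RNG seed controlling both the split and the weight
#'   initialization; the same seed and data reproduce the fit exactly.
#' @param maxit maximum BFGS iterations per start.
#' @param n_starts random restarts; the restart with the smallest
#'   validation error is kept (train-set error when no validation rows
#'   exist), mirroring the practice of retaining several candidate
#'   networks and choosing one by external validation.
#' @param decay L2 weight-decay coefficient(s) added to the sum-of-squares
#'   objective (on the scaled problem). A vector is treated as a candidate
#'   grid searched jointly with the restarts and resolved by validation
#'   error. Small data sets of a smooth surface need this to keep the
#'   network from exploiting the redundancy among the four correlated
#'   inputs; set 0 for pure least-squares interpolation.
#' @return an object of class `pyro_mlp` with the weights, scalers,
#'   per-split R-squared (`r2`), iteration counts and a `converged` flag.
#' @export
train_surrogate <- function(table, hidden_units = 10L,
                            hidden_activation = c("exponential", "tanh",
                                                  "logistic"),
                            output_activation = c("sine", "identity"),
                            split = c(train = 0.70, test = 0.15,
                                      validation = 0.15),
                            seed = 1L, maxit = 2000L, n_starts = 8L,
                            decay = c(1e-4, 3e-4, 1e-3)) {
  hidden_activation <- match.arg(hidden_activation)
  output_activation <- match.arg(output_activation)
  stopifnot(inherits(table, "data.frame"), hidden_units >= 1L)
  if (abs(sum(split) - 1) > 1e-9) stop("split fractions must sum to 1")
  n <- nrow(table)
  if (n < 20L) stop("need at least 20 rows to train, got ", n)
  feats <- c("T", "beta", "alpha", "rate")
  ctr <- attr(table, "center"); scl <- attr(table, "scale")
  if (is.null(ctr)) {
    ctr <- vapply(table[feats], mean, 0)
    scl <- vapply(table[feats], stats::sd, 0); scl[scl == 0] <- 1
  }
  X <- .scale_features(table[feats], ctr, scl)
  y <- table$Ea
  ymin <- min(y); ymax <- max(y)
  yr <- ymax - ymin
  ys <- if (yr > 0) -0.9 + 1.8 * (y - ymin) / yr else rep(0, n)

  set.seed(seed)
  idx <- sample.int(n)
  n_tr <- max(1L, round(split[[1]] * n))
  n_te <- max(1L, round(split[[2]] * n))
  i_tr <- idx[seq_len(n_tr)]
  i_te <- idx[n_tr + seq_len(min(n_te, n - n_tr))]
  i_va <- setdiff(idx, c(i_tr, i_te))

  act <- .activations[[hidden_activation]]
  oact <- .out_activations[[output_activation]]
  h <- as.integer(hidden_units)
  npar <- 4L * h + h + h + 1L
  unpack <- function(p) list(W1 = matrix(p[1:(4 * h)], 4, h),
                             b1 = p[4 * h + 1:h],
                             W2 = p[5 * h + 1:h],
                             b2 = p[6 * h + 1])
  fwd <- function(p, X) {
    w <- unpack(p)
    Z <- sweep(X %*% w$W1, 2, w$b1, "+")
    A <- act$f(Z)
    pre <- drop(A %*% w$W2) + w$b2
    list(Z = Z, A = A, pre = pre, out = oact$f(pre), w = w)
  }
  Xtr <- X[i_tr, , drop = FALSE]
  ttr <- ys[i_tr]
  Xva <- X[i_va, , drop = FALSE]
  mk_loss <- function(lam) function(p) {
    o <- fwd(p, Xtr)$out
    if (any(!is.finite(o))) return(1e10)
    sum((o - ttr)^2) + lam * sum(p^2)
  }
  mk_grad <- function(lam) function(p) {
    s <- fwd(p, Xtr)
    if (any(!is.finite(s$out))) return(rep(0, npar))
    d <- 2 * (s$out - ttr) * oact$df(s$pre)          # n
    gb2 <- sum(d)
    gW2 <- drop(crossprod(s$A, d))                    # h
    dZ <- outer(d, s$w$W2) * act$df(s$Z, s$A)         # n x h
    gW1 <- crossprod(Xtr, dZ)                         # 4 x h
    gb1 <- colSums(dZ)
    c(as.vector(gW1), gb1, gW2, gb2) + 2 * lam * p
  }
  select_err <- function(p, lam) {
    if (length(i_va)) {
      o <- fwd(p, Xva)$out
      if (any(!is.finite(o))) Inf else sum((o - ys[i_va])^2)
    } else mk_loss(lam)(p)
  }
  best <- NULL
  iters <- 0L
  for (lam in decay) {
    loss <- mk_loss(lam)
    grad <- mk_grad(lam)
    for (s in seq_len(n_starts)) {
      p0 <- stats::runif(npar, -0.5, 0.5)
      fit <- stats::optim(p0, loss, grad, method = "BFGS",
                          control = list(maxit = maxit, reltol = 1e-15))
      iters <- iters + fit$counts[["function"]]
      fit$sel <- select_err(fit$par, lam)
      fit$lam <- lam
      if (is.null(best) || fit$sel < best$sel) best <- fit
    }
  }
  unscale <- function(o) if (yr > 0) ymin + (o + 0.9) / 1.8 * yr else
    rep(ymin, length(o))
  pred_all <- unscale(fwd(best$par, X)$out)
  r2 <- c(train = .r2(y[i_tr], pred_all[i_tr]),
          test = if (length(i_te)) .r2(y[i_te], pred_all[i_te]) else NA_real_,
          validation = if (length(i_va)) .r2(y[i_va], pred_all[i_va])
                       else NA_real_)
  structure(list(par = best$par, hidden_units = h,
                 hidden_activation = hidden_activation,
                 output_activation = output_activation,
                 center = ctr, scale = scl,
                 target_min = ymin, target_range = yr,
                 split_idx = list(train = i_tr, test = i_te,
                                  validation = i_va),
                 r2 = r2, sse = best$value, decay = best$lam,
                 iterations = iters,
                 converged = best$convergence == 0, seed = seed),
            class = "pyro_mlp")
}

#' @export
print.pyro_mlp <- function(x, ...) {
  cat(sprintf(
    "MLP 4-%d-1 surrogate (%s hidden / %s output), BFGS%s\n",
    x$hidden_units, x$hidden_activation, x$output_activation,
    if (x$converged) "" else "  [NOT CONVERGED: best-so-far]"))
  cat(sprintf("  R2: train %.5f  test %.5f  validation %.5f\n",
              x$r2[["train"]], x$r2[["test"]], x$r2[["validation"]]))
  invisible(x)
}

#' Predict activation energy with a trained surrogate
#'
#' @param object a `pyro_mlp`.
#' @param newdata data frame with columns `T`, `beta`, `alpha`, `rate`.
#' @param ... unused.
#' @return predicted Ea, kJ/mol.
#' @export
predict.pyro_mlp <- function(object, newdata, ...) {
  feats <- c("T", "beta", "alpha", "rate")
  X <- .scale_features(newdata[feats], object$center, object$scale)
  w <- object
  h <- w$hidden_units
  W1 <- matrix(w$par[1:(4 * h)], 4, h)
  b1 <- w$par[4 * h + 1:h]
  W2 <- w$par[5 * h + 1:h]
  b2 <- w$par[6 * h + 1]
  A <- .activations[[w$hidden_activation]]$f(sweep(X %*% W1, 2, b1, "+"))
  o <- .out_activations[[w$output_activation]]$f(drop(A %*% W2) + b2)
  if (w$target_range > 0) w$target_min + (o + 0.9) / 1.8 * w$target_range
  else rep(w$target_min, length(o))
}

#' Serialize / restore a trained surrogate as structured text
#'
#' Writes the architecture, activations, weights and scalers to a YAML
#' file (plain text), and restores a `pyro_mlp` from one.
#'
#' @param model a `pyro_mlp`.
#' @param path file path.
#' @return `path` invisibly (write) / a `pyro_mlp` (read).
#' @export
write_surrogate <- function(model, path) {
  stopifnot(inherits(model, "pyro_mlp"))
  yaml::write_yaml(list(
    architecture = c(4L, model$hidden_units, 1L),
    hidden_activation = model$hidden_activation,
    output_activation = model$output_activation,
    par = model$par,
    center = as.list(model$center), scale = as.list(model$scale),
    target_min = model$target_min, target_range = model$target_range,
    r2 = as.list(model$r2), seed = model$seed), path, precision = 12)
  invisible(path)
}

#' @rdname write_surrogate
#' @export
read_surrogate <- function(path) {
  x <- yaml::read_yaml(path)
  structure(list(par = as.numeric(x$par),
                 hidden_units = x$architecture[[2]],
                 hidden_activation = x$hidden_activation,
                 output_activation = x$output_activation,
                 center = unlist(x$center), scale = unlist(x$scale),
                 target_min = x$target_min, target_range = x$target_range,
                 r2 = unlist(x$r2), seed = x$seed),
            class = "pyro_mlp")
}
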