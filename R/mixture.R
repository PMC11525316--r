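## von Mises mixture models of circular reproduction errors.
## Angles are degrees at the interface and radians internally; densities are
## per radian on the wrapped error, so the uniform component is 1/(2*pi).

# mean resultant length A1(kappa) = I1(kappa)/I0(kappa), overflow-safe
A1 <- function(kappa) {
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

# numeric inverse of A1: Fisher's piecewise start + Newton refinement
A1inv <- function(R) {
  stopifnot(R >= 0, R < 1)
  if (R < 1e-12) return(0)
  k <- if (R < 0.53) 2 * R + R^3 + 5 * R^5 / 6
       else if (R < 0.85) -0.4 + 1.39 * R + 0.43 / (1 - R)
       else 1 / (R^3 - 4 * R^2 + 3 * R)
  for (i in 1:25) {
    a <- A1(k)
    step <- (a - R) / (1 - a / k - a^2)    # d A1/d kappa
    k <- max(k - step, 1e-12)
    if (abs(step) < 1e-12 * max(1, k)) break
  }
  k
}

#' Convert between circular standard deviation and von Mises concentration
#'
#' Uses the wrapped-normal correspondence: the circular SD \eqn{\sigma}
#' (degrees) maps to mean resultant length
#' \eqn{\bar R = \exp(-\sigma_r^2 / 2)} (\eqn{\sigma_r} in radians), and the
#' concentration is \eqn{\kappa = A_1^{-1}(\bar R)} with
#' \eqn{A_1(\kappa) = I_1(\kappa)/I_0(\kappa)} inverted numerically. The two
#' functions are inverse to each other to better than 1e-6. Beyond roughly
#' 150 degrees the map saturates (\eqn{\kappa \to 0}).
#'
#' @param sd Circular standard deviation in degrees (> 0).
#' @return \code{sd_to_kappa}: the concentration \eqn{\kappa};
#'   \code{kappa_to_sd}: the circular SD in degrees.
#' @examples
#' kappa_to_sd(sd_to_kappa(29.1))  # 29.1
#' @export
sd_to_kappa <- function(sd) {
  if (any(!is.finite(sd)) || any(sd <= 0))
    stop("sd must be positive and finite", call. = FALSE)
  vapply(sd, function(s) A1inv(exp(-(s * pi / 180)^2 / 2)), numeric(1))
}

#' @param kappa von Mises concentration (> 0).
#' @rdname sd_to_kappa
#' @export
kappa_to_sd <- function(kappa) {
  if (any(!is.finite(kappa)) || any(kappa <= 0))
    stop("kappa must be positive and finite", call. = FALSE)
  sqrt(-2 * log(A1(kappa))) * 180 / pi
}

# von Mises density at x radians, mean 0, per radian; overflow-safe
dvm <- function(x, kappa) {
  exp(kappa * (cos(x) - 1)) / (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

#' Density of the standard mixture model of reproduction errors
#'
#' \eqn{f(x; g, \sigma) = (1-g)\,\phi(x; \kappa(\sigma)) + g/(2\pi)}: with
#' probability \eqn{1-g} the response is a von Mises draw around the target
#' (an in-memory response of precision \eqn{\sigma}); with probability
#' \eqn{g} it is a uniform guess.
#'
#' @param x Signed wrapped errors in degrees, \code{(-180, 180]}.
#' @param g Guess rate in \code{[0, 1]}.
#' @param sd Circular SD of the von Mises component, degrees.
#' @return Density per radian (integrates to 1 over the circle in radians).
#' @export
standard_pdf <- function(x, g, sd) {
  if (!is.finite(g) || g < 0 || g > 1) stop("g must be in [0, 1]", call. = FALSE)
  kappa <- sd_to_kappa(sd)
  (1 - g) * dvm(x * pi / 180, kappa) + g / (2 * pi)
}

#' Density of the swap model of reproduction errors
#'
#' Adds to the standard mixture a component of responses centered on
#' non-probed items: \eqn{f = g/(2\pi) + (1-g-\beta)\phi(x) +
#' (\beta/m)\sum_m \phi(x - x_m)} where the \eqn{x_m} are the non-target
#' positions relative to the target.
#'
#' @inheritParams standard_pdf
#' @param beta Swap rate; \code{g + beta <= 1}.
#' @param offsets Non-target offsets relative to the target, degrees: a
#'   numeric vector (one distractor per trial, recycled to \code{length(x)})
#'   or a list of numeric vectors parallel to \code{x}.
#' @return Density per radian.
#' @export
swap_pdf <- function(x, g, beta, sd, offsets) {
  if (!is.finite(g) || !is.finite(beta) || g < 0 || beta < 0 || g + beta > 1)
    stop("need g, beta >= 0 and g + beta <= 1", call. = FALSE)
  off <- as_offset_list(offsets, length(x))
  m <- lengths(off)
  if (beta > 0 && any(m < 1))
    stop("beta > 0 requires at least one non-target offset per trial",
         call. = FALSE)
  kappa <- sd_to_kappa(sd)
  xr <- x * pi / 180
  # NA-padded n x max(m) offset matrix -> one vectorized density evaluation
  off_mat <- matrix(NA_real_, length(x), max(c(1L, m)))
  if (any(m > 0))
    off_mat[cbind(rep(seq_along(off), m), sequence(m))] <-
      unlist(off) * pi / 180
  vm <- dvm(xr - off_mat, kappa)
  swap_term <- rowSums(vm, na.rm = TRUE) / pmax(m, 1L)
  g / (2 * pi) + (1 - g - beta) * dvm(xr, kappa) + beta * swap_term
}

as_offset_list <- function(offsets, n) {
  if (is.null(offsets)) return(rep(list(numeric(0)), n))
  if (is.list(offsets)) {
    if (length(offsets) != n) stop("offsets list must match x", call. = FALSE)
    return(lapply(offsets, as.numeric))
  }
  offsets <- as.numeric(offsets)
  if (length(offsets) == 1) offsets <- rep(offsets, n)
  if (length(offsets) != n) stop("offsets must match x", call. = FALSE)
  lapply(offsets, function(v) v[!is.na(v)])
}

#' Fit a mixture model of circular reproduction errors by maximum likelihood
#'
#' Fits the standard mixture (uniform guesses + von Mises around the target)
#' or the swap model (adding von Mises components around non-probed items) to
#' signed wrapped errors. Optimization is multi-start Nelder--Mead on
#' transformed parameters: \code{g} (and \code{g + beta} for the swap model)
#' live on the unit simplex via a softmax map and \code{sd} is boxed to
#' \code{[0.5, 100]} degrees by a logistic map; the best of six grid starts
#' is returned.
#'
#' @param errors Signed wrapped errors in degrees (response minus target,
#'   wrapped to \code{(-180, 180]}); at least 20 trials (50 for swap).
#' @param offsets Non-target offsets for the swap model (see
#'   \code{\link{swap_pdf}}); ignored for the standard model.
#' @param model \code{"standard"} or \code{"swap"}.
#' @return An object of class \code{mixture_fit} with components \code{g},
#'   \code{beta} (\code{NA} for the standard model), \code{sd},
#'   \code{kappa}, \code{loglik}, \code{n}, \code{model}.
#' @seealso \code{\link{simulate_standard}}, \code{\link{summarize_errors}}
#' @examples
#' e <- simulate_standard(500, g = 0.2, sd = 30, seed = 1)
#' fit <- fit_mixture(e)
#' coef(fit)
#' @export
fit_mixture <- function(errors, offsets = NULL,
                        model = c("standard", "swap")) {
  model <- match.arg(model)
  errors <- wrap_angle(as.numeric(errors))
  n <- length(errors)
  if (model == "standard" && n < 20)
    stop("need at least 20 errors to fit the standard model", call. = FALSE)
  if (model == "swap" && n < 50)
    stop("need at least 50 errors to fit the swap model", call. = FALSE)
  if (stats::sd(errors) == 0)
    warning("all errors identical; fit will sit on the parameter boundary")
  off <- if (model == "swap") as_offset_list(offsets, n) else NULL
  if (model == "swap" && any(vapply(off, length, integer(1)) < 1))
    stop("swap model needs at least one non-target offset per trial",
         call. = FALSE)

  sd_box <- function(s) 0.5 + 99.5 * stats::plogis(s)
  sd_unbox <- function(sd) stats::qlogis((sd - 0.5) / 99.5)
  negll <- if (model == "standard") {
    function(par) {
      g <- stats::plogis(par[1]); sd <- sd_box(par[2])
      -sum(log(pmax(standard_pdf(errors, g, sd), 1e-300)))
    }
  } else {
    function(par) {
      ea <- exp(par[1]); eb <- exp(par[2]); den <- 1 + ea + eb
      g <- ea / den; beta <- eb / den; sd <- sd_box(par[3])
      -sum(log(pmax(swap_pdf(errors, g, beta, sd, off), 1e-300)))
    }
  }
  starts <- if (model == "standard") {
    as.matrix(expand.grid(g = c(0.05, 0.3, 0.7), sd = c(15, 45)))
  } else {
    cbind(g = c(0.05, 0.2, 0.4, 0.1, 0.3, 0.6),
          beta = c(0.05, 0.1, 0.2, 0.3, 0.05, 0.2),
          sd = c(20, 40, 20, 40, 30, 30))
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    par0 <- if (model == "standard") {
      c(stats::qlogis(starts[i, "g"]), sd_unbox(starts[i, "sd"]))
    } else {
      rest <- 1 - starts[i, "g"] - starts[i, "beta"]
      c(log(starts[i, "g"] / rest), log(starts[i, "beta"] / rest),
        sd_unbox(starts[i, "sd"]))
    }
    opt <- stats::optim(par0, negll, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-10))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  par <- unname(best$par)
  fit <- if (model == "standard") {
    list(g = stats::plogis(par[1]), beta = NA_real_, sd = sd_box(par[2]))
  } else {
    ea <- exp(par[1]); eb <- exp(par[2]); den <- 1 + ea + eb
    list(g = ea / den, beta = eb / den, sd = sd_box(par[3]))
  }
  structure(
    c(fit,
      list(kappa = sd_to_kappa(fit$sd), loglik = -best$value, n = n,
           model = model, errors = errors, offsets = off,
           convergence = best$convergence)),
    class = "mixture_fit")
}

#' @rdname fit_mixture
#' @export
fit_standard <- function(errors) fit_mixture(errors, model = "standard")

#' @rdname fit_mixture
#' @export
fit_swap <- function(errors, offsets) {
  fit_mixture(errors, offsets = offsets, model = "swap")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("%s mixture model fit (n = %d)\n",
              if (x$model == "swap") "Swap" else "Standard", x$n))
  cat(sprintf("  guess rate g : %.3f\n", x$g))
  if (x$model == "swap") cat(sprintf("  swap rate b  : %.3f\n", x$beta))
  cat(sprintf("  circular SD  : %.2f degrees (kappa = %.3f)\n", x$sd, x$kappa))
  cat(sprintf("  log-likelihood: %.2f\n", x$loglik))
  invisible(x)
}

#' @export
summary.mixture_fit <- function(object, ...) {
  p_target <- if (object$model == "swap") 1 - object$g - object$beta
              else 1 - object$g
  out <- list(fit = object, p_target = p_target,
              aic = -2 * object$loglik + 2 * (2 + (object$model == "swap")))
  class(out) <- "summary.mixture_fit"
  out
}

#' @export
print.summary.mixture_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  on-target proportion: %.3f\n", x$p_target))
  cat(sprintf("  AIC: %.2f\n", x$aic))
  invisible(x)
}

#' @export
coef.mixture_fit <- function(object, ...) {
  if (object$model == "swap")
    c(g = object$g, beta = object$beta, sd = object$sd)
  else c(g = object$g, sd = object$sd)
}

#' @export
logLik.mixture_fit <- function(object, ...) {
  structure(object$loglik,
            df = if (object$model == "swap") 3 else 2,
            nobs = object$n, class = "logLik")
}

#' @export
residuals.mixture_fit <- function(object, ...) object$errors

#' @export
predict.mixture_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$errors else wrap_angle(newdata)
  if (object$model == "swap") {
    off <- if (is.null(newdata)) object$offsets else NULL
    if (is.null(off))
      stop("predict for a swap fit needs the original errors (newdata = NULL)",
           call. = FALSE)
    swap_pdf(x, object$g, object$beta, object$sd, off)
  } else {
    standard_pdf(x, object$g, object$sd)
  }
}

#' @export
simulate.mixture_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  replicate(nsim, simplify = FALSE, {
    if (object$model == "swap") {
      sim <- simulate_swap(object$n, object$g, object$beta, object$sd,
                           object$offsets)
      sim$error
    } else {
      simulate_standard(object$n, object$g, object$sd)
    }
  })
}

#' @export
plot.mixture_fit <- function(x, breaks = 36, ...) {
  graphics::hist(x$errors, breaks = seq(-180, 180, length.out = breaks + 1),
                 freq = FALSE, xlab = "error (degrees)",
                 main = sprintf("%s mixture fit", x$model), ...)
  grid_x <- seq(-179.5, 180, by = 0.5)
  dens <- standard_pdf(grid_x, x$g, if (x$model == "swap") x$sd else x$sd)
  if (x$model == "swap") {
    # marginal over stored offsets
    dens <- rowMeans(vapply(seq_along(x$offsets), function(i)
      swap_pdf(grid_x, x$g, x$beta, x$sd,
               rep(list(x$offsets[[i]]), length(grid_x))),
      numeric(length(grid_x))))
  }
  graphics::lines(grid_x, dens * pi / 180, col = 2, lwd = 2)
  invisible(x)
}

# von Mises sampler, mean 0, Best & Fisher (1979) rejection; radians
rvm <- function(n, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n); got <- 0
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    vals <- sign(u3[ok] - 0.5) * acos(pmax(-1, pmin(1, f[ok])))
    k <- length(vals)
    if (k) { out[got + seq_len(k)] <- vals; got <- got + k }
  }
  out
}

#' Simulate errors from the standard or swap mixture model
#'
#' Exact component-wise sampling: each trial is a uniform guess with
#' probability \code{g}, a swap to a non-target with probability \code{beta}
#' (swap model only), otherwise a von Mises draw around the target. Von Mises
#' variates use Best--Fisher rejection sampling. Results are signed wrapped
#' degrees in \code{(-180, 180]}.
#'
#' @param n Number of trials.
#' @param g Guess rate.
#' @param sd Circular SD of the von Mises component, degrees.
#' @param seed Optional integer seed (\code{set.seed}) for reproducibility.
#' @return \code{simulate_standard}: numeric vector of \code{n} errors.
#' @export
simulate_standard <- function(n, g, sd, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.finite(g) || g < 0 || g > 1) stop("g must be in [0, 1]", call. = FALSE)
  kappa <- sd_to_kappa(sd)
  guess <- stats::runif(n) < g
  err <- rvm(n, kappa) * 180 / pi
  err[guess] <- stats::runif(sum(guess), -180, 180)
  wrap_angle(err)
}

#' @param beta Swap rate (\code{g + beta <= 1}).
#' @param offsets Non-target offsets relative to the target, degrees (vector
#'   or list, see \code{\link{swap_pdf}}).
#' @rdname simulate_standard
#' @return \code{simulate_swap}: data frame with columns \code{error} and
#'   \code{component} (\code{"target"}, \code{"guess"} or \code{"swap"}).
#' @export
simulate_swap <- function(n, g, beta, sd, offsets, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.finite(g) || !is.finite(beta) || g < 0 || beta < 0 || g + beta > 1)
    stop("need g, beta >= 0 and g + beta <= 1", call. = FALSE)
  off <- as_offset_list(offsets, n)
  if (beta > 0 && any(vapply(off, length, integer(1)) < 1))
    stop("beta > 0 requires non-target offsets", call. = FALSE)
  kappa <- sd_to_kappa(sd)
  u <- stats::runif(n)
  comp <- ifelse(u < g, "guess", ifelse(u < g + beta, "swap", "target"))
  noise <- rvm(n, kappa) * 180 / pi
  err <- noise
  err[comp == "guess"] <- stats::runif(sum(comp == "guess"), -180, 180)
  sw <- which(comp == "swap")
  if (length(sw)) {
    centers <- vapply(off[sw], function(o) o[sample.int(length(o), 1)],
                      numeric(1))
    err[sw] <- centers + noise[sw]
  }
  data.frame(error = wrap_angle(err), component = comp,
             stringsAsFactors = FALSE)
}

#' Descriptive summaries of a reproduction-trial table
#'
#' Computes mean absolute reproduction error (participant means first, then
#' mean and SD across participants) by set size, by serial position within
#' set size 2, and by block crossed with set size.
#'
#' @param trials Data frame with columns \code{participant_id},
#'   \code{block}, \code{set_size}, \code{serial_position},
#'   \code{target_deg}, \code{response_deg}.
#' @return List of data frames \code{by_set_size},
#'   \code{by_serial_position}, \code{by_block}.
#' @export
summarize_errors <- function(trials) {
  need <- c("participant_id", "block", "set_size", "serial_position",
            "target_deg", "response_deg")
  if (!is.data.frame(trials) || !all(need %in% names(trials)))
    stop("trials must contain columns ", paste(need, collapse = ", "),
         call. = FALSE)
  trials$abs_err <- abs_error(trials$target_deg, trials$response_deg)
  across <- function(df, by) {
    pm <- stats::aggregate(abs_err ~ ., data = df[c("participant_id", by,
                                                    "abs_err")], FUN = mean)
    agg_m <- stats::aggregate(pm$abs_err, by = pm[by], FUN = mean)
    agg_s <- stats::aggregate(pm$abs_err, by = pm[by], FUN = stats::sd)
    out <- agg_m
    names(out)[ncol(out)] <- "mean_abs_error"
    out$sd_across_participants <- agg_s$x
    out
  }
  list(
    by_set_size = across(trials, "set_size"),
    by_serial_position = across(trials[trials$set_size == 2, , drop = FALSE],
                                "serial_position"),
    by_block = across(trials, c("block", "set_size")))
}
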