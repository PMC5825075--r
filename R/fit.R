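#' Fit the two-step hierarchical model of log excess cost
#'
#' Ordinary least squares on the natural log of excess cost, entered in two
#' pre-specified blocks: demographics first (age in years, male indicator),
#' then case-complexity (surgical status, dementia, admission severity as
#' the DRG cost weight, the modified Charlson index, and the number of
#' complications). Block entry is fixed-order -- no data-driven variable
#' selection -- so the reported full model is exactly the specified one.
#' For each predictor the fit reports the log-scale coefficient, its
#' standardised beta (relative importance), a back-transformed dollar effect
#' per unit, and that effect as a percentage of the sample mean excess cost;
#' plus R-squared for each step, adjusted R-squared, the overall F statistic
#' and n.
#'
#' Rows with a missing value in any model variable are dropped listwise
#' (count kept in `n_dropped`). All rows must have positive `extra_cost`,
#' i.e. the input is the above-average subset from
#' [select_above_average()].
#'
#' @param data Data.frame containing `extra_cost` and every predictor:
#'   `age`, `male` (or `sex`, from which `male` is derived), `surgical`,
#'   `dementia`, `cost_weight`, `charlson`, `n_complications`. Logical
#'   predictors are coerced to 0/1.
#' @param step1,step2 Ordered predictor blocks.
#' @param back_transform_method How the dollar effect is evaluated:
#'   `"mean_multiplicative"` (default) applies the multiplicative effect
#'   `exp(b) - 1` at the sample mean excess cost, `"median_multiplicative"`
#'   at the median, `"exp_at_means"` at the geometric-mean-style baseline
#'   `exp(mean(fitted))`. The percentage column always uses the sample mean
#'   as denominator.
#' @param complication_coding `"count"` enters the 0--4 complication count;
#'   `"any"` replaces it with an any-complication indicator.
#' @param robust If TRUE, report heteroscedasticity-consistent (HC0)
#'   standard errors instead of the plain OLS ones.
#' @return An object of class `excess_cost_fit`; see Details. Methods:
#'   [print()], [summary()], [coef()], [predict()], [plot()],
#'   [residuals()], [simulate()].
#' @export
#' @examples
#' set.seed(1)
#' d <- data.frame(age = sample(50:90, 200, TRUE),
#'                 male = rbinom(200, 1, 0.5),
#'                 surgical = rbinom(200, 1, 0.2),
#'                 dementia = rbinom(200, 1, 0.1),
#'                 cost_weight = rlnorm(200), charlson = rpois(200, 1),
#'                 n_complications = rpois(200, 0.2))
#' d$extra_cost <- exp(7 + 0.14 * d$dementia + rnorm(200, 0, 0.9))
#' fit <- fit_excess_cost(d)
#' coef(fit)
fit_excess_cost <- function(data,
                            step1 = c("age", "male"),
                            step2 = c("surgical", "dementia", "cost_weight",
                                      "charlson", "n_complications"),
                            back_transform_method = c("mean_multiplicative",
                                                      "median_multiplicative",
                                                      "exp_at_means"),
                            complication_coding = c("count", "any"),
                            robust = FALSE) {
  back_transform_method <- match.arg(back_transform_method)
  complication_coding <- match.arg(complication_coding)
  df <- as.data.frame(data)
  if (!"male" %in% names(df) && "sex" %in% names(df)) {
    df$male <- as.numeric(df$sex == "male")
  }
  vars <- c(step1, step2)
  missing_cols <- setdiff(c(vars, "extra_cost"), names(df))
  if (length(missing_cols)) {
    stop("data is missing model column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (complication_coding == "any" && "n_complications" %in% vars) {
    df$n_complications <- as.numeric(df$n_complications > 0)
  }
  for (v in vars) {
    if (is.logical(df[[v]])) df[[v]] <- as.numeric(df[[v]])
    if (!is.numeric(df[[v]])) {
      stop("predictor '", v, "' is not numeric")
    }
  }
  use <- df[, c(vars, "extra_cost"), drop = FALSE]
  cc <- stats::complete.cases(use)
  n_dropped <- sum(!cc)
  use <- use[cc, , drop = FALSE]
  n <- nrow(use)
  if (n < length(vars) + 2L) {
    stop("too few complete rows (", n, ") to fit ", length(vars),
         " predictors")
  }
  if (any(use$extra_cost <= 0)) {
    stop("extra_cost must be strictly positive (log outcome); ",
         "fit on the above-average subset only")
  }
  use$log_extra_cost <- log(use$extra_cost)

  X <- cbind(`(Intercept)` = 1, as.matrix(use[vars]))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("perfectly collinear predictor(s): ",
         paste(aliased, collapse = ", "))
  }
  zero_var <- vars[vapply(use[vars], stats::sd, 0) == 0]
  if (length(zero_var)) {
    stop("zero-variance predictor(s): ", paste(zero_var, collapse = ", "))
  }

  f1 <- stats::as.formula(paste("log_extra_cost ~",
                                paste(step1, collapse = " + ")))
  f2 <- stats::as.formula(paste("log_extra_cost ~",
                                paste(vars, collapse = " + ")))
  fit1 <- stats::lm(f1, data = use)
  fit2 <- stats::lm(f2, data = use)
  s1 <- summary(fit1)
  s2 <- summary(fit2)

  b <- stats::coef(fit2)[vars]
  se <- stats::coef(s2)[vars, "Std. Error"]
  pval <- stats::coef(s2)[vars, "Pr(>|t|)"]
  if (robust) {
    V <- vcov_hc0(fit2)
    se <- sqrt(diag(V))[vars]
    tstat <- b / se
    pval <- 2 * stats::pt(abs(tstat), df = fit2$df.residual,
                          lower.tail = FALSE)
  }
  sd_y <- stats::sd(use$log_extra_cost)
  sd_x <- vapply(use[vars], stats::sd, 0)
  beta_std <- unname(b * sd_x / sd_y)

  mean_cost <- mean(use$extra_cost)
  baseline <- switch(back_transform_method,
                     mean_multiplicative = mean_cost,
                     median_multiplicative = stats::median(use$extra_cost),
                     exp_at_means = exp(mean(stats::fitted(fit2))))
  b_dollars <- back_transform(unname(b), baseline)
  pct <- percentage_of_mean(b_dollars, mean_cost)

  tab <- data.frame(
    term = vars,
    b_log = unname(b),
    se_log = unname(se),
    beta_std = beta_std,
    b_dollars = b_dollars,
    pct_of_mean = pct,
    p_value = unname(pval),
    stringsAsFactors = FALSE
  )
  fstat <- s2$fstatistic
  out <- list(
    coefficients = tab,
    r2_step1 = unname(s1$r.squared),
    r2_step2 = unname(s2$r.squared),
    adj_r2 = unname(s2$adj.r.squared),
    f_value = unname(fstat[["value"]]),
    f_df = c(fstat[["numdf"]], fstat[["dendf"]]),
    n = n,
    n_dropped = n_dropped,
    mean_extra_cost = mean_cost,
    baseline = baseline,
    back_transform_method = back_transform_method,
    complication_coding = complication_coding,
    robust = robust,
    step1 = step1,
    step2 = step2,
    smearing = mean(exp(stats::residuals(fit2))),
    fit_step1 = fit1,
    fit_step2 = fit2,
    call = match.call()
  )
  class(out) <- "excess_cost_fit"
  out
}

# HC0 heteroscedasticity-consistent covariance for an lm fit
vcov_hc0 <- function(fit) {
  X <- stats::model.matrix(fit)
  e <- stats::residuals(fit)
  XtXinv <- chol2inv(qr.R(fit$qr))
  meat <- crossprod(X * e)
  V <- XtXinv %*% meat %*% XtXinv
  dimnames(V) <- list(colnames(X), colnames(X))
  V
}

#' Back-transform a log-scale coefficient to a dollar effect
#'
#' A coefficient `b` on the natural-log cost scale multiplies cost by
#' `exp(b)` per unit of the predictor; evaluated at a reference cost this is
#' a dollar effect of `(exp(b) - 1) * reference`. Exactly zero for `b = 0`.
#'
#' @param b_log Log-scale coefficient(s).
#' @param reference_cost Reference cost at which to evaluate the effect
#'   (typically the sample mean excess cost); must be > 0.
#' @return Dollar effect(s), same length as `b_log`.
#' @export
#' @examples
#' back_transform(log(2), 100)   # doubling at a $100 mean: +$100
back_transform <- function(b_log, reference_cost) {
  if (!is.numeric(reference_cost) || any(reference_cost <= 0)) {
    stop("reference_cost must be > 0")
  }
  (exp(b_log) - 1) * reference_cost
}

#' Express a dollar effect as a percentage of mean excess cost
#'
#' `round(100 * b_dollars / mean_extra_cost)` with half-away-from-zero
#' rounding (so 14.5 -> 15 and -14.5 -> -15, independent of the
#' banker's-rounding default).
#'
#' @param b_dollars Dollar effect(s).
#' @param mean_extra_cost Mean excess cost (> 0).
#' @return Integer percentage(s).
#' @export
#' @examples
#' percentage_of_mean(c(873, 812), 5875)
percentage_of_mean <- function(b_dollars, mean_extra_cost) {
  if (!is.numeric(mean_extra_cost) || any(mean_extra_cost <= 0)) {
    stop("mean_extra_cost must be > 0")
  }
  x <- 100 * b_dollars / mean_extra_cost
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' @export
print.excess_cost_fit <- function(x, digits = 3, ...) {
  cat("Two-step hierarchical model of log excess length-of-stay cost\n")
  cat(sprintf("n = %d (listwise dropped: %d); mean excess cost = %.2f\n",
              x$n, x$n_dropped, x$mean_extra_cost))
  cat(sprintf("R2 step 1 (%s) = %.3f; R2 step 2 (full) = %.3f; adj R2 = %.3f\n",
              paste(x$step1, collapse = " + "),
              x$r2_step1, x$r2_step2, x$adj_r2))
  cat(sprintf("F(%d, %d) = %.1f\n", x$f_df[1], x$f_df[2], x$f_value))
  tab <- x$coefficients
  tab$b_log <- signif(tab$b_log, digits)
  tab$se_log <- signif(tab$se_log, digits)
  tab$beta_std <- round(tab$beta_std, 2)
  tab$b_dollars <- round(tab$b_dollars)
  print(tab[, c("term", "b_log", "se_log", "beta_std", "b_dollars",
                "pct_of_mean")], row.names = FALSE)
  invisible(x)
}

#' @export
summary.excess_cost_fit <- function(object, ...) {
  structure(list(fit = object, step2_summary = summary(object$fit_step2)),
            class = "summary.excess_cost_fit")
}

#' @export
print.summary.excess_cost_fit <- function(x, ...) {
  print(x$fit)
  cat("\nUnderlying OLS fit (log scale):\n")
  print(stats::coef(x$step2_summary))
  invisible(x)
}

#' @export
coef.excess_cost_fit <- function(object, scale = c("log", "dollars"), ...) {
  scale <- match.arg(scale)
  with(object$coefficients,
       stats::setNames(if (scale == "log") b_log else b_dollars, term))
}

#' Predict excess cost (or its log) for new episodes
#'
#' @param object An `excess_cost_fit`.
#' @param newdata Data.frame with the model predictors (a `sex` column is
#'   converted to `male` as in fitting). Omit to use the estimation sample.
#' @param type `"log"` for the linear predictor on the log scale, `"cost"`
#'   for the currency scale with Duan's smearing correction for the
#'   retransformation bias.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.excess_cost_fit <- function(object, newdata = NULL,
                                    type = c("log", "cost"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    p <- stats::fitted(object$fit_step2)
  } else {
    nd <- as.data.frame(newdata)
    if (!"male" %in% names(nd) && "sex" %in% names(nd)) {
      nd$male <- as.numeric(nd$sex == "male")
    }
    if (object$complication_coding == "any" &&
        "n_complications" %in% names(nd)) {
      nd$n_complications <- as.numeric(nd$n_complications > 0)
    }
    for (v in c(object$step1, object$step2)) {
      if (v %in% names(nd) && is.logical(nd[[v]])) {
        nd[[v]] <- as.numeric(nd[[v]])
      }
    }
    p <- stats::predict(object$fit_step2, newdata = nd)
  }
  if (type == "cost") exp(p) * object$smearing else p
}

#' @export
residuals.excess_cost_fit <- function(object, ...) {
  stats::residuals(object$fit_step2)
}

#' Simulate excess costs from a fitted model
#'
#' Draws new log-scale outcomes from the fitted full model (Gaussian
#' residuals at the estimated sigma) and exponentiates to the currency
#' scale.
#'
#' @param object An `excess_cost_fit`.
#' @param nsim Number of simulated datasets.
#' @param seed Optional seed, as in [stats::simulate()].
#' @param ... Unused.
#' @return Data.frame of `nsim` columns of simulated excess costs.
#' @export
simulate.excess_cost_fit <- function(object, nsim = 1, seed = NULL, ...) {
  sims <- stats::simulate(object$fit_step2, nsim = nsim, seed = seed)
  as.data.frame(lapply(sims, exp))
}

#' Bar chart of dollar effects per predictor
#'
#' The effect-size figure: one bar per predictor at its back-transformed
#' dollar effect.
#'
#' @param x An `excess_cost_fit`.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the bar midpoints.
#' @export
plot.excess_cost_fit <- function(x, ...) {
  tab <- x$coefficients
  graphics::barplot(stats::setNames(tab$b_dollars, tab$term),
                    ylab = "Effect on excess cost (currency units)",
                    las = 2, ...)
}
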