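# One-phase exponential decay fitting (plasma half-lives from peak areas
# or functional activity) and 4PL antibody-competition dose-response
# fitting (IC50, remaining activity). Fits use bounded Levenberg-Marquardt
# least squares with deterministic initialization, so results are
# reproducible without random restarts.

.K_LOWER <- 1e-6   # /min; below this a half-life is not reportable
.K_UPPER <- 10     # /min

#' Fit a one-phase exponential decay
#'
#' Least-squares fit of `Y(t) = (Y0 - Plateau) * exp(-K * t) + Plateau`.
#' Initialization is deterministic: `Y0` from the earliest observation,
#' plateau from the minimum (or fixed 0), and `K` from a log-linear
#' regression over the first decade of decay. When the data do not decay
#' (best `K` at or below 1e-6/min) the fit is returned with the half-life
#' flagged not determined, never a fabricated number.
#'
#' @param time Times (minutes by convention; any consistent unit works and
#'   rescales `K` accordingly).
#' @param value Non-negative measured values (areas or percent activity).
#' @param plateau_mode `"zero"` (plateau fixed at 0, the default for MS
#'   peak-area decays) or `"free"` (plateau fitted in `[0, max(value)]`,
#'   the default for functional-activity decays).
#' @return An object of class `decay_fit`: list with `Y0`, `plateau`, `K`
#'   (rate constant), `half_life` (`log(2)/K`; `NA` when not determined),
#'   `se` (named standard errors incl. the delta-method half-life SE),
#'   `rss`, `plateau_mode`, `determined`, `n`.
#' @examples
#' t <- c(0, 5, 10, 20, 30, 45, 60, 90, 120)
#' fit_one_phase_decay(t, 100 * exp(-log(2) * t / 9))$half_life  # 9
#' @export
fit_one_phase_decay <- function(time, value,
                                plateau_mode = c("zero", "free")) {
  plateau_mode <- match.arg(plateau_mode)
  stopifnot(is.numeric(time), is.numeric(value),
            length(time) == length(value))
  if (any(value < 0)) stop("values must be non-negative")
  n_distinct <- length(unique(time))
  need <- if (plateau_mode == "free") 4L else 3L
  if (n_distinct < need) {
    stop("need at least ", need, " distinct timepoints for plateau_mode='",
         plateau_mode, "' (got ", n_distinct, ")")
  }
  ord <- order(time)
  t <- time[ord]
  y <- value[ord]
  y0_init <- max(y[t == min(t)])
  p_init <- if (plateau_mode == "free") min(y) else 0

  # K init: log-linear regression over the first decade of decay
  decade <- which(y > max(y) / 10 & y > 0)
  k_init <- if (length(decade) >= 2 && length(unique(t[decade])) >= 2) {
    sl <- stats::coef(stats::lm(log(y[decade]) ~ t[decade]))[2]
    if (is.finite(sl) && sl < 0) min(max(-sl, .K_LOWER), .K_UPPER) else 1e-3
  } else 1e-3

  df <- data.frame(t = t, y = y)
  fit <- if (plateau_mode == "zero") {
    try(minpack.lm::nlsLM(
      y ~ Y0 * exp(-K * t), data = df,
      start = list(Y0 = max(y0_init, 1e-12), K = k_init),
      lower = c(Y0 = 0, K = .K_LOWER), upper = c(Y0 = Inf, K = .K_UPPER),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  } else {
    try(minpack.lm::nlsLM(
      y ~ (Y0 - P) * exp(-K * t) + P, data = df,
      start = list(Y0 = max(y0_init, 1e-12), P = p_init, K = k_init),
      lower = c(Y0 = 0, P = 0, K = .K_LOWER),
      upper = c(Y0 = Inf, P = max(y), K = .K_UPPER),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  }
  if (inherits(fit, "try-error")) {
    return(structure(list(Y0 = y0_init, plateau = p_init, K = NA_real_,
                          half_life = NA_real_, se = NULL, rss = NA_real_,
                          plateau_mode = plateau_mode, determined = FALSE,
                          n = length(t)),
                     class = "decay_fit"))
  }
  cf <- stats::coef(fit)
  K <- cf[["K"]]
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) NULL)
  determined <- is.finite(K) && K > .K_LOWER * 1.01
  half_life <- if (determined) log(2) / K else NA_real_
  se_out <- NULL
  if (!is.null(se)) {
    se_out <- se
    if (determined && "K" %in% names(se)) {
      se_out <- c(se, half_life = unname(se[["K"]]) * log(2) / K^2)
    }
  }
  structure(list(
    Y0 = cf[["Y0"]],
    plateau = if (plateau_mode == "zero") 0 else cf[["P"]],
    K = K, half_life = half_life, se = se_out,
    rss = sum(stats::resid(fit)^2), plateau_mode = plateau_mode,
    determined = determined, n = length(t)),
    class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("<decay_fit> Y(t) = (Y0 - Plateau) exp(-K t) + Plateau\n")
  cat(sprintf("  Y0 = %.4g, plateau = %.4g (%s), K = %.4g /min\n",
              x$Y0, x$plateau, x$plateau_mode, x$K))
  if (x$determined) {
    cat(sprintf("  half-life = %.4g min (RSS %.4g, n = %d)\n",
                x$half_life, x$rss, x$n))
  } else {
    cat("  half-life: not determined\n")
  }
  invisible(x)
}

#' Fit a four-parameter logistic (4PL) competition curve
#'
#' Fits `Y = Bottom + (Top - Bottom) / (1 + 10^((logIC50 - log10(c)) *
#' Hill))` on log-concentration, the standard inhibitor dose-response
#' model (Hill < 0 for inhibition). Initialization is deterministic:
#' top = max response, bottom = min response, IC50 at the concentration
#' closest to half-range, Hill = -1.
#'
#' @param concentration Concentrations (`> 0`, any consistent unit;
#'   typically nM), spanning at least two log units.
#' @param response Normalized responses on the 0-100 percent scale (100 =
#'   vehicle only, 0 = isotype control; normalization happens upstream).
#' @param constrain `"none"` (top/bottom free) or `"top_bottom"`
#'   (top = 100, bottom = 0).
#' @return An object of class `dose_response_fit`: list with `ic50`,
#'   `hill`, `top`, `bottom`, `se`, `rss`, `constrained`, `determined`,
#'   `n`. Monotone-increasing (non-inhibiting) data yield
#'   `determined = FALSE` with `ic50 = NA`.
#' @examples
#' conc <- 10000 / 3^(0:7)
#' y <- 0 + 100 / (1 + 10^((log10(100) - log10(conc)) * -1))
#' fit_ic50(conc, y)$ic50   # 100
#' @export
fit_ic50 <- function(concentration, response,
                     constrain = c("none", "top_bottom")) {
  constrain <- match.arg(constrain)
  stopifnot(is.numeric(concentration), is.numeric(response),
            length(concentration) == length(response),
            all(concentration > 0))
  if (length(unique(concentration)) < 4) {
    stop("need at least 4 distinct concentrations")
  }
  lx <- log10(concentration)
  if (diff(range(lx)) < 2) {
    stop("concentrations must span at least 2 log units")
  }
  top0 <- if (constrain == "top_bottom") 100 else max(response)
  bot0 <- if (constrain == "top_bottom") 0 else min(response)
  half <- (top0 + bot0) / 2
  l50_0 <- lx[which.min(abs(response - half))]
  df <- data.frame(lx = lx, y = response)
  fit <- if (constrain == "top_bottom") {
    try(minpack.lm::nlsLM(
      y ~ 100 / (1 + 10^((l50 - lx) * hill)), data = df,
      start = list(l50 = l50_0, hill = -1),
      lower = c(l50 = min(lx) - 3, hill = -10),
      upper = c(l50 = max(lx) + 3, hill = 10),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  } else {
    try(minpack.lm::nlsLM(
      y ~ bot + (top - bot) / (1 + 10^((l50 - lx) * hill)), data = df,
      start = list(l50 = l50_0, hill = -1, top = top0, bot = bot0),
      lower = c(l50 = min(lx) - 3, hill = -10, top = -Inf, bot = -Inf),
      upper = c(l50 = max(lx) + 3, hill = 10, top = Inf, bot = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  }
  if (inherits(fit, "try-error")) {
    return(structure(list(ic50 = NA_real_, hill = NA_real_, top = top0,
                          bottom = bot0, se = NULL, rss = NA_real_,
                          constrained = constrain, determined = FALSE,
                          n = length(response)),
                     class = "dose_response_fit"))
  }
  cf <- stats::coef(fit)
  hill <- cf[["hill"]]
  top <- if (constrain == "top_bottom") 100 else cf[["top"]]
  bottom <- if (constrain == "top_bottom") 0 else cf[["bot"]]
  # inhibition requires a falling curve (negative hill) with top > bottom
  determined <- is.finite(hill) && hill < -1e-3 && top > bottom
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) NULL)
  structure(list(
    ic50 = if (determined) 10^cf[["l50"]] else NA_real_,
    hill = hill, top = top, bottom = bottom, se = se,
    rss = sum(stats::resid(fit)^2), constrained = constrain,
    determined = determined, n = length(response)),
    class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("<dose_response_fit> 4PL competition curve\n")
  if (x$determined) {
    cat(sprintf("  IC50 = %.4g, hill = %.3g, top = %.3g, bottom = %.3g\n",
                x$ic50, x$hill, x$top, x$bottom))
  } else {
    cat("  IC50: not determined (no inhibition detected)\n")
  }
  invisible(x)
}

#' Remaining activity from two IC50 fits
#'
#' As a compound loses activity its IC50 rises, so remaining activity is
#' reported as `IC50(t=0) / IC50(t) * 100` (falls from 100 percent as
#' potency is lost). The literal ratio `IC50(t) / IC50(t=0) * 100`, which
#' grows as activity is lost, is also returned labeled `as_printed`.
#'
#' @param fit_t,fit_0 [fit_ic50()] results at time t and time 0; both must
#'   be determined.
#' @return A list with `remaining_pct` (default convention) and
#'   `as_printed_pct` (the literal IC50 ratio).
#' @export
remaining_activity <- function(fit_t, fit_0) {
  stopifnot(inherits(fit_t, "dose_response_fit"),
            inherits(fit_0, "dose_response_fit"))
  if (!fit_0$determined) stop("IC50 at t = 0 is not determined")
  if (!fit_t$determined) {
    # no inhibition even at the top tested concentration: activity gone
    return(list(remaining_pct = 0, as_printed_pct = NA_real_))
  }
  list(remaining_pct = fit_0$ic50 / fit_t$ic50 * 100,
       as_printed_pct = fit_t$ic50 / fit_0$ic50 * 100)
}

#' Half-life of functional activity loss
#'
#' One-phase decay fit of remaining activity (percent) versus incubation
#' time; the plateau is free by default since residual plateaus of
#' activity are commonly observed for albumin-bound species.
#'
#' @param time Incubation times (minutes).
#' @param activity_pct Remaining activity values (percent; 100 at t = 0 by
#'   construction).
#' @param plateau_mode Passed to [fit_one_phase_decay()]; default
#'   `"free"`.
#' @return A `decay_fit`.
#' @export
activity_half_life <- function(time, activity_pct,
                               plateau_mode = "free") {
  fit_one_phase_decay(time, activity_pct, plateau_mode = plateau_mode)
}
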