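#' Aalen-Johansen cumulative incidence under competing risks
#'
#' Nonparametric cumulative incidence of the event of interest in the
#' presence of a competing event, \deqn{CIF_k(t) = \sum_{t_i \le t}
#' S(t_i-) \, d_k(t_i)/n(t_i),} with `S` the all-cause Kaplan-Meier
#' survivor function. Pointwise variance uses the standard counting-process
#' (Marubini-Valsecchi) estimator; 95% confidence intervals are computed on
#' the complementary log-log scale and clipped to `[0, 1]`.
#'
#' @param records data.frame with columns `time` (> 0) and `event`
#'   (0 censored, 1 event of interest, 2 competing event).
#' @param cause event code treated as the event of interest (1 or 2).
#' @param conf_level confidence level for the pointwise intervals.
#' @return object of class `"cif"`: list with `time` (distinct event times),
#'   `cif`, `cif_competing`, `surv` (all-cause KM), `se`, `lower`, `upper`,
#'   `n`, `n_events`. Evaluate with [cif_at()]. All-censored input returns a
#'   zero CIF with a warning.
#' @export
aalen_johansen <- function(records, cause = 1, conf_level = 0.95) {
  stopifnot(nrow(records) >= 1, all(records$time > 0),
            all(records$event %in% 0:2))
  n <- nrow(records)
  other <- setdiff(c(1, 2), cause)
  if (all(records$event == 0)) {
    warning("all observations censored; cumulative incidence is identically zero")
    out <- list(time = numeric(0), cif = numeric(0), cif_competing = numeric(0),
                surv = numeric(0), se = numeric(0), lower = numeric(0),
                upper = numeric(0), n = n, n_events = 0L,
                conf_level = conf_level, cause = cause)
    class(out) <- "cif"
    return(out)
  }
  tt <- sort(unique(records$time[records$event != 0]))
  m <- length(tt)
  atrisk <- d1 <- d2 <- dall <- numeric(m)
  for (i in seq_len(m)) {
    atrisk[i] <- sum(records$time >= tt[i])
    d1[i] <- sum(records$time == tt[i] & records$event == cause)
    d2[i] <- sum(records$time == tt[i] & records$event == other)
    dall[i] <- d1[i] + d2[i]
  }
  surv <- cumprod(1 - dall / atrisk)
  s_minus <- c(1, surv[-m])
  jump1 <- s_minus * d1 / atrisk
  jump2 <- s_minus * d2 / atrisk
  cif1 <- cumsum(jump1)
  cif2 <- cumsum(jump2)
  # Marubini-Valsecchi pointwise variance of CIF_1(t)
  a <- dall / (atrisk * pmax(atrisk - dall, 1))          # KM variance increments
  b <- s_minus^2 * ((atrisk - d1) / atrisk) * d1 / atrisk^2
  cc <- s_minus * d1 / atrisk^2
  var1 <- numeric(m)
  for (i in seq_len(m)) {
    diff <- cif1[i] - cif1[seq_len(i)]
    var1[i] <- sum(diff^2 * a[seq_len(i)]) + sum(b[seq_len(i)]) -
      2 * sum(diff * cc[seq_len(i)])
  }
  se <- sqrt(pmax(var1, 0))
  z <- qnorm(1 - (1 - conf_level) / 2)
  lower <- upper <- cif1
  pos <- cif1 > 0 & cif1 < 1 & se > 0
  # cloglog transform: theta = log(-log(CIF)), se_theta = se/(CIF*|log CIF|)
  th_se <- se[pos] / (cif1[pos] * abs(log(cif1[pos])))
  lower[pos] <- cif1[pos]^exp(z * th_se)
  upper[pos] <- cif1[pos]^exp(-z * th_se)
  lower <- pmin(pmax(lower, 0), 1)
  upper <- pmin(pmax(upper, 0), 1)
  out <- list(time = tt, cif = cif1, cif_competing = cif2, surv = surv,
              se = se, lower = lower, upper = upper, n = n,
              n_events = sum(d1), conf_level = conf_level, cause = cause)
  class(out) <- "cif"
  out
}

#' Evaluate a cumulative incidence curve at given times
#'
#' Right-continuous step-function evaluation: at a jump time the post-jump
#' value is returned; before the first jump the CIF is 0; beyond the last
#' jump the final value carries forward.
#'
#' @param estimate a `"cif"` object from [aalen_johansen()].
#' @param t non-negative evaluation time(s).
#' @return data.frame: `time`, `cif`, `lower`, `upper`, `se`.
#' @export
cif_at <- function(estimate, t) {
  stopifnot(inherits(estimate, "cif"))
  if (any(t < 0)) stop("evaluation times must be non-negative")
  i <- findInterval(t, estimate$time)  # right-continuous: t == jump -> include
  pick <- function(x) ifelse(i == 0, 0, x[pmax(i, 1)])
  data.frame(time = t, cif = pick(estimate$cif), lower = pick(estimate$lower),
             upper = pick(estimate$upper), se = pick(estimate$se))
}

#' @export
print.cif <- function(x, ...) {
  cat("Aalen-Johansen cumulative incidence (cause ", x$cause, ")\n", sep = "")
  cat("  n = ", x$n, ", events of interest = ", x$n_events, "\n", sep = "")
  if (length(x$time) > 0) {
    last <- length(x$time)
    cat(sprintf("  CIF at t = %g: %.1f%% (%d%% CI %.1f, %.1f)\n",
                x$time[last], 100 * x$cif[last], round(100 * x$conf_level),
                100 * x$lower[last], 100 * x$upper[last]))
  }
  invisible(x)
}

#' Kaplan-Meier estimate of the censoring distribution
#'
#' Estimates `G(t) = P(censoring time > t)` by treating censoring as the
#' event and any failure (either cause) as censoring -- the ingredient of
#' inverse-probability-of-censoring weights. At tied times, failures are
#' taken to precede censorings, so subjects failing at `t` remain in the
#' risk set for censoring at `t`.
#'
#' @param records data.frame with `time` and `event` (0 = censored).
#' @return list with `time` (distinct censoring times), `G` (survival of the
#'   censoring distribution), and evaluators `G_at(t)` (right-continuous)
#'   and `G_minus(t)` (left limit `G(t-)`).
#' @export
censoring_km <- function(records) {
  tt <- sort(unique(records$time[records$event == 0]))
  if (length(tt) == 0L) {
    Gfun <- function(t) rep(1, length(t))
    return(list(time = numeric(0), G = numeric(0), G_at = Gfun, G_minus = Gfun))
  }
  atrisk <- vapply(tt, function(u) sum(records$time >= u), numeric(1))
  dc <- vapply(tt, function(u) sum(records$time == u & records$event == 0), numeric(1))
  G <- cumprod(1 - dc / atrisk)
  G_at <- function(t) {
    i <- findInterval(t, tt)
    ifelse(i == 0, 1, G[pmax(i, 1)])
  }
  G_minus <- function(t) {
    i <- findInterval(t, tt, left.open = TRUE)  # jumps at t excluded
    ifelse(i == 0, 1, G[pmax(i, 1)])
  }
  list(time = tt, G = G, G_at = G_at, G_minus = G_minus)
}
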