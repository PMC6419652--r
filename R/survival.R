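#' Paired Wilcoxon signed-rank comparison
#'
#' Two-sided signed-rank test for paired feature values from the two
#' reconstructions. Zero differences are dropped per standard practice; the
#' exact null distribution is used for up to 25 informative pairs and the
#' normal approximation with continuity correction beyond that. If every pair
#' is tied the test is undefined and a flagged p of 1 is returned.
#'
#' @param x,y equal-length paired value vectors (e.g. ungated vs gated).
#' @return List with \code{statistic} (V), \code{p}, \code{n_pairs}
#'   (informative pairs) and logical \code{flagged}.
#' @export
wilcoxon_paired <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  if (length(x) < 6) stop("paired test needs at least 6 pairs")
  d <- y - x
  nz <- d != 0
  if (!any(nz))
    return(list(statistic = NA_real_, p = 1, n_pairs = 0L, flagged = TRUE))
  n <- sum(nz)
  dd <- d[nz]
  r <- rank(abs(dd))
  V <- sum(r[dd > 0])
  if (n <= 25) {
    # Exact two-sided p by dynamic programming over the 2^n sign flips.
    # Doubling the (possibly .5-valued average) ranks makes them integers.
    w <- as.integer(round(2 * r))
    total <- sum(w)
    cnt <- c(1, numeric(total))      # cnt[s + 1] = #assignments with sum s
    for (wi in w) {
      shifted <- c(numeric(wi), cnt[seq_len(total + 1 - wi)])
      cnt <- cnt + shifted
    }
    cnt <- cnt / 2^n
    v2 <- as.integer(round(2 * V))
    pl <- sum(cnt[seq_len(v2 + 1)])
    pu <- sum(cnt[seq.int(v2 + 1, total + 1)])
    p <- min(1, 2 * min(pl, pu))
  } else {
    res <- suppressWarnings(
      stats::wilcox.test(y[nz], x[nz], paired = TRUE,
                         exact = FALSE, correct = TRUE))
    p <- res$p.value
  }
  list(statistic = V, p = p, n_pairs = n, flagged = FALSE)
}

#' Standard scaling (z-score with population SD)
#'
#' Centers to mean 0 and scales by the population standard deviation
#' (divisor n), matching the usual machine-learning standard scaler. A
#' constant input cannot be scaled and returns flagged zeros.
#'
#' @param values numeric vector, length >= 2.
#' @return Scaled vector with logical attribute \code{"flagged"}.
#' @export
standard_scale <- function(values) {
  if (length(values) < 2) stop("need at least 2 values")
  mu <- mean(values)
  s <- sqrt(mean((values - mu)^2))
  if (s == 0) {
    out <- rep(0, length(values))
    attr(out, "flagged") <- TRUE
    return(out)
  }
  out <- (values - mu) / s
  attr(out, "flagged") <- FALSE
  out
}

#' Univariate Cox proportional-hazards model
#'
#' Fits a single-covariate Cox model by partial-likelihood maximisation with
#' Efron tie handling and reports the hazard ratio per unit of the covariate
#' (per 1 SD when the covariate is standard-scaled), its Wald 95% CI and
#' p value. Monotone likelihood (perfect separation) is flagged.
#'
#' @param x covariate vector (typically standard-scaled).
#' @param time follow-up times.
#' @param event 1 = event observed, 0 = censored.
#' @return List of class \code{cox_result}: hr, ci95 (length 2), p, beta, se,
#'   n, n_events, flagged.
#' @export
cox_univariate <- function(x, time, event) {
  if (length(unique(c(length(x), length(time), length(event)))) != 1)
    stop("x, time and event lengths differ")
  if (any(time <= 0)) stop("times must be positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  if (sum(event) < 10)
    warning("fewer than 10 events; estimates will be unstable")
  fit <- survival::coxph(survival::Surv(time, event) ~ x, ties = "efron",
                         control = survival::coxph.control(iter.max = 100))
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(diag(stats::vcov(fit))))
  flagged <- !is.finite(beta) || !is.finite(se) || abs(beta) > 15 || se > 50
  z <- beta / se
  structure(list(hr = exp(beta),
                 ci95 = exp(beta + c(-1, 1) * 1.96 * se),
                 p = 2 * stats::pnorm(-abs(z)),
                 beta = beta, se = se,
                 n = length(x), n_events = sum(event),
                 flagged = flagged),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat("<cox_result> HR ", signif(x$hr, 4), " (95% CI ",
      signif(x$ci95[1], 4), "-", signif(x$ci95[2], 4), "), p = ",
      signif(x$p, 3), "; n = ", x$n, ", events = ", x$n_events,
      if (x$flagged) " [flagged]" else "", "\n", sep = "")
  invisible(x)
}

#' Two-group log-rank test with Kaplan-Meier curves
#'
#' Hand-computed product-limit estimates per group and the 1-df log-rank
#' chi-square from the hypergeometric 2x2 table at each distinct event time.
#'
#' @param times follow-up times.
#' @param events event indicators (0/1).
#' @param groups two-level grouping vector.
#' @return List with \code{chi2}, \code{p}, \code{observed}/\code{expected}
#'   per group, and \code{km_curves}: a data.frame (group, time, n_risk,
#'   n_event, surv).
#' @export
km_logrank <- function(times, events, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("exactly 2 groups required")
  for (g in levels(groups))
    if (sum(groups == g) == 0) stop("empty group: ", g)
  g1 <- groups == levels(groups)[1]
  evt <- sort(unique(times[events == 1]))
  O1 <- 0; E1 <- 0; V <- 0
  for (t in evt) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & g1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- if (V > 0) (O1 - E1)^2 / V else 0
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  km <- do.call(rbind, lapply(levels(groups), function(g) {
    tt <- times[groups == g]; ee <- events[groups == g]
    et <- sort(unique(tt[ee == 1]))
    s <- 1
    rows <- lapply(et, function(t) {
      nr <- sum(tt >= t); ne <- sum(tt == t & ee == 1)
      s <<- s * (1 - ne / nr)
      data.frame(group = g, time = t, n_risk = nr, n_event = ne, surv = s)
    })
    if (length(rows)) do.call(rbind, rows) else NULL
  }))
  list(chi2 = chi2, p = p,
       observed = c(O1, sum(events) - O1),
       expected = c(E1, sum(events) - E1),
       km_curves = km)
}

#' Maximally selected log-rank cutoff
#'
#' Dichotomizes a feature at each candidate cutoff (the unique observed values
#' between the 10th and 90th percentiles) and returns the cutoff maximising
#' the two-group log-rank chi-square, subject to both groups containing at
#' least \code{min_group_size} subjects. Ties go to the smaller cutoff. The
#' reported p value is the naive log-rank p at the selected cutoff and is
#' anti-conservative (no correction for the maximal selection).
#'
#' @param values feature values, one per subject.
#' @param times,events survival data.
#' @param min_group_size minimum subjects per group
#'   (default \code{max(5, ceiling(0.1 * n))}).
#' @return List of class \code{cutoff_result}: cutoff, group_sizes,
#'   logrank_chi2, logrank_p, n_candidates.
#' @export
optimal_cutoff <- function(values, times, events,
                           min_group_size = NULL) {
  n <- length(values)
  if (n < 20) stop("optimal cutoff search needs at least 20 subjects")
  if (is.null(min_group_size)) min_group_size <- max(5, ceiling(0.1 * n))
  q <- stats::quantile(values, c(0.10, 0.90), type = 7, names = FALSE)
  cand <- sort(unique(values[values >= q[1] & values <= q[2]]))
  best <- NULL; best_chi2 <- -Inf
  n_valid <- 0L
  for (cth in cand) {
    hi <- values > cth
    if (sum(hi) < min_group_size || sum(!hi) < min_group_size) next
    if (sum(events[hi]) == 0 || sum(events[!hi]) == 0) next
    n_valid <- n_valid + 1L
    lr <- km_logrank(times, events, ifelse(hi, "high", "low"))
    if (lr$chi2 > best_chi2) {  # strict: ties keep the smaller cutoff
      best_chi2 <- lr$chi2
      best <- list(cutoff = cth, group_sizes = c(low = sum(!hi),
                                                 high = sum(hi)),
                   logrank_chi2 = lr$chi2, logrank_p = lr$p)
    }
  }
  if (is.null(best)) stop("no cutoff satisfies the group-size constraint")
  best$n_candidates <- n_valid
  structure(best, class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat("<cutoff_result> cutoff ", signif(x$cutoff, 5), " (groups ",
      x$group_sizes[1], "/", x$group_sizes[2], "), log-rank chi2 = ",
      signif(x$logrank_chi2, 4), ", naive p = ", signif(x$logrank_p, 3),
      "\n", sep = "")
  invisible(x)
}

#' Simulate survival times with a proportional-hazards dependence on features
#'
#' Exponential baseline hazard \eqn{\lambda_0} with linear predictor
#' \eqn{X \beta} on standard-scaled features, and independent uniform
#' censoring calibrated so the realised censoring fraction matches the target
#' in expectation.
#'
#' @param X numeric matrix (subjects x features), typically standard-scaled.
#' @param beta log hazard ratios, one per column of X.
#' @param lambda0 baseline hazard (events per week).
#' @param censor_frac target censoring fraction in [0, 1).
#' @param seed RNG seed.
#' @return data.frame(subject_id, time_weeks, event).
#' @export
simulate_survival <- function(X, beta, lambda0 = 0.015, censor_frac = 0.2,
                              seed = 1L) {
  X <- as.matrix(X)
  if (ncol(X) != length(beta)) stop("beta length must match ncol(X)")
  n <- nrow(X)
  set.seed(seed)
  rate <- lambda0 * exp(drop(X %*% beta))
  T <- stats::rexp(n, rate = rate)
  event <- rep(1L, n)
  time <- T
  if (censor_frac > 0) {
    # With C ~ U(0, cmax), P(censor subject i) = min(1, E[.]) has closed form
    # mean(pmin(T/cmax, 1)) is not it exactly, but conditioning on the drawn T
    # gives P(C < T_i) = min(T_i / cmax, 1); calibrate cmax on that.
    f <- function(cmax) mean(pmin(T / cmax, 1)) - censor_frac
    lo <- min(T) / 2; hi <- max(T) * 1e3
    cmax <- stats::uniroot(f, c(lo, hi))$root
    C <- stats::runif(n, 0, cmax)
    event <- as.integer(T <= C)
    time <- pmin(T, C)
  }
  data.frame(subject_id = seq_len(n), time_weeks = time, event = event)
}

#' Feature-by-feature survival analysis for both reconstructions
#'
#' For every feature and each reconstruction (ungated and gated), fits the
#' standard-scaled univariate Cox model and finds the maximally selected
#' log-rank cutoff, reproducing the structure of a per-feature HR/CI/p table.
#' Constant features are skipped with NA rows. No multiple-testing correction
#' is applied across the 70 tests; interpret the p values accordingly.
#'
#' @param feature_table data.frame with columns \code{subject_id},
#'   \code{reconstruction} (values \code{"nonORG"}/\code{"ORG"}) and one
#'   column per feature.
#' @param survival_table data.frame(subject_id, time_weeks, event).
#' @param cutoffs also run the cutoff search (needs >= 20 subjects).
#' @return List with data.frames \code{cox} (feature, reconstruction, hr,
#'   ci_low, ci_high, p, flagged) and \code{cutoffs} (feature,
#'   reconstruction, cutoff, chi2, p).
#' @export
table2_analysis <- function(feature_table, survival_table, cutoffs = TRUE) {
  recons <- c("nonORG", "ORG")
  if (!all(recons %in% feature_table$reconstruction))
    stop("feature_table must contain nonORG and ORG rows")
  feats <- setdiff(names(feature_table), c("subject_id", "reconstruction"))
  ids <- sort(unique(feature_table$subject_id))
  if (length(ids) < 2) stop("need at least 2 subjects")
  sv <- survival_table[match(ids, survival_table$subject_id), ]
  if (any(is.na(sv$subject_id))) stop("subject mismatch with survival table")
  cox_rows <- list(); cut_rows <- list()
  for (rc in recons) {
    sub <- feature_table[feature_table$reconstruction == rc, ]
    sub <- sub[match(ids, sub$subject_id), ]
    if (any(is.na(sub$subject_id)))
      stop("subject mismatch across reconstructions")
    for (f in feats) {
      v <- sub[[f]]
      sc <- standard_scale(v)
      if (isTRUE(attr(sc, "flagged"))) {
        cox_rows[[length(cox_rows) + 1L]] <- data.frame(
          feature = f, reconstruction = rc, hr = NA, ci_low = NA,
          ci_high = NA, p = NA, flagged = TRUE)
        next
      }
      cr <- suppressWarnings(
        cox_univariate(as.numeric(sc), sv$time_weeks, sv$event))
      cox_rows[[length(cox_rows) + 1L]] <- data.frame(
        feature = f, reconstruction = rc, hr = cr$hr, ci_low = cr$ci95[1],
        ci_high = cr$ci95[2], p = cr$p, flagged = cr$flagged)
      if (cutoffs && length(ids) >= 20) {
        co <- tryCatch(optimal_cutoff(v, sv$time_weeks, sv$event),
                       error = function(e) NULL)
        if (!is.null(co))
          cut_rows[[length(cut_rows) + 1L]] <- data.frame(
            feature = f, reconstruction = rc, cutoff = co$cutoff,
            chi2 = co$logrank_chi2, p = co$logrank_p)
      }
    }
  }
  list(cox = do.call(rbind, cox_rows),
       cutoffs = if (length(cut_rows)) do.call(rbind, cut_rows) else NULL)
}
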