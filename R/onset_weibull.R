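# Time-to-onset (TTO): days from initiation of the suspect drug to the
# event date, summarized by median/IQR and by the Weibull shape parameter
# (WSP) test. Month-precision dates impute day 1 on both sides;
# year-precision dates are unusable. Intervals <= 0 are excluded (the
# Weibull log-likelihood is undefined at 0 for shape < 1).

# round half up, away from banker's rounding
.roundHalfUp <- function(x, digits = 0L) {
  p <- 10^digits
  s <- signif(x * p, 12)   # shed float fuzz before the half-up decision
  floor(s + 0.5) / p
}

#' Compute time-to-onset intervals for a case cohort
#'
#' For each report in \code{caseIds}, TTO = event date minus the earliest
#' therapy start date among the report's suspect-drug therapy rows, in
#' days. When \code{drug} is supplied, therapy rows are restricted to
#' those whose \code{dsg_drug_seq} matches a drug record with a suspect
#' role (\code{roles}, default primary suspect only); otherwise every
#' therapy row of the report is eligible. Reports with missing or
#' year-precision dates, or with a non-positive interval, are excluded and
#' counted.
#'
#' @param ther THER data.frame (\code{primaryid}, \code{dsg_drug_seq},
#'   \code{start_dt}) from deduplicated reports.
#' @param demo DEMO data.frame carrying \code{event_dt}.
#' @param caseIds primaryids of the target-condition cohort.
#' @param drug optional DRUG data.frame used to restrict therapy rows to
#'   suspect drugs.
#' @param roles suspect role codes (default \code{"PS"}).
#' @return An [OnsetSample-class] object.
#' @export
computeTto <- function(ther, demo, caseIds, drug = NULL, roles = "PS") {
  demo <- demo[demo$primaryid %in% caseIds, , drop = FALSE]
  n_source <- nrow(demo)
  ther <- ther[ther$primaryid %in% caseIds, , drop = FALSE]
  if (!is.null(drug)) {
    sus <- drug[toupper(trimws(ifelse(is.na(drug$role_cod), "",
                                      drug$role_cod))) %in% toupper(roles),
                c("primaryid", "drug_seq"), drop = FALSE]
    key <- paste(ther$primaryid, ther$dsg_drug_seq)
    ther <- ther[key %in% paste(sus$primaryid, sus$drug_seq), , drop = FALSE]
  }

  startPd <- parseFaersDate(ther$start_dt, onError = "na")
  startDate <- .partialToDate(startPd)
  okStart <- !is.na(startDate)
  starts <- data.table::data.table(primaryid = ther$primaryid[okStart],
                                   start = startDate[okStart])
  earliest <- if (nrow(starts))
    starts[, list(start = min(start)), by = "primaryid"]
  else data.table::data.table(primaryid = character(), start = as.Date(character()))

  eventPd <- parseFaersDate(demo$event_dt, onError = "na")
  eventDate <- .partialToDate(eventPd)
  ev <- data.table::data.table(primaryid = demo$primaryid, event = eventDate)
  merged <- merge(ev, earliest, by = "primaryid", all.x = TRUE)

  tto <- as.numeric(merged$event - merged$start)
  noEvent <- is.na(merged$event)
  noStart <- !noEvent & is.na(merged$start)
  nonPos <- !noEvent & !noStart & tto <= 0
  usable <- !noEvent & !noStart & !nonPos

  new("OnsetSample",
      values = tto[usable],
      nSourceReports = as.integer(n_source),
      nUsable = as.integer(sum(usable)),
      exclusions = c(missing_event_date = as.integer(sum(noEvent)),
                     missing_start_date = as.integer(sum(noStart)),
                     nonpositive_interval = as.integer(sum(nonPos))))
}

#' Median and quartiles of a time-to-onset sample
#'
#' Linear-interpolation quantiles, reported as whole days after half-up
#' rounding.
#'
#' @param x an [OnsetSample-class] or a numeric vector of positive days.
#' @return named numeric vector \code{c(median=, q25=, q75=)}.
#' @examples
#' medianIqr(c(1, 2, 3, 4, 5))
#' @export
medianIqr <- function(x) {
  v <- if (is(x, "OnsetSample")) x@values else as.numeric(x)
  if (!length(v)) stop("empty time-to-onset sample", call. = FALSE)
  q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(median = .roundHalfUp(q[2]), q25 = .roundHalfUp(q[1]),
    q75 = .roundHalfUp(q[3]))
}

# Weibull log-likelihood in theta = (log alpha, log beta)
.weibullNll <- function(theta, x, sumLog, n) {
  alpha <- exp(theta[1]); beta <- exp(theta[2])
  -(n * log(beta) - n * beta * log(alpha) + (beta - 1) * sumLog -
      sum((x / alpha)^beta))
}

#' Maximum-likelihood Weibull fit with Wald confidence intervals
#'
#' Fits the two-parameter Weibull by maximizing the likelihood over
#' (log alpha, log beta) from a moment-based start (shape initialized from
#' the log-spacing estimator \eqn{\pi/(\sqrt{6}\,sd(\log x))}). 95\% CIs
#' are Wald intervals on the log-parameter scale from the observed
#' information at the optimum, transformed back; the shape CI then
#' classifies the failure profile via [classifyProfile()].
#'
#' @param x an [OnsetSample-class] or numeric vector of positive days.
#' @param minN minimum usable sample size (default 30).
#' @param level confidence level (default 0.95).
#' @return A [WeibullFit-class] object.
#' @export
fitWeibull <- function(x, minN = 30L, level = 0.95) {
  v <- if (is(x, "OnsetSample")) x@values else as.numeric(x)
  if (any(is.na(v)) || any(v <= 0))
    stop("onset values must be positive and non-missing", call. = FALSE)
  n <- length(v)
  if (n < minN)
    stop(sprintf("sample size %d below the minimum of %d", n, minN),
         call. = FALSE)
  lg <- log(v)
  slog <- sd(lg)
  beta0 <- if (is.finite(slog) && slog > 0) pi / (sqrt(6) * slog) else 1
  alpha0 <- exp(mean(lg) + 0.5772156649 / beta0)
  sumLog <- sum(lg)
  opt <- optim(c(log(alpha0), log(beta0)), .weibullNll, x = v,
               sumLog = sumLog, n = n, method = "BFGS", hessian = TRUE,
               control = list(reltol = 1e-12, maxit = 1000))
  if (opt$convergence != 0)
    stop(sprintf("Weibull fit did not converge (code %d): %s",
                 opt$convergence, paste(opt$message, collapse = " ")),
         call. = FALSE)
  info <- opt$hessian  # observed information in the log parametrization
  cov <- tryCatch(solve(info), error = function(e)
    stop("Weibull fit: singular observed information", call. = FALSE))
  se <- sqrt(pmax(diag(cov), 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- exp(opt$par)
  ci <- rbind(exp(opt$par - z * se), exp(opt$par + z * se))
  fit <- new("WeibullFit", alpha = est[1], beta = est[2],
             alphaCi = ci[, 1], betaCi = ci[, 2], n = as.integer(n),
             logLik = -opt$value, profile = "random failure")
  fit@profile <- classifyProfile(fit)
  fit
}

#' Classify the hazard (failure) profile from the shape-parameter CI
#'
#' Early failure: the 95\% CI for the shape lies entirely below 1 (hazard
#' decreasing over time). Random failure: the CI contains 1 (constant
#' hazard). Wear-out failure: the CI lies entirely above 1 (hazard
#' increasing). The three rules partition all valid CIs.
#'
#' @param fit a [WeibullFit-class], or a length-2 numeric CI for the shape.
#' @return one of \code{"early failure"}, \code{"random failure"},
#'   \code{"wear-out failure"}.
#' @export
classifyProfile <- function(fit) {
  ci <- if (is(fit, "WeibullFit")) fit@betaCi else as.numeric(fit)
  stopifnot(length(ci) == 2L, all(is.finite(ci)), ci[1] <= ci[2])
  if (ci[2] < 1) "early failure"
  else if (ci[1] > 1) "wear-out failure"
  else "random failure"
}

#' Time-to-onset summary row (Table-2 style)
#'
#' Median with quartiles, Weibull scale and shape with CIs, and the
#' failure profile, for one database label.
#'
#' @param sample an [OnsetSample-class].
#' @param label database label (e.g. \code{"heart failure"}).
#' @param minN minimum sample size for the Weibull fit; below it the fit
#'   columns are NA.
#' @return one-row data.frame.
#' @export
ttoSummaryRow <- function(sample, label, minN = 30L) {
  out <- data.frame(database = label, case_reports = sample@nUsable,
                    median_days = NA_real_, q25 = NA_real_, q75 = NA_real_,
                    alpha = NA_real_, alpha_lo = NA_real_, alpha_hi = NA_real_,
                    beta = NA_real_, beta_lo = NA_real_, beta_hi = NA_real_,
                    profile = NA_character_, stringsAsFactors = FALSE)
  if (sample@nUsable >= 1L) {
    m <- medianIqr(sample)
    out$median_days <- m[["median"]]; out$q25 <- m[["q25"]]; out$q75 <- m[["q75"]]
  }
  if (sample@nUsable >= minN) {
    fit <- fitWeibull(sample, minN = minN)
    out$alpha <- fit@alpha; out$alpha_lo <- fit@alphaCi[1]
    out$alpha_hi <- fit@alphaCi[2]
    out$beta <- fit@beta; out$beta_lo <- fit@betaCi[1]
    out$beta_hi <- fit@betaCi[2]
    out$profile <- fit@profile
  }
  out
}
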