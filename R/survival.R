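#' Kaplan-Meier estimate of a survival curve
#'
#' Product-limit estimator with Greenwood-based 95% confidence limits
#' (computed by [survival::survfit()]; samples censored exactly at an
#' event time are counted at risk for that time, per the standard
#' convention).
#'
#' @param time Follow-up times (years), `>= 0`.
#' @param event Event indicator, 0 = censored, 1 = event.
#' @return An object of class `km_curve`; its `steps` element is a tibble
#'   (time, n_risk, n_event, n_censor, surv, lower, upper). Query the step
#'   function with [survival_at()].
#' @examples
#' km <- km_estimate(c(1, 2, 3), c(1, 0, 1))
#' survival_at(km, 1)   # 2/3
#' @export
km_estimate <- function(time, event) {
  if (!length(time)) abort("Need at least one sample.")
  if (length(time) != length(event)) abort("`time` and `event` lengths differ.")
  if (any(time < 0)) abort("Negative follow-up time.")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, conf.type = "plain")
  steps <- tibble(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                  n_censor = fit$n.censor, surv = fit$surv,
                  lower = pmax(fit$lower, 0), upper = pmin(fit$upper, 1))
  structure(list(steps = steps, n = length(time)), class = "km_curve")
}

#' Survival probability at a time point
#' @param km A `km_curve` from [km_estimate()].
#' @param t Time(s) at which to evaluate the step function.
#' @return Numeric vector of survival probabilities (1 before the first
#'   event time).
#' @export
survival_at <- function(km, t) {
  stopifnot(inherits(km, "km_curve"))
  ev <- km$steps |> filter(.data$n_event > 0)
  if (!nrow(ev)) return(rep(1, length(t)))
  vapply(t, function(tt) {
    i <- which(ev$time <= tt)
    if (!length(i)) 1 else ev$surv[max(i)]
  }, numeric(1))
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n = %d, %d event time(s)\n", x$n, sum(x$steps$n_event > 0)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.km_curve <- function(x, ...) x$steps

#' Two-group log-rank test
#'
#' Standard (Mantel-Cox) chi-square on 1 df via [survival::survdiff()].
#'
#' @param time,event Follow-up time and 0/1 event indicator.
#' @param group Two-level grouping vector.
#' @return One-row tibble (statistic, p_value, n_a, n_b).
#' @export
log_rank_test <- function(time, event, group) {
  g <- as.factor(group)
  if (nlevels(droplevels(g)) != 2L) {
    abort("`group` must have exactly two non-empty levels.")
  }
  d <- survival::survdiff(survival::Surv(time, event) ~ g)
  stat <- d$chisq
  tibble(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE),
         n_a = sum(g == levels(g)[1]), n_b = sum(g == levels(g)[2]))
}

#' Cox proportional-hazards fit with Efron tie handling
#'
#' Thin, validated wrapper around [survival::coxph()]. `grade` (if used)
#' enters as two indicators, low and high, against an intermediate-grade
#' baseline. Rows with missing values in the requested covariates are
#' dropped with a message (complete-case analysis; nothing is imputed).
#'
#' @param clinical Clinical tibble with `time`, `event` and covariate
#'   columns (see [read_clinical_table()]).
#' @param covariates Character vector of covariate column names.
#' @return Object of class `cox_fit` wrapping the `coxph` fit; use
#'   [tidy()] for per-covariate hazard ratios and [glance()] for the
#'   overall model.
#' @export
cox_fit <- function(clinical, covariates) {
  clinical <- as_tibble(clinical)
  miss <- setdiff(c("time", "event", covariates), names(clinical))
  if (length(miss)) abort(paste0("Missing columns: ", paste(miss, collapse = ", ")))
  dat <- clinical[, c("time", "event", covariates)]
  cc <- complete.cases(dat)
  if (!all(cc)) {
    inform(sprintf("cox_fit: dropping %d of %d rows with missing covariates.",
                   sum(!cc), nrow(dat)))
    dat <- dat[cc, ]
  }
  if (sum(dat$event) == 0) abort("No events in the data.")
  if ("grade" %in% covariates) {
    dat$grade <- stats::relevel(factor(dat$grade,
                                       levels = c("low", "intermediate", "high")),
                                ref = "intermediate")
  }
  for (v in covariates) {
    vals <- dat[[v]]
    if (length(unique(vals[!is.na(vals)])) < 2L) {
      abort(paste0("Constant covariate: ", v))
    }
  }
  f <- stats::as.formula(paste("survival::Surv(time, event) ~",
                               paste(covariates, collapse = " + ")))
  fit <- survival::coxph(f, data = dat, ties = "efron")
  if (!is.null(fit$info) && isTRUE(fit$info$convergence > 0)) {
    abort("Cox fit did not converge.")
  }
  structure(list(fit = fit, n = nrow(dat), n_event = sum(dat$event),
                 covariates = covariates),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> n = %d (%d events), covariates: %s\n",
              x$n, x$n_event, paste(x$covariates, collapse = ", ")))
  print(tidy(x))
  invisible(x)
}

#' Tidy a Cox fit into per-covariate hazard ratios
#' @param x A `cox_fit`.
#' @param conf_level Confidence level for the Wald interval.
#' @param ... Unused.
#' @return Tibble (term, estimate, hazard_ratio, conf_low, conf_high,
#'   statistic, p_value); hazard ratios are `exp(estimate)`.
#' @exportS3Method generics::tidy
tidy.cox_fit <- function(x, conf_level = 0.95, ...) {
  s <- summary(x$fit, conf.int = conf_level)
  co <- s$coefficients
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble(term = rownames(co),
         estimate = co[, "coef"],
         hazard_ratio = exp(co[, "coef"]),
         conf_low = exp(co[, "coef"] - z * co[, "se(coef)"]),
         conf_high = exp(co[, "coef"] + z * co[, "se(coef)"]),
         statistic = co[, "z"],
         p_value = co[, "Pr(>|z|)"])
}

#' One-row summary of a Cox fit
#' @param x A `cox_fit`.
#' @param ... Unused.
#' @return Tibble (n, n_event, logLik, p_value_lr, concordance); the
#'   overall model p is the likelihood-ratio test.
#' @exportS3Method generics::glance
glance.cox_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble(n = x$n, n_event = x$n_event,
         logLik = as.numeric(stats::logLik(x$fit)),
         statistic_lr = unname(s$logtest["test"]),
         p_value_lr = unname(s$logtest["pvalue"]),
         concordance = unname(s$concordance["C"]))
}

# Vectorised two-group log-rank over the rows of a binary membership
# matrix G (groups x samples): for each row, outlier class (1) vs rest.
# Exactly the Mantel-Cox statistic survdiff computes; implemented as
# matrix products so thousands of genes can be screened at once.
logrank_vec <- function(G, time, event) {
  stopifnot(ncol(G) == length(time), length(time) == length(event))
  tau <- sort(unique(time[event == 1]))
  if (!length(tau)) {
    return(tibble(o_minus_e = rep(0, nrow(G)), variance = 0,
                  statistic = 0, p_value = 1))
  }
  Rm <- outer(time, tau, `>=`) * 1          # samples x event-times, at risk
  Em <- outer(time, tau, `==`) * event      # event happened at tau
  n_t <- colSums(Rm)
  d_t <- colSums(Em)
  n1 <- G %*% Rm                            # at risk in group, per time
  d1 <- G %*% Em
  O <- rowSums(d1)
  E <- as.vector(n1 %*% (d_t / n_t))
  frac <- sweep(n1, 2, n_t, `/`)
  vfac <- ifelse(n_t > 1, d_t * (n_t - d_t) / (n_t - 1), 0)
  V <- as.vector((frac * (1 - frac)) %*% vfac)
  stat <- ifelse(V > 0, (O - E)^2 / V, 0)
  tibble(o_minus_e = O - E, variance = V, statistic = stat,
         p_value = ifelse(V > 0, pchisq(stat, 1, lower.tail = FALSE), 1))
}

#' Per-gene outlier-vs-normal survival screen
#'
#' For every gene retained in the (filtered) outlier pair and each
#' direction, samples are split into the outlier class and the
#' normal-expression class and compared by a log-rank test; genes with
#' `p < alpha` are retained, with a hazard ratio from a univariate Cox
#' model on the outlier indicator. The screen is run on both the high-
#' and low-outlier matrices.
#'
#' @param pair An `outlier_pair`, normally after [filter_informative()].
#' @param clinical Clinical tibble covering exactly the pair's samples.
#' @param alpha Log-rank significance cutoff for retention.
#' @param compute_hr Compute the per-gene univariate Cox hazard ratio for
#'   retained genes (set `FALSE` to skip the Cox pass and keep only the
#'   log-rank screen with a sign-based direction).
#' @return Tibble (gene_id, direction, n_outlier, hazard_ratio, hr_low,
#'   hr_high, logrank_stat, p_value), restricted to `p < alpha`.
#' @export
outlier_survival_screen <- function(pair, clinical, alpha = 0.05,
                                    compute_hr = TRUE) {
  stopifnot(inherits(pair, "outlier_pair"))
  clinical <- as_tibble(clinical)
  samples <- colnames(pair$B_high)
  if (!setequal(samples, clinical$sample_id)) {
    abort("Samples of outlier matrices and clinical table do not match.")
  }
  clin <- clinical[match(samples, clinical$sample_id), ]
  empty_screen <- tibble(gene_id = character(), direction = character(),
                         n_outlier = numeric(), hazard_ratio = numeric(),
                         hr_low = numeric(), hr_high = numeric(),
                         logrank_stat = numeric(), p_value = numeric())
  screen_one <- function(B, direction) {
    if (!nrow(B)) return(empty_screen)
    lr <- logrank_vec(B, clin$time, clin$event)
    res <- tibble(gene_id = rownames(B), direction = direction,
                  n_outlier = rowSums(B),
                  hazard_ratio = NA_real_, hr_low = NA_real_, hr_high = NA_real_,
                  logrank_stat = lr$statistic, p_value = lr$p_value,
                  o_minus_e = lr$o_minus_e) |>
      filter(.data$p_value < alpha)
    if (nrow(res) && compute_hr) {
      hr <- purrr::map(res$gene_id, function(g) {
        fit <- survival::coxph(survival::Surv(clin$time, clin$event) ~ B[g, ],
                               ties = "efron")
        ci <- exp(stats::confint(fit))
        c(exp(stats::coef(fit)), ci[1], ci[2])
      })
      res$hazard_ratio <- vapply(hr, `[[`, numeric(1), 1)
      res$hr_low <- vapply(hr, `[[`, numeric(1), 2)
      res$hr_high <- vapply(hr, `[[`, numeric(1), 3)
    } else if (nrow(res)) {
      # sign of observed-minus-expected events in the outlier class
      res$hazard_ratio <- ifelse(res$o_minus_e > 0, Inf, 0)
    }
    res |> select(-"o_minus_e")
  }
  bind_rows(screen_one(pair$B_high, "high"), screen_one(pair$B_low, "low")) |>
    arrange(.data$direction, .data$p_value)
}
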