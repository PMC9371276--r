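# Independent oracle implementations used to cross-check the package.
# These deliberately share no code with the implementation paths they test.

# CKD-EPI 2009 creatinine equation (no ethnicity factor), written as a
# direct per-element transcription of the published formula.
oracle_ckd_epi <- function(scr_umol, age, sex) {
  vapply(seq_along(scr_umol), function(i) {
    scr <- scr_umol[i] / 88.42
    if (sex[i] == "female") {
      k <- 0.7; a <- -0.329; s <- 1.018
    } else {
      k <- 0.9; a <- -0.411; s <- 1
    }
    141 * min(scr / k, 1)^a * max(scr / k, 1)^(-1.209) * 0.993^age[i] * s
  }, numeric(1))
}

# Brute-force CKD case detection: enumerate every pair of qualifying
# measurements per criterion and take the minimal second-of-pair date.
oracle_detect_ckd <- function(series, gap = 90) {
  pair_confirm <- function(dates) {
    best <- as.Date(NA)
    if (length(dates) >= 2) {
      for (i in seq_along(dates)) {
        for (j in seq_along(dates)) {
          if (i != j && as.numeric(abs(dates[j] - dates[i])) >= gap) {
            second <- max(dates[i], dates[j])
            if (is.na(best) || second < best) best <- second
          }
        }
      }
    }
    best
  }
  conf <- c(
    egfr = pair_confirm(series$date[!is.na(series$egfr) & series$egfr < 60]),
    uac  = pair_confirm(series$date[!is.na(series$uac) & series$uac >= 20]),
    acr  = pair_confirm(series$date[!is.na(series$acr) & series$acr >= 3])
  )
  if (all(is.na(conf))) {
    return(list(confirmed = FALSE, evidence_date = as.Date(NA),
                criterion = NA_character_))
  }
  ed <- min(conf, na.rm = TRUE)
  list(confirmed = TRUE, evidence_date = ed,
       criterion = names(conf)[which(!is.na(conf) & conf == ed)][1])
}

# random renal-function series for property tests
random_rf_series <- function(n_max = 20) {
  n <- sample.int(n_max, 1)
  dates <- sort(as.Date("2013-01-01") + sample.int(2500, n, replace = FALSE))
  has_e <- runif(n) < 0.7
  has_a <- runif(n) < 0.3
  has_u <- runif(n) < 0.3
  tibble::tibble(
    date = dates,
    egfr = ifelse(has_e, runif(n, 10, 120), NA_real_),
    acr = ifelse(has_a, exp(rnorm(n, log(2.5), 1)), NA_real_),
    uac = ifelse(has_u, exp(rnorm(n, log(15), 1)), NA_real_)
  )
}

# Marginal log-likelihood of the random-intercept logistic model by
# fine-grid trapezoidal integration over each cluster's intercept.
grid_loglik <- function(beta, sigma_b, y, X, cluster, width = 10, n_grid = 4001) {
  if (sigma_b < 1e-6) {
    # degenerate limit: all intercepts zero, plain Bernoulli likelihood
    p <- stats::plogis(as.numeric(X %*% beta))
    return(sum(ifelse(y == 1, log(p), log(1 - p))))
  }
  bgrid <- seq(-width * max(sigma_b, 0.2), width * max(sigma_b, 0.2),
               length.out = n_grid)
  h <- bgrid[2] - bgrid[1]
  phi <- stats::dnorm(bgrid, 0, sigma_b)
  eta0 <- as.numeric(X %*% beta)
  total <- 0
  for (g in unique(cluster)) {
    idx <- cluster == g
    # likelihood of cluster g at each grid value of b
    lik <- vapply(bgrid, function(b) {
      p <- stats::plogis(eta0[idx] + b)
      prod(ifelse(y[idx] == 1, p, 1 - p))
    }, numeric(1))
    total <- total + log(sum(lik * phi) * h)
  }
  total
}

# straight-line per-patient recount of a window-based lab indicator
oracle_window_rate <- function(members, labs, analytes, window_days) {
  achieved <- vapply(seq_len(nrow(members)), function(i) {
    d <- labs$date[labs$patient_id == members$patient_id[i] &
                     labs$analyte %in% analytes]
    any(d > members$index_date[i] &
          as.numeric(d - members$index_date[i]) < window_days)
  }, logical(1))
  100 * mean(achieved)
}
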