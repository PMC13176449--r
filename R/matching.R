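#' Fit an age + gender propensity-score model
#'
#' Maximum-likelihood logistic regression of group membership (treated = 1)
#' on age and gender (male = 1, female = 0) with an intercept, optimised by
#' the quasi-Newton L-BFGS algorithm with a hard cap of 1000 iterations and
#' a gradient-norm convergence tolerance of 1e-6. Rows with a missing age or
#' gender are excluded before fitting. Non-convergence (including complete
#' separation, where coefficients stop at the iteration cap) yields a
#' warning, never an error, and scores are still produced.
#'
#' @param data tibble with one row per patient.
#' @param group name of the logical/0-1 column marking the treated group.
#' @param age,gender column names (gender coded `"male"`/`"female"` or
#'   already 0/1).
#' @param max_iter iteration cap (default 1000).
#' @param tol gradient-norm convergence tolerance (default 1e-6).
#' @return Object of class `propensity_model`: list with `coefficients`
#'   (`intercept`, `age`, `gender_male`), `converged`, `n_iterations`,
#'   `n_used`, `n_dropped`, and `scores` (named by `patient_id` when
#'   present, in `(0, 1)`).
#' @export
fit_propensity <- function(data, group = "group", age = "age",
                           gender = "gender", max_iter = 1000L, tol = 1e-6) {
  g <- data[[gender]]
  if (!is.numeric(g)) g <- ifelse(tolower(as.character(g)) == "male", 1, 0)
  y <- as.numeric(data[[group]])
  ok <- !is.na(data[[age]]) & !is.na(g) & !is.na(y)
  n_dropped <- sum(!ok)
  X <- cbind(1, data[[age]][ok], g[ok])
  y <- y[ok]
  stopifnot(length(unique(y)) == 2)

  nll <- function(beta) {
    eta <- drop(X %*% beta)
    # stable log(1 + exp(eta))
    sum(pmax(eta, 0) + log1p(exp(-abs(eta))) - y * eta)
  }
  grad <- function(beta) {
    p <- stats::plogis(drop(X %*% beta))
    drop(crossprod(X, p - y))
  }
  fit <- stats::optim(c(0, 0, 0), nll, grad, method = "L-BFGS-B",
                      control = list(maxit = max_iter, factr = 1e1))
  gnorm <- sqrt(sum(grad(fit$par)^2))
  converged <- fit$convergence == 0 && gnorm <= tol * max(1, nrow(X))
  if (!converged)
    warning("propensity model did not converge (gradient norm ",
            format(gnorm, digits = 3), "); scores still emitted")
  scores <- stats::plogis(drop(X %*% fit$par))
  # a perfect fit means the groups are separable; the MLE diverges and the
  # optimiser stops wherever the likelihood flattens out
  if (all(abs(y - scores) < 1e-4))
    warning("possible complete separation: groups perfectly discriminated; ",
            "coefficients capped at the optimiser stopping point")
  if ("patient_id" %in% names(data))
    names(scores) <- data$patient_id[ok]
  structure(list(
    coefficients = c(intercept = fit$par[1], age = fit$par[2],
                     gender_male = fit$par[3]),
    converged = converged,
    n_iterations = min(unname(fit$counts[1]), max_iter),
    n_used = nrow(X), n_dropped = n_dropped,
    scores = scores, treated = y == 1
  ), class = "propensity_model")
}

#' @export
print.propensity_model <- function(x, ...) {
  cat("Propensity model (logistic, L-BFGS)\n")
  print(round(x$coefficients, 4))
  cat(sprintf("converged: %s after %d iterations; n = %d (%d dropped)\n",
              x$converged, x$n_iterations, x$n_used, x$n_dropped))
  invisible(x)
}

#' Greedy 1:1 nearest-neighbour caliper matching
#'
#' Treated patients are processed in a deterministic order (descending
#' propensity score, ties by id); each is matched without replacement to the
#' nearest remaining control within the caliper on the raw probability
#' scale (ties to the lower control id), and that control leaves the pool.
#' Treated patients with no control inside the caliper stay unmatched and
#' are excluded from downstream analyses.
#'
#' @param treated,control tibbles with `patient_id` and `score`.
#' @param caliper maximum |score difference| within a pair (default 0.1).
#' @return Object of class `matched_cohort`: list with `pairs` (tibble
#'   `treated_id`, `control_id`, `score_t`, `score_c`, `abs_diff`),
#'   `unmatched_treated`, and `caliper`.
#' @export
greedy_match <- function(treated, control, caliper = 0.1) {
  stopifnot(all(c("patient_id", "score") %in% names(treated)),
            all(c("patient_id", "score") %in% names(control)))
  ord <- order(-treated$score, treated$patient_id)
  t_id <- treated$patient_id[ord]; t_s <- treated$score[ord]
  c_id <- control$patient_id; c_s <- control$score
  avail <- rep(TRUE, length(c_id))
  m_t <- character(0); m_c <- character(0); m_st <- m_sc <- numeric(0)
  unmatched <- character(0)
  for (i in seq_along(t_id)) {
    d <- abs(c_s - t_s[i])
    d[!avail] <- Inf
    j_ok <- which(d <= caliper)
    if (!length(j_ok)) {
      unmatched <- c(unmatched, t_id[i])
      next
    }
    j <- j_ok[order(d[j_ok], c_id[j_ok])][1]
    avail[j] <- FALSE
    m_t <- c(m_t, t_id[i]); m_c <- c(m_c, c_id[j])
    m_st <- c(m_st, t_s[i]); m_sc <- c(m_sc, c_s[j])
  }
  structure(list(
    pairs = tibble::tibble(treated_id = m_t, control_id = m_c,
                           score_t = m_st, score_c = m_sc,
                           abs_diff = abs(m_st - m_sc)),
    unmatched_treated = unmatched,
    caliper = caliper
  ), class = "matched_cohort")
}

#' Standardised mean difference
#'
#' `SMD = (mean_t - mean_c) / sqrt((var_t + var_c) / 2)`. A zero pooled
#' standard deviation (covariate constant in both arms) yields SMD 0 with a
#' flag rather than NaN.
#'
#' @param x_t,x_c numeric covariate values in the treated / control arm.
#' @return List with `smd` and `zero_sd` flag.
#' @export
smd <- function(x_t, x_c) {
  pooled <- sqrt((stats::var(x_t) + stats::var(x_c)) / 2)
  if (!is.finite(pooled) || pooled == 0)
    return(list(smd = 0, zero_sd = TRUE))
  list(smd = (mean(x_t) - mean(x_c)) / pooled, zero_sd = FALSE)
}

#' Covariate balance diagnostics for a matched cohort
#'
#' Per-covariate means and standardised mean differences between the two
#' arms of a matched cohort. Non-numeric covariates are converted to 0/1
#' indicators (gender: male = 1; logicals as is; factors/characters: one
#' indicator per level).
#'
#' @param matched a `matched_cohort` from [greedy_match()].
#' @param data tibble with `patient_id` and the covariate columns.
#' @param covariates character vector of covariate column names.
#' @return Tibble `covariate`, `mean_treated`, `mean_control`, `smd`,
#'   `zero_sd`.
#' @export
balance_diagnostics <- function(matched, data, covariates) {
  stopifnot(nrow(matched$pairs) >= 2)
  expand <- function(df) {
    out <- list()
    for (cv in covariates) {
      x <- df[[cv]]
      if (is.numeric(x)) {
        out[[cv]] <- x
      } else if (is.logical(x)) {
        out[[cv]] <- as.numeric(x)
      } else if (identical(sort(unique(as.character(stats::na.omit(x)))),
                           c("female", "male"))) {
        out[[paste0(cv, "_male")]] <- as.numeric(as.character(x) == "male")
      } else {
        for (lv in sort(unique(as.character(x))))
          out[[paste0(cv, "_", lv)]] <- as.numeric(as.character(x) == lv)
      }
    }
    tibble::as_tibble(out)
  }
  all_num <- expand(data)  # single expansion so both arms share columns
  dt <- all_num[match(matched$pairs$treated_id, data$patient_id), ]
  dc <- all_num[match(matched$pairs$control_id, data$patient_id), ]
  purrr::map_dfr(names(dt), function(cv) {
    s <- smd(dt[[cv]], dc[[cv]])
    tibble::tibble(covariate = cv,
                   mean_treated = mean(dt[[cv]]),
                   mean_control = mean(dc[[cv]]),
                   smd = s$smd, zero_sd = s$zero_sd)
  })
}
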