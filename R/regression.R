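#' Encode the regression design for one measure and cut-off
#'
#' Builds the adjusted design used throughout: an intercept, a
#' nonadherence indicator (the measure dichotomized at the cut-off), a male
#' indicator and a TLE-regimen indicator. Reference levels are *female*
#' and *non-TLE regimen*. Participants missing the measure or the outcome
#' are dropped, with the count reported as a message.
#'
#' @param panel A panel tibble from [build_panel()].
#' @param measure A measure label (see [default_measures()]).
#' @param cutoff Adherence cut-off percent in (0, 100].
#' @return A list: `x` (numeric design matrix with columns `(Intercept)`,
#'   `nonadherent`, `male`, `tle`), `y` (logical outcome), `n_dropped`.
#' @examples
#' panel <- build_panel(simulate_cohort(sim_config(n_participants = 40)))
#' d <- encode_design(panel, "sr", 95)
#' @export
encode_design <- function(panel, measure, cutoff) {
  if (length(cutoff) != 1 || is.na(cutoff) || cutoff <= 0 || cutoff > 100)
    stop("`cutoff` must be a single percent in (0, 100]", call. = FALSE)
  for (col in c("sex", "regimen_class", "vl_detectable"))
    if (!col %in% names(panel))
      stop("panel lacks column: ", col, call. = FALSE)
  scores <- measure_scores(panel, measure)
  keep <- !is.na(scores) & !is.na(panel$vl_detectable)
  if (!any(keep))
    stop(sprintf("measure \"%s\" is absent for all participants", measure),
         call. = FALSE)
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(sprintf("encode_design: dropped %d row(s) with missing %s or outcome",
                    n_dropped, measure))
  x <- cbind(
    `(Intercept)` = 1,
    nonadherent = as.numeric(dichotomize(scores[keep], cutoff) == "nonadherent"),
    male = as.numeric(panel$sex[keep] == "male"),
    tle = as.numeric(panel$regimen_class[keep] == "TLE")
  )
  list(x = x, y = panel$vl_detectable[keep], n_dropped = n_dropped)
}

#' Logistic regression with Wald inference and separation diagnostics
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares, gradient tolerance 1e-8) of a binary outcome on a numeric
#' design matrix, reporting Wald standard errors, odds ratios, confidence
#' intervals and two-sided p-values per term. Constant non-intercept
#' columns are rejected.
#'
#' (Quasi-)complete separation — some fitted probability within 1e-6 of 0
#' or 1 together with a diverging coefficient — is *flagged* and warned
#' about, with the estimates still reported: at high adherence cut-offs a
#' cell of the adherence-by-outcome table can empty out, and silently
#' penalizing would change the estimand. A Firth-penalized fit
#' (`method = "firth"`) is available for such cells but is off by default.
#'
#' @param design A design list from [encode_design()], or a numeric matrix
#'   whose first column is the intercept.
#' @param outcomes Logical outcome vector (ignored when `design` carries
#'   its own `y`).
#' @param method `"ml"` (default) or `"firth"`.
#' @param conf_level Confidence level for Wald intervals (default 0.95).
#' @param max_iter IRLS iteration cap (default 100).
#' @return An object of class `logistic_fit`: a list with `terms` (tibble
#'   of `term`, `estimate`, `std_error`, `odds_ratio`, `conf_low`,
#'   `conf_high`, `p_value`), `converged`, `separation`, `n`, `method`.
#' @examples
#' x <- cbind(`(Intercept)` = 1, exposed = rep(c(0, 1), each = 50))
#' y <- rep(c(FALSE, TRUE, FALSE, TRUE), c(40, 10, 25, 25))
#' fit_logistic(x, y)
#' @export
fit_logistic <- function(design, outcomes = NULL, method = c("ml", "firth"),
                         conf_level = 0.95, max_iter = 100) {
  method <- match.arg(method)
  if (is.list(design) && !is.null(design$x)) {
    x <- design$x
    y <- design$y
  } else {
    x <- as.matrix(design)
    y <- outcomes
  }
  if (is.null(y)) stop("outcomes are required", call. = FALSE)
  y <- as.numeric(y)
  if (length(y) != nrow(x))
    stop("design and outcomes must have matching length", call. = FALSE)
  if (all(y == 0) || all(y == 1))
    stop("both outcome classes are required for a logistic fit", call. = FALSE)
  if (ncol(x) > 1) {
    const <- apply(x[, -1, drop = FALSE], 2, function(v) length(unique(v)) == 1)
    if (any(const))
      stop("constant predictor column(s): ",
           paste(colnames(x)[-1][const], collapse = ", "), call. = FALSE)
  }

  if (method == "ml") {
    fit <- stats::glm.fit(x, y, family = stats::binomial(),
                          control = stats::glm.control(epsilon = 1e-8,
                                                       maxit = max_iter))
    beta <- fit$coefficients
    mu <- fit$fitted.values
    w <- mu * (1 - mu)
    info <- crossprod(x * w, x)
    vcov <- solve(info)
    converged <- fit$converged
  } else {
    firth <- firth_logistic(x, y, max_iter = max_iter)
    beta <- firth$beta
    mu <- firth$mu
    vcov <- firth$vcov
    converged <- firth$converged
  }

  separation <- any(mu < 1e-6 | mu > 1 - 1e-6) && any(abs(beta) > 8)
  if (separation)
    warning("possible (quasi-)complete separation: estimates diverge and ",
            "Wald intervals are unreliable; consider method = \"firth\"",
            call. = FALSE)
  if (!converged && !separation)
    stop(sprintf("logistic fit failed to converge in %d iterations", max_iter),
         call. = FALSE)

  se <- sqrt(diag(vcov))
  z <- beta / se
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  terms <- tibble::tibble(
    term = colnames(x),
    estimate = unname(beta),
    std_error = unname(se),
    odds_ratio = exp(unname(beta)),
    conf_low = exp(unname(beta - zq * se)),
    conf_high = exp(unname(beta + zq * se)),
    p_value = 2 * stats::pnorm(-abs(unname(z)))
  )
  structure(list(terms = terms, converged = converged,
                 separation = separation, n = length(y), method = method),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> n = %d, method = %s%s%s\n", x$n, x$method,
              if (x$separation) ", SEPARATION FLAGGED" else "",
              if (!x$converged) ", NOT CONVERGED" else ""))
  print(as.data.frame(x$terms), digits = 4)
  invisible(x)
}

# Firth bias-reduced logistic regression: penalized IRLS with the
# Jeffreys-prior score correction h_i * (1/2 - mu_i).
firth_logistic <- function(x, y, max_iter = 100, tol = 1e-8) {
  beta <- rep(0, ncol(x))
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    info <- crossprod(x * w, x)
    inv_info <- solve(info)
    # leverages of the weighted design
    h <- rowSums((x %*% inv_info) * x) * w
    score <- drop(crossprod(x, y - mu + h * (0.5 - mu)))
    step <- drop(inv_info %*% score)
    beta <- beta + step
    if (max(abs(score)) < tol) {
      converged <- TRUE
      break
    }
  }
  eta <- drop(x %*% beta)
  mu <- stats::plogis(eta)
  w <- mu * (1 - mu)
  info <- crossprod(x * w, x)
  list(beta = stats::setNames(beta, colnames(x)), mu = mu,
       vcov = solve(info), converged = converged)
}

#' Adjusted logistic regressions across measures and cut-offs
#'
#' One adjusted model per (measure, cut-off) cell — each measure fitted in
#' its own model, dichotomized at each grid cut-off, always adjusted for
#' sex and TLE-vs-other regimen. Cells whose fit fails (e.g. a constant
#' predictor after restriction) are recorded and skipped.
#'
#' @param panel A panel tibble from [build_panel()].
#' @param measures Measure labels (see [default_measures()]).
#' @param grid A [cutoff_grid()].
#' @param method Passed to [fit_logistic()].
#' @return A tibble with one row per (measure, cutoff, term):
#'   `measure`, `cutoff`, `term`, `estimate`, `std_error`, `odds_ratio`,
#'   `conf_low`, `conf_high`, `p_value`, `separation`, `converged`, `n`.
#'   Failed cells are attached as attribute `"failures"` (a tibble of
#'   `measure`, `cutoff`, `message`).
#' @examples
#' panel <- build_panel(simulate_cohort(sim_config(n_participants = 120)))
#' fits <- regression_sweep(panel, measures = c("sr", "pr"))
#' @export
regression_sweep <- function(panel, measures = default_measures(),
                             grid = cutoff_grid(), method = "ml") {
  grid <- cutoff_grid(grid)
  failures <- list()
  rows <- list()
  for (m in measures) {
    for (cutoff in grid) {
      res <- tryCatch({
        design <- suppressMessages(encode_design(panel, m, cutoff))
        fit <- suppressWarnings(fit_logistic(design, method = method))
        dplyr::mutate(fit$terms, measure = m, cutoff = cutoff,
                      separation = fit$separation, converged = fit$converged,
                      n = fit$n, .before = 1)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1]] <-
          tibble::tibble(measure = m, cutoff = cutoff,
                         message = conditionMessage(res))
      } else {
        rows[[length(rows) + 1]] <- res
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "failures") <- dplyr::bind_rows(failures)
  if (length(failures) > 0)
    warning(sprintf("%d regression cell(s) failed; see attr(, \"failures\")",
                    length(failures)), call. = FALSE)
  out
}
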