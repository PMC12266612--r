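#' Build the doctor-week regression panel
#'
#' Joins weekly demand with the five dimension sentiment scores lagged by
#' `lag` weeks and with doctor controls. A row is emitted for doctor i and
#' week t only when demand at t and all five dimension scores at t - lag are
#' defined under the chosen missing-score policy. Count controls are
#' transformed as `log(1 + count)` and renamed with a `log_` prefix.
#'
#' @param scores Dimension-score tibble (`doctor_id`, `week`, `dimension`,
#'   `score`), long form as returned by [aggregate_dimension_scores()].
#' @param demand Tibble `doctor_id`, `week`, `y` (one row per doctor-week).
#' @param controls Optional tibble keyed by `doctor_id` (time-invariant) or
#'   by (`doctor_id`, `week`).
#' @param lag Sentiment lag in weeks (default 1).
#' @param count_controls Names of control columns to log(1 + x) transform.
#' @param missing Missing-score policy: `"drop"` (default) keeps only weeks
#'   with observed scores; `"carry"` carries the last observed score
#'   forward within each doctor.
#' @return Tibble with `doctor_id`, `week`, `y`, one column per dimension
#'   (the lagged scores), and the control columns.
#' @export
build_panel <- function(scores, demand, controls = NULL, lag = 1,
                        count_controls = character(),
                        missing = c("drop", "carry")) {
  missing <- match.arg(missing)
  if (anyDuplicated(demand[c("doctor_id", "week")])) {
    stop("duplicate (doctor_id, week) keys in demand table", call. = FALSE)
  }
  if (anyDuplicated(scores[c("doctor_id", "week", "dimension")])) {
    stop("duplicate (doctor_id, week, dimension) keys in score table", call. = FALSE)
  }
  wide <- tidyr::pivot_wider(scores, id_cols = c("doctor_id", "week"),
                             names_from = "dimension", values_from = "score")
  for (d in setdiff(DIMENSIONS, names(wide))) wide[[d]] <- NA_real_
  wide <- wide[c("doctor_id", "week", DIMENSIONS)]

  if (missing == "carry") {
    wide <- wide |>
      dplyr::group_by(.data$doctor_id) |>
      tidyr::complete(week = tidyr::full_seq(.data$week, 1L)) |>
      tidyr::fill(dplyr::all_of(DIMENSIONS), .direction = "down") |>
      dplyr::ungroup()
  }

  lagged <- wide
  lagged$week <- lagged$week + as.integer(lag)
  panel <- dplyr::inner_join(demand, lagged, by = c("doctor_id", "week"))
  panel <- panel[stats::complete.cases(panel[DIMENSIONS]), , drop = FALSE]

  if (!is.null(controls)) {
    keys <- intersect(c("doctor_id", "week"), names(controls))
    if (anyDuplicated(controls[keys])) {
      stop("duplicate keys in controls table", call. = FALSE)
    }
    panel <- dplyr::inner_join(panel, controls, by = keys)
    for (cc in count_controls) {
      if (!cc %in% names(panel)) stop(sprintf("count control '%s' not found", cc), call. = FALSE)
      panel[[paste0("log_", cc)]] <- log1p(panel[[cc]])
      panel[[cc]] <- NULL
    }
  }
  dplyr::arrange(tibble::as_tibble(panel), .data$doctor_id, .data$week)
}

## Internal: project out doctor and week group means by alternating
## demeaning (converges immediately on balanced panels, iterates otherwise).
demean_two_way <- function(M, f1, f2, tol = 1e-11, max_iter = 200L) {
  M <- as.matrix(M)
  for (iter in seq_len(max_iter)) {
    delta <- 0
    for (f in list(f1, f2)) {
      gm <- apply(M, 2L, function(v) ave(v, f))
      M <- M - gm
      delta <- max(delta, max(abs(gm)))
    }
    if (delta < tol) break
  }
  M
}

#' Fit the demand regression with fixed effects and clustered errors
#'
#' Two estimation modes:
#' \describe{
#'   \item{`twoway_fe`}{The two-way within estimator: doctor and week
#'     intercepts are absorbed, which is numerically identical to least
#'     squares with full doctor and week indicator variables. Controls that
#'     never vary within doctor are dropped with a notice, since the doctor
#'     effects absorb them.}
#'   \item{`pooled_weekfe`}{Week indicators only, keeping time-invariant
#'     doctor controls identifiable (the form needed to report coefficients
#'     on chronic status, rank, or gender).}
#' }
#' Standard errors are the CR1 cluster-robust sandwich with the
#' \eqn{G/(G-1)\cdot(N-1)/(N-K)} finite-sample correction, G = number of
#' clusters (doctors), K = number of model parameters including absorbed
#' intercepts. p-values use a normal reference.
#'
#' @param panel Tibble from [build_panel()] (columns `doctor_id`, `week`,
#'   `y`, regressors).
#' @param dims Names of the sentiment regressors (default the five
#'   dimensions).
#' @param controls Names of control regressors (default none).
#' @param mode `"twoway_fe"` or `"pooled_weekfe"`.
#' @return An object of class `fe_result`: `coefficients` tibble (`term`,
#'   `estimate`, `se`, `statistic`, `p_value`), `r_squared` (overall, fixed
#'   effects included), `n`, `n_doctors`, `n_weeks`, `mode`, `dropped`
#'   (controls removed as time-invariant in `twoway_fe` mode), `vcov`.
#' @export
fit_fe <- function(panel, dims = DIMENSIONS, controls = character(),
                   mode = c("twoway_fe", "pooled_weekfe")) {
  mode <- match.arg(mode)
  fd <- factor(panel$doctor_id)
  fw <- factor(panel$week)
  G <- nlevels(fd); Tn <- nlevels(fw); N <- nrow(panel)
  if (G < 2 || Tn < 2) stop("need at least 2 doctors and 2 weeks", call. = FALSE)
  y <- panel$y
  dropped <- character()

  if (mode == "twoway_fe") {
    if (length(controls) > 0L) {
      invariant <- vapply(controls, function(cc) {
        all(tapply(panel[[cc]], fd, function(v) max(v) - min(v)) == 0)
      }, logical(1))
      dropped <- controls[invariant]
      if (length(dropped) > 0L) {
        rlang::inform(paste0("dropping time-invariant control(s) absorbed by doctor effects: ",
                             paste(dropped, collapse = ", ")),
                      class = "hsq5d_fe_dropped")
      }
      controls <- controls[!invariant]
    }
    terms <- c(dims, controls)
    X <- as.matrix(panel[terms])
    XY <- demean_two_way(cbind(y, X), fd, fw)
    yt <- XY[, 1L]
    Xt <- XY[, -1L, drop = FALSE]
    K <- length(terms) + (G - 1L) + (Tn - 1L) + 1L
  } else {
    terms <- c(dims, controls)
    Xw <- stats::model.matrix(~fw)[, -1L, drop = FALSE]
    colnames(Xw) <- paste0("week_", levels(fw)[-1L])
    X <- cbind("(Intercept)" = 1, as.matrix(panel[terms]), Xw)
    terms <- colnames(X)
    Xt <- X; yt <- y
    K <- ncol(X)
  }

  if (ncol(Xt) > 0L) {
    qrX <- qr(Xt)
    if (qrX$rank < ncol(Xt)) {
      bad <- colnames(Xt)[qrX$pivot[(qrX$rank + 1L):ncol(Xt)]]
      stop(paste0("rank-deficient design; collinear column(s): ",
                  paste(bad, collapse = ", ")), call. = FALSE)
    }
    XtXinv <- solve(crossprod(Xt))
    beta <- qr.coef(qrX, yt)
    e <- as.vector(yt - Xt %*% beta)
    ## CR1 sandwich: sum score outer products by doctor
    S <- rowsum(Xt * e, group = fd)
    meat <- crossprod(S)
    c_adj <- (G / (G - 1)) * ((N - 1) / (N - K))
    V <- c_adj * XtXinv %*% meat %*% XtXinv
    se <- sqrt(diag(V))
    stat <- beta / se
    coefs <- tibble::tibble(
      term = if (mode == "twoway_fe") c(dims, controls) else terms,
      estimate = unname(beta), se = unname(se), statistic = unname(stat),
      p_value = 2 * stats::pnorm(-abs(unname(stat)))
    )
  } else {
    e <- if (mode == "twoway_fe") demean_two_way(cbind(y), fd, fw)[, 1L] else y - mean(y)
    V <- matrix(numeric(0), 0, 0)
    coefs <- tibble::tibble(term = character(), estimate = numeric(),
                            se = numeric(), statistic = numeric(),
                            p_value = numeric())
  }

  r2 <- 1 - sum(e^2) / sum((y - mean(y))^2)
  structure(
    list(coefficients = coefs, r_squared = r2, n = N, n_doctors = G,
         n_weeks = Tn, mode = mode, dropped = dropped, vcov = V,
         residuals = e),
    class = "fe_result"
  )
}

#' @export
print.fe_result <- function(x, ...) {
  cat(sprintf("Fixed-effects demand regression (%s), N = %d, doctors = %d, weeks = %d\n",
              x$mode, x$n, x$n_doctors, x$n_weeks))
  cat(sprintf("Overall R-squared (fixed effects included): %.4f\n\n", x$r_squared))
  print(as.data.frame(x$coefficients), digits = 4, row.names = FALSE)
  if (length(x$dropped) > 0L) {
    cat("\nDropped time-invariant control(s):", paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Marginal effect of a one-SD sentiment increase on demand
#'
#' With log-transformed demand, a one-standard-deviation increase in a
#' dimension sentiment raises log demand by \eqn{\gamma\sigma} and demand
#' itself by \eqn{e^{\gamma\sigma} - 1}.
#'
#' @param gamma Regression coefficient(s).
#' @param sigma Standard deviation(s) of the regressor (>= 0).
#' @param dimension Optional label column.
#' @return Tibble with `dimension`, `gamma`, `sigma`, `log_effect`
#'   (\eqn{\gamma\sigma}) and `pct_effect` (percent change in demand,
#'   \eqn{100(e^{\gamma\sigma} - 1)}).
#' @export
marginal_effect <- function(gamma, sigma, dimension = NA_character_) {
  stopifnot(all(sigma >= 0))
  log_eff <- gamma * sigma
  tibble::tibble(
    dimension = dimension, gamma = gamma, sigma = sigma,
    log_effect = log_eff, pct_effect = 100 * (exp(log_eff) - 1)
  )
}

#' Stepwise variance explained as dimensions are added
#'
#' Fits the controls-only model, then adds the dimension regressors one at a
#' time in the given order, recording the overall R-squared at each step.
#' Nested least-squares models make the sequence non-decreasing. A step
#' whose new regressor is perfectly collinear with those already present
#' adds no explained variance and repeats the previous R-squared rather
#' than failing.
#'
#' @param panel Panel tibble.
#' @param order Order in which the regressors enter (defaults to the five
#'   dimensions).
#' @param controls Control regressor names present at every step.
#' @param mode Estimation mode passed to [fit_fe()].
#' @return Tibble with `step` (0 = controls only), `added` and `r_squared`;
#'   6 rows for the default order.
#' @export
stepwise_r2 <- function(panel, order = DIMENSIONS, controls = character(),
                        mode = "twoway_fe") {
  out <- tibble::tibble(step = 0:length(order),
                        added = c("(controls only)", order),
                        r_squared = NA_real_)
  prev <- NA_real_
  for (k in 0:length(order)) {
    r2 <- tryCatch(
      suppressMessages(
        fit_fe(panel, dims = order[seq_len(k)], controls = controls, mode = mode)
      )$r_squared,
      error = function(e) {
        if (grepl("rank-deficient", conditionMessage(e)) && k > 0) prev else stop(e)
      }
    )
    out$r_squared[k + 1L] <- r2
    prev <- r2
  }
  out
}

#' Censor extreme demand observations
#'
#' Removes the rows whose dependent variable lies in the bottom and top
#' `fraction` of its distribution: the \eqn{\lfloor fN \rfloor} smallest and
#' \eqn{\lfloor fN \rfloor} largest values, ties resolved by original row
#' order (first occurrence trimmed first).
#'
#' @param panel Panel tibble with a `y` column.
#' @param fraction Fraction trimmed from each tail, in \[0, 0.5).
#' @return The panel with the extreme rows removed, original order kept.
#' @export
censor_dependent <- function(panel, fraction = 0.10) {
  stopifnot(fraction >= 0, fraction < 0.5)
  n_drop <- floor(fraction * nrow(panel))
  if (n_drop == 0L) return(panel)
  ord <- order(panel$y)  # stable: ties keep original order
  drop_idx <- c(ord[seq_len(n_drop)], ord[seq.int(nrow(panel) - n_drop + 1L, nrow(panel))])
  panel[-drop_idx, , drop = FALSE]
}
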