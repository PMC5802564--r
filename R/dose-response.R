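# Dose-response summarization: normalized area under the survival curve,
# two-parameter IC50 fit with censoring, and the four-level response call.

#' Normalized area under the dose-response survival curve
#'
#' Trapezoidal integral of viability (clipped to \[0, 1\]) over log2(dose),
#' divided by the log2 range of the tested doses. A flat no-response curve at
#' viability 1 therefore scores exactly 1, and stronger response lowers the
#' score toward 0.
#'
#' @param dose Dose vector, uM, strictly positive; any order.
#' @param viability Viability fractions, same length.
#' @return AUSC in \[0, 1\].
#' @export
compute_ausc <- function(dose, viability) {
  if (length(dose) != length(viability)) stop("dose/viability length mismatch", call. = FALSE)
  if (length(dose) < 3) stop("insufficient data: need >= 3 doses", call. = FALSE)
  if (any(!is.finite(dose)) || any(dose <= 0)) {
    stop("doses must be positive and finite (log scale undefined otherwise)", call. = FALSE)
  }
  if (anyDuplicated(dose)) stop("duplicate doses within a series", call. = FALSE)
  o <- order(dose)
  x <- log2(dose[o])
  y <- pmin(1, pmax(0, viability[o]))
  area <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  area / (x[length(x)] - x[1])
}

#' Fit a two-parameter inhibition curve and extract IC50
#'
#' Least-squares fit of `v(c) = e_inf + (1 - e_inf) / (1 + c / k)` (top
#' asymptote fixed at 1, unit Hill slope) by bounded Levenberg-Marquardt in
#' log-dose space, multi-started over `k` at the lowest dose, the geometric
#' mid-dose, and the highest dose. The IC50 is the concentration where the
#' fitted curve crosses viability 0.5; when the fitted floor `e_inf` sits at
#' or above 0.5, or the crossing falls beyond the tested range, the IC50 is
#' right-censored and reported at the maximum tested dose.
#'
#' @param dose,viability The series (>= 4 doses).
#' @return A list of class `curve_fit`: `k`, `e_inf`, `rss`, `converged`,
#'   `ic50`, `ic50_censored`, `max_conc`.
#' @export
fit_ic50 <- function(dose, viability) {
  if (length(dose) != length(viability)) stop("dose/viability length mismatch", call. = FALSE)
  if (length(dose) < 4) stop("insufficient data: need >= 4 doses", call. = FALSE)
  if (any(dose <= 0)) stop("doses must be positive", call. = FALSE)
  o <- order(dose)
  c_ <- dose[o]
  v <- viability[o]
  max_conc <- c_[length(c_)]

  starts_k <- c(min(c_), exp(mean(log(range(c_)))), max(c_))
  e0 <- min(1, max(0, min(v)))
  resid_fn <- function(p) v - (p[2] + (1 - p[2]) / (1 + c_ / exp(p[1])))
  best <- NULL
  for (k0 in starts_k) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = c(log(k0), e0), fn = resid_fn,
        lower = c(log(min(c_)) - 20, 0),
        upper = c(log(max(c_)) + 20, 1),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$info %in% 1:4) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(k = exp(fit$par[1]), e_inf = fit$par[2], rss = rss)
    }
  }

  if (is.null(best)) {
    out <- list(k = NA_real_, e_inf = NA_real_, rss = NA_real_, converged = FALSE,
                ic50 = max_conc, ic50_censored = TRUE, max_conc = max_conc)
    class(out) <- "curve_fit"
    return(out)
  }

  if (best$e_inf < 0.5) {
    c50 <- best$k * ((1 - best$e_inf) / (0.5 - best$e_inf) - 1)
    censored <- c50 > max_conc
  } else {
    c50 <- Inf
    censored <- TRUE
  }
  out <- list(k = best$k, e_inf = best$e_inf, rss = best$rss, converged = TRUE,
              ic50 = if (censored) max_conc else c50,
              ic50_censored = censored, max_conc = max_conc)
  class(out) <- "curve_fit"
  out
}

#' Assign a response class from AUSC and IC50
#'
#' Discovery mode uses the extreme-group definitions: RESPONDER requires
#' AUSC < 0.75 together with an uncensored IC50 below a quarter of the
#' maximum tested dose; NON_RESPONDER requires AUSC > 0.98 with the IC50
#' censored beyond the tested range. Between those, AUSC in \[0.75, 0.85\] is
#' PARTIAL and (0.85, 0.98\] is LIMITED. Lines whose AUSC and IC50 disagree
#' (e.g. low AUSC but censored IC50) stay UNCLASSIFIED. Validation mode is
#' the binary rule used for newly assayed lines: Responder strictly below
#' AUSC 0.8, Non-Responder otherwise.
#'
#' @param ausc AUSC in \[0, 1\].
#' @param ic50 IC50, uM.
#' @param ic50_censored Logical; `TRUE` when 50% viability is never reached.
#' @param max_conc Maximum tested dose, uM.
#' @param mode `"discovery"` or `"validation"`.
#' @return A character class: one of `RESPONDER, PARTIAL, LIMITED,
#'   NON_RESPONDER, UNCLASSIFIED` (discovery) or `RESPONDER, NON_RESPONDER`
#'   (validation).
#' @export
classify_response <- function(ausc, ic50, ic50_censored, max_conc,
                              mode = c("discovery", "validation")) {
  mode <- match.arg(mode)
  stopifnot(is.finite(ausc))
  if (mode == "validation") {
    return(if (ausc < 0.8) "RESPONDER" else "NON_RESPONDER")
  }
  if (ausc < 0.75 && !ic50_censored && ic50 < max_conc / 4) return("RESPONDER")
  if (ausc > 0.98 && ic50_censored) return("NON_RESPONDER")
  if (ausc >= 0.75 && ausc <= 0.85) return("PARTIAL")
  if (ausc > 0.85 && ausc <= 0.98) return("LIMITED")
  "UNCLASSIFIED"
}

#' Summarize every (sample, drug) series into a response call
#'
#' Runs [compute_ausc()], [fit_ic50()] and [classify_response()] over each
#' series of a dose-response table.
#'
#' @param dr Dose-response data frame (`sample_id, drug_id, dose_uM,
#'   viability`).
#' @param mode Passed to [classify_response()].
#' @return Data frame: `sample_id, drug_id, ausc, ic50_uM, ic50_censored,
#'   max_conc, response_class`.
#' @export
response_calls <- function(dr, mode = c("discovery", "validation")) {
  mode <- match.arg(mode)
  validate_dose_response(dr)
  key <- interaction(dr$sample_id, dr$drug_id, drop = TRUE, lex.order = TRUE)
  pieces <- lapply(split(dr, key), function(series) {
    ausc <- compute_ausc(series$dose_uM, series$viability)
    fit <- fit_ic50(series$dose_uM, series$viability)
    data.frame(
      sample_id = series$sample_id[1],
      drug_id = series$drug_id[1],
      ausc = ausc,
      ic50_uM = fit$ic50,
      ic50_censored = fit$ic50_censored,
      max_conc = fit$max_conc,
      response_class = classify_response(ausc, fit$ic50, fit$ic50_censored,
                                         fit$max_conc, mode),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
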