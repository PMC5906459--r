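hill_model <- function(conc, r_max, lec50, hill) {
  ec50 <- 10^lec50
  ifelse(conc <= 0, 0, r_max * conc^hill / (conc^hill + ec50^hill))
}

#' Fit a Hill dose-response curve to peak responses
#'
#' Least-squares fit of `peak = r_max * c^h / (c^h + EC50^h)` to per-trace
#' peak dF/F0 responses, with EC50 parameterised on the log10 scale.
#' Initialisation: `r_max` at the maximum per-concentration mean peak, EC50
#' at the first tested concentration whose mean peak exceeds half that
#' maximum, Hill slope 1; the EC50 search is bounded to the tested
#' concentration span widened by one decade each way. Buffer (zero
#' concentration) enters the fit with model value 0. A third-degree
#' polynomial of mean peak versus log10 concentration (buffer excluded,
#' which has no log) is fitted alongside as the display convention, and
#' per-concentration means are summarised with SEM under both conventions:
#' over animals (pulse-averaged per animal first) and over all traces.
#'
#' @param peaks data.frame with columns `conc` and `peak`; optional
#'   `animal` and `pulse` enable the per-animal SEM.
#' @param conf_level Confidence level for the EC50 interval.
#' @return Object of class `dose_response_fit` with elements `params`
#'   (`r_max`, `ec50`, `hill`), `ec50_ci`, `ec50_in_span`, `converged`,
#'   `message`, `summary` (per-concentration table), `poly_coef`, and the
#'   underlying `nls` fit.
#' @seealso [coef.dose_response_fit()], [predict.dose_response_fit()]
#' @export
dose_response_fit <- function(peaks, conf_level = 0.95) {
  stopifnot(all(c("conc", "peak") %in% names(peaks)))
  concs <- sort(unique(peaks$conc))
  if (length(concs) < 4L) {
    stop("need at least 4 concentrations to fit a dose-response",
         call. = FALSE)
  }
  mean_by_conc <- tapply(peaks$peak, peaks$conc, mean)
  conc_levels <- as.numeric(names(mean_by_conc))
  r_max0 <- max(mean_by_conc)
  pos <- conc_levels > 0
  half_idx <- which(pos & mean_by_conc >= r_max0 / 2)
  ec50_0 <- if (length(half_idx) > 0) conc_levels[half_idx[1]] else
    stats::median(conc_levels[pos])
  span <- range(conc_levels[pos])
  lec_lo <- log10(span[1]) - 1
  lec_hi <- log10(span[2]) + 1
  fit <- tryCatch(
    minpack.lm::nlsLM(
      peak ~ hill_model(conc, r_max, lec50, hill),
      data = peaks,
      start = list(r_max = r_max0, lec50 = log10(ec50_0), hill = 1),
      lower = c(r_max = 1e-9, lec50 = lec_lo, hill = 0.1),
      upper = c(r_max = Inf, lec50 = lec_hi, hill = 10),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    params <- c(r_max = NA_real_, ec50 = NA_real_, hill = NA_real_)
    ec50_ci <- c(NA_real_, NA_real_)
    converged <- FALSE
    msg <- conditionMessage(fit)
    fit <- NULL
  } else {
    cf <- stats::coef(fit)
    params <- c(r_max = unname(cf["r_max"]), ec50 = 10^unname(cf["lec50"]),
                hill = unname(cf["hill"]))
    se_lec <- tryCatch(sqrt(stats::vcov(fit)["lec50", "lec50"]),
                       error = function(e) NA_real_)
    dfree <- nrow(peaks) - 3L
    tq <- stats::qt(1 - (1 - conf_level) / 2, dfree)
    ec50_ci <- 10^(cf["lec50"] + c(-1, 1) * tq * se_lec)
    converged <- fit$convInfo$isConv %||% TRUE
    msg <- "converged"
    if (abs(cf["lec50"] - lec_lo) < 1e-6 || abs(cf["lec50"] - lec_hi) < 1e-6) {
      msg <- "EC50 at search bound; estimate unreliable"
    }
  }
  in_span <- !is.na(params["ec50"]) &&
    params["ec50"] >= span[1] && params["ec50"] <= span[2]
  summary_tab <- dose_summary(peaks)
  poly_coef <- dose_poly(peaks)
  structure(list(params = params, ec50_ci = unname(ec50_ci),
                 conf_level = conf_level, ec50_in_span = in_span,
                 converged = isTRUE(converged), message = msg,
                 conc_span = span, summary = summary_tab,
                 poly_coef = poly_coef, fit = fit, data = peaks),
            class = "dose_response_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

dose_summary <- function(peaks) {
  out <- do.call(rbind, lapply(split(peaks, peaks$conc), function(g) {
    sem_animals <- NA_real_; n_animals <- NA_integer_
    if ("animal" %in% names(g)) {
      per_animal <- tapply(g$peak, g$animal, mean)
      n_animals <- length(per_animal)
      sem_animals <- stats::sd(per_animal) / sqrt(n_animals)
    }
    data.frame(conc = g$conc[1], mean_peak = mean(g$peak),
               sem_traces = stats::sd(g$peak) / sqrt(nrow(g)),
               n_traces = nrow(g), sem_animals = sem_animals,
               n_animals = n_animals)
  }))
  out <- out[order(out$conc), ]
  rownames(out) <- NULL
  out
}

dose_poly <- function(peaks, degree = 3) {
  g <- peaks[peaks$conc > 0, ]
  mp <- tapply(g$peak, g$conc, mean)
  lc <- log10(as.numeric(names(mp)))
  if (length(mp) <= degree) return(rep(NA_real_, degree + 1))
  stats::coef(stats::lm(y ~ stats::poly(x, degree, raw = TRUE),
                        data = data.frame(x = lc, y = as.numeric(mp))))
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("<dose_response_fit>\n")
  if (x$converged) {
    cat(sprintf("  r_max = %.3f dF/F0, EC50 = %.3g M, hill = %.2f\n",
                x$params["r_max"], x$params["ec50"], x$params["hill"]))
    cat(sprintf("  EC50 %d%% CI: [%.3g, %.3g] M%s\n",
                round(100 * x$conf_level), x$ec50_ci[1], x$ec50_ci[2],
                if (x$ec50_in_span) "" else "  [outside tested span]"))
  }
  if (x$message != "converged") cat("  note:", x$message, "\n")
  invisible(x)
}

#' @export
summary.dose_response_fit <- function(object, ...) {
  print(object)
  cat("\nPer-concentration peaks:\n")
  print(object$summary, row.names = FALSE, digits = 3)
  invisible(object)
}

#' @export
coef.dose_response_fit <- function(object, ...) object$params

#' Predicted dose-response curve
#' @param object A `dose_response_fit`.
#' @param conc Molar concentrations.
#' @param ... Unused.
#' @return Predicted peak dF/F0 at each concentration.
#' @export
predict.dose_response_fit <- function(object, conc, ...) {
  p <- object$params
  hill_model(conc, p["r_max"], log10(p["ec50"]), p["hill"])
}

#' @export
plot.dose_response_fit <- function(x, ...) {
  s <- x$summary[x$summary$conc > 0, ]
  lc <- log10(s$conc)
  sem <- ifelse(is.na(s$sem_animals), s$sem_traces, s$sem_animals)
  graphics::plot(lc, s$mean_peak, pch = 19, xlab = "log10 concentration (M)",
                 ylab = "peak dF/F0",
                 ylim = range(c(s$mean_peak - sem, s$mean_peak + sem, 0)), ...)
  graphics::arrows(lc, s$mean_peak - sem, lc, s$mean_peak + sem,
                   angle = 90, code = 3, length = 0.04)
  if (x$converged) {
    cg <- seq(min(lc) - 0.5, max(lc) + 0.5, length.out = 200)
    graphics::lines(cg, predict(x, 10^cg), col = "steelblue", lwd = 2)
    graphics::abline(v = log10(x$params["ec50"]), lty = 3)
  }
  invisible(x)
}

#' Export a dose-response fit
#'
#' Writes the fitted parameters and CI as JSON and the per-concentration
#' summary as CSV.
#'
#' @param x A `dose_response_fit`.
#' @param json_path,csv_path Output paths (`NULL` to skip either).
#' @return `x`, invisibly.
#' @export
write_dose_response <- function(x, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(r_max = unname(x$params["r_max"]),
           ec50 = unname(x$params["ec50"]),
           hill = unname(x$params["hill"]),
           ec50_ci = x$ec50_ci, conf_level = x$conf_level,
           ec50_in_span = x$ec50_in_span, converged = x$converged,
           message = x$message, poly_coef = unname(x$poly_coef)),
      json_path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  if (!is.null(csv_path)) {
    utils::write.csv(x$summary, csv_path, row.names = FALSE)
  }
  invisible(x)
}

#' Rank correlation between two neurons' peak responses
#'
#' Spearman correlation of per-(concentration, pulse) mean peaks between
#' two neuron types, the descriptive cross-neuron readout of the
#' dose-response run. By default the comparison is restricted to the high
#' concentrations at which the second neuron is actually active (mean peak
#' more than twice its zero-concentration, i.e. noise-floor, mean), where
#' cross-suppression would show as a negative correlation; over the full
#' range both neurons simply rise with concentration.
#'
#' @param peaks data.frame from [trace_peaks()] with a `neuron` column
#'   containing both types.
#' @param neurons Character pair to correlate (second neuron gates the
#'   concentration range).
#' @param high_conc_only Restrict to concentrations where the second
#'   neuron responds?
#' @return `stats::cor.test` result (Spearman).
#' @export
neuron_peak_correlation <- function(peaks, neurons = c("AWA", "ASH"),
                                    high_conc_only = TRUE) {
  a <- peaks[peaks$neuron == neurons[1], ]
  b <- peaks[peaks$neuron == neurons[2], ]
  if (high_conc_only) {
    mb <- tapply(b$peak, b$conc, mean)
    floor_b <- if ("0" %in% names(mb)) mb[["0"]] else min(mb)
    concs <- as.numeric(names(mb))
    active <- concs[concs > 0 & mb > 2 * floor_b]
    a <- a[a$conc %in% active, ]
    b <- b[b$conc %in% active, ]
  }
  ka <- tapply(a$peak, interaction(a$conc, a$pulse), mean)
  kb <- tapply(b$peak, interaction(b$conc, b$pulse), mean)
  common <- intersect(names(ka), names(kb))
  stats::cor.test(ka[common], kb[common], method = "spearman", exact = FALSE)
}
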