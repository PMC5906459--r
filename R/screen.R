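#' One-sample t statistic from its definition
#'
#' `t = mean(x) * sqrt(n) / sd(x)`, tested two-sided against zero, computed
#' directly from the formula.
#'
#' @param x Numeric sample (n >= 2).
#' @return List with `t`, `df`, `p`, `mean`, `sd`, `n`, and `degenerate`
#'   (`TRUE` when the sample variance is zero, leaving t undefined).
#' @export
one_sample_t <- function(x) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 observations", call. = FALSE)
  m <- sum(x) / n
  s <- sqrt(sum((x - m)^2) / (n - 1))
  if (s <= sqrt(.Machine$double.eps) * max(abs(m), 1)) {
    return(list(t = NA_real_, df = n - 1L, p = NA_real_, mean = m, sd = s,
                n = n, degenerate = TRUE))
  }
  t <- m * sqrt(n) / s
  list(t = t, df = n - 1L, p = 2 * stats::pt(-abs(t), n - 1L), mean = m,
       sd = s, n = n, degenerate = FALSE)
}

#' Paired screen statistics against the immediately prior buffer control
#'
#' For every solvent-concentration well along the delivery sequence, the
#' per-animal difference between its peak response and the same animal's
#' peak in the immediately preceding buffer-control well is tested against
#' zero (no effect) with a one-sample t-test, two-sided, implemented from
#' the t-statistic definition. Significance uses the Bonferroni-corrected
#' threshold `alpha / m` with `alpha = 0.001` printed convention and `m`
#' the number of solvent-concentration comparisons (28 for 14 solvents at
#' two concentrations).
#'
#' @param peaks A `screen_peaks` data.frame (`animal,well,fluid,
#'   concentration,peak`), e.g. from [gen_screen()].
#' @param map The screen `plate_map` (defaults to the one attached to
#'   `peaks`).
#' @param control Control fluid name.
#' @param alpha Family-wise level (default 0.001).
#' @param m Number of comparisons for the Bonferroni correction (default:
#'   the number of solvent wells in the sequence).
#' @return Object of class `screen_result`: data.frame with one row per
#'   solvent-concentration (`solvent,concentration,well,prior_well,
#'   mean_peak,mean_diff,sd_diff,n,t,df,p,significant,degenerate`), with
#'   `alpha` and `m` attributes.
#' @export
screen_stats <- function(peaks, map = attr(peaks, "map"), control = "buffer",
                         alpha = 0.001, m = NULL) {
  if (is.null(map) || is.null(map$order)) {
    stop("no screen delivery order available", call. = FALSE)
  }
  n_animals <- length(unique(peaks$animal))
  if (n_animals < 2L) stop("need at least 2 animals", call. = FALSE)
  order <- map$order
  asg <- map$assignments[match(order, map$assignments$well), ]
  solvent_idx <- which(asg$fluid != control)
  if (is.null(m)) m <- length(solvent_idx)
  rows <- NULL
  for (i in solvent_idx) {
    if (i == 1L || asg$fluid[i - 1L] != control) {
      stop("solvent well ", asg$well[i],
           " has no immediately prior buffer control", call. = FALSE)
    }
    w <- asg$well[i]; wc <- asg$well[i - 1L]
    ps <- peaks[peaks$well == w, ]
    pc <- peaks[peaks$well == wc, ]
    d <- ps$peak[order(ps$animal)] - pc$peak[order(pc$animal)]
    tt <- one_sample_t(d)
    rows <- rbind(rows, data.frame(
      solvent = asg$fluid[i], concentration = asg$concentration[i],
      well = w, prior_well = wc, mean_peak = mean(ps$peak),
      mean_diff = tt$mean, sd_diff = tt$sd, n = tt$n, t = tt$t, df = tt$df,
      p = tt$p,
      significant = !tt$degenerate && !is.na(tt$p) && tt$p < alpha / m,
      degenerate = tt$degenerate, stringsAsFactors = FALSE))
  }
  rownames(rows) <- NULL
  structure(rows, class = c("screen_result", "data.frame"),
            alpha = alpha, m = m, control = control)
}

#' @export
print.screen_result <- function(x, ...) {
  sig <- x[x$significant, ]
  cat(sprintf("<screen_result> %d comparisons, Bonferroni alpha = %g / %d\n",
              nrow(x), attr(x, "alpha"), attr(x, "m")))
  if (nrow(sig) > 0) {
    cat("  significant suppressors:\n")
    for (i in seq_len(nrow(sig))) {
      cat(sprintf("    %s @ %g%%: mean diff %+.3f dF/F0 (t = %.1f, p = %.2g)\n",
                  sig$solvent[i], sig$concentration[i], sig$mean_diff[i],
                  sig$t[i], sig$p[i]))
    }
  } else cat("  no significant effects\n")
  invisible(x)
}

#' Significant solvent-concentration pairs
#' @param x A `screen_result`.
#' @return data.frame `solvent,concentration` of flagged comparisons.
#' @export
significant_suppressors <- function(x) {
  s <- as.data.frame(x)[x$significant, c("solvent", "concentration")]
  rownames(s) <- NULL
  s
}

#' Secondary repeated-measures F report for the screen
#'
#' A simple one-way repeated-measures ANOVA of peak response across wells
#' with animal as the blocking factor, offered as a descriptive companion
#' to the paired t-test path.
#'
#' @param peaks A `screen_peaks` data.frame.
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
screen_rm_f <- function(peaks) {
  d <- data.frame(peak = peaks$peak, well = factor(peaks$well),
                  animal = factor(peaks$animal))
  fit <- stats::aov(peak ~ well + Error(animal), data = d)
  tab <- summary(fit)[["Error: Within"]][[1]]
  list(F = tab["well", "F value"], df1 = tab["well", "Df"],
       df2 = tab["Residuals", "Df"], p = tab["well", "Pr(>F)"])
}

#' Write screen results as CSV
#' @param x A `screen_result`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_screen_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
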