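#' Fit a sigmoid geographic cline
#'
#' Maximum-likelihood fit of the allele-frequency cline
#' \deqn{p(x) = pmin + (pmax - pmin) / (1 + exp(-4 (x - c) / w))}
#' to per-site binomial counts along a transect, where c is the cline
#' centre (km), w the width (km, the inverse of the maximal slope scaled
#' to the frequency range), and pmin/pmax the asymptotes. Two model
#' variants are fitted: \code{"fixed"} pins the asymptotes at 0 and 1
#' (2 free parameters), \code{"free"} estimates them (4 free parameters).
#' Optimization is multi-start (seeded) L-BFGS-B on transformed
#' parameters; AIC = 2k - 2 logL.
#'
#' @param site_freqs data frame with columns \code{distance_km},
#'   \code{allele_count} (reference-allele copies observed) and
#'   \code{allele_total} (gene copies sampled); one row per site. Sites
#'   with fewer than \code{min_n} diploid individuals
#'   (\code{allele_total/2}) are dropped before fitting.
#' @param variant \code{"free"} (default) or \code{"fixed"} scaling.
#' @param n_starts random multi-starts (default 5).
#' @param seed integer seed for the starts.
#' @param min_n minimum diploid sample size per retained site
#'   (default 10).
#' @return object of class \code{"cline_fit"} with elements \code{centre},
#'   \code{width}, \code{pmin}, \code{pmax}, \code{logL}, \code{AIC},
#'   \code{k}, \code{variant}, \code{data}, and (via
#'   \code{\link{centre_support}}) a two-log-likelihood support interval.
#'   Methods: \code{print}, \code{coef}, \code{logLik}, \code{AIC},
#'   \code{predict}, \code{plot}.
#' @export
fit_cline <- function(site_freqs, variant = c("free", "fixed"),
                      n_starts = 5L, seed = 1L, min_n = 10) {
  variant <- match.arg(variant)
  stopifnot(all(c("distance_km", "allele_count", "allele_total") %in%
                  names(site_freqs)))
  d <- site_freqs[site_freqs$allele_total >= 2 * min_n, , drop = FALSE]
  if (length(unique(d$distance_km)) < 3L)
    stop("need at least 3 sites with distinct distances after the size filter")
  if (any(d$allele_count < 0 | d$allele_count > d$allele_total))
    stop("allele_count must lie in [0, allele_total]")
  x <- d$distance_km; y <- d$allele_count; n <- d$allele_total
  rng <- range(x); span <- diff(rng)

  nll <- function(par) {
    p <- cline_p(x, par)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(y * log(p) + (n - y) * log(1 - p))
  }
  # par = (c, log w, logit pmin, logit pmax-range) depending on variant
  unpack <- function(th) {
    if (variant == "fixed")
      list(c = th[1L], w = exp(th[2L]), pmin = 0, pmax = 1)
    else {
      lo <- stats::plogis(th[3L])
      hi <- lo + (1 - lo) * stats::plogis(th[4L])
      list(c = th[1L], w = exp(th[2L]), pmin = lo, pmax = hi)
    }
  }
  cline_p <- function(x, th) {
    pr <- unpack(th)
    pr$pmin + (pr$pmax - pr$pmin) / (1 + exp(-4 * (x - pr$c) / pr$w))
  }

  set.seed(seed)
  k <- if (variant == "fixed") 2L else 4L
  best <- NULL
  obs_p <- y / n
  for (s in seq_len(n_starts)) {
    th0 <- c(stats::runif(1, rng[1L], rng[2L]),
             log(stats::runif(1, span / 20, span)))
    if (variant == "free")
      th0 <- c(th0, stats::qlogis(pmin(pmax(min(obs_p), 0.02), 0.4)) +
                 stats::rnorm(1, 0, 0.5),
               stats::rnorm(1, 2, 0.5))
    opt <- try(stats::optim(th0, nll, method = "L-BFGS-B",
                            lower = c(rng[1L] - span, log(span / 200),
                                      -8, -8)[seq_len(k)],
                            upper = c(rng[2L] + span, log(4 * span),
                                      8, 8)[seq_len(k)]),
               silent = TRUE)
    if (inherits(opt, "try-error") || !is.finite(opt$value)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("cline optimization failed from every start")
  pr <- unpack(best$par)
  logL <- -best$value
  flat <- stats::sd(obs_p) < 1e-3 || abs(pr$pmax - pr$pmin) < 1e-3
  if (flat)
    warning("essentially flat frequencies: cline width is unidentifiable")
  structure(list(centre = pr$c, width = pr$w, pmin = pr$pmin,
                 pmax = pr$pmax, logL = logL, AIC = 2 * k - 2 * logL,
                 k = k, variant = variant, flat = flat,
                 data = d, theta = best$par,
                 transect_range = rng, n_starts = n_starts, seed = seed),
            class = "cline_fit")
}

cline_predict_p <- function(fit, x)
  fit$pmin + (fit$pmax - fit$pmin) / (1 + exp(-4 * (x - fit$centre) / fit$width))

#' @export
print.cline_fit <- function(x, ...) {
  cat(sprintf("cline_fit (%s scaling): centre = %.1f km, width = %.1f km\n",
              x$variant, x$centre, x$width))
  cat(sprintf("asymptotes %.3f-%.3f; logL = %.2f, AIC = %.2f (k = %d)\n",
              x$pmin, x$pmax, x$logL, x$AIC, x$k))
  if (!is.null(x$centre_support))
    cat(sprintf("centre support (2 logL units): %.1f-%.1f km%s\n",
                x$centre_support[1L], x$centre_support[2L],
                if (isTRUE(attr(x$centre_support, "open"))) " (open-ended)" else ""))
  invisible(x)
}

#' @export
coef.cline_fit <- function(object, ...)
  c(centre = object$centre, width = object$width,
    pmin = object$pmin, pmax = object$pmax)

#' @export
logLik.cline_fit <- function(object, ...)
  structure(object$logL, df = object$k, class = "logLik")

#' @export
predict.cline_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$distance_km else
    if (is.data.frame(newdata)) newdata$distance_km else newdata
  cline_predict_p(object, x)
}

#' @export
plot.cline_fit <- function(x, ...) {
  d <- x$data
  graphics::plot(d$distance_km, d$allele_count / d$allele_total,
                 xlab = "transect distance (km)",
                 ylab = "reference-allele frequency", pch = 19, ylim = c(0, 1),
                 ...)
  xs <- seq(min(d$distance_km), max(d$distance_km), length.out = 200)
  graphics::lines(xs, cline_predict_p(x, xs))
  graphics::abline(v = x$centre, lty = 2)
  invisible(x)
}

#' Choose a cline model by AIC
#'
#' @param fits list of \code{"cline_fit"} objects fitted to the same data.
#' @return the minimum-AIC fit; AIC ties go to the fit with fewer
#'   parameters.
#' @export
select_cline_model <- function(fits) {
  stopifnot(length(fits) >= 2L)
  aic <- vapply(fits, function(f) f$AIC, numeric(1))
  kk <- vapply(fits, function(f) f$k, numeric(1))
  fits[[order(aic, kk)[1L]]]
}

#' Two-log-likelihood support interval of the cline centre
#'
#' Profiles the log-likelihood over the centre (re-optimizing every other
#' parameter) and returns the interval where the profile stays within two
#' log-likelihood units of the maximum. Bounds that never drop two units
#' inside the search range (transect extended by one width) are reported
#' open-ended and flagged.
#'
#' @param fit a \code{"cline_fit"}.
#' @param grid_n profile grid resolution per side (default 80).
#' @return the fit with \code{$centre_support} set (numeric length-2,
#'   attribute \code{"open"} when a bound is open-ended).
#' @export
centre_support <- function(fit, grid_n = 80L) {
  d <- fit$data
  x <- d$distance_km; y <- d$allele_count; n <- d$allele_total
  variant <- fit$variant
  prof_nll <- function(cc) {
    obj <- function(th2) {
      w <- exp(th2[1L])
      if (variant == "fixed") { lo <- 0; hi <- 1 } else {
        lo <- stats::plogis(th2[2L]); hi <- lo + (1 - lo) * stats::plogis(th2[3L])
      }
      p <- lo + (hi - lo) / (1 + exp(-4 * (x - cc) / w))
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      -sum(y * log(p) + (n - y) * log(1 - p))
    }
    th2 <- fit$theta[-1L]
    if (length(th2) == 1L) {
      span <- diff(fit$transect_range)
      opt <- try(stats::optimize(function(v) obj(v),
                                 lower = log(span / 200),
                                 upper = log(4 * span)), silent = TRUE)
      if (inherits(opt, "try-error")) Inf else opt$objective
    } else {
      opt <- try(stats::optim(th2, obj, method = "Nelder-Mead",
                              control = list(maxit = 400)), silent = TRUE)
      if (inherits(opt, "try-error")) Inf else opt$value
    }
  }
  lo_lim <- fit$transect_range[1L] - fit$width
  hi_lim <- fit$transect_range[2L] + fit$width
  target <- -fit$logL + 2
  scan_side <- function(from, to) {
    cs <- seq(from, to, length.out = grid_n)
    nn <- vapply(cs, prof_nll, numeric(1))
    drop_idx <- which(nn > target)
    if (!length(drop_idx)) return(list(bound = to, open = TRUE))
    j <- drop_idx[1L]
    if (j == 1L) return(list(bound = cs[1L], open = FALSE))
    # linear interpolation of the crossing
    b <- cs[j - 1L] + (target - nn[j - 1L]) / (nn[j] - nn[j - 1L]) *
      (cs[j] - cs[j - 1L])
    list(bound = b, open = FALSE)
  }
  left  <- scan_side(fit$centre, lo_lim)
  right <- scan_side(fit$centre, hi_lim)
  sup <- sort(c(left$bound, right$bound))
  attr(sup, "open") <- left$open || right$open
  fit$centre_support <- sup
  fit
}

#' Test a locus cline for displacement from a reference cline
#'
#' A locus cline is significantly displaced when the two-log-likelihood
#' support intervals of the two cline centres do not overlap. Open-ended
#' intervals are conservatively called concordant and flagged.
#'
#' @param locus_fit,reference_fit \code{"cline_fit"} objects carrying
#'   centre support intervals (see \code{\link{centre_support}}).
#' @return list with \code{$displaced} (logical), \code{$call}
#'   (\code{"displaced"} or \code{"concordant"}) and \code{$open} flag.
#' @export
displacement_test <- function(locus_fit, reference_fit) {
  s1 <- locus_fit$centre_support; s2 <- reference_fit$centre_support
  if (is.null(s1) || is.null(s2))
    stop("both fits need centre_support (run centre_support() first)")
  open <- isTRUE(attr(s1, "open")) || isTRUE(attr(s2, "open"))
  displaced <- if (open) FALSE else (s1[2L] < s2[1L] || s2[2L] < s1[1L])
  list(displaced = displaced,
       call = if (displaced) "displaced" else "concordant",
       open = open,
       support_locus = as.numeric(s1), support_reference = as.numeric(s2))
}
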