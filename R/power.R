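#' Efficiency and accuracy of class assignment
#'
#' Efficiency is the fraction of truly class-c individuals assigned to c
#' (a recall); accuracy is the fraction of individuals assigned to c that
#' truly are c (a precision). Unassigned individuals count against
#' efficiency but never against accuracy. When \code{cls} names a pooled
#' group present in \code{assigned}, \code{members} gives the true classes
#' counted as belonging to it.
#'
#' @param true_labels,assigned_labels aligned character vectors;
#'   \code{assigned_labels} may contain \code{"unassigned"}.
#' @param cls the class (or pooled-group label) evaluated.
#' @param members true classes belonging to \code{cls} (default
#'   \code{cls} itself).
#' @return list with \code{efficiency}, \code{accuracy} (NA when nothing
#'   is assigned to the class) and the underlying counts.
#' @export
confusion_metrics <- function(true_labels, assigned_labels, cls,
                              members = cls) {
  if (length(true_labels) != length(assigned_labels))
    stop("label vectors must be aligned")
  known <- c(hybrid_classes(), "unassigned")
  bad <- setdiff(unique(c(true_labels, setdiff(assigned_labels, cls))), known)
  bad <- setdiff(bad, cls)
  if (length(bad)) stop("unknown class label(s): ", paste(bad, collapse = ", "))
  is_true <- true_labels %in% members
  is_assigned <- assigned_labels == cls
  n_true <- sum(is_true)
  n_assigned <- sum(is_assigned)
  n_correct <- sum(is_true & is_assigned)
  if (n_true == 0L) stop("no individual is truly of class ", cls)
  list(efficiency = n_correct / n_true,
       accuracy = if (n_assigned > 0L) n_correct / n_assigned else NA_real_,
       n_true = n_true, n_assigned = n_assigned, n_correct = n_correct)
}

#' Assignment power
#'
#' @param efficiency,accuracy fractions in [0, 1].
#' @return power = efficiency * accuracy (NA when accuracy is NA).
#' @export
assignment_power <- function(efficiency, accuracy) efficiency * accuracy

#' Simulation study of hybrid-assignment power
#'
#' Builds replicated labelled datasets of the six hybrid classes from a
#' reference panel, classifies each with the Gibbs six-class model (or the
#' fixed-frequency ML path), and scores per-class and pooled-hybrid
#' efficiency, accuracy and power across posterior-probability thresholds.
#' The default layout is the calibration design of the panel: 3 replicates
#' x 3 datasets of 288 individuals (48 per class).
#'
#' Cluster orientation: the classifier cannot know which of its two
#' inferred gene pools is "population A", so its posterior is re-oriented
#' against the generating reference frequencies (whichever orientation
#' makes the estimated cluster-A frequencies correlate better with the
#' panel's p_A) before scoring.
#'
#' @param ref a \code{"reference_panel"} or two-population reference
#'   \code{genotype_matrix}.
#' @param n_individuals,n_datasets,n_replicates study layout (defaults
#'   288, 3, 3).
#' @param thresholds posterior thresholds scored (default 0.5-0.9).
#' @param method \code{"gibbs"} (default) or \code{"ml"} (true-frequency
#'   oracle path).
#' @param burnin,sweeps Gibbs settings (defaults 5000 / 30000).
#' @param seed integer seed driving both simulation and classification.
#' @return object of class \code{"power_report"}: \code{$metrics} (data
#'   frame: replicate, dataset, class, threshold, efficiency, accuracy,
#'   power with power on the 0-100 scale), \code{$summary} (minimum and
#'   mean over runs per class x threshold), and the study settings.
#' @export
run_power_study <- function(ref, n_individuals = 288L, n_datasets = 3L,
                            n_replicates = 3L,
                            thresholds = c(0.5, 0.6, 0.7, 0.8, 0.9),
                            method = c("gibbs", "ml"),
                            burnin = 5000L, sweeps = 30000L, seed = 1L) {
  method <- match.arg(method)
  fr <- panel_freqs(ref)
  sets <- build_power_datasets(ref, n_individuals = n_individuals,
                               n_datasets = n_datasets,
                               n_replicates = n_replicates, seed = seed)
  pool <- list(hybrid = c("F1", "F2", "BCA", "BCB"))
  rows <- list()
  for (s in sets) {
    fit <- if (method == "gibbs")
      classify_gibbs(s$gm, burnin = burnin, sweeps = sweeps,
                     seed = (s$seed + 17L) %% .Machine$integer.max)
    else
      classify_ml(s$gm, fr$p_A, fr$p_B)
    fit <- orient_to_reference(fit, fr)
    for (t in thresholds) {
      lab <- assign_classes(fit, threshold = t)
      lab_pooled <- assign_classes(fit, threshold = t, pooling = pool)
      for (cl in hybrid_classes()) {
        m <- confusion_metrics(s$labels, lab, cl)
        rows[[length(rows) + 1L]] <- data.frame(
          replicate = s$replicate, dataset = s$dataset, class = cl,
          threshold = t, efficiency = m$efficiency, accuracy = m$accuracy,
          power = 100 * assignment_power(m$efficiency, m$accuracy),
          stringsAsFactors = FALSE)
      }
      mh <- confusion_metrics(s$labels, lab_pooled, "hybrid",
                              members = pool$hybrid)
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = s$replicate, dataset = s$dataset, class = "hybrid_pooled",
        threshold = t, efficiency = mh$efficiency, accuracy = mh$accuracy,
        power = 100 * assignment_power(mh$efficiency, mh$accuracy),
        stringsAsFactors = FALSE)
    }
  }
  metrics <- do.call(rbind, rows)
  min_mean <- function(x) {
    x <- x[is.finite(x)]
    if (!length(x)) return(c(min = NA_real_, mean = NA_real_))
    c(min = min(x), mean = mean(x))
  }
  summary_df <- stats::aggregate(
    metrics[, c("efficiency", "accuracy", "power")],
    by = metrics[, c("class", "threshold")], min_mean)
  structure(list(metrics = metrics, summary = summary_df,
                 settings = list(method = method, burnin = burnin,
                                 sweeps = sweeps, seed = seed,
                                 n_individuals = n_individuals,
                                 n_datasets = n_datasets,
                                 n_replicates = n_replicates,
                                 thresholds = thresholds)),
            class = "power_report")
}

#' Orient a fitted posterior against reference frequencies
#'
#' A classifier fitted without labelled references cannot know which of
#' its two inferred gene pools is "population A"; this helper flips the
#' A/B orientation of a \code{"hybrid_posterior"} (PureA/PureB and
#' BCA/BCB swap, F1 and F2 are symmetric) whenever its estimated
#' cluster-A frequencies correlate better with the reference panel's p_B
#' than with its p_A.
#'
#' @param fit a \code{"hybrid_posterior"} carrying \code{freq_A},
#'   \code{freq_B} (as returned by \code{\link{classify_gibbs}}).
#' @param fr a \code{"reference_panel"}, or any list with per-locus
#'   \code{p_A} and \code{p_B}.
#' @return the (possibly flipped) \code{"hybrid_posterior"}.
#' @export
orient_to_reference <- function(fit, fr) {
  same <- stats::cor(c(fit$freq_A, fit$freq_B), c(fr$p_A, fr$p_B))
  swapped <- stats::cor(c(fit$freq_B, fit$freq_A), c(fr$p_A, fr$p_B))
  if (!is.na(same) && !is.na(swapped) && swapped > same) {
    fit$posterior <- swap_ab(fit$posterior)
    tmp <- fit$freq_A; fit$freq_A <- fit$freq_B; fit$freq_B <- tmp
  }
  fit
}

#' Minimum metric over classes, thresholds and runs
#'
#' Convenience accessor for the headline numbers of a power study: the
#' minimum of a metric over every run and every listed class at the listed
#' thresholds, on the percent scale for efficiency/accuracy (power is
#' already on the 0-100 scale).
#'
#' @param report a \code{"power_report"}.
#' @param metric \code{"efficiency"}, \code{"accuracy"} or \code{"power"}.
#' @param classes classes included (default the six single classes).
#' @param thresholds thresholds included (default all scored).
#' @return a single number (percent scale for all three metrics).
#' @export
power_min <- function(report, metric = c("efficiency", "accuracy", "power"),
                      classes = hybrid_classes(), thresholds = NULL) {
  metric <- match.arg(metric)
  m <- report$metrics
  sel <- m$class %in% classes
  if (!is.null(thresholds)) sel <- sel & m$threshold %in% thresholds
  v <- m[[metric]][sel]
  v <- v[is.finite(v)]
  if (!length(v)) return(NA_real_)
  if (metric == "power") min(v) else 100 * min(v)
}

#' @export
print.power_report <- function(x, ...) {
  s <- x$settings
  cat(sprintf("power_report: %d x %d datasets of %d individuals (%s)\n",
              s$n_replicates, s$n_datasets, s$n_individuals, s$method))
  for (t in s$thresholds) {
    cat(sprintf("T = %.1f: min over six classes E = %.1f%%, A = %.1f%%, P = %.1f\n",
                t,
                power_min(x, "efficiency", thresholds = t),
                power_min(x, "accuracy", thresholds = t),
                power_min(x, "power", thresholds = t)))
  }
  cat(sprintf("pooled hybrids, all thresholds: E = %.1f%%, A = %.1f%%, P = %.1f\n",
              power_min(x, "efficiency", classes = "hybrid_pooled"),
              power_min(x, "accuracy", classes = "hybrid_pooled"),
              power_min(x, "power", classes = "hybrid_pooled")))
  invisible(x)
}
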