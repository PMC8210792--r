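#' Default run configuration
#'
#' The package-wide defaults for an end-to-end run: QC thresholds (10%
#' site missingness, 0.5 heterozygote fraction, 20% individual
#' missingness, 2 discordant replicate genotypes), panel design (top 500
#' ranked loci per comparison, absolute theta threshold 0.4), sampler
#' settings, assignment thresholds 0.5-0.9, and permutation counts (999
#' AMOVA permutations, 5000 F_ST Monte-Carlo replicates).
#'
#' @param ... named overrides merged over the defaults (nested lists are
#'   merged by name).
#' @return a named list of class \code{"run_config"}.
#' @export
run_config <- function(...) {
  base <- list(
    out_dir = "hybridscan_out",
    seed = 1L,
    stages = c("qc", "stats", "panel", "power", "admix"),
    input = NULL,                      # list(path=, format=)
    simulate = list(n_loci = 84L, n_per_pop = 40L, f_div = 0.5),
    qc = list(max_missing_site = 0.1, max_het = 0.5,
              max_missing_ind = 0.2, max_discordant = 2L),
    stats = list(amova_permutations = 999L, fst_reps = 5000L),
    panel = list(focal = NULL, against = NULL, top_k = 500L, min_fst = 0.4),
    power = list(n_individuals = 288L, n_datasets = 3L, n_replicates = 3L,
                 burnin = 5000L, sweeps = 30000L,
                 thresholds = c(0.5, 0.6, 0.7, 0.8, 0.9)),
    classify = list(burnin = 5000L, sweeps = 30000L,
                    thresholds = c(0.5, 0.8)),
    admix = list(k_range = 1:4, replicates = 2L),
    cline = list(sites = NULL, variant = "free", n_starts = 5L, min_n = 10)
  )
  cfg <- modify_list_deep(base, list(...))
  class(cfg) <- c("run_config", "list")
  cfg
}

modify_list_deep <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && is.list(over[[nm]]) &&
        !is.null(names(over[[nm]])))
      base[[nm]] <- modify_list_deep(base[[nm]], over[[nm]])
    else base[[nm]] <- over[[nm]]
  }
  base
}

#' Read a YAML run configuration
#'
#' @param path YAML file whose keys mirror \code{\link{run_config}}.
#' @return a validated \code{"run_config"}.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  do.call(run_config, yaml::read_yaml(path))
}

validate_config <- function(cfg) {
  if (!is.null(cfg$input)) {
    if (is.null(cfg$input$path) || !file.exists(cfg$input$path))
      stop("validation error: input path missing or not found: ",
           cfg$input$path)
  }
  bad <- setdiff(cfg$stages, c("qc", "stats", "panel", "power", "admix",
                               "cline", "classify"))
  if (length(bad))
    stop("validation error: unknown stage(s): ", paste(bad, collapse = ", "))
  if ("cline" %in% cfg$stages && is.null(cfg$cline$sites))
    stop("validation error: cline stage requested without cline$sites")
  invisible(cfg)
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in order — QC, diversity/divergence
#' statistics, panel design, assignment-power simulation, admixture
#' clustering + PCA, cline fitting — writing one TSV per stage plus a run
#' log (with every seed used) and a JSON summary under
#' \code{cfg$out_dir}. Identical configuration and seed give identical
#' numeric outputs. When no input file is configured, a synthetic
#' two-population reference is generated first and analysed end to end.
#'
#' @param cfg a \code{\link{run_config}} (or path to a YAML file).
#' @return invisibly, a list with the per-stage result objects and the
#'   paths written.
#' @export
run_pipeline <- function(cfg = run_config()) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  validate_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "run_log.txt")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  logf("hybridscan run, seed = %d", cfg$seed)
  res <- list(); written <- character(0)
  emit <- function(df, name) {
    p <- file.path(cfg$out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, p)
  }

  stage <- "input"
  result <- try({
    if (!is.null(cfg$input)) {
      gm <- read_genotypes(cfg$input$path, cfg$input$format)
      ref <- NULL
      logf("input: %s (%s), %d x %d", cfg$input$path, cfg$input$format,
           nrow(gm$calls), ncol(gm$calls))
    } else {
      sim <- simulate_reference_pops(cfg$simulate$n_loci,
                                     cfg$simulate$n_per_pop,
                                     cfg$simulate$f_div, seed = cfg$seed)
      gm <- sim$gm; ref <- sim$panel
      logf("input: simulated reference (%d loci, F_div %.2f, seed %d)",
           cfg$simulate$n_loci, cfg$simulate$f_div, cfg$seed)
    }

    if ("qc" %in% cfg$stages) {
      stage <- "qc"
      gm <- filter_sites(gm, cfg$qc$max_missing_site, cfg$qc$max_het)
      removed_sites <- attr(gm, "removed")
      gm <- filter_individuals(gm, cfg$qc$max_missing_ind)
      removed_ind <- attr(gm, "removed")
      logf("qc: removed %d loci, %d individuals",
           nrow(removed_sites), nrow(removed_ind))
      res$qc <- list(removed_sites = removed_sites,
                     removed_individuals = removed_ind)
      emit(data.frame(sample_id = rownames(gm$calls), pop = gm$pop),
           "qc_retained_samples.tsv")
    }

    if ("stats" %in% cfg$stages) {
      stage <- "stats"
      div <- diversity(gm)
      emit(div, "diversity.tsv")
      fst <- pairwise_fst(gm, n_permutations = cfg$stats$fst_reps,
                          seed = cfg$seed)
      emit(fst$pairs, "fst_pairs.tsv")
      logf("stats: global theta %.4f (fst seed %d)", fst$global, cfg$seed)
      res$stats <- list(diversity = div, fst = fst)
      if (!is.null(gm$group) && length(unique(gm$group)) >= 2L) {
        am <- amova(gm, n_permutations = cfg$stats$amova_permutations,
                    seed = cfg$seed)
        emit(am$table, "amova.tsv")
        res$stats$amova <- am
      }
    }

    if ("panel" %in% cfg$stages) {
      stage <- "panel"
      focal <- cfg$panel$focal
      against <- cfg$panel$against
      if (is.null(focal)) {
        pops <- sort(unique(gm$pop))
        focal <- pops[1L]; against <- pops[-1L]
      }
      ranked <- rank_loci(gm, focal, against)
      top_k <- min(cfg$panel$top_k, ncol(gm$calls))
      sel <- select_panel(ranked, top_k = top_k, min_fst = cfg$panel$min_fst)
      emit(data.frame(locus_id = sel$panel), "panel.tsv")
      logf("panel: %d in intersection, %d past theta >= %.2f",
           length(sel$intersection), length(sel$panel), cfg$panel$min_fst)
      res$panel <- sel
    }

    if ("power" %in% cfg$stages) {
      stage <- "power"
      ref_for_power <- if (!is.null(ref)) ref else gm
      pw <- run_power_study(ref_for_power,
                            n_individuals = cfg$power$n_individuals,
                            n_datasets = cfg$power$n_datasets,
                            n_replicates = cfg$power$n_replicates,
                            thresholds = cfg$power$thresholds,
                            burnin = cfg$power$burnin,
                            sweeps = cfg$power$sweeps, seed = cfg$seed)
      emit(pw$metrics, "power.tsv")
      logf("power: min E %.1f%%, A %.1f%%, P %.1f over six classes",
           power_min(pw, "efficiency"), power_min(pw, "accuracy"),
           power_min(pw, "power"))
      res$power <- pw
    }

    if ("classify" %in% cfg$stages) {
      stage <- "classify"
      fit <- classify_gibbs(gm, burnin = cfg$classify$burnin,
                            sweeps = cfg$classify$sweeps, seed = cfg$seed)
      pool <- list(hybrid = c("F1", "F2", "BCA", "BCB"))
      lab <- assign_classes(fit, cfg$classify$thresholds[1L])
      emit(data.frame(sample_id = rownames(gm$calls), pop = gm$pop,
                      round(fit$posterior, 5),
                      hybrid_pooled = round(rowSums(
                        fit$posterior[, pool$hybrid]), 5),
                      label = lab), "posteriors.tsv")
      emit(summarize_assignments(fit, gm$pop,
                                 thresholds = cfg$classify$thresholds),
           "site_composition.tsv")
      logf("classify: %d individuals, discrepancy %.4f (seed %d)",
           nrow(gm$calls), fit$diagnostics$discrepancy, cfg$seed)
      res$classify <- fit
    }

    if ("admix" %in% cfg$stages) {
      stage <- "admix"
      runs <- list(); i <- 0L
      for (k in cfg$admix$k_range) for (r in seq_len(cfg$admix$replicates)) {
        i <- i + 1L
        sd_kr <- (cfg$seed + 1009L * k + 31L * r) %% .Machine$integer.max
        fit <- admixture_em(gm, K = k, seed = sd_kr)
        runs[[i]] <- data.frame(K = k, replicate = r, loglik = fit$loglik,
                                seed = sd_kr)
        if (k == 2L && r == 1L) {
          emit(data.frame(sample_id = rownames(fit$q), pop = gm$pop,
                          round(fit$q, 5)), "q_K2.tsv")
          res$admix_q2 <- fit
        }
        logf("admix: K=%d rep=%d logL=%.2f seed=%d", k, r, fit$loglik, sd_kr)
      }
      runs <- do.call(rbind, runs)
      emit(runs, "admix_runs.tsv")
      if (length(cfg$admix$k_range) >= 3L && cfg$admix$replicates >= 2L) {
        dk <- evanno_delta_k(runs)
        emit(dk, "delta_k.tsv")
        res$delta_k <- dk
      }
      pca <- pca_genotypes(gm)
      emit(data.frame(sample_id = rownames(pca$scores), pop = gm$pop,
                      round(pca$scores[, seq_len(min(4L, ncol(pca$scores))),
                                       drop = FALSE], 5)),
           "pca_scores.tsv")
      res$pca <- pca
    }

    if ("cline" %in% cfg$stages) {
      stage <- "cline"
      sites <- if (is.character(cfg$cline$sites))
        utils::read.delim(cfg$cline$sites) else cfg$cline$sites
      fit_free <- fit_cline(sites, variant = "free",
                            n_starts = cfg$cline$n_starts, seed = cfg$seed,
                            min_n = cfg$cline$min_n)
      fit_fixed <- fit_cline(sites, variant = "fixed",
                             n_starts = cfg$cline$n_starts, seed = cfg$seed,
                             min_n = cfg$cline$min_n)
      best <- centre_support(select_cline_model(list(fit_free, fit_fixed)))
      emit(data.frame(variant = best$variant, centre = best$centre,
                      width = best$width, pmin = best$pmin, pmax = best$pmax,
                      logL = best$logL, AIC = best$AIC,
                      support_lo = best$centre_support[1L],
                      support_hi = best$centre_support[2L]),
           "cline.tsv")
      logf("cline: centre %.1f km (%.1f-%.1f), width %.1f km",
           best$centre, best$centre_support[1L], best$centre_support[2L],
           best$width)
      res$cline <- best
    }
    TRUE
  }, silent = TRUE)
  if (inherits(result, "try-error"))
    stop("pipeline aborted at stage '", stage, "': ",
         attr(result, "condition")$message)

  summary_path <- file.path(cfg$out_dir, "summary.json")
  jsonlite::write_json(list(seed = cfg$seed, stages = cfg$stages,
                            outputs = basename(written)),
                       summary_path, auto_unbox = TRUE)
  invisible(list(results = res, files = c(written, summary_path, log_path)))
}

#' Per-site composition of hybrid assignments
#'
#' Tabulates, per sampling site and threshold, how many individuals are
#' assigned to each of the six classes, how many to the pooled hybrid
#' group (posteriors of the four hybrid classes summed before
#' thresholding), and how many stay unassigned; fractions are of the site
#' total, so the six class fractions plus unassigned sum to 1.
#'
#' @param post a \code{"hybrid_posterior"} (or posterior matrix).
#' @param site character vector of site labels aligned with the
#'   individuals.
#' @param thresholds posterior thresholds tabulated (default 0.5 and 0.8).
#' @return data frame with one row per site x threshold.
#' @export
summarize_assignments <- function(post, site,
                                  thresholds = c(0.5, 0.8)) {
  pm <- if (inherits(post, "hybrid_posterior")) post$posterior else post
  if (length(site) != nrow(pm))
    stop("site labels must align with the posterior rows")
  pool <- list(hybrid = c("F1", "F2", "BCA", "BCB"))
  lvls <- c(hybrid_classes(), "unassigned")
  rows <- list()
  for (t in thresholds) {
    lab <- assign_classes(pm, threshold = t)
    labp <- assign_classes(pm, threshold = t, pooling = pool)
    for (s in unique(site)) {
      sel <- site == s
      n <- sum(sel)
      cnt <- table(factor(lab[sel], levels = lvls))
      rows[[length(rows) + 1L]] <- data.frame(
        site = s, threshold = t, n = n, t(as.matrix(cnt)),
        hybrid_pooled = sum(labp[sel] == "hybrid"),
        frac_pureA = cnt[["PureA"]] / max(n, 1L),
        frac_pureB = cnt[["PureB"]] / max(n, 1L),
        frac_hybrid_pooled = sum(labp[sel] == "hybrid") / max(n, 1L),
        frac_unassigned = cnt[["unassigned"]] / max(n, 1L),
        stringsAsFactors = FALSE, check.names = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Geographic-group assignment from coordinates
#'
#' The coastal grouping rule used for Norwegian wrasse sampling sites:
#' latitudes above 62 degrees N are \code{"mid-western"}; below 62 with
#' longitude below 8 degrees E, \code{"south-western"}; below 60 with
#' longitude above 8, \code{"south-eastern"}. Sites matching none of the
#' rules get \code{NA}.
#'
#' @param lat,lon numeric vectors of decimal degrees.
#' @return character vector of group labels.
#' @export
assign_geo_groups <- function(lat, lon) {
  out <- rep(NA_character_, length(lat))
  out[lat > 62] <- "mid-western"
  out[lat < 62 & lon < 8] <- "south-western"
  out[lat < 60 & lon > 8] <- "south-eastern"
  out
}
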