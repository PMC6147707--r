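#' Pipeline configuration
#'
#' Collects every tunable of the full analysis with the study defaults:
#' landscape buffer radii 1.6/3.2/6.4 km, border margin 6.4 km, Omega
#' evaluated between 5% and 75% cover, species retained at >= 25 occupied
#' plots, 1000 bootstrap replicates and 1000 uncertainty iterations.
#'
#' @param radii landscape buffer radii (km), ascending.
#' @param border_margin_km border-exclusion margin (km).
#' @param F_low,F_high Omega evaluation covers (%).
#' @param min_occupied species-inclusion threshold (occupied plots).
#' @param n_boot bootstrap replicates per species and scale.
#' @param n_iter lambda uncertainty iterations.
#' @param link Poisson link, `"identity"` or `"log"`.
#' @param occupied_only fit each species only on its occupied plots instead
#'   of all plots (the alternative reading of the fitting subset).
#' @param seed master seed; all stage streams derive from it.
#' @param synthetic a [synthetic_config()] used when the pipeline simulates
#'   its own data (its seed is overridden by `seed`).
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(radii = c(1.6, 3.2, 6.4), border_margin_km = 6.4,
                            F_low = 5, F_high = 75, min_occupied = 25,
                            n_boot = 1000, n_iter = 1000,
                            link = c("identity", "log"),
                            occupied_only = FALSE,
                            seed = 1L,
                            synthetic = synthetic_config()) {
  link <- match.arg(link)
  stopifnot(all(radii > 0), !is.unsorted(radii), border_margin_km >= 0,
            F_low < F_high, min_occupied >= 1, n_boot >= 2, n_iter >= 1)
  structure(list(radii = radii, border_margin_km = border_margin_km,
                 F_low = F_low, F_high = F_high, min_occupied = min_occupied,
                 n_boot = as.integer(n_boot), n_iter = as.integer(n_iter),
                 link = link, occupied_only = occupied_only,
                 seed = as.integer(seed), synthetic = synthetic),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys override [pipeline_config()] defaults; a `synthetic` block
#' overrides [synthetic_config()] defaults.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read config files")
  raw <- yaml::read_yaml(path)
  syn <- do.call(synthetic_config, raw$synthetic %||% list())
  raw$synthetic <- NULL
  do.call(pipeline_config, c(raw, list(synthetic = syn)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' simulate (or take given data) -> border exclusion -> multi-scale cover ->
#' species selection -> per-species Poisson fits, Omega and bootstrap CIs at
#' each scale -> best scale by AICc -> phylogenetic signal (all species and
#' per clade) at each scale. Returns every stage table plus a JSON-ready run
#' manifest with per-stage counts.
#'
#' @param config a [pipeline_config()].
#' @param data optional list with `plots`, `tree`, `clades` (as produced by
#'   [simulate_dataset()] or read from files); when NULL a synthetic dataset
#'   is generated from `config$synthetic` with `config$seed`.
#' @return list of class `pipeline_result`: `plots`, `cover`, `fits`,
#'   `omega`, `best_scale`, `signal`, `tree`, `truth` (synthetic runs only),
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), data = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  truth <- NULL
  if (is.null(data)) {
    syn <- config$synthetic
    syn$seed <- config$seed
    data <- simulate_dataset(syn)
    truth <- data$truth
  }
  plots_all <- data$plots
  tree <- data$tree
  clades <- data$clades

  plots <- exclude_border(plots_all, config$border_margin_km)
  cover <- multiscale_cover(plots, config$radii)
  species <- select_species(plots, config$min_occupied, tree$tip.label)

  scales <- c("local", as.character(config$radii))
  cover_cols <- c("cover_local",
                  paste0("cover_", vapply(config$radii, scale_tag, "")))
  fits <- list(); omegas <- list()
  for (sp in species) {
    cnt_all <- plots[[sp]]
    for (k in seq_along(scales)) {
      FF <- cover[[cover_cols[k]]]
      cnt <- cnt_all
      if (isTRUE(config$occupied_only)) {
        keep <- cnt_all > 0
        cnt <- cnt_all[keep]; FF <- FF[keep]
      }
      fit <- tryCatch(fit_poisson(cnt, FF, config$link),
                      error = function(e) NULL)
      if (is.null(fit)) next
      fits[[length(fits) + 1L]] <- data.frame(
        species = sp, scale = scales[k], M = fit$M, C = fit$C,
        logLik = fit$logLik, n_plots = fit$n_plots, AICc = fit$AICc,
        delta_AICc = fit$delta_AICc, informative = fit$informative,
        stringsAsFactors = FALSE)
      if (fit$informative) {
        oe <- tryCatch(
          bootstrap_omega(cnt, FF, config$link, config$n_boot,
                          seed = derive_seed(config$seed, paste0(sp, ":", scales[k])),
                          F_low = config$F_low, F_high = config$F_high,
                          species = sp),
          error = function(e) NULL)
        if (!is.null(oe))
          omegas[[length(omegas) + 1L]] <- data.frame(
            species = sp, scale = scales[k], omega = oe$omega,
            ci_low = oe$ci_low, ci_high = oe$ci_high,
            response_class = oe$response_class,
            n_redrawn = oe$n_redrawn, stringsAsFactors = FALSE)
      }
    }
  }
  fits <- do.call(rbind, fits)
  omega_tab <- if (length(omegas)) do.call(rbind, omegas) else
    data.frame(species = character(), scale = character(), omega = numeric(),
               ci_low = numeric(), ci_high = numeric(),
               response_class = character(), n_redrawn = integer())
  bs <- best_scale(fits, scale_order = scales)

  signal <- list()
  for (k in seq_along(scales)) {
    oc <- omega_tab[omega_tab$scale == scales[k], , drop = FALSE]
    sig <- if (nrow(oc) >= 3)
      clade_subset_signal(oc, tree, clades, config$n_iter,
                          derive_seed(config$seed, paste0("sig:", scales[k])))
    else NULL
    if (!is.null(sig)) {
      sig$scale <- scales[k]
      attr(sig, "runs") <- NULL
      signal[[length(signal) + 1L]] <- sig
    }
  }
  signal <- if (length(signal)) do.call(rbind, signal) else NULL

  manifest <- list(
    config = unclass(config[setdiff(names(config), "synthetic")]),
    synthetic = unclass(config$synthetic),
    seed = config$seed,
    r_version = as.character(getRversion()),
    n_plots_input = nrow(plots_all),
    n_plots_border_excluded = nrow(plots_all) - nrow(plots),
    n_plots_analysed = nrow(plots),
    n_species_retained = length(species),
    n_informative_by_scale = as.list(
      vapply(scales, function(s)
        sum(fits$informative[fits$scale == s]), numeric(1))))

  structure(list(plots = plots, cover = cover, fits = fits,
                 omega = omega_tab, best_scale = bs, signal = signal,
                 tree = tree, truth = truth, manifest = manifest),
            class = "pipeline_result")
}

#' Summarize pipeline results
#'
#' Per scale: counts and fractions of negative/neutral/positive responses
#' and of species left unexplained (no informative model at that scale);
#' plus the fraction of species best explained at each scale.
#'
#' @param result a `pipeline_result`.
#' @return list with `by_scale` (data frame) and `best_scale_fraction`
#'   (named numeric, including `unexplained`).
#' @export
summarize_results <- function(result) {
  fits <- result$fits
  om <- result$omega
  scales <- unique(fits$scale)
  n_retained <- length(unique(fits$species))
  by_scale <- do.call(rbind, lapply(scales, function(s) {
    o <- om[om$scale == s, , drop = FALSE]
    cls <- factor(o$response_class, levels = c("negative", "neutral", "positive"))
    tab <- table(cls)
    unexp <- n_retained - nrow(o)
    data.frame(scale = s, n_species = n_retained,
               n_negative = as.integer(tab["negative"]),
               n_neutral = as.integer(tab["neutral"]),
               n_positive = as.integer(tab["positive"]),
               n_unexplained = unexp,
               frac_negative = as.integer(tab["negative"]) / n_retained,
               frac_neutral = as.integer(tab["neutral"]) / n_retained,
               frac_positive = as.integer(tab["positive"]) / n_retained,
               frac_unexplained = unexp / n_retained,
               stringsAsFactors = FALSE)
  }))
  bs <- result$best_scale$best_scale
  bs[is.na(bs)] <- "unexplained"
  frac <- table(factor(bs, levels = c(scales, "unexplained"))) / length(bs)
  list(by_scale = by_scale,
       best_scale_fraction = stats::setNames(as.numeric(frac), names(frac)))
}

# ---- I/O -------------------------------------------------------------------

#' Read and write the plots CSV dialect
#'
#' Columns: `plot_id`, `x_km`, `y_km`, `cover_pct`, then one integer count
#' column per species. Per-hectare stem densities must be rounded to counts
#' explicitly via `round_counts = TRUE`; non-integer counts are refused
#' otherwise.
#'
#' @param path CSV file path.
#' @param round_counts round non-integer species columns to counts.
#' @return plot table data frame.
#' @export
read_plots_csv <- function(path, round_counts = FALSE) {
  plots <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  assert_plot_table(plots)
  for (s in species_columns(plots)) {
    if (round_counts) plots[[s]] <- as.integer(round(plots[[s]]))
    else if (any(abs(plots[[s]] - round(plots[[s]])) > 1e-8))
      stop("non-integer counts in column '", s,
           "'; pass round_counts = TRUE to round densities to counts")
  }
  plots
}

#' @rdname read_plots_csv
#' @param plots plot table to write.
#' @export
write_plots_csv <- function(plots, path) {
  utils::write.csv(plots, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write pipeline result tables and manifest to a directory
#'
#' Emits `cover.csv`, `fits.csv`, `omega.csv`, `best_scale.csv`,
#' `signal.csv`, `tree.nwk` and `manifest.json`.
#'
#' @param result a `pipeline_result`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_results <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$cover, file.path(dir, "cover.csv"), row.names = FALSE)
  utils::write.csv(result$fits, file.path(dir, "fits.csv"), row.names = FALSE)
  utils::write.csv(result$omega, file.path(dir, "omega.csv"), row.names = FALSE)
  utils::write.csv(result$best_scale, file.path(dir, "best_scale.csv"),
                   row.names = FALSE)
  if (!is.null(result$signal))
    utils::write.csv(result$signal, file.path(dir, "signal.csv"),
                     row.names = FALSE)
  ape::write.tree(result$tree, file.path(dir, "tree.nwk"))
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
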