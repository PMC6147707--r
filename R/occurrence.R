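#' Select species for analysis
#'
#' Retains the species occupying at least `min_occupied` plots (count > 0)
#' and whose names match tips of the phylogeny. Species occupying fewer
#' plots, or absent from the tree, are dropped.
#'
#' @param plots plot table with per-species count columns.
#' @param min_occupied minimum number of occupied plots (default 25).
#' @param tree_tips character vector of phylogeny tip labels.
#' @return character vector of retained species names.
#' @export
select_species <- function(plots, min_occupied = 25, tree_tips) {
  assert_plot_table(plots)
  sp <- species_columns(plots)
  occ <- vapply(sp, function(s) sum(plots[[s]] > 0), integer(1))
  keep <- sp[occ >= min_occupied & sp %in% tree_tips]
  if (!length(keep))
    stop("no species pass the filters (>= ", min_occupied,
         " occupied plots and phylogeny tip match)")
  keep
}

#' Fit a Poisson occurrence model of counts against canopy cover
#'
#' Maximum-likelihood fit of stem counts on cover with rate
#' `lambda(F) = M + C * F` (identity link, the model as stated; fitted under
#' a positivity constraint with the rate clipped at 1e-10 during the search)
#' or `lambda(F) = exp(M + C * F)` (log link, the standard Poisson GLM
#' reading). The intercept-only model (`C = 0`) is fitted on the same data
#' and the AICc difference recorded; a difference above 10 marks the cover
#' model as informative.
#'
#' @param counts nonnegative integer counts, one per plot.
#' @param F canopy cover (%) per plot, same length.
#' @param link `"identity"` or `"log"`.
#' @return object of class `species_fit`: list with `M`, `C`, `link`,
#'   `logLik`, `logLik_intercept`, `n_plots`, `AICc`, `AICc_intercept`,
#'   `delta_AICc`, `informative`.
#' @export
fit_poisson <- function(counts, F, link = c("identity", "log")) {
  link <- match.arg(link)
  if (length(counts) != length(F)) stop("counts and F must have equal length")
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integers; densities per hectare must be rounded ",
         "explicitly (round_counts = TRUE in read_plots_csv) before fitting")
  counts <- as.integer(round(counts))
  n <- length(counts)
  if (all(counts == 0)) stop("all counts are zero; model not identifiable")

  mbar <- mean(counts)
  ll_intercept <- sum(stats::dpois(counts, mbar, log = TRUE))

  if (link == "identity") {
    nll <- function(par) {
      lam <- pmax(par[1] + par[2] * F, 1e-10)
      -sum(counts * log(lam) - lam)
    }
    gr <- function(par) {
      raw <- par[1] + par[2] * F
      lam <- pmax(raw, 1e-10)
      g <- (counts / lam - 1) * (raw > 1e-10)
      -c(sum(g), sum(g * F))
    }
    opt <- stats::optim(c(mbar, 0), nll, gr, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    M <- opt$par[1]; C <- opt$par[2]
    ll <- sum(stats::dpois(counts, pmax(M + C * F, 1e-10), log = TRUE))
  } else {
    fit <- suppressWarnings(
      stats::glm.fit(cbind(1, F), counts, family = stats::poisson()))
    M <- fit$coefficients[1]; C <- fit$coefficients[2]
    ll <- sum(stats::dpois(counts, exp(M + C * F), log = TRUE))
  }

  a2 <- aicc(ll, 2, n)
  a1 <- aicc(ll_intercept, 1, n)
  structure(list(M = unname(M), C = unname(C), link = link,
                 M_intercept = mbar,
                 logLik = ll, logLik_intercept = ll_intercept,
                 n_plots = n, AICc = a2, AICc_intercept = a1,
                 delta_AICc = a1 - a2, informative = (a1 - a2) > 10),
            class = "species_fit")
}

#' Occurrence probability along the cover gradient
#'
#' Probability that at least one stem is present: `P(F) = 1 - exp(-lambda(F))`
#' with the rate from the fitted model. Under the identity link a nonpositive
#' rate is clipped at 1e-10 (with a warning), keeping the probability in
#' (0, 1).
#'
#' @param fit a `species_fit`.
#' @param F canopy cover (%) at which to evaluate.
#' @return occurrence probability in `[0, 1)`.
#' @export
occurrence_probability <- function(fit, F) {
  lam <- if (fit$link == "identity") fit$M + fit$C * F
         else exp(fit$M + fit$C * F)
  if (fit$link == "identity" && any(lam <= 0)) {
    warning("identity-link rate nonpositive at F = ",
            paste(F[lam <= 0], collapse = ", "), "; clipped at 1e-10")
    lam <- pmax(lam, 1e-10)
  }
  -expm1(-lam)
}

#' Omega: log-ratio response to forest loss
#'
#' `Omega = ln[P(F_low) / P(F_high)]`, the natural log of the ratio between
#' occurrence probabilities at low and high canopy cover (defaults 5% and
#' 75%). Positive values mean the species is more likely under open
#' canopies (favoured by forest loss); negative values mean forest
#' affiliation.
#'
#' @param fit a `species_fit`.
#' @param F_low,F_high cover evaluation points (%), `F_low < F_high`.
#' @return scalar Omega.
#' @export
omega <- function(fit, F_low = 5, F_high = 75) {
  stopifnot(F_low < F_high)
  p <- suppressWarnings(occurrence_probability(fit, c(F_low, F_high)))
  if (any(p == 0))
    stop("degenerate fit: occurrence probability 0 after rate clipping")
  log(p[1] / p[2])
}

# Percentile-rank positions of the bootstrap 95% CI: for B replicates the
# bounds sit at ranks floor((B+1)*0.025) and ceiling((B+1)*0.975) of the
# sorted values (25 and 976 for B = 1000).
boot_ci_ranks <- function(n_boot) {
  c(low = floor((n_boot + 1) * 0.025), high = ceiling((n_boot + 1) * 0.975))
}

#' Bootstrap confidence interval for Omega
#'
#' Draws `n_boot` plot-level resamples (same size as the original, with
#' replacement), refits the Poisson model on each and recomputes Omega. The
#' 95% CI bounds are the ranked values at positions
#' `floor((B+1)*0.025)` and `ceiling((B+1)*0.975)` — the 25th and 976th of
#' 1000. Replicates whose refit fails (or yields a non-finite Omega) are
#' redrawn so B stays fixed; more than 20% failures aborts.
#'
#' @param counts,F,link as in [fit_poisson()].
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed integer seed for the resampling stream.
#' @param F_low,F_high cover evaluation points passed to [omega()].
#' @param species optional species name carried into the result and errors.
#' @return object of class `omega_estimate`: list with `species`, `omega`,
#'   `ci_low`, `ci_high`, `n_boot`, `n_redrawn`, `response_class`, `F_low`,
#'   `F_high`, `boot_values`.
#' @export
bootstrap_omega <- function(counts, F, link = c("identity", "log"),
                            n_boot = 1000, seed = 1L,
                            F_low = 5, F_high = 75, species = NA_character_) {
  link <- match.arg(link)
  stopifnot(n_boot >= 2)
  fit <- fit_poisson(counts, F, link)
  om <- omega(fit, F_low, F_high)
  n <- length(counts)
  vals <- with_seed(seed, {
    out <- numeric(n_boot)
    fails <- 0L
    max_fail <- ceiling(0.2 * n_boot)
    b <- 1L
    while (b <= n_boot) {
      idx <- sample.int(n, n, replace = TRUE)
      ob <- tryCatch({
        fb <- fit_poisson(counts[idx], F[idx], link)
        omega(fb, F_low, F_high)
      }, error = function(e) NA_real_)
      if (is.finite(ob)) {
        out[b] <- ob
        b <- b + 1L
      } else {
        fails <- fails + 1L
        if (fails > max_fail)
          stop("bootstrap for species ", species, ": more than 20% of ",
               "replicates failed to refit")
      }
    }
    attr(out, "n_redrawn") <- fails
    out
  })
  rk <- boot_ci_ranks(n_boot)
  sv <- sort(vals)
  ci <- c(sv[rk["low"]], sv[rk["high"]])
  structure(list(species = species, omega = om,
                 ci_low = ci[1], ci_high = ci[2],
                 n_boot = n_boot, n_redrawn = attr(vals, "n_redrawn"),
                 response_class = classify_response(ci[1], ci[2]),
                 F_low = F_low, F_high = F_high,
                 boot_values = as.numeric(vals)),
            class = "omega_estimate")
}

#' Classify a species response from its Omega confidence interval
#'
#' Negative when the 95% CI lies entirely below zero, positive when entirely
#' above, neutral when the CI includes zero (bounds exactly at zero count as
#' including it).
#'
#' @param ci_low,ci_high CI bounds, or an `omega_estimate` as first argument.
#' @return `"negative"`, `"neutral"` or `"positive"`.
#' @export
classify_response <- function(ci_low, ci_high) {
  if (inherits(ci_low, "omega_estimate")) {
    ci_high <- ci_low$ci_high; ci_low <- ci_low$ci_low
  }
  stopifnot(ci_low <= ci_high)
  if (ci_high < 0) "negative" else if (ci_low > 0) "positive" else "neutral"
}

#' Best spatial scale per species by AICc
#'
#' Among a species' informative fits across scales, the scale with minimum
#' AICc; ties broken toward the smaller (more local) scale. Species with no
#' informative scale are reported as unexplained.
#'
#' @param fits data frame with columns `species`, `scale`, `AICc`,
#'   `informative` (one row per species x scale, as produced by
#'   [run_pipeline()]'s fit stage).
#' @param scale_order ordering of scales from most local to largest.
#' @return data frame `species`, `best_scale` (`NA` for unexplained species).
#' @export
best_scale <- function(fits, scale_order = c("local", "1.6", "3.2", "6.4")) {
  stopifnot(all(c("species", "scale", "AICc", "informative") %in% names(fits)))
  res <- lapply(split(fits, fits$species), function(d) {
    d <- d[d$informative, , drop = FALSE]
    if (nrow(d) == 0) return(NA_character_)
    d$rank <- match(as.character(d$scale), scale_order)
    d <- d[order(d$AICc, d$rank), ]
    as.character(d$scale[1])
  })
  data.frame(species = names(res), best_scale = unlist(res),
             row.names = NULL, stringsAsFactors = FALSE)
}
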