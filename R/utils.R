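#' Small-sample corrected Akaike information criterion
#'
#' AICc = -2 lnL + 2k + 2k(k+1)/(n - k - 1). Used to screen cover models
#' against intercept-only models and to compare fits across spatial scales.
#'
#' @param logLik log-likelihood at the optimum.
#' @param k number of estimated parameters.
#' @param n number of observations; must exceed k + 1.
#' @return numeric AICc value.
#' @export
aicc <- function(logLik, k, n) {
  stopifnot(is.finite(logLik), k >= 1, n > k + 1)
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# Stable 31-bit string hash (polynomial rolling hash). Used to derive
# per-species RNG streams from the master seed so that per-species results
# do not depend on the order species are processed in.
stable_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 0
  for (cc in utf8ToInt(x)) h <- (h * 31 + cc) %% 2147483647
  as.integer(h)
}

# Derive a child seed below 2^31 from a master seed and a label or index.
derive_seed <- function(seed, what) {
  key <- if (is.character(what)) stable_hash(what) else as.integer(what)
  as.integer((as.numeric(seed) * 48271 + key) %% 2147483647)
}

# Run expr with a locally set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Columns of a plot table that hold per-species counts (everything beyond
# the positional/cover columns).
species_columns <- function(plots) {
  setdiff(names(plots), c("plot_id", "x_km", "y_km", "cover_pct"))
}

assert_plot_table <- function(plots) {
  needed <- c("plot_id", "x_km", "y_km", "cover_pct")
  missing <- setdiff(needed, names(plots))
  if (length(missing))
    stop("plot table lacks column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(plots$plot_id))
    stop("plot_id values must be unique")
  if (anyDuplicated(plots[, c("x_km", "y_km")]))
    stop("lattice coordinates (x_km, y_km) must be unique")
  if (any(plots$cover_pct < 0 | plots$cover_pct > 100))
    stop("cover_pct must lie in [0, 100]")
  invisible(plots)
}
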