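#' Phylogenetic variance-covariance matrix
#'
#' Entry (a, b) is the shared root-to-MRCA path length of tips a and b; the
#' diagonal holds root-to-tip depths. If `tip_subset` is given the tree is
#' first pruned to those tips (re-rooted at their MRCA), so the matrix is the
#' one a clade-level analysis uses.
#'
#' @param tree an `ape::phylo` with branch lengths (Myr).
#' @param tip_subset optional character vector of tips to keep.
#' @return symmetric positive-semidefinite matrix with tip-labelled dimnames.
#' @export
vcv_matrix <- function(tree, tip_subset = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(tip_subset)) {
    unknown <- setdiff(tip_subset, tree$tip.label)
    if (length(unknown))
      stop("unknown tip(s): ", paste(unknown, collapse = ", "))
    tree <- ape::keep.tip(tree, tip_subset)
  }
  ape::vcv.phylo(tree)
}

#' Pagel's lambda transform of a phylogenetic covariance matrix
#'
#' Multiplies the off-diagonal entries by `lam`, leaving the diagonal
#' untouched. `lam = 1` returns the Brownian-motion covariance unchanged;
#' `lam = 0` removes all phylogenetic covariance (star phylogeny).
#'
#' @param V phylogenetic covariance matrix.
#' @param lam lambda in `[0, 1]`.
#' @return transformed matrix.
#' @export
lambda_transform <- function(V, lam) {
  if (!is.numeric(lam) || length(lam) != 1 || lam < 0 || lam > 1)
    stop("lambda must be a scalar in [0, 1]")
  W <- V * lam
  diag(W) <- diag(V)
  W
}

# Profiled multivariate-normal log-likelihood of trait y at a given lambda:
# mean mu profiled by GLS, variance sigma2 by ML (divisor n).
loglik_lambda <- function(lam, V, y) {
  W <- lambda_transform(V, lam)
  ch <- tryCatch(chol(W), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  n <- length(y)
  z1 <- backsolve(ch, rep(1, n), transpose = TRUE)
  zy <- backsolve(ch, y, transpose = TRUE)
  mu <- sum(z1 * zy) / sum(z1 * z1)
  q <- sum((zy - mu * z1)^2)
  if (q <= 0) return(-Inf)
  s2 <- q / n
  logdet <- 2 * sum(log(diag(ch)))
  -0.5 * (n * log(2 * pi) + n * log(s2) + logdet + n)
}

#' Estimate Pagel's lambda for a trait on a phylogeny
#'
#' Maximum-likelihood estimate of lambda on `[0, 1]`: the trait is modelled
#' as multivariate normal with mean `mu * 1` and covariance
#' `sigma2 * lambda_transform(V, lambda)`; `mu` (GLS) and `sigma2` (ML,
#' divisor n) are profiled analytically and lambda optimized by bounded
#' scalar search (tolerance 1e-8, boundary values checked explicitly).
#' Significance is a likelihood-ratio test against `lambda = 0` referred to
#' the upper tail of chi-square with 1 df — the usual convention, though
#' conservative when the estimate sits on the boundary.
#'
#' @param trait named numeric vector (names = tip labels), or unnamed in tip
#'   order when `V` is supplied directly.
#' @param tree an `ape::phylo`, or a precomputed covariance matrix from
#'   [vcv_matrix()].
#' @param check_grid if TRUE, verify the optimum against a 101-point grid
#'   (debug aid; errors if any grid point beats the optimum).
#' @return object of class `lambda_result`: list with `lambda`, `logLik`,
#'   `logLik0`, `lrt_stat`, `p_value`, `n_tips`.
#' @export
fit_lambda <- function(trait, tree, check_grid = FALSE) {
  V <- if (inherits(tree, "phylo")) {
    if (is.null(names(trait)))
      stop("trait must be named by tip label when a tree is supplied")
    vcv_matrix(tree, names(trait))
  } else as.matrix(tree)
  if (!is.null(names(trait)) && !is.null(rownames(V)))
    V <- V[names(trait), names(trait)]
  y <- as.numeric(trait)
  n <- length(y)
  if (n < 3) stop("at least 3 tips required to estimate lambda")
  if (stats::var(y) == 0)
    stop("constant trait: sigma2 estimate is 0, lambda undefined")

  opt <- stats::optimize(function(l) loglik_lambda(l, V, y),
                         interval = c(0, 1), maximum = TRUE, tol = 1e-8)
  cand_l <- c(opt$maximum, 0, 1)
  cand_ll <- c(opt$objective, loglik_lambda(0, V, y), loglik_lambda(1, V, y))
  best <- which.max(cand_ll)
  lam_hat <- cand_l[best]
  ll_hat <- cand_ll[best]
  ll0 <- cand_ll[2]
  if (check_grid) {
    grid <- seq(0, 1, length.out = 101)
    gll <- vapply(grid, function(l) loglik_lambda(l, V, y), numeric(1))
    if (any(gll > ll_hat + 1e-6))
      stop("grid point beats optimizer; lambda surface is pathological")
  }
  lrt <- max(0, 2 * (ll_hat - ll0))
  structure(list(lambda = lam_hat, logLik = ll_hat, logLik0 = ll0,
                 lrt_stat = lrt,
                 p_value = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
                 n_tips = n),
            class = "lambda_result")
}

#' Phylogenetic signal in Omega with interval-uncertainty propagation
#'
#' For each of `n_iter` iterations, one Omega value per species is drawn
#' uniformly from its 95% CI `[ci_low, ci_high]` and Pagel's lambda is
#' re-estimated; the reported lambda and p-value are the medians across
#' iterations. Species without a finite CI (uninformative occurrence models)
#' are pruned from the tree first, mirroring the gaps such species leave in
#' the response figure.
#'
#' @param omega_cis data frame with `species`, `ci_low`, `ci_high`.
#' @param tree an `ape::phylo` whose tips include the species.
#' @param n_iter number of iterations (default 1000).
#' @param seed master seed; iteration i uses a stream derived from it.
#' @return object of class `lambda_uncertainty`: list with `median_lambda`,
#'   `median_p`, `n_tips`, `n_iter`, `n_pruned`, and per-iteration vectors
#'   `lambda` and `p_value`.
#' @export
lambda_with_uncertainty <- function(omega_cis, tree, n_iter = 1000, seed = 1L) {
  stopifnot(all(c("species", "ci_low", "ci_high") %in% names(omega_cis)),
            n_iter >= 1)
  ok <- is.finite(omega_cis$ci_low) & is.finite(omega_cis$ci_high)
  n_pruned <- sum(!ok)
  if (n_pruned)
    message("pruning ", n_pruned, " species without finite Omega CIs")
  d <- omega_cis[ok, , drop = FALSE]
  d <- d[d$species %in% tree$tip.label, , drop = FALSE]
  if (nrow(d) < 3)
    stop("fewer than 3 species with usable Omega CIs on the tree")
  V <- vcv_matrix(tree, d$species)
  V <- V[d$species, d$species]
  lam <- p <- numeric(n_iter)
  for (i in seq_len(n_iter)) {
    y <- with_seed(derive_seed(seed, i),
                   stats::runif(nrow(d), d$ci_low, d$ci_high))
    names(y) <- d$species
    fi <- fit_lambda(y, V)
    lam[i] <- fi$lambda
    p[i] <- fi$p_value
  }
  structure(list(median_lambda = stats::median(lam),
                 median_p = stats::median(p),
                 n_tips = nrow(d), n_iter = n_iter, n_pruned = n_pruned,
                 lambda = lam, p_value = p),
            class = "lambda_uncertainty")
}

#' Clade-subset phylogenetic signal
#'
#' Runs [lambda_with_uncertainty()] for all species together and separately
#' within each labelled clade (e.g. angiosperms and gymnosperms), pruning
#' the tree to each clade's tips. Clades with fewer than 3 usable species
#' are reported as not estimable rather than aborting the run.
#'
#' @param omega_cis data frame with `species`, `ci_low`, `ci_high`.
#' @param tree an `ape::phylo`.
#' @param clade_labels data frame with `species`, `clade`.
#' @param n_iter,seed passed to [lambda_with_uncertainty()].
#' @return data frame with one row per scope (`all` plus each clade):
#'   `scope`, `median_lambda`, `median_p`, `n_tips`, `estimable`; the
#'   underlying `lambda_uncertainty` objects are in attribute `"runs"`.
#' @export
clade_subset_signal <- function(omega_cis, tree, clade_labels,
                                n_iter = 1000, seed = 1L) {
  stopifnot(all(c("species", "clade") %in% names(clade_labels)))
  scopes <- c(list(all = omega_cis$species),
              split(clade_labels$species, clade_labels$clade))
  runs <- list()
  rows <- lapply(names(scopes), function(sc) {
    sub <- omega_cis[omega_cis$species %in% scopes[[sc]], , drop = FALSE]
    res <- tryCatch(
      lambda_with_uncertainty(sub, tree, n_iter, derive_seed(seed, sc)),
      error = function(e) NULL)
    runs[[sc]] <<- res
    if (is.null(res))
      data.frame(scope = sc, median_lambda = NA_real_, median_p = NA_real_,
                 n_tips = nrow(sub), estimable = FALSE,
                 stringsAsFactors = FALSE)
    else
      data.frame(scope = sc, median_lambda = res$median_lambda,
                 median_p = res$median_p, n_tips = res$n_tips,
                 estimable = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "runs") <- runs
  out
}
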