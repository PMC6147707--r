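# Independent oracles used across tests. These deliberately avoid the code
# paths of the package functions they check.

# Brute-force count of integer lattice points inside a closed disc.
brute_circle_count <- function(radius, spacing = 1) {
  k <- ceiling(radius / spacing)
  cnt <- 0L
  for (i in -k:k) for (j in -k:k)
    if ((i * spacing)^2 + (j * spacing)^2 <= radius^2) cnt <- cnt + 1L
  cnt
}

# Exhaustive grid-search maximizer of the Poisson log-likelihood.
grid_fit_poisson <- function(counts, F, link, M_grid, C_grid) {
  best <- c(NA, NA, -Inf)
  for (M in M_grid) for (C in C_grid) {
    lam <- if (link == "identity") pmax(M + C * F, 1e-10) else exp(M + C * F)
    ll <- sum(stats::dpois(counts, lam, log = TRUE))
    if (ll > best[3]) best <- c(M, C, ll)
  }
  list(M = best[1], C = best[2], logLik = best[3])
}

# Expected (Fisher) standard errors for the identity-link Poisson model.
identity_poisson_se <- function(M, C, F) {
  lam <- pmax(M + C * F, 1e-10)
  X <- cbind(1, F)
  info <- t(X) %*% (X / lam)
  sqrt(diag(solve(info)))
}

# Dense, self-contained profiled log-likelihood for Pagel's lambda, written
# with solve()/determinant() rather than Cholesky backsolves.
dense_lambda_loglik <- function(lam, V, y) {
  W <- V * lam
  diag(W) <- diag(V)
  n <- length(y)
  Wi <- solve(W)
  one <- rep(1, n)
  mu <- as.numeric((one %*% Wi %*% y) / (one %*% Wi %*% one))
  r <- y - mu
  s2 <- as.numeric(r %*% Wi %*% r) / n
  ld <- as.numeric(determinant(W, logarithm = TRUE)$modulus)
  -0.5 * (n * log(2 * pi) + n * log(s2) + ld + n)
}

# Brute-force phylogenetic covariance: shared path of tips a, b equals
# (depth_a + depth_b - patristic distance) / 2.
brute_vcv <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  names(depth) <- tree$tip.label
  D <- ape::cophenetic.phylo(tree)
  tips <- tree$tip.label
  V <- outer(depth[tips], depth[tips], "+") - D[tips, tips]
  V / 2
}

# Lattice plot table with a supplied cover function of (x, y).
make_lattice_plots <- function(nx, ny, cover_fun) {
  xy <- expand.grid(x_km = 0:(nx - 1), y_km = 0:(ny - 1))
  data.frame(plot_id = sprintf("q%05d", seq_len(nrow(xy))),
             x_km = xy$x_km, y_km = xy$y_km,
             cover_pct = cover_fun(xy$x_km, xy$y_km),
             stringsAsFactors = FALSE)
}

# Hand-built species_fit for scalar-evaluation tests.
manual_fit <- function(M, C, link = "identity") {
  structure(list(M = M, C = C, link = link, informative = TRUE),
            class = "species_fit")
}

# Two ultrametric clades of equal depth joined at the root; used for
# clade-contrast simulations.
two_clade_tree <- function(n_per_clade, seed) {
  set.seed(seed)
  scale_depth <- function(tr) {
    d <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length / d
    tr
  }
  t1 <- scale_depth(ape::rphylo(n_per_clade, 0.1, 0))
  t2 <- scale_depth(ape::rphylo(n_per_clade, 0.1, 0))
  t1$tip.label <- sprintf("a%02d", seq_len(n_per_clade))
  t2$tip.label <- sprintf("b%02d", seq_len(n_per_clade))
  t1$root.edge <- 0.5
  t2$root.edge <- 0.5
  ape::bind.tree(t1, t2, where = "root", position = 0.5)
}

# Multivariate-normal draw by Cholesky, for simulating BM tip traits on a
# fixed covariance.
rmvn_chol <- function(V) {
  as.numeric(t(chol(V)) %*% stats::rnorm(nrow(V)))
}
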