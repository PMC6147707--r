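#' Configuration for the synthetic forest-inventory generator
#'
#' Builds the parameter list consumed by [simulate_cover_field()],
#' [simulate_tree_and_traits()], [simulate_counts()] and [simulate_dataset()].
#' The generator emulates a national-forest-inventory design: circular sample
#' plots at the intersections of a 1-km grid, a spatially autocorrelated
#' canopy-cover field, sparse per-species stem counts that are Poisson given
#' cover, and species response slopes structured by Brownian motion on a
#' dated phylogeny.
#'
#' @param grid_nx,grid_ny lattice dimensions (plots sit at integer km
#'   coordinates with 1-km spacing).
#' @param cover_smoothing_scale correlation length (km) of the canopy-cover
#'   field; 0 gives spatially uncorrelated cover.
#' @param n_species number of simulated species (>= 3).
#' @param tree_birth_rate speciation rate (per Myr) of the pure-birth tree.
#' @param bm_sigma2 Brownian-motion rate of the response trait (trait^2/Myr).
#' @param m_range length-2 interval from which baseline intensities `M_j`
#'   (expected stems at 0% cover) are drawn uniformly.
#' @param c_range length-2 interval into which the Brownian trait is mapped
#'   affinely to give cover slopes `C_j` (stems per % cover).
#' @param occupancy target fraction of plots in which a species is present
#'   (count > 0); sparsity is created by structural-zero thinning.
#' @param link generating link for the Poisson rate: `"identity"` uses
#'   `lambda = M + C * F`, `"log"` uses `lambda = exp(M + C * F)`.
#' @param seed integer RNG seed; identical seed and config give bit-identical
#'   output.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(grid_nx = 100, grid_ny = 100,
                             cover_smoothing_scale = 3,
                             n_species = 61,
                             tree_birth_rate = 0.02,
                             bm_sigma2 = 0.01,
                             m_range = c(1, 3),
                             c_range = c(-0.01, 0.01),
                             occupancy = 0.3,
                             link = c("identity", "log"),
                             seed = 1L) {
  link <- match.arg(link)
  stopifnot(grid_nx >= 1, grid_ny >= 1,
            cover_smoothing_scale >= 0,
            n_species >= 3,
            tree_birth_rate > 0, bm_sigma2 >= 0,
            length(m_range) == 2, length(c_range) == 2,
            occupancy > 0, occupancy <= 1)
  structure(list(grid_nx = as.integer(grid_nx), grid_ny = as.integer(grid_ny),
                 cover_smoothing_scale = cover_smoothing_scale,
                 n_species = as.integer(n_species),
                 tree_birth_rate = tree_birth_rate, bm_sigma2 = bm_sigma2,
                 m_range = sort(as.numeric(m_range)),
                 c_range = sort(as.numeric(c_range)),
                 occupancy = occupancy, link = link,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Simulate a spatially autocorrelated canopy-cover field on the plot lattice
#'
#' Gaussian white noise on the `grid_nx` x `grid_ny` lattice is convolved with
#' a Gaussian kernel of standard deviation `cover_smoothing_scale` km
#' (truncated at three standard deviations, edge-renormalized) and rescaled
#' to the range 0-100%. Any smoother with correlation decaying at that scale
#' would do; the contract is that cover correlation between plots 1 km apart
#' exceeds that between distant plots.
#'
#' @param config a [synthetic_config()].
#' @return a plot table: `plot_id`, `x_km`, `y_km` (0-based integer km) and
#'   `cover_pct`.
#' @export
simulate_cover_field <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  nx <- config$grid_nx; ny <- config$grid_ny
  if (nx * ny < 1) stop("degenerate grid: no lattice cells")
  field <- with_seed(derive_seed(config$seed, "cover"), {
    z <- matrix(stats::rnorm(nx * ny), nrow = ny, ncol = nx)
    smooth_gaussian(z, config$cover_smoothing_scale)
  })
  rng <- range(field)
  cover <- if (rng[2] > rng[1])
    pmin(pmax(100 * (field - rng[1]) / (rng[2] - rng[1]), 0), 100)
  else matrix(50, ny, nx)
  xy <- expand.grid(x_km = 0:(nx - 1), y_km = 0:(ny - 1))
  data.frame(plot_id = sprintf("p%06d", seq_len(nx * ny)),
             x_km = xy$x_km, y_km = xy$y_km,
             cover_pct = cover[cbind(xy$y_km + 1, xy$x_km + 1)],
             stringsAsFactors = FALSE)
}

# Separable Gaussian blur with kernel sd `scale` (grid units), truncated at
# 3 sd. scale = 0 (or kernel shorter than 2 taps) returns the input.
smooth_gaussian <- function(z, scale) {
  if (scale <= 0) return(z)
  half <- max(1L, ceiling(3 * scale))
  k <- stats::dnorm(seq(-half, half), sd = scale)
  k <- k / sum(k)
  conv1 <- function(m, kern) {
    # convolve each column with edge renormalization
    n <- nrow(m); h <- (length(kern) - 1L) %/% 2L
    out <- matrix(0, n, ncol(m))
    wt <- numeric(n)
    for (o in -h:h) {
      src <- seq_len(n) + o
      ok <- src >= 1L & src <= n
      out[ok, ] <- out[ok, ] + kern[o + h + 1L] * m[src[ok], , drop = FALSE]
      wt[ok] <- wt[ok] + kern[o + h + 1L]
    }
    out / wt
  }
  t(conv1(t(conv1(z, k)), k))
}

#' Simulate a dated phylogeny and Brownian-motion response parameters
#'
#' Grows a pure-birth (Yule) tree with `n_species` tips, rescales so branch
#' lengths read in Myr, evolves a trait under Brownian motion with rate
#' `bm_sigma2`, and maps the trait affinely into the slope interval `c_range`
#' to give each species its cover slope `C_j`. Baselines `M_j` are drawn
#' uniformly from `m_range`. The two children of the root define two labelled
#' clades (`"angiosperm"` for the larger, `"gymnosperm"` for the smaller), a
#' synthetic stand-in for the angiosperm/gymnosperm split used in clade
#' subset analyses.
#'
#' @param config a [synthetic_config()].
#' @return list with `tree` (an `ape::phylo`, ultrametric), and `truth`, a
#'   data frame with one row per species: `species`, `trait` (the Brownian
#'   values), `M`, `C`, `clade`.
#' @export
simulate_tree_and_traits <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$n_species < 3)
    stop("n_species must be >= 3 (phylogenetic signal is not estimable below 3 tips)")
  n <- config$n_species
  with_seed(derive_seed(config$seed, "tree"), {
    tree <- ape::rphylo(n, birth = config$tree_birth_rate, death = 0)
    tree$tip.label <- sprintf("sp%03d", seq_len(n))
    trait <- ape::rTraitCont(tree, model = "BM",
                             sigma = sqrt(config$bm_sigma2), root.value = 0)
    M <- stats::runif(n, config$m_range[1], config$m_range[2])
    names(M) <- tree$tip.label
    truth <- data.frame(species = tree$tip.label,
                        trait = as.numeric(trait[tree$tip.label]),
                        M = as.numeric(M),
                        C = affine_to_range(as.numeric(trait[tree$tip.label]),
                                            config$c_range),
                        clade = root_clades(tree),
                        stringsAsFactors = FALSE)
    list(tree = tree, truth = truth)
  })
}

# Affine map of x onto [lo, hi]; constant input maps to the midpoint.
affine_to_range <- function(x, range) {
  r <- diff(range(x))
  if (r == 0) return(rep(mean(range), length(x)))
  range[1] + (x - min(x)) / r * diff(range)
}

# Label tips by the root bipartition: larger clade "angiosperm", smaller
# "gymnosperm" (synthetic stand-ins).
root_clades <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  tips_under <- function(node) {
    if (node <= n) return(node)
    unlist(lapply(tree$edge[tree$edge[, 1] == node, 2], tips_under))
  }
  side <- lapply(kids, tips_under)
  big <- which.max(lengths(side))
  lab <- rep("gymnosperm", n)
  lab[side[[big]]] <- "angiosperm"
  lab
}

#' Draw per-species stem counts given cover and ground-truth parameters
#'
#' For species j in plot q the count is Poisson with rate
#' `lambda = M_j + C_j * F_q` (identity link, clipped below at 1e-10) or
#' `lambda = exp(M_j + C_j * F_q)` (log link). Sparsity is then created by
#' structural-zero thinning: each species is eligible only in a random subset
#' of plots, sized so the realized occupied-plot fraction targets
#' `config$occupancy`.
#'
#' @param plots plot table with `cover_pct` (from [simulate_cover_field()]).
#' @param truth ground-truth data frame (from [simulate_tree_and_traits()]),
#'   or any data frame with `species`, `M`, `C`.
#' @param config a [synthetic_config()].
#' @return the plot table with one integer count column appended per species.
#' @export
simulate_counts <- function(plots, truth, config) {
  stopifnot(inherits(config, "synthetic_config"))
  assert_plot_table(plots)
  stopifnot(all(c("species", "M", "C") %in% names(truth)))
  FF <- plots$cover_pct
  nq <- length(FF)
  if (config$link == "identity") {
    neg <- truth$M + truth$C * 100 < 0 | truth$M < 0
    if (any(neg))
      warning(sum(neg), " species have M + C*F < 0 somewhere on F in [0,100]; ",
              "rates clipped at 1e-10 (identity-link support leaves the axis)")
  }
  counts <- with_seed(derive_seed(config$seed, "counts"), {
    out <- matrix(0L, nrow = nq, ncol = nrow(truth))
    for (j in seq_len(nrow(truth))) {
      lam <- if (config$link == "identity")
        pmax(truth$M[j] + truth$C[j] * FF, 1e-10)
      else exp(truth$M[j] + truth$C[j] * FF)
      p_occ <- mean(1 - exp(-lam))
      keep_frac <- if (p_occ > 0) min(1, config$occupancy / p_occ) else 1
      eligible <- stats::runif(nq) < keep_frac
      cnt <- integer(nq)
      cnt[eligible] <- stats::rpois(sum(eligible), lam[eligible])
      out[, j] <- cnt
    }
    out
  })
  colnames(counts) <- truth$species
  cbind(plots, as.data.frame(counts))
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper running [simulate_cover_field()],
#' [simulate_tree_and_traits()] and [simulate_counts()] in sequence.
#'
#' @param config a [synthetic_config()].
#' @return list with `plots` (cover + counts), `tree`, `truth` and `clades`
#'   (two-column data frame: species, clade).
#' @export
simulate_dataset <- function(config = synthetic_config()) {
  plots <- simulate_cover_field(config)
  tt <- simulate_tree_and_traits(config)
  plots <- simulate_counts(plots, tt$truth, config)
  list(plots = plots, tree = tt$tree, truth = tt$truth,
       clades = data.frame(species = tt$truth$species,
                           clade = tt$truth$clade,
                           stringsAsFactors = FALSE))
}
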