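# WHAM reconstruction of pore-formation free-energy profiles, Bayesian
# bootstrap errors, and translation of simulation-box pore free energies to
# experimentally sized membranes.

#' A reconstructed potential of mean force
#'
#' @param grid Chain-coordinate bin centers.
#' @param G Free energy (kJ/mol), minimum shifted to 0; `NA` for unsampled
#'   bins.
#' @param err Pointwise standard deviation (kJ/mol) or `NA`.
#' @param temperature Temperature (K).
#' @return Object of class `pmf`.
#' @export
pmf_profile <- function(grid, G, err = rep(NA_real_, length(G)),
                        temperature = 323) {
  if (length(grid) != length(G) || length(G) != length(err))
    .stopf("grid, G and err must have equal length")
  if (any(err < 0, na.rm = TRUE)) .stopf("err must be non-negative")
  G <- G - min(G, na.rm = TRUE)
  structure(list(grid = grid, G = G, err = err, temperature = temperature),
            class = "pmf")
}

#' @export
print.pmf <- function(x, ...) {
  cat(sprintf("pmf: %d bins on [%.3g, %.3g], max G = %.3g kJ/mol, T = %g K\n",
              length(x$grid), min(x$grid), max(x$grid),
              max(x$G, na.rm = TRUE), x$temperature))
  invisible(x)
}

#' @keywords internal
.wham_matrices <- function(ds, n_bins, range = c(0, 1)) {
  edges <- seq(range[1], range[2], length.out = n_bins + 1L)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  W <- length(ds$windows)
  H <- matrix(0, W, n_bins)
  for (i in seq_len(W)) {
    xi <- ds$windows[[i]]$samples
    xi <- xi[xi >= range[1] & xi <= range[2]]
    H[i, ] <- tabulate(findInterval(xi, edges, rightmost.closed = TRUE,
                                    all.inside = TRUE), n_bins)
  }
  beta <- 1 / (.kB_kJmol * ds$temperature)
  # average Boltzmann factor of the harmonic bias over each bin (exact
  # Gaussian integral); a bin-center evaluation would bias the window
  # matching where the bias potential is steep across a bin
  C <- t(vapply(ds$windows, function(w) {
    s <- 1 / sqrt(beta * w$force_constant)
    a <- (edges[-length(edges)] - w$center) / s
    b <- (edges[-1] - w$center) / s
    d <- ifelse(a > 0,
                stats::pnorm(a, lower.tail = FALSE) -
                  stats::pnorm(b, lower.tail = FALSE),
                stats::pnorm(b) - stats::pnorm(a))
    sqrt(2 * pi) * s * pmax(d, 0) / diff(edges)
  }, numeric(n_bins)))
  list(H = H, C = C, centers = centers, beta = beta, N = rowSums(H))
}

#' @keywords internal
.wham_solve <- function(m, tolerance, max_iter, f_init = NULL) {
  W <- nrow(m$H); B <- ncol(m$H)
  M <- colSums(m$H)
  C <- m$C                         # W x B bin-averaged bias factors
  f <- if (is.null(f_init)) numeric(W) else f_init
  for (it in seq_len(max_iter)) {
    num <- M
    den <- colSums(m$N * exp(m$beta * f) * C)
    P <- ifelse(den > 0, num / den, 0)
    Z <- as.numeric(C %*% P)
    f_new <- -log(Z) / m$beta
    f_new <- f_new - f_new[1]
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tolerance) {
      return(list(f = f, P = P / sum(P), iterations = it, converged = TRUE))
    }
  }
  list(f = f, P = P / sum(P), iterations = max_iter, converged = FALSE,
       residual = delta)
}

#' Weighted histogram analysis of an umbrella dataset
#'
#' Solves the self-consistent WHAM equations for the unbiased probability on
#' a chain-coordinate grid and returns the free-energy profile
#' `G = -kT ln P`, shifted so its minimum is 0. Window free-energy offsets
#' are iterated until their maximum change falls below `tolerance` (kJ/mol).
#'
#' @param dataset An `umbrella_dataset` (see [generate_umbrella_dataset()],
#'   [read_umbrella_dataset()]).
#' @param n_bins Number of histogram bins over `[0, 1]` (default 200).
#' @param tolerance Convergence tolerance on the window offsets (kJ/mol).
#' @param max_iter Iteration cap; exceeding it is an error reporting the
#'   residual.
#' @return A [pmf_profile()]; unvisited bins carry `NA`.
#' @export
wham <- function(dataset, n_bins = 200, tolerance = 1e-6, max_iter = 100000) {
  stopifnot(inherits(dataset, "umbrella_dataset"))
  .check_scalar_pos(tolerance, "tolerance")
  m <- .wham_matrices(dataset, n_bins)
  .check_histogram_overlap(m)
  sol <- .wham_solve(m, tolerance, max_iter)
  if (!sol$converged)
    .stopf("WHAM did not converge in %d iterations (residual %.3g kJ/mol)",
           max_iter, sol$residual)
  G <- ifelse(sol$P > 0, -log(sol$P) / m$beta, NA_real_)
  out <- pmf_profile(m$centers, G - min(G, na.rm = TRUE),
                     temperature = dataset$temperature)
  attr(out, "window_offsets") <- sol$f
  attr(out, "iterations") <- sol$iterations
  out
}

# Histogram-level overlap check: any empty bin inside the sampled range
# wider than a couple of bins means the windows do not connect.
#' @keywords internal
.check_histogram_overlap <- function(m) {
  M <- colSums(m$H)
  occ <- which(M > 0)
  if (!length(occ)) .stopf("umbrella dataset contains no samples in [0, 1]")
  inner <- seq.int(min(occ), max(occ))
  gap <- inner[M[inner] == 0]
  if (length(gap) > 2L) {
    .stopf("umbrella windows do not overlap: empty histogram gap at grid [%.3g, %.3g]",
           min(m$centers[gap]), max(m$centers[gap]))
  }
  invisible(NULL)
}

#' Bayesian bootstrap errors for a WHAM profile
#'
#' Each round draws Dirichlet(1, ..., 1) weights over the complete window
#' histograms, re-solves WHAM with the reweighted histograms, and shifts the
#' resulting profile to zero at its minimum; the pointwise mean and standard
#' deviation over rounds give the profile and its error band.
#'
#' @inheritParams wham
#' @param rounds Number of bootstrap rounds (>= 2; default 50).
#' @param seed Integer seed.
#' @return A [pmf_profile()] with `G` the bootstrap mean and `err` the
#'   pointwise SD.
#' @export
bayesian_bootstrap_pmf <- function(dataset, rounds = 50, seed = 1,
                                   n_bins = 200, tolerance = 1e-6,
                                   max_iter = 100000) {
  stopifnot(inherits(dataset, "umbrella_dataset"))
  if (rounds < 2) .stopf("'rounds' must be >= 2")
  m <- .wham_matrices(dataset, n_bins)
  .check_histogram_overlap(m)
  base <- .wham_solve(m, tolerance, max_iter)
  if (!base$converged)
    .stopf("WHAM did not converge in %d iterations (residual %.3g kJ/mol)",
           max_iter, base$residual)
  W <- nrow(m$H)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  acc <- matrix(NA_real_, rounds, ncol(m$H))
  for (b in seq_len(rounds)) {
    g <- stats::rexp(W)
    g <- g / sum(g) * W            # Dirichlet(1,...,1), mean weight 1
    mb <- m
    mb$H <- m$H * g
    mb$N <- rowSums(mb$H)
    sol <- .wham_solve(mb, tolerance, max_iter, f_init = base$f)
    if (!sol$converged) next
    Gb <- ifelse(sol$P > 0, -log(sol$P) / mb$beta, NA_real_)
    acc[b, ] <- Gb - min(Gb, na.rm = TRUE)
  }
  Gm <- colMeans(acc, na.rm = TRUE)
  Gs <- apply(acc, 2, stats::sd, na.rm = TRUE)
  Gm[!is.finite(Gm)] <- NA_real_
  pmf_profile(m$centers, Gm, Gs, temperature = dataset$temperature)
}

#' Pore-formation free energy from a profile
#'
#' `dG_pore` is the mean free energy over the open-pore plateau minus the
#' minimum over the flat-membrane region. The error combines, in quadrature,
#' the mean pointwise error over the plateau (bootstrap errors of
#' neighbouring bins are correlated, so no 1/sqrt(n) reduction is claimed)
#' with the error at the flat-state minimum.
#'
#' @param pmf A [pmf_profile()].
#' @param flat_region Chain-coordinate interval of the flat membrane state.
#' @param pore_region Interval of the open-pore plateau.
#' @return List with `value` (kJ/mol, may be negative) and `err` (kJ/mol, NA
#'   when the profile carries no error band).
#' @export
pore_free_energy <- function(pmf, flat_region = c(0.15, 0.35),
                             pore_region = c(0.85, 1.0)) {
  stopifnot(inherits(pmf, "pmf"))
  sel <- function(rg) {
    i <- which(pmf$grid >= rg[1] & pmf$grid <= rg[2] & !is.na(pmf$G))
    if (!length(i)) .stopf("region [%g, %g] not covered by the profile",
                           rg[1], rg[2])
    i
  }
  ip <- sel(pore_region); if_ <- sel(flat_region)
  imin <- if_[which.min(pmf$G[if_])]
  value <- mean(pmf$G[ip]) - pmf$G[imin]
  err <- if (all(is.na(pmf$err[ip]))) NA_real_ else
    sqrt(mean(pmf$err[ip], na.rm = TRUE)^2 +
           (if (is.na(pmf$err[imin])) 0 else pmf$err[imin]^2))
  list(value = value, err = err)
}

#' Membrane areas of standard experimental geometries
#'
#' @param radius_nm Sphere (vesicle) radius in nm.
#' @return Area in nm^2.
#' @export
sphere_area <- function(radius_nm) 4 * pi * radius_nm^2

#' @rdname sphere_area
#' @param diameter_nm Disc (aperture) diameter in nm.
#' @export
disc_area <- function(diameter_nm) pi * (diameter_nm / 2)^2

#' Area-scale a simulation-box pore free energy
#'
#' Because the probability of finding a pore is proportional to membrane
#' area, the free energy of a pore in a membrane of area `A_exp` relates to
#' the simulation-box value by
#' `dG_exp = dG_pore - kT ln(A_exp / A_sim)`.
#'
#' @param dg_pore Simulation-box pore free energy (kJ/mol).
#' @param area_exp Experimental membrane area (nm^2); build it with
#'   [sphere_area()] or [disc_area()].
#' @param area_sim Simulation membrane area (nm^2), default 45.
#' @param temperature Temperature (K), default 300.
#' @return `dG_exp` in kJ/mol.
#' @examples
#' area_scaled_dg(65, sphere_area(1e4))   # 10-um-radius vesicle -> ~22
#' area_scaled_dg(65, disc_area(1e6))     # 1-mm aperture -> ~6
#' @export
area_scaled_dg <- function(dg_pore, area_exp, area_sim = 45,
                           temperature = 300) {
  .check_scalar_pos(area_exp, "area_exp")
  .check_scalar_pos(area_sim, "area_sim")
  dg_pore - .kB_kJmol * temperature * log(area_exp / area_sim)
}

#' Two-state open-pore probability
#'
#' `p_open = 1 / (1 + exp(dG / kT))`, the occupancy of the open-pore state
#' in a two-state picture.
#'
#' @param dg Pore free energy (kJ/mol); vectorised.
#' @param temperature Temperature (K), default 300.
#' @return Probability in (0, 1).
#' @export
pore_probability <- function(dg, temperature = 300) {
  1 / (1 + exp(dg / (.kB_kJmol * temperature)))
}

#' Write a PMF as TSV
#'
#' @param pmf A [pmf_profile()].
#' @param path Output file; columns `xi`, `G_kJmol`, `err_kJmol`.
#' @return `path`, invisibly.
#' @export
write_pmf <- function(pmf, path) {
  stopifnot(inherits(pmf, "pmf"))
  utils::write.table(data.frame(xi = pmf$grid, G_kJmol = pmf$G,
                                err_kJmol = pmf$err),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
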