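#' Solve the mass balance of an n:1 ligand:metal complex
#'
#' For total metal `M_t` and total ligand `L_t` with a single overall
#' equilibrium `M + nL <-> MLn`, `beta_n = [MLn] / ([M][L]^n)`, the free
#' ligand concentration satisfies
#' `beta_n * (M_t - (L_t - L)/n) * L^n = (L_t - L)/n`,
#' whose left side minus right side is strictly increasing in `L` on
#' `[0, L_t]`; the unique physical root is found by bisection to machine
#' precision. In the tight-binding limit (`beta = Inf`) the complex is
#' simply `min(M_t, L_t/n)`.
#'
#' @param M_total total metal, muM (vectorised).
#' @param L_total total ligand, muM.
#' @param beta overall formation constant in M^-n (`Inf` for the tight
#'   limit).
#' @param n ligands per metal (default 2).
#' @return Data frame `M_total`, `M_free`, `L_free`, `complex`, all muM.
#' @export
solve_mass_balance <- function(M_total, L_total, beta = Inf, n = 2) {
  if (L_total <= 0) stop("L_total must be > 0")
  if (any(M_total < 0)) stop("negative concentrations")
  if (n < 1 || n != round(n)) stop("n must be a positive integer")
  if (is.infinite(beta)) {
    cplx <- pmin(M_total, L_total / n)
    return(data.frame(M_total = M_total, M_free = M_total - cplx,
                      L_free = L_total - n * cplx, complex = cplx))
  }
  if (beta <= 0) stop("beta must be > 0")
  Lt <- L_total * 1e-6
  out <- vapply(M_total * 1e-6, function(Mt) {
    f <- function(L) {
      ml <- (Lt - L) / n
      beta * (Mt - ml) * L^n - ml
    }
    lo <- 0; hi <- Lt
    for (i in 1:100) {
      mid <- (lo + hi) / 2
      if (f(mid) < 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, 0)
  L_free <- out * 1e6
  cplx <- (L_total - L_free) / n
  data.frame(M_total = M_total, M_free = M_total - cplx,
             L_free = L_free, complex = cplx)
}

#' Simulate a titration isotherm
#'
#' Absorbance at each metal addition is `epsilon * [MLn] + baseline`,
#' with the complex concentration from [solve_mass_balance()].
#'
#' @param L_total total ligand, muM.
#' @param additions added metal, muM; non-negative and strictly
#'   increasing.
#' @param beta overall formation constant, M^-n (`Inf`: tight binding).
#' @param epsilon response coefficient, absorbance per muM complex.
#' @param baseline absorbance offset.
#' @param n ligands per metal.
#' @return A `titration_curve` data frame: `added`, `equivalents`
#'   (metal per ligand), `complex`, `absorbance`; attributes record the
#'   model.
#' @export
simulate_isotherm <- function(L_total, additions, beta = Inf,
                              epsilon = 0.01, baseline = 0, n = 2) {
  if (any(additions < 0)) stop("negative concentrations")
  if (is.unsorted(additions, strictly = TRUE)) {
    stop("additions must be strictly increasing")
  }
  mb <- solve_mass_balance(additions, L_total, beta = beta, n = n)
  out <- data.frame(
    added = additions,
    equivalents = additions / L_total,
    complex = mb$complex,
    absorbance = epsilon * mb$complex + baseline
  )
  attr(out, "L_total") <- L_total
  attr(out, "epsilon") <- epsilon
  attr(out, "beta") <- beta
  attr(out, "n") <- n
  class(out) <- c("titration_curve", "data.frame")
  out
}

#' Generate a noisy titration curve
#'
#' [simulate_isotherm()] plus i.i.d. Gaussian absorbance noise,
#' deterministic given the seed.
#'
#' @inheritParams simulate_isotherm
#' @param points added metal, muM.
#' @param beta2 overall formation constant, M^-2 (`Inf`: tight).
#' @param noise_sd absorbance noise SD.
#' @param seed integer seed.
#' @return A `titration_curve`.
#' @export
gen_titration <- function(L_total, points, beta2 = Inf, epsilon = 0.01,
                          noise_sd = 0, seed = 1) {
  curve <- simulate_isotherm(L_total, points, beta = beta2,
                             epsilon = epsilon, n = 2)
  if (noise_sd > 0) {
    curve$absorbance <- withr::with_seed(
      seed, curve$absorbance + rnorm(nrow(curve), 0, noise_sd))
  }
  curve
}

# Continuous two-segment fit at fixed breakpoint b: y = a + s1*min(x,b)
# + s2*max(x-b, 0), with the plateau slope constrained s2 >= 0.
fit_two_segments <- function(x, y, b) {
  X <- cbind(1, pmin(x, b), pmax(x - b, 0))
  fit <- .lm.fit(X, y)
  cf <- fit$coefficients
  if (cf[3] < 0) {
    X <- X[, 1:2, drop = FALSE]
    fit <- .lm.fit(X, y)
    cf <- c(fit$coefficients, 0)
  }
  list(ss = sum(fit$residuals^2), intercept = cf[1],
       slope_rise = cf[2], slope_plateau = cf[3])
}

#' Fit a saturation breakpoint to a titration curve
#'
#' Continuous two-segment linear least squares: a rising segment followed
#' by a plateau whose slope is constrained non-negative. The breakpoint
#' is located by a coarse-to-fine grid search over the interior of the
#' equivalents range (derivative-free, robust on 8–12-point curves; ties
#' resolved to the smallest breakpoint). The saturation point in
#' equivalents directly encodes the binding stoichiometry: an n:1
#' ligand:metal complex saturates the ligand at 1/n metal equivalents.
#'
#' @param curve a `titration_curve`, or any data frame with
#'   `equivalents` (or `added` plus an `L_total` attribute) and
#'   `absorbance`.
#' @return A `breakpoint_fit` list: `x_break` (equivalents),
#'   `stoichiometry` (ligands per metal, `1 / x_break`),
#'   `stoichiometry_rounded` (nearest half-integer), `slope_rise`,
#'   `slope_plateau`, `intercept`, `ss`, `n_points`.
#' @export
fit_breakpoint <- function(curve) {
  if (!is.null(curve$equivalents)) {
    x <- curve$equivalents
  } else if (!is.null(curve$added) && !is.null(attr(curve, "L_total"))) {
    x <- curve$added / attr(curve, "L_total")
  } else {
    stop("curve must carry equivalents (or added + L_total attribute)")
  }
  y <- curve$absorbance
  if (length(x) < 5) stop("need at least 5 titration points")
  rng <- range(x)
  span <- diff(rng)
  lo <- rng[1] + 0.02 * span
  hi <- rng[2] - 0.02 * span
  best <- NULL
  grid <- seq(lo, hi, length.out = 81)
  for (round in 1:4) {
    ss <- vapply(grid, function(b) fit_two_segments(x, y, b)$ss, 0)
    # tie-break: smallest breakpoint among SS-equal minima
    i <- which(ss <= min(ss) + 1e-12 * (1 + min(ss)))[1]
    best <- grid[i]
    step <- if (length(grid) > 1) grid[2] - grid[1] else 0
    if (round == 1 && (i == 1 || i == length(grid))) {
      stop("no interior breakpoint: best fit lies at the data edge")
    }
    grid <- seq(max(lo, best - step), min(hi, best + step),
                length.out = 41)
  }
  fit <- fit_two_segments(x, y, best)
  structure(
    list(x_break = best,
         stoichiometry = 1 / best,
         stoichiometry_rounded = round(2 / best) / 2,
         slope_rise = fit$slope_rise,
         slope_plateau = fit$slope_plateau,
         intercept = fit$intercept,
         ss = fit$ss, n_points = length(x)),
    class = "breakpoint_fit"
  )
}

#' @export
print.breakpoint_fit <- function(x, ...) {
  cat(sprintf(
    "breakpoint fit: x_break = %.4g equivalents (%.3g:1 ligand:metal, rounded %.1f:1)\n",
    x$x_break, x$stoichiometry, x$stoichiometry_rounded))
  cat(sprintf("  rising slope %.4g, plateau slope %.4g, SS %.4g (n = %d)\n",
              x$slope_rise, x$slope_plateau, x$ss, x$n_points))
  invisible(x)
}

#' Metal quantification arithmetic
#'
#' Converts a measured metal amount per culture into atoms per cell and
#' atoms per total cell volume, and estimates the accumulated
#' metal-to-ionophore mole ratio under the assumption that all ionophore
#' added to the culture was accumulated by the cells. When no untreated
#' baseline is supplied the ratio uses the treated total alone and is
#' flagged.
#'
#' @param mol_metal metal per culture, mol.
#' @param cells cell count (needed for atoms per cell).
#' @param total_volume_fl aggregate cell volume, fL (needed for atoms per
#'   volume).
#' @param mean_cell_volume_fl optional mean single-cell volume, fL.
#' @param bpq_added_mol ionophore added to the culture, mol (needed for
#'   the ratio).
#' @param baseline_mol metal in an untreated control culture, mol.
#' @return A `metal_quant` list: `atoms_total`, `atoms_per_cell`,
#'   `atoms_per_fl`, `cu_bpq_ratio`, `baseline_subtracted`, `flags`.
#' @export
quantify_metal <- function(mol_metal, cells = NULL, total_volume_fl = NULL,
                           mean_cell_volume_fl = NULL,
                           bpq_added_mol = NULL, baseline_mol = NULL) {
  if (mol_metal < 0) stop("mol_metal must be >= 0")
  atoms <- mol_metal * AVOGADRO
  per_cell <- if (!is.null(cells)) {
    if (cells <= 0) stop("cell count must be > 0 for per-cell output")
    atoms / cells
  } else NA_real_
  per_fl <- if (!is.null(total_volume_fl)) {
    if (total_volume_fl <= 0) stop("total cell volume must be > 0")
    atoms / total_volume_fl
  } else NA_real_
  flags <- character()
  ratio <- NA_real_
  if (!is.null(bpq_added_mol)) {
    if (bpq_added_mol <= 0) stop("bpq_added_mol must be > 0")
    net <- if (!is.null(baseline_mol)) {
      mol_metal - baseline_mol
    } else {
      flags <- c(flags, "no-baseline")
      mol_metal
    }
    ratio <- net * AVOGADRO / (bpq_added_mol * AVOGADRO)
  }
  structure(
    list(atoms_total = atoms, atoms_per_cell = per_cell,
         atoms_per_fl = per_fl,
         mean_cell_volume_fl = mean_cell_volume_fl,
         cu_bpq_ratio = ratio,
         baseline_subtracted = !is.null(baseline_mol),
         flags = flags),
    class = "metal_quant"
  )
}
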