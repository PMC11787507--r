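# Parameter vector layout used by the optimizer: the 10 thermodynamic
# parameters followed by two oxidized-shift nuisances per probe.
param_names <- function(probes) {
  c("g_ox_I", "g_ox_III", "g_ox_IV",
    "i_redox_I-III", "i_redox_I-IV", "i_redox_III-IV",
    "g_H", "i_bohr_I", "i_bohr_III", "i_bohr_IV",
    paste0("delta_ox_prot[", probes$probe_id, "]"),
    paste0("delta_ox_deprot[", probes$probe_id, "]"))
}

theta_to_params <- function(theta, temperature, protein = NULL) {
  structure(list(
    g_ox = stats::setNames(theta[1:3], HEMES),
    i_redox = stats::setNames(theta[4:6], HEME_PAIRS),
    g_h = unname(theta[7]),
    i_bohr = stats::setNames(theta[8:10], HEMES),
    temperature = temperature, protein = protein
  ), class = "thermo_params")
}

params_to_theta <- function(params) {
  c(params$g_ox[HEMES], params$i_redox[HEME_PAIRS], params$g_h,
    params$i_bohr[HEMES])
}

theta_to_probes <- function(theta, probes) {
  np <- nrow(probes)
  probes$delta_ox_prot <- unname(theta[10 + seq_len(np)])
  probes$delta_ox_deprot <- unname(theta[10 + np + seq_len(np)])
  probes
}

#' Define a simultaneous NMR + visible fitting problem
#'
#' Bundles the two datasets, the probe definitions (reduced-state shifts are
#' fixed from stage-0 data and not fitted), the initialization, and the
#' optimizer settings for the global weighted least-squares estimation of the
#' 10 thermodynamic parameters plus two oxidized-shift nuisance parameters
#' per probe.
#'
#' The NMR chemical shifts constrain only energy *differences* within
#' oxidation stages: a uniform shift of all three oxidation energies
#' (matched by a shift of the potential scale) leaves every NMR prediction
#' unchanged. The absolute potential scale therefore comes from the visible
#' titrations, and a fit with free oxidation energies requires a non-empty
#' visible dataset.
#'
#' @param nmr NMR dataset tibble (`probe_id, stage, pH, shift_ppm,
#'   sigma_ppm`), stages 1-3.
#' @param vis Visible dataset tibble (`pH, potential_mV, reduced_fraction,
#'   sigma`), or `NULL` for an NMR-only (relative) problem.
#' @param probes A [methyl_probes] tibble; `delta_red` is fixed, the oxidized
#'   shift columns (if finite) serve as initial guesses.
#' @param init Optional [thermo_params] used as initialization; if `NULL` a
#'   default is constructed (oxidation energies at the visible half-reduction
#'   potential, redox interactions +20 meV, deprotonation energy 500 meV,
#'   redox-Bohr interactions -30 meV).
#' @param fixed Character vector of parameter names to hold at their initial
#'   values (see `tidy()` output for the names).
#' @param temperature Absolute temperature, K.
#' @param nmr_weight Optional multiplier applied to the NMR residual weights
#'   (default 1: pure inverse-variance weighting, no inter-dataset
#'   rebalancing).
#' @param lower,upper Optional named bounds on parameters.
#' @param ftol,ptol,max_iter Convergence controls: relative cost tolerance,
#'   parameter tolerance, iteration budget.
#' @return A list of class `fit_problem`.
#' @export
fit_problem <- function(nmr, vis, probes, init = NULL,
                        fixed = character(0), temperature = 288.15,
                        nmr_weight = 1, lower = NULL, upper = NULL,
                        ftol = 1e-12, ptol = 1e-10, max_iter = 500) {
  stopifnot(nrow(nmr) > 0, inherits(probes, "data.frame"))
  if (!all(nmr$stage %in% 1:3)) abort("NMR records must have stage in 1..3")
  if (any(nmr$sigma_ppm <= 0)) abort("sigma_ppm must be positive")
  if (!is.null(vis) && nrow(vis) > 0 && any(vis$sigma <= 0)) {
    abort("visible sigma must be positive")
  }
  if (!all(nmr$probe_id %in% probes$probe_id)) {
    abort("NMR dataset references probes missing from `probes`")
  }
  has_vis <- !is.null(vis) && nrow(vis) > 0
  free_gox <- !all(c("g_ox_I", "g_ox_III", "g_ox_IV") %in% fixed)
  if (!has_vis && free_gox) {
    abort(paste(
      "unidentifiable problem: NMR shifts are invariant to a uniform shift",
      "of all oxidation energies, so absolute potentials require a visible",
      "dataset (or fixing g_ox_I, g_ox_III, g_ox_IV)."))
  }
  structure(list(nmr = nmr, vis = if (has_vis) vis else NULL,
                 probes = probes, init = init, fixed = fixed,
                 temperature = temperature, nmr_weight = nmr_weight,
                 lower = lower, upper = upper,
                 ftol = ftol, ptol = ptol, max_iter = max_iter),
            class = "fit_problem")
}

# default initialization: g_ox at the visible half-reduction potential,
# interactions +20 meV, g_H 500 meV, i_bohr -30 meV; oxidized shifts from
# the stage-3 records at the pH extremes (probe columns as fallback)
default_init_theta <- function(problem) {
  nmr <- problem$nmr; vis <- problem$vis; probes <- problem$probes
  if (!is.null(vis)) {
    v <- vis[vis$pH == min(vis$pH), ]
    v <- v[order(v$potential_mV), ]
    e_half <- stats::approx(v$reduced_fraction, v$potential_mV, xout = 0.5,
                            ties = mean)$y
    if (is.na(e_half)) e_half <- stats::median(v$potential_mV)
  } else {
    e_half <- 0
  }
  theta <- c(rep(e_half, 3), rep(20, 3), 500, rep(-30, 3))
  dop <- dod <- numeric(nrow(probes))
  s3 <- nmr[nmr$stage == 3, ]
  for (i in seq_len(nrow(probes))) {
    rec <- s3[s3$probe_id == probes$probe_id[i], ]
    if (nrow(rec) > 0) {
      dop[i] <- rec$shift_ppm[which.min(rec$pH)]
      dod[i] <- rec$shift_ppm[which.max(rec$pH)]
    } else {
      dop[i] <- probes$delta_ox_prot[i]
      dod[i] <- probes$delta_ox_deprot[i]
    }
  }
  if (anyNA(c(dop, dod))) {
    abort("no stage-3 records and no oxidized-shift guesses for some probe")
  }
  stats::setNames(c(theta, dop, dod), param_names(probes))
}

# weighted residual vector at parameter vector theta (full, incl. fixed)
fit_residuals <- function(theta, problem) {
  params <- theta_to_params(theta, problem$temperature)
  probes <- theta_to_probes(theta, problem$probes)
  mu_nmr <- predicted_shift(params, probes, problem$nmr$probe_id,
                            problem$nmr$stage, problem$nmr$pH)
  r <- (problem$nmr$shift_ppm - mu_nmr) / problem$nmr$sigma_ppm *
    sqrt(problem$nmr_weight)
  if (!is.null(problem$vis)) {
    mu_vis <- predicted_reduced_fraction(params, problem$vis$potential_mV,
                                         problem$vis$pH)
    r <- c(r, (problem$vis$reduced_fraction - mu_vis) / problem$vis$sigma)
  }
  r
}

# central-difference Jacobian of the weighted residuals wrt free parameters
fit_jacobian <- function(theta, free, problem, h = 1e-4) {
  r0 <- fit_residuals(theta, problem)
  J <- matrix(0, length(r0), sum(free))
  cols <- which(free)
  for (k in seq_along(cols)) {
    step <- max(h, abs(theta[cols[k]]) * h)
    tp <- tm <- theta
    tp[cols[k]] <- tp[cols[k]] + step
    tm[cols[k]] <- tm[cols[k]] - step
    J[, k] <- (fit_residuals(tp, problem) - fit_residuals(tm, problem)) /
      (2 * step)
  }
  J
}

#' Simultaneous weighted least-squares fit of NMR and visible data
#'
#' Minimizes the combined chi-square
#' `sum(((obs - pred) / sigma)^2)` over the NMR shift records (linewidth-
#' derived sigma) and the visible titration records (3%-of-signal sigma),
#' with the 10 thermodynamic parameters and per-probe oxidized-shift
#' nuisances free, using Levenberg-Marquardt least squares
#' ([minpack.lm::nls.lm]) with optional box bounds. Deterministic given
#' identical inputs and initialization.
#'
#' @param problem A [fit_problem].
#' @return An object of class `redox_fit`: estimated [thermo_params]
#'   (`$params`), probe table with estimated oxidized shifts (`$probes`),
#'   named estimate and standard-error vectors, per-record weighted
#'   residuals, chi-square and reduced chi-square, convergence flag and
#'   message, and the initialization used. Non-convergence is flagged, not
#'   an error. Standard errors are asymptotic: `(J'J)^-1` scaled by the
#'   reduced chi-square, from a central-difference Jacobian at the optimum;
#'   a singular Jacobian raises an error naming the unidentifiable parameter
#'   combination. Use [tidy()] / [glance()] to extract results.
#' @examples
#' \donttest{
#' spec <- generator_spec(ppc_params("ppcA_Gu"), seed = 1)
#' prob <- fit_problem(generate_nmr(spec), generate_visible(spec),
#'                     synthetic_probes())
#' fit <- simultaneous_fit(prob)
#' tidy(fit)
#' }
#' @export
simultaneous_fit <- function(problem) {
  stopifnot(inherits(problem, "fit_problem"))
  nm <- param_names(problem$probes)
  theta0 <- if (is.null(problem$init)) default_init_theta(problem) else {
    if (inherits(problem$init, "thermo_params")) {
      t0 <- default_init_theta(problem)
      t0[1:10] <- params_to_theta(problem$init)
      t0
    } else stats::setNames(rep_len(problem$init, length(nm)), nm)
  }
  names(theta0) <- nm
  bad <- setdiff(problem$fixed, nm)
  if (length(bad)) abort(paste0("unknown fixed parameter(s): ",
                                paste(bad, collapse = ", ")))
  free <- !(nm %in% problem$fixed)
  lower <- rep(-Inf, sum(free)); upper <- rep(Inf, sum(free))
  if (!is.null(problem$lower)) {
    lower <- ifelse(nm[free] %in% names(problem$lower),
                    problem$lower[nm[free]], lower)
  }
  if (!is.null(problem$upper)) {
    upper <- ifelse(nm[free] %in% names(problem$upper),
                    problem$upper[nm[free]], upper)
  }
  fn <- function(x) {
    th <- theta0
    th[free] <- x
    fit_residuals(th, problem)
  }
  res <- minpack.lm::nls.lm(
    par = theta0[free], fn = fn, lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(
      ftol = problem$ftol, ptol = problem$ptol,
      maxiter = min(problem$max_iter, 1024), maxfev = 100000)
  )
  theta <- theta0
  theta[free] <- res$par
  converged <- res$info %in% 1:4
  r <- fit_residuals(theta, problem)
  chisq <- sum(r^2)
  n_obs <- length(r)
  df <- n_obs - sum(free)
  # asymptotic covariance at the optimum
  J <- fit_jacobian(theta, free, problem)
  JtJ <- crossprod(J)
  ev <- eigen(JtJ, symmetric = TRUE)
  if (min(ev$values) <= max(ev$values) * 1e-12) {
    v <- ev$vectors[, which.min(ev$values)]
    top <- order(abs(v), decreasing = TRUE)[1:3]
    abort(paste0(
      "singular Jacobian: unidentifiable parameter combination, dominated ",
      "by ", paste(sprintf("%+.2f*%s", v[top], nm[free][top]),
                   collapse = " ")))
  }
  s2 <- chisq / max(df, 1)
  se_free <- sqrt(diag(solve(JtJ)) * s2)
  se <- stats::setNames(rep(NA_real_, length(nm)), nm)
  se[free] <- se_free
  residual_tbl <- dplyr::bind_rows(
    tibble(dataset = "nmr",
           id = paste0(problem$nmr$probe_id, "/s", problem$nmr$stage,
                       "/pH", problem$nmr$pH),
           residual = r[seq_len(nrow(problem$nmr))]),
    if (!is.null(problem$vis)) tibble(
      dataset = "visible",
      id = paste0("pH", problem$vis$pH, "/", problem$vis$potential_mV, "mV"),
      residual = r[nrow(problem$nmr) + seq_len(nrow(problem$vis))])
  )
  structure(list(
    params = theta_to_params(theta, problem$temperature),
    probes = theta_to_probes(theta, problem$probes),
    estimate = theta, std_error = se, fixed = problem$fixed,
    residuals = residual_tbl, chisq = chisq, df = df,
    reduced_chisq = chisq / max(df, 1), n_obs = n_obs,
    n_free = sum(free), iterations = res$niter,
    converged = converged, message = res$message,
    init = theta0, problem = problem
  ), class = "redox_fit")
}

#' @export
print.redox_fit <- function(x, ...) {
  cat("<redox_fit> ", x$n_free, " free parameters, ", x$n_obs,
      " records\n", sep = "")
  cat(sprintf("  chi-square %.4g on %d df (reduced %.3f); %s in %d iterations\n",
              x$chisq, x$df, x$reduced_chisq,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  print(x$params)
  invisible(x)
}

#' Asymptotic standard errors of a fit
#'
#' @param fit A `redox_fit`.
#' @return Named vector of standard errors for the free parameters (fixed
#'   parameters are omitted).
#' @export
standard_errors <- function(fit) {
  stopifnot(inherits(fit, "redox_fit"))
  fit$std_error[!is.na(fit$std_error)]
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a redox fit
#'
#' @param x A `redox_fit`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `std.error` (`NA` for
#'   fixed parameters), `fixed`.
#' @export
tidy.redox_fit <- function(x, ...) {
  tibble(term = names(x$estimate),
         estimate = unname(x$estimate),
         std.error = unname(x$std_error),
         fixed = names(x$estimate) %in% x$fixed)
}

#' Glance at a redox fit
#'
#' @param x A `redox_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `chisq`, `df.residual`, `reduced.chisq`,
#'   `n.obs`, `n.free`, `iterations`, `converged`.
#' @export
glance.redox_fit <- function(x, ...) {
  tibble(chisq = x$chisq, df.residual = x$df,
         reduced.chisq = x$reduced_chisq, n.obs = x$n_obs,
         n.free = x$n_free, iterations = x$iterations,
         converged = x$converged)
}

#' Best-of-n multistart fit
#'
#' Runs [simultaneous_fit()] from the problem's initialization and from
#' `n_starts - 1` perturbed initializations (Gaussian perturbations: SD
#' `energy_sd` meV on the thermodynamic parameters, `shift_sd` ppm on the
#' nuisance shifts) and returns the fit with the lowest chi-square.
#' Deterministic given `seed`; `n_starts = 1` is exactly
#' `simultaneous_fit(problem)`.
#'
#' @param problem A [fit_problem].
#' @param n_starts Number of starts.
#' @param seed Integer seed for the perturbations.
#' @param energy_sd,shift_sd Perturbation SDs.
#' @return The best `redox_fit`, with `$n_starts` recorded.
#' @export
multi_start <- function(problem, n_starts = 5, seed = 20241214,
                        energy_sd = 20, shift_sd = 0.5) {
  stopifnot(inherits(problem, "fit_problem"), n_starts >= 1)
  base_init <- if (is.null(problem$init)) default_init_theta(problem) else
    problem$init
  fits <- vector("list", n_starts)
  fits[[1]] <- simultaneous_fit(problem)
  if (n_starts > 1) {
    theta0 <- fits[[1]]$init
    perturbs <- withr::with_seed(seed, {
      lapply(seq_len(n_starts - 1), function(i) {
        c(stats::rnorm(10, 0, energy_sd),
          stats::rnorm(length(theta0) - 10, 0, shift_sd))
      })
    })
    for (i in seq_len(n_starts - 1)) {
      pr <- problem
      pr$init <- theta0 + perturbs[[i]]
      fits[[i + 1]] <- simultaneous_fit(pr)
    }
  }
  best <- fits[[which.min(vapply(fits, function(f) f$chisq, numeric(1)))]]
  best$n_starts <- n_starts
  best
}
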