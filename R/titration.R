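# Two-state model of ion-induced k-turn folding followed by FRET.
#
# The folded fraction follows a Hill dependence on ion concentration c:
#     E(c) = E0 + dE * (KA * c^n) / (1 + KA * c^n)
# where E0 is the FRET efficiency without added ions, dE the increase at
# saturation, KA the apparent association constant (units conc^-n) and n a
# Hill coefficient.  The transition is half complete at
#     c_1/2 = (1/KA)^(1/n),
# which pins down the functional form.  Fitting is unweighted nonlinear
# least squares; KA is optimized on a log scale so positivity is structural,
# and n is bounded to [0.3, 5] to avoid pathological exponents on sparse
# data.

#' Two-state ion-titration model
#'
#' @param E0 baseline FRET efficiency (no added ions).
#' @param dE amplitude of the FRET increase at saturating ions.
#' @param KA apparent association constant (> 0; units concentration^-n).
#' @param n Hill coefficient (> 0).
#' @param conc ion concentration(s), >= 0, in the unit implied by `KA`.
#' @return E_FRET value(s), vectorized over `conc`.
#' @examples
#' model_efret(0.2, 0.36, KA = 1 / 70, n = 1, conc = 70)  # E0 + dE/2
#' @export
model_efret <- function(E0, dE, KA, n, conc) {
  if (!all(is.finite(c(E0, dE, KA, n))))
    kt_stop("kt_input_error", "model parameters must be finite")
  if (KA <= 0) kt_stop("kt_input_error", "KA must be > 0")
  if (n <= 0) kt_stop("kt_input_error", "n must be > 0")
  if (any(!is.finite(conc)) || any(conc < 0))
    kt_stop("kt_input_error", "concentrations must be finite and >= 0")
  x <- KA * conc^n
  f <- x / (1 + x)
  f[is.infinite(x)] <- 1
  f[conc == 0] <- 0
  E0 + dE * f
}

#' Half-completion concentration of the two-state transition
#'
#' @param KA apparent association constant (> 0).
#' @param n Hill coefficient (> 0).
#' @return `(1/KA)^(1/n)`, the ion concentration at half-completion.
#' @export
half_point <- function(KA, n) {
  if (!is.finite(KA) || KA <= 0 || !is.finite(n) || n <= 0)
    kt_stop("kt_domain_error", "half_point requires KA > 0 and n > 0")
  (1 / KA)^(1 / n)
}

#' Construct a titration curve
#'
#' @param concentrations non-negative ion (or protein) concentrations.
#' @param efret FRET efficiencies, same length; values must lie in
#'   [-0.1, 1.1] (noise may push measurements slightly outside [0, 1]).
#' @param ligand name of the titrated species (e.g. "Mg2+", "Na+", "L7Ae").
#' @param unit concentration unit ("uM" or "mM").
#' @param meta optional metadata list (generators record their parameters).
#' @return Object of class `titration_curve`, sorted by concentration.
#' @export
titration_curve <- function(concentrations, efret, ligand = "Mg2+",
                            unit = "uM", meta = list()) {
  if (length(concentrations) != length(efret))
    kt_stop("kt_input_error", "concentrations and efret differ in length")
  if (any(!is.finite(concentrations)) || any(concentrations < 0))
    kt_stop("kt_input_error", "concentrations must be finite and >= 0")
  if (any(!is.finite(efret)) || any(efret < -0.1) || any(efret > 1.1))
    kt_stop("kt_input_error", "efret values must be finite and within [-0.1, 1.1]")
  o <- order(concentrations)
  structure(list(conc = as.numeric(concentrations[o]),
                 efret = as.numeric(efret[o]),
                 ligand = ligand, unit = unit, meta = meta),
            class = "titration_curve")
}

#' @export
print.titration_curve <- function(x, ...) {
  cat(sprintf("titration of %s (%s): %d points, conc %s-%s, E_FRET %.3f-%.3f\n",
              x$ligand, x$unit, length(x$conc),
              format(min(x$conc)), format(max(x$conc)),
              min(x$efret), max(x$efret)))
  invisible(x)
}

#' Read a titration table from delimited text
#'
#' Whitespace- or tab-delimited with a header row naming at least
#' `concentration` (or `conc`) and `efret` columns; optional `replicate`.
#' Leading comment lines of the form `# key=value` may declare `ligand` and
#' `unit`.
#'
#' @param path file path.
#' @return A [titration_curve()]; replicate points are pooled (unweighted).
#' @export
read_titration_table <- function(path) {
  if (!file.exists(path)) kt_stop("kt_input_error", sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- list(ligand = "Mg2+", unit = "uM")
  for (h in hdr) {
    toks <- regmatches(h, gregexpr("[A-Za-z_]+=[^[:space:]]+", h))[[1]]
    for (t in toks) {
      p <- strsplit(t, "=", fixed = TRUE)[[1]]
      if (p[1] %in% c("ligand", "unit")) kv[[p[1]]] <- p[2]
    }
  }
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body) < 2L) kt_stop("kt_format_error", "titration table has no data rows")
  df <- utils::read.table(text = body, header = TRUE,
                          stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  ccol <- intersect(c("concentration", "conc"), names(df))[1]
  if (is.na(ccol) || !"efret" %in% names(df))
    kt_stop("kt_format_error",
            "titration table needs 'concentration' (or 'conc') and 'efret' columns")
  titration_curve(df[[ccol]], df$efret, ligand = kv$ligand, unit = kv$unit)
}

#' Convert the concentration unit of a titration curve
#'
#' @param curve a [titration_curve()].
#' @param to `"uM"` or `"mM"`.
#' @return The converted curve.
#' @export
convert_unit <- function(curve, to = c("uM", "mM")) {
  to <- match.arg(to)
  from <- curve$unit
  if (!from %in% c("uM", "mM")) kt_stop("kt_input_error", "unknown source unit")
  factor <- if (from == to) 1 else if (from == "uM") 1e-3 else 1e3
  titration_curve(curve$conc * factor, curve$efret, ligand = curve$ligand,
                  unit = to, meta = curve$meta)
}

rss_of <- function(curve, E0, dE, KA, n)
  sum((curve$efret - model_efret(E0, dE, KA, n, curve$conc))^2)

# Initialization heuristic: E0 <- min(E); dE <- max - min; half-point from
# the first linear-interpolated crossing of the midpoint; n <- 1.
init_guess <- function(curve) {
  e <- curve$efret; conc <- curve$conc
  E0 <- min(e); dE <- max(e) - min(e)
  mid <- E0 + dE / 2
  cross <- which(e[-1] >= mid & e[-length(e)] < mid)
  hp <- if (length(cross) > 0L) {
    i <- cross[1]
    c0 <- conc[i]; c1 <- conc[i + 1]
    f <- (mid - e[i]) / (e[i + 1] - e[i])
    c0 + f * (c1 - c0)
  } else stats::median(conc[conc > 0])
  if (!is.finite(hp) || hp <= 0) hp <- stats::median(conc[conc > 0])
  list(E0 = E0, dE = dE, KA = 1 / hp, n = 1)
}

#' Fit the two-state ion-titration model
#'
#' Unweighted nonlinear least squares of [model_efret()] to a titration
#' curve.  KA is optimized as log(KA); n is constrained to [0.3, 5] unless
#' fixed.  A flat curve (no measurable transition) returns a `dE = 0` fit
#' flagged `"no_transition"` instead of failing.
#'
#' @param curve a [titration_curve()] with at least 5 points; a warning flag
#'   is recorded if the positive concentrations span less than 10-fold.
#' @param fix_n optional fixed Hill coefficient (e.g. 1); default free.
#' @param init optional named list overriding the initialization heuristic
#'   (any of `E0`, `dE`, `KA`, `n`).
#' @return Object of class `twostate_fit` with fields `E0`, `dE`, `KA`, `n`,
#'   `half_point`, `rss`, `converged`, `flags`, `fitted`, `residuals`,
#'   `curve` and `ci` (populated by [bootstrap_ci()]).
#' @examples
#' curve <- simulate_titration(kt7_titration_spec(noise_sd = 0))
#' fit <- fit_titration(curve)
#' fit$half_point  # ~70 (uM)
#' @export
fit_titration <- function(curve, fix_n = NULL, init = NULL) {
  stopifnot(inherits(curve, "titration_curve"))
  if (length(curve$conc) < 5L)
    kt_stop("kt_precondition_error",
            sprintf("need >= 5 titration points for fitting, got %d",
                    length(curve$conc)))
  flags <- character(0)
  pos <- curve$conc[curve$conc > 0]
  if (length(pos) == 0L || max(pos) / min(pos) < 10)
    flags <- c(flags, "narrow_range")

  if (diff(range(curve$efret)) < 1e-8) {
    fit <- list(E0 = mean(curve$efret), dE = 0, KA = 1, n = 1)
    return(finish_fit(curve, fit, rss_of(curve, fit$E0, fit$dE, fit$KA, fit$n),
                      converged = TRUE, flags = c(flags, "no_transition"),
                      fixed_n = !is.null(fix_n)))
  }

  g <- init_guess(curve)
  for (nm in names(init)) g[[nm]] <- init[[nm]]
  if (!is.null(fix_n)) {
    if (!is.finite(fix_n) || fix_n <= 0)
      kt_stop("kt_input_error", "fix_n must be > 0")
    g$n <- fix_n
  }

  conc <- curve$conc; efret <- curve$efret
  free_n <- is.null(fix_n)
  lower <- c(E0 = -2, dE = -2.2, lka = -700)
  upper <- c(E0 = 2, dE = 2.2, lka = 700)
  start <- list(E0 = g$E0, dE = g$dE, lka = log(g$KA))
  if (free_n) {
    start$n <- min(max(g$n, 0.3), 5)
    lower <- c(lower, n = 0.3); upper <- c(upper, n = 5)
  }

  pred <- function(p) {
    n_use <- if (free_n) p[["n"]] else fix_n
    model_efret(p[["E0"]], p[["dE"]], exp(p[["lka"]]), n_use, conc)
  }
  obj <- function(p) sum((efret - pred(p))^2)

  fit_ok <- FALSE
  ans <- tryCatch({
    df <- data.frame(conc = conc, efret = efret)
    form <- if (free_n) efret ~ E0 + dE * (exp(lka) * conc^n) / (1 + exp(lka) * conc^n)
            else substitute(efret ~ E0 + dE * (exp(lka) * conc^NN) / (1 + exp(lka) * conc^NN),
                            list(NN = fix_n))
    m <- stats::nls(stats::as.formula(form), data = df, start = start,
                    lower = lower, upper = upper, algorithm = "port",
                    control = stats::nls.control(maxiter = 500,
                                                 warnOnly = FALSE))
    p <- stats::coef(m)
    fit_ok <- TRUE
    p
  }, error = function(e) NULL)

  if (is.null(ans)) {
    # fall back to box-constrained quasi-Newton on the same objective
    p0 <- unlist(start)
    opt <- tryCatch(
      stats::optim(p0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 2000, factr = 1e4)),
      error = function(e) NULL)
    if (is.null(opt)) {
      cond <- errorCondition(
        "two-state fit failed to converge",
        best = c(start, list(rss = obj(unlist(start)))),
        diagnostics = "both nls(port) and L-BFGS-B failed",
        class = c("kt_fit_error", "kt_error"))
      stop(cond)
    }
    ans <- opt$par
    fit_ok <- opt$convergence == 0
    if (!fit_ok) flags <- c(flags, "not_converged")
  }

  E0 <- unname(ans[["E0"]]); dE <- unname(ans[["dE"]])
  KA <- exp(unname(ans[["lka"]]))
  n_hat <- if (free_n) unname(ans[["n"]]) else fix_n
  if (abs(dE) < 1e-3) flags <- c(flags, "no_transition")
  finish_fit(curve, list(E0 = E0, dE = dE, KA = KA, n = n_hat),
             rss_of(curve, E0, dE, KA, n_hat), converged = fit_ok,
             flags = flags, fixed_n = !free_n)
}

finish_fit <- function(curve, p, rss, converged, flags, fixed_n) {
  fitted <- model_efret(p$E0, p$dE, p$KA, p$n, curve$conc)
  structure(list(E0 = p$E0, dE = p$dE, KA = p$KA, n = p$n,
                 half_point = half_point(p$KA, p$n), rss = rss,
                 ci = NULL, converged = converged, flags = flags,
                 fixed_n = fixed_n, fitted = fitted,
                 residuals = curve$efret - fitted, curve = curve),
            class = "twostate_fit")
}

#' @export
print.twostate_fit <- function(x, ...) {
  cat(sprintf(
    "two-state fit (%s, %s): E0=%.4f  dE=%.4f  KA=%.4g %s^-n  n=%.3f\n",
    x$curve$ligand, x$curve$unit, x$E0, x$dE, x$KA, x$curve$unit, x$n))
  cat(sprintf("  half-point [%s]_1/2 = %.4g %s   rss = %.3g%s\n",
              x$curve$ligand, x$half_point, x$curve$unit, x$rss,
              if (length(x$flags)) paste0("   flags: ",
                                          paste(x$flags, collapse = ",")) else ""))
  invisible(x)
}

#' Residual-resampling bootstrap intervals for a titration fit
#'
#' Resamples fit residuals with replacement onto the fitted curve, refits,
#' and returns percentile intervals for E0, dE, KA, n and the half-point.
#' Reproducible for a given seed; the caller's RNG state is untouched.
#'
#' @param curve the fitted [titration_curve()].
#' @param fit the [fit_titration()] result.
#' @param n_boot number of bootstrap replicates (a warning is recorded in
#'   the output below 50).
#' @param seed integer seed.
#' @param level interval coverage (default 0.95).
#' @return List with `ci` (matrix, parameters x lower/upper), `n_boot`,
#'   `n_failed`, `seed`, `level`, `warnings`.
#' @export
bootstrap_ci <- function(curve, fit, n_boot = 200L, seed = 1L, level = 0.95) {
  stopifnot(inherits(fit, "twostate_fit"))
  if (!fit$converged) kt_stop("kt_precondition_error",
                              "bootstrap requires a converged fit")
  warnings <- character(0)
  if (n_boot < 50L)
    warnings <- c(warnings, sprintf("n_boot=%d is below 50; intervals unstable",
                                    n_boot))
  pars <- c("E0", "dE", "KA", "n", "half_point")
  fix_n <- if (fit$fixed_n) fit$n else NULL
  draws <- with_seed(seed, {
    res <- fit$residuals
    out <- matrix(NA_real_, nrow = n_boot, ncol = length(pars),
                  dimnames = list(NULL, pars))
    for (b in seq_len(n_boot)) {
      ystar <- fit$fitted + sample(res, length(res), replace = TRUE)
      ystar <- pmin(pmax(ystar, -0.1), 1.1)
      cb <- titration_curve(curve$conc, ystar, ligand = curve$ligand,
                            unit = curve$unit)
      fb <- tryCatch(
        fit_titration(cb, fix_n = fix_n,
                      init = list(E0 = fit$E0, dE = fit$dE, KA = fit$KA,
                                  n = fit$n)),
        kt_error = function(e) NULL, error = function(e) NULL)
      if (!is.null(fb))
        out[b, ] <- c(fb$E0, fb$dE, fb$KA, fb$n, fb$half_point)
    }
    out
  })
  ok <- stats::complete.cases(draws)
  alpha <- (1 - level) / 2
  ci <- t(apply(draws[ok, , drop = FALSE], 2, stats::quantile,
                probs = c(alpha, 1 - alpha), names = FALSE))
  colnames(ci) <- c("lower", "upper")
  list(ci = ci, n_boot = n_boot, n_failed = sum(!ok), seed = seed,
       level = level, warnings = warnings)
}

#' Write a fit report as key=value text
#'
#' @param fit a `twostate_fit`.
#' @param path output file.
#' @param seed optional seed to echo in the header.
#' @export
write_fit_report <- function(fit, path, seed = NULL) {
  lines <- c(kt_version_header(seed),
             sprintf("ligand=%s", fit$curve$ligand),
             sprintf("unit=%s", fit$curve$unit),
             sprintf("n_points=%d", length(fit$curve$conc)),
             sprintf("E0=%.10g", fit$E0),
             sprintf("dE=%.10g", fit$dE),
             sprintf("KA=%.10g", fit$KA),
             sprintf("n=%.10g", fit$n),
             sprintf("half_point=%.10g", fit$half_point),
             sprintf("rss=%.10g", fit$rss),
             sprintf("converged=%s", fit$converged),
             sprintf("flags=%s", paste(fit$flags, collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}
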