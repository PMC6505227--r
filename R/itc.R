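#' Titration scheme for an ITC experiment
#'
#' Describes the cell and syringe of a perfusion-type microcalorimeter
#' (iTC200-style): cell volume, macromolecule (lectin) concentration in the
#' cell, ligand concentration in the syringe, the injection schedule and the
#' temperature. Defaults give an 18 x 2 uL schedule reaching roughly three
#' equivalents past a stoichiometry of ~1/3.
#'
#' @param V0 Cell volume (L).
#' @param M0 Initial cell macromolecule concentration (mol/L).
#' @param X0 Syringe ligand concentration (mol/L).
#' @param injection_volumes Injection volumes (L); at least 5.
#' @param temperature Temperature (K).
#' @return A `titration_scheme` list.
#' @export
titration_scheme <- function(V0 = 2e-4, M0 = 5e-5, X0 = 2.5e-4,
                             injection_volumes = rep(2e-6, 18),
                             temperature = 298.15) {
  stopifnot(V0 > 0, M0 > 0, X0 > 0, temperature > 0,
            length(injection_volumes) >= 5, all(injection_volumes > 0))
  structure(list(V0 = V0, M0 = M0, X0 = X0,
                 injection_volumes = injection_volumes,
                 temperature = temperature),
            class = "titration_scheme")
}

#' One-site binding parameters
#'
#' @param n Stoichiometry (ligand sites per macromolecule); its reciprocal is
#'   the ligand's functional valency toward the lectin.
#' @param Ka Association constant (1/M).
#' @param dH Binding enthalpy change (cal/mol of ligand).
#' @return A `one_site_params` list.
#' @export
one_site_params <- function(n, Ka, dH) {
  stopifnot(n > 0, Ka > 0, is.finite(dH))
  structure(list(n = n, Ka = Ka, dH = dH), class = "one_site_params")
}

#' Gas constant in calories
#' @format Numeric, 1.987 cal / (mol K).
#' @export
R_CAL <- 1.987

# cell concentrations after cumulative injected volume v (displaced-volume
# perfusion correction), and total cumulative heat Q of the one-site model
.itc_state <- function(scheme, v) {
  V0 <- scheme$V0
  list(Mt = scheme$M0 * (1 - v / (2 * V0)) / (1 + v / (2 * V0)),
       Xt = scheme$X0 * (v / V0) / (1 + v / (2 * V0)))
}

.one_site_Q <- function(Xt, Mt, V0, n, Ka, dH) {
  A <- 1 + Xt / (n * Mt) + 1 / (n * Ka * Mt)
  disc <- pmax(A^2 - 4 * Xt / (n * Mt), 0)
  (n * Mt * dH * V0 / 2) * (A - sqrt(disc))
}

.injection_heats <- function(scheme, n, Ka, dH) {
  dv <- scheme$injection_volumes
  v <- cumsum(dv)
  st <- .itc_state(scheme, v)
  Q <- .one_site_Q(st$Xt, st$Mt, scheme$V0, n, Ka, dH)
  Qprev <- c(0, Q[-length(Q)])
  dQ <- Q + (dv / scheme$V0) * (Q + Qprev) / 2 - Qprev
  list(molar_ratio = st$Xt / st$Mt, heat = dQ, Q = Q)
}

#' Simulate a one-site binding isotherm
#'
#' Forward model of the one-site (Wiseman) isotherm with displaced-volume
#' dilution correction: the cumulative heat after injection i is
#' \deqn{Q_i = \frac{n M_t \Delta H V_0}{2}\left[A - \sqrt{A^2 - 4X_t/(nM_t)}\right],
#'   \quad A = 1 + \frac{X_t}{n M_t} + \frac{1}{n K_a M_t}}
#' and the observed per-injection heat is
#' \eqn{\Delta Q_i = Q_i + (dV_i/V_0)(Q_i + Q_{i-1})/2 - Q_{i-1}}. Every heat
#' has the sign of `dH` and heats approach zero after saturation.
#'
#' @param scheme A [titration_scheme()].
#' @param params A [one_site_params()].
#' @return Tibble (`isotherm`): `injection`, `volume` (L), `molar_ratio`
#'   (ligand/macromolecule in cell, strictly increasing) and `heat` (cal),
#'   with the scheme attached as attribute `scheme`.
#' @export
simulate_isotherm <- function(scheme, params) {
  stopifnot(inherits(scheme, "titration_scheme"),
            inherits(params, "one_site_params"))
  h <- .injection_heats(scheme, params$n, params$Ka, params$dH)
  out <- tibble::tibble(injection = seq_along(scheme$injection_volumes),
                        volume = scheme$injection_volumes,
                        molar_ratio = h$molar_ratio,
                        heat = h$heat)
  attr(out, "scheme") <- scheme
  class(out) <- c("isotherm", class(out))
  out
}

# robust starting values from the shape of a sigmoidal isotherm
.auto_init <- function(isotherm, scheme) {
  heat <- isotherm$heat
  ratio <- isotherm$molar_ratio
  dv <- scheme$injection_volumes
  dH0 <- heat[1] / (dv[1] * scheme$X0)
  cum <- cumsum(heat)
  half <- abs(cum) >= abs(cum[length(cum)]) / 2
  n0 <- ratio[which(half)[1]]
  n0 <- max(min(n0, 10), 1e-3)
  rss <- function(lKa) {
    pred <- .injection_heats(scheme, n0, exp(lKa), dH0)$heat
    sum((isotherm$heat - pred)^2)
  }
  lKa0 <- optimize(rss, c(log(1e2), log(1e10)))$minimum
  list(n = n0, Ka = exp(lKa0), dH = dH0)
}

#' Fit the one-site binding model to an isotherm
#'
#' Least-squares estimation of (n, Ka, dH) from per-injection heats by
#' Levenberg-Marquardt (via \pkg{minpack.lm}), with Ka fitted on the log
#' scale for positivity. Standard errors come from the local curvature of
#' the objective (the fit's variance-covariance matrix); the SE of Ka is
#' obtained from the SE of log Ka by the delta method.
#'
#' @param isotherm Tibble with columns `molar_ratio` and `heat` (cal), e.g.
#'   from [simulate_isotherm()] or [gen_isotherm()].
#' @param scheme The [titration_scheme()] that produced it.
#' @param init Optional [one_site_params()] starting values; by default they
#'   are derived from the curve shape (enthalpy from the first-injection heat
#'   per mole injected, stoichiometry from the molar ratio at half the total
#'   heat, Ka from a one-dimensional profile search).
#' @return A `one_site_fit`: list with `params` ([one_site_params()]), `se`
#'   (named SEs for n, Ka, dH), `valency` (`round(1/n)`), `converged`,
#'   `fitted`, `residuals`, `rss`.
#' @export
fit_one_site <- function(isotherm, scheme, init = NULL) {
  stopifnot(inherits(scheme, "titration_scheme"),
            all(c("heat") %in% names(isotherm)))
  heat <- isotherm$heat
  if (length(heat) < 5) stop("need at least 5 injections", call. = FALSE)
  if (max(abs(heat)) < 1e-12)
    stop("degenerate isotherm: all injection heats are ~0", call. = FALSE)
  if (is.null(init)) init <- .auto_init(isotherm, scheme)
  df <- data.frame(heat = heat)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      heat ~ .injection_heats(scheme, n, exp(lKa), dH)$heat,
      data = df,
      start = list(n = init$n, lKa = log(init$Ka), dH = init$dH),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)),
    error = function(e) e)
  if (inherits(fit, "error"))
    stop("one-site fit failed to converge: ", conditionMessage(fit),
         call. = FALSE)
  cf <- coef(fit)
  vc <- tryCatch(vcov(fit), error = function(e) matrix(NA, 3, 3))
  se_l <- sqrt(diag(vc))
  se <- c(n = unname(se_l[1]),
          Ka = unname(exp(cf[["lKa"]]) * se_l[2]),
          dH = unname(se_l[3]))
  params <- one_site_params(n = unname(cf[["n"]]),
                            Ka = unname(exp(cf[["lKa"]])),
                            dH = unname(cf[["dH"]]))
  structure(list(params = params, se = se,
                 valency = round(1 / params$n),
                 converged = fit$convInfo$isConv %||% TRUE,
                 fitted = unname(fitted(fit)),
                 residuals = unname(residuals(fit)),
                 rss = sum(residuals(fit)^2)),
            class = "one_site_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.one_site_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "One-site fit: n = %.4g (SE %.2g), Ka = %.4g 1/M (SE %.2g), dH = %.4g cal/mol (SE %.2g)\n",
    p$n, x$se[["n"]], p$Ka, x$se[["Ka"]], p$dH, x$se[["dH"]]))
  cat(sprintf("functional valency round(1/n) = %d; converged: %s\n",
              x$valency, x$converged))
  invisible(x)
}

#' Thermodynamic parameters from a one-site fit
#'
#' Applies dG = -RT ln(Ka) and dS = (dH - dG)/T with
#' R = 1.987 cal/(mol K), so that dG = dH - T dS holds identically. dG < 0
#' exactly when Ka > 1 (spontaneous association).
#'
#' @param params A [one_site_params()] (or a `one_site_fit`).
#' @param temperature Temperature (K).
#' @return List with `dG` (cal/mol), `dH` (cal/mol), `dS` (cal/mol/K), `Ka`,
#'   `n`, `temperature`, `R`.
#' @export
thermodynamics <- function(params, temperature = 298.15) {
  if (inherits(params, "one_site_fit")) params <- params$params
  stopifnot(inherits(params, "one_site_params"), temperature > 0)
  dG <- -R_CAL * temperature * log(params$Ka)
  dS <- (params$dH - dG) / temperature
  list(dG = dG, dH = params$dH, dS = dS, Ka = params$Ka, n = params$n,
       temperature = temperature, R = R_CAL)
}
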