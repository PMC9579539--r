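#' Closed-form 1:1 Langmuir sensorgram prediction
#'
#' Association: \eqn{R(t) = R_{eq} (1 - e^{-(k_a C + k_d) t})} with
#' \eqn{R_{eq} = R_{max} k_a C / (k_a C + k_d)}; dissociation:
#' \eqn{R(t) = R_0 e^{-k_d (t - t_{assoc})}} where \eqn{R_0} is the
#' response at the end of association.  Times are relative to the
#' injection (association start).
#'
#' @param ka,kd,rmax kinetic parameters (1/(M*s), 1/s, RU).
#' @param conc analyte concentration, M.
#' @param t time vector, s (non-negative; for the dissociation phase,
#'   measured from the injection, so `t >= t_assoc`).
#' @param phase `"assoc"` or `"dissoc"`.
#' @param t_assoc association duration, s (needed for dissociation).
#' @return response vector, RU.
#' @export
langmuir_predict <- function(ka, kd, rmax, conc, t,
                             phase = c("assoc", "dissoc"), t_assoc = 60) {
  phase <- match.arg(phase)
  if (any(t < 0))
    stop_ibcrep("negative time", "ibcrep_input_error")
  kobs <- ka * conc + kd
  req <- rmax * ka * conc / kobs
  if (phase == "assoc") {
    req * (1 - exp(-kobs * t))
  } else {
    r0 <- req * (1 - exp(-kobs * t_assoc))
    r0 * exp(-kd * (t - t_assoc))
  }
}

#' Preprocess a raw sensorgram set
#'
#' Per concentration trace: the pre-injection baseline (mean response of
#' the `baseline` phase) is subtracted, time is re-zeroed at the first
#' association sample, and samples within `spike_window` seconds after
#' either phase boundary (injection at t = 0 and dissociation start at
#' t = t_assoc) are dropped.
#'
#' @param raw a `sensorgram_set` (columns `time_s`, `ru`, `conc_M`,
#'   `phase`).
#' @param spike_window seconds discarded after each phase boundary
#'   (default 2).
#' @return a `sensorgram_set` containing only `assoc`/`dissoc` samples,
#'   baseline-subtracted and re-zeroed; per-concentration baselines are
#'   attached as attribute `baselines`.
#' @export
preprocess_sensorgram <- function(raw, spike_window = 2) {
  t_assoc <- attr(raw, "t_assoc")
  pieces <- lapply(split(seq_len(nrow(raw)), raw$conc_M), function(i) {
    tr <- raw[i, , drop = FALSE]
    base <- tr$ru[tr$phase == "baseline"]
    if (length(base) == 0)
      stop_ibcrep("no pre-injection samples for baseline estimation",
                  "ibcrep_input_error")
    t0 <- min(tr$time_s[tr$phase == "assoc"])
    tr$ru <- tr$ru - mean(base)
    tr$time_s <- tr$time_s - t0
    tr <- tr[tr$phase != "baseline", , drop = FALSE]
    if (is.null(t_assoc)) t_assoc <- min(tr$time_s[tr$phase == "dissoc"])
    drop <- (tr$time_s >= 0 & tr$time_s < spike_window) |
      (tr$time_s >= t_assoc & tr$time_s < t_assoc + spike_window)
    list(trace = tr[!drop, , drop = FALSE], baseline = mean(base))
  })
  out <- do.call(rbind, lapply(pieces, `[[`, "trace"))
  rownames(out) <- NULL
  attr(out, "t_assoc") <- t_assoc
  attr(out, "baselines") <- vapply(pieces, `[[`, numeric(1), "baseline")
  class(out) <- c("sensorgram_set", "data.frame")
  out
}

#' Fit the 1:1 Langmuir model to a sensorgram set
#'
#' Global nonlinear least squares: a single (ka, kd, Rmax) triple is
#' shared by all concentration traces (the default; per-curve fits are
#' available with `per_curve = TRUE`).  Parameters are optimized on the
#' log scale with `nlminb` from a grid of log-spaced ka/kd starts;
#' standard errors come from the Jacobian of the best fit (Gauss-Newton
#' approximation), and `KD = kd / ka` by definition.
#'
#' @param set a preprocessed `sensorgram_set` (time zeroed at injection).
#' @param t_assoc association duration, s (taken from the set's
#'   attribute when present).
#' @param per_curve fit each concentration separately instead of
#'   globally.
#' @param ka_starts,kd_starts multi-start grids (1/(M*s), 1/s).
#' @return list of class `kinetic_fit`: `ka`, `kd`, `kD`, `rmax`, `se`
#'   (named vector), `rms` (residual RMS, RU), `converged`,
#'   `n_concentrations`; with `per_curve`, also `curves` (per-curve
#'   fits).
#' @export
fit_langmuir <- function(set, t_assoc = NULL, per_curve = FALSE,
                         ka_starts = 10^c(3, 4.5, 6),
                         kd_starts = 10^c(-4, -2.5, -1)) {
  if (is.null(t_assoc)) t_assoc <- attr(set, "t_assoc")
  if (is.null(t_assoc))
    stop_ibcrep("t_assoc is required", "ibcrep_input_error")
  concs <- sort(unique(set$conc_M), decreasing = TRUE)
  if (length(concs) == 0)
    stop_ibcrep("no traces to fit", "ibcrep_input_error")
  if (per_curve) {
    curves <- lapply(concs, function(C) {
      fit_langmuir(set[set$conc_M == C, , drop = FALSE],
                   t_assoc = t_assoc, per_curve = FALSE,
                   ka_starts = ka_starts, kd_starts = kd_starts)
    })
    names(curves) <- signif(concs, 3)
    avg <- vapply(c("ka", "kd", "rmax"), function(p)
      mean(vapply(curves, `[[`, numeric(1), p)), numeric(1))
    out <- list(ka = avg[["ka"]], kd = avg[["kd"]],
                kD = avg[["kd"]] / avg[["ka"]], rmax = avg[["rmax"]],
                se = NULL, rms = NA_real_,
                converged = all(vapply(curves, `[[`, logical(1),
                                       "converged")),
                n_concentrations = length(concs), curves = curves)
    class(out) <- "kinetic_fit"
    return(out)
  }
  if (length(concs) == 1)
    warning("single concentration: reduced identifiability of ka and kd")

  predict_all <- function(theta) {
    ka <- exp(theta[1]); kd <- exp(theta[2]); rmax <- exp(theta[3])
    unlist(lapply(concs, function(C) {
      tr <- set[set$conc_M == C, ]
      ifelse(tr$phase == "assoc",
             langmuir_predict(ka, kd, rmax, C, tr$time_s, "assoc",
                              t_assoc),
             langmuir_predict(ka, kd, rmax, C, pmax(tr$time_s, t_assoc),
                              "dissoc", t_assoc))
    }))
  }
  obs <- unlist(lapply(concs, function(C) set$ru[set$conc_M == C]))
  objective <- function(theta) sum((obs - predict_all(theta))^2)
  rmax0 <- max(obs, 1)
  best <- NULL
  for (ka0 in ka_starts) for (kd0 in kd_starts) {
    fit <- tryCatch(
      nlminb(log(c(ka0, kd0, rmax0)), objective,
             control = list(iter.max = 500, eval.max = 1000)),
      error = function(e) NULL)
    if (!is.null(fit) &&
        (is.null(best) || fit$objective < best$objective)) best <- fit
  }
  if (is.null(best))
    stop_ibcrep("Langmuir fit failed to converge from all starts",
                "ibcrep_fit_error")
  theta <- best$par
  n <- length(obs)
  dof <- max(n - 3, 1)
  rms <- sqrt(best$objective / dof)
  # Gauss-Newton standard errors via a numerical Jacobian (log scale),
  # delta-method back to the natural scale
  eps <- 1e-6
  f0 <- predict_all(theta)
  jac <- vapply(1:3, function(p) {
    tp <- theta; tp[p] <- tp[p] + eps
    (predict_all(tp) - f0) / eps
  }, numeric(n))
  se_log <- tryCatch(sqrt(diag(solve(crossprod(jac))) * rms^2),
                     error = function(e) rep(NA_real_, 3))
  pars <- exp(theta)
  se <- setNames(se_log * pars, c("ka", "kd", "rmax"))
  structure(list(ka = pars[1], kd = pars[2], kD = pars[2] / pars[1],
                 rmax = pars[3], se = se, rms = rms,
                 converged = best$convergence == 0,
                 n_concentrations = length(concs)),
            class = "kinetic_fit")
}

#' Area under an ELISA titration curve
#'
#' Trapezoidal area of OD over log10(dilution); units OD x log10-dilution.
#'
#' @param curve data.frame with `dilution` (fold, strictly increasing)
#'   and `od450`, or the two vectors given separately.
#' @param od450 optional OD vector when `curve` is a dilution vector.
#' @return the AUC (a single number).
#' @export
elisa_auc <- function(curve, od450 = NULL) {
  if (is.data.frame(curve)) {
    dilution <- curve$dilution
    od <- curve$od450
  } else {
    dilution <- curve
    od <- od450
  }
  if (length(dilution) < 2)
    stop_ibcrep("at least 2 titration points are required",
                "ibcrep_input_error")
  if (any(diff(dilution) <= 0))
    stop_ibcrep("dilution vector must be strictly increasing",
                "ibcrep_input_error")
  x <- log10(dilution)
  sum(diff(x) * (head(od, -1) + od[-1]) / 2)
}

#' One-way ANOVA with Tukey's post-hoc comparisons
#'
#' Thin convenience wrapper around `stats::aov` / `stats::TukeyHSD` for
#' comparing, e.g., ELISA AUC values across antibody groups.
#'
#' @param values numeric response vector.
#' @param groups group factor (>= 2 groups, >= 2 observations each).
#' @return list: `f` (F statistic), `p` (ANOVA p-value), `tukey`
#'   (data.frame of pairwise comparisons with adjusted p-values).
#' @export
compare_groups <- function(values, groups) {
  groups <- factor(groups)
  sizes <- table(groups)
  if (length(sizes) < 2 || any(sizes < 2))
    stop_ibcrep("need >= 2 groups with >= 2 observations each",
                "ibcrep_input_error")
  fit <- aov(values ~ groups)
  s <- summary(fit)[[1]]
  tk <- as.data.frame(TukeyHSD(fit)$groups)
  tk$comparison <- rownames(tk)
  rownames(tk) <- NULL
  list(f = s[["F value"]][1], p = s[["Pr(>F)"]][1], tukey = tk)
}
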