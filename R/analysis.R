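#' Local sensitivity coefficient of the migration potential
#'
#' \eqn{S = (\Delta MP / MP) / (\Delta P / P)}: the relative change of the
#' migration potential divided by the relative change of the perturbed
#' parameter.
#'
#' @param mp_base migration potential at reference parameters (non-zero).
#' @param mp_pert migration potential with the parameter changed by
#'   `rel_delta`.
#' @param rel_delta relative parameter change (+0.10 / -0.10 by default
#'   protocol).
#' @return S (signed, dimensionless).
#' @export
sensitivity_coefficient <- function(mp_base, mp_pert, rel_delta) {
  if (mp_base == 0) stop("sensitivity undefined: baseline MP is zero")
  stopifnot(rel_delta != 0)
  ((mp_pert - mp_base) / mp_base) / rel_delta
}

#' Migration-potential readout for parameter scans
#'
#' Integrates a single cell's pathway from its reference initial condition
#' for `hours` (default 48 h) with the ligand free to deplete (no imposed
#' extracellular field, no drug) and returns d[PLC\eqn{\gamma}]/dt at the
#' readout time.
#'
#' @param spec a [pathway_spec()].
#' @param hours readout time.
#' @param rtol,atol integrator tolerances.
#' @return migration potential (concentration/h).
#' @export
mp_readout <- function(spec, hours = 48, rtol = 1e-8, atol = 1e-10) {
  tab <- compile_pathway(spec)
  out <- pathway_integrate_cpp(matrix(unname(spec$initial), nrow = 1), tab,
                               hours, rtol, atol, 1e7)
  if (out$status[1] != 0L) stop("readout integration failed")
  out$dy[1, match("PLCg", spec$species)]
}

# apply a multiplicative perturbation to a named target: an alias (X1, X2,
# X6, ...) scales that species' initial concentration, a rate-constant name
# scales the constant
perturb_spec <- function(spec, target, factor) {
  if (target %in% names(spec$aliases)) {
    sp <- spec$aliases[[target]]
    ini <- spec$initial
    ini[[sp]] <- ini[[sp]] * factor
    spec$initial <- ini
  } else if (target %in% names(spec$params)) {
    spec$params[[target]] <- spec$params[[target]] * factor
  } else stop("unknown scan target: ", target)
  spec
}

#' Local parameter sensitivity scan
#'
#' Perturbs each target by +/-10% (default), recomputes the
#' migration-potential readout, and reports the sensitivity coefficient S
#' and the percentage change of MP.  Deterministic given a spec.
#'
#' @param spec a [pathway_spec()].
#' @param targets character vector of initial-concentration aliases and/or
#'   rate-constant names.
#' @param deltas relative perturbations.
#' @param hours readout time passed to [mp_readout()].
#' @return data frame with columns `target`, `delta`, `mp_base`, `mp_pert`,
#'   `S`, `pct_mp_change`.
#' @export
sensitivity_scan <- function(spec = default_pathway(),
                             targets = c("X1", "X2", "X6", "k1", "k2", "k3",
                                         "k5", "K4", "V4"),
                             deltas = c(0.1, -0.1), hours = 48) {
  mp0 <- mp_readout(spec, hours)
  rows <- list()
  for (tg in targets) for (d in deltas) {
    mp1 <- mp_readout(perturb_spec(spec, tg, 1 + d), hours)
    rows[[length(rows) + 1L]] <- data.frame(
      target = tg, delta = d, mp_base = mp0, mp_pert = mp1,
      S = sensitivity_coefficient(mp0, mp1, d),
      pct_mp_change = 100 * (mp1 - mp0) / mp0)
  }
  do.call(rbind, rows)
}

#' Robustness index of a whole-model outcome
#'
#' \eqn{R = (ACN_p - ACN_0) / ACN_0} where \eqn{ACN_p} is the active cell
#' number with the varied parameter and \eqn{ACN_0} the stochastic baseline
#' mean.
#'
#' @param acn_p outcome with the perturbed parameter.
#' @param acn_0 baseline mean outcome (> 0).
#' @return R (signed, dimensionless; vectorized over `acn_p`).
#' @export
robustness_index <- function(acn_p, acn_0) {
  if (acn_0 <= 0) stop("robustness undefined: baseline ACN must be > 0")
  (acn_p - acn_0) / acn_0
}

#' Coefficient of variation of outcomes
#'
#' Sample standard deviation divided by the mean.
#'
#' @param values numeric vector, length >= 2, non-zero mean.
#' @return CV (fraction).
#' @export
cv_of_outcomes <- function(values) {
  if (length(values) < 2) stop("CV needs at least two values")
  m <- mean(values)
  if (m == 0) stop("CV undefined: mean is zero")
  sd(values) / m
}

# active cell number at a given hour of a run's census
acn_at <- function(metrics, hour) {
  row <- metrics[metrics$hour == hour, ]
  if (nrow(row) != 1) stop("no census row at hour ", hour)
  row$active
}

# build a config with one robustness target applied as a fold change
apply_fold <- function(config, target, fold) {
  ov <- switch(target,
    X1 = list(pathway_input = list(tgf_scale = fold)),
    X2 = list(pathway = list(initial = list(
          EGFR = unname(default_pathway()$initial[["EGFR"]]) * fold))),
    X6 = list(pathway = list(initial = list(
          PLCg = unname(default_pathway()$initial[["PLCg"]]) * fold))),
    {
      p0 <- default_pathway()$params
      if (!target %in% names(p0)) stop("unknown robustness target: ", target)
      ov <- list(pathway = list(params = setNames(
        list(unname(p0[[target]]) * fold), target)))
      ov
    })
  merge_config(unclass(config), ov) |>
    structure(class = "sim_config")
}

#' One-at-a-time robustness experiment on the full model
#'
#' Runs the agent-based model to `hours` for every (target, fold) pair, one
#' parameter varied at a time, and compares the active cell number (ACN) at
#' the final hour against a stochastic baseline mean over `n_baseline`
#' replicate runs at reference parameters.  The reference protocol uses 100
#' baseline replicates; reduce `n_baseline` (and note the sampling error)
#' when compute-constrained.
#'
#' @param config base configuration; `horizon` is overridden by `hours`.
#' @param targets parameters to vary (aliases X1/X2/X6 and rate names).
#' @param folds fold-change multipliers.
#' @param hours outcome readout hour (default 100).
#' @param n_baseline baseline replicate count.
#' @param baseline optional precomputed baseline ACN vector (skips the
#'   baseline runs).
#' @return list with `baseline` (vector of baseline ACNs), `acn0` (their
#'   mean), `report` (data frame: target, fold, acn, R) and `cv` (CV of the
#'   variational outcomes).
#' @export
run_robustness <- function(config = default_config(),
                           targets = c("X1", "X2", "X6", "k1", "k2", "k3",
                                       "k5", "K4", "V4"),
                           folds = c(0.1, 2, 5, 6, 7, 8, 9, 10),
                           hours = 100, n_baseline = 100, baseline = NULL) {
  cfg <- config; cfg$horizon <- hours
  base_seed <- cfg$seed
  if (is.null(baseline))
    baseline <- vapply(seq_len(n_baseline), function(k) {
      ck <- cfg; ck$seed <- base_seed + k
      acn_at(run_simulation(ck)$metrics, hours)
    }, numeric(1))
  acn0 <- mean(baseline)
  rows <- list()
  for (tg in targets) for (f in folds) {
    ck <- apply_fold(cfg, tg, f)
    ck$seed <- base_seed
    acn <- acn_at(run_simulation(ck)$metrics, hours)
    rows[[length(rows) + 1L]] <- data.frame(target = tg, fold = f,
                                            acn = acn,
                                            R = robustness_index(acn, acn0))
  }
  report <- do.call(rbind, rows)
  list(baseline = baseline, acn0 = acn0, report = report,
       cv = cv_of_outcomes(report$acn))
}

#' Cell survival percentage under treatment
#'
#' `100 * viable_treated / viable_reference`, where the reference is the
#' paired drug-free run with the same seed (treated/control convention).
#' Undefined (NA) wherever the reference is zero.
#'
#' @param viable_treated,viable_reference aligned viable-cell time series.
#' @return percentage series.
#' @export
survival_percentage <- function(viable_treated, viable_reference) {
  stopifnot(length(viable_treated) == length(viable_reference))
  ifelse(viable_reference == 0, NA_real_,
         100 * viable_treated / viable_reference)
}

#' Proliferation rate series
#'
#' Fold-increase of the viable population per `window`:
#' `(N(t) - N(t - window)) / N(t - window)`, so a population doubling over
#' the window reads 1.0.  NA for the first `window` hours.
#'
#' @param census a run's `metrics` data frame (uses the `live` column) or a
#'   numeric viable-count series at 1 h spacing.
#' @param window window length in hours (>= 1).
#' @return numeric series aligned with the input hours.
#' @export
proliferation_rate <- function(census, window = 24) {
  stopifnot(window >= 1)
  n <- if (is.data.frame(census)) census$live else as.numeric(census)
  w <- as.integer(window)
  out <- rep(NA_real_, length(n))
  if (length(n) > w) {
    idx <- (w + 1L):length(n)
    out[idx] <- (n[idx] - n[idx - w]) / n[idx - w]
  }
  out
}

#' Paired treated / drug-free runs
#'
#' Runs the model twice with identical seed and configuration except the
#' treatment switch, and derives the survival-percentage series.
#'
#' @param config base configuration (treatment flag is overridden).
#' @return list with `treated`, `reference` (run results) and `survival`
#'   (percentage series indexed by hour).
#' @export
run_paired_treatment <- function(config = default_config()) {
  cfg_on <- cfg_off <- config
  cfg_on$treatment_on <- TRUE
  cfg_off$treatment_on <- FALSE
  treated <- run_simulation(cfg_on)
  reference <- run_simulation(cfg_off)
  list(treated = treated, reference = reference,
       survival = survival_percentage(treated$metrics$live,
                                      reference$metrics$live))
}
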