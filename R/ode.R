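#' Kinetic parameters for the presynapse model
#'
#' Builds the parameter set for the eight-state kinetic model of the 5-HT
#' presynapse. Genotype-scaled steps (TPH2 synthesis, SERT reuptake, MAOA
#' degradation) follow Michaelis-Menten kinetics; AADC decarboxylation,
#' vesicular release and the two clearance paths are first order. Genotype
#' scaling acts on the Vmax values only (protein abundance), never on Km, and
#' 5-HIAA removal (`k_hiaa`) is shared by every individual in a run.
#'
#' Defaults (all overridable): a single dietary tryptophan pulse
#' `trp_ext0 = 100` uM taken up at `k_up = 0.1`/min; `vmax_tph2 = 0.25`
#' uM/min, `km_tph2 = 40` uM; `k_aadc = 0.5`/min; `vmax_vmat = 0.75` uM/min,
#' `km_vmat = 0.3` uM; `k_rel = 0.2`/min; `vmax_sert = 0.1` uM/min,
#' `km_sert = 0.2` uM; `k_eloss = 10`/min; `vmax_maoa = 0.4` uM/min,
#' `km_maoa = 1` uM; `k_hiaa = 0.001`/min; simulated for `t_end = 600` min
#' sampled every `dt_sample = 1` min.
#'
#' The exact constants of the published presynapse model are not available,
#' so these defaults are a phenomenological calibration chosen to reproduce
#' its qualitative regime rather than literature rate constants: (i) TPH2
#' stays rate-limiting over the whole window for every genotype (part of the
#' tryptophan load is unconverted at `t_end` even at the largest activity
#' coefficient), so synthesis - and with it every downstream pool - is
#' genotype-governed; (ii) 5-HIAA removal is slow relative to the window
#' (clearance timescale 1000 min), so 5-HIAA accumulates toward a late
#' peak, giving the left-skewed concentration profile of delayed
#' accumulation; (iii) cytosolic serotonin is partitioned between vesicular
#' packaging and MAOA degradation at comparable capacities, and extracellular
#' clearance of the synaptic-cleft pool is diffusion-dominated (`k_eloss`
#' large relative to SERT reuptake at this compartment scale), so the MAOA
#' activity coefficient controls the share of serotonin that ends up as
#' 5-HIAA, not merely its timing. See the package vignette for the full
#' rationale.
#'
#' @param ... Named overrides of any default listed above, plus:
#'   `input` (`"pulse"`, the default, or `"infusion"` for a constant
#'   tryptophan supply), `infusion_rate` (uM/min, used only for
#'   `input = "infusion"`), solver tolerances `rtol` (1e-8) and `atol`
#'   (1e-10 uM), and `neg_tol` (magnitude of negative solver noise clipped
#'   to zero, 1e-12 uM).
#' @return A named list of class `"kinetic_params"`.
#' @export
#' @examples
#' kinetic_defaults()
#' kinetic_defaults(t_end = 100, k_hiaa = 0.02)
kinetic_defaults <- function(...) {
  p <- list(
    trp_ext0 = 100, k_up = 0.1,
    vmax_tph2 = 0.25, km_tph2 = 40,
    k_aadc = 0.5,
    vmax_vmat = 0.75, km_vmat = 0.3,
    k_rel = 0.2,
    vmax_sert = 0.1, km_sert = 0.2,
    k_eloss = 10,
    vmax_maoa = 0.4, km_maoa = 1,
    k_hiaa = 0.001,
    t_end = 600, dt_sample = 1,
    rtol = 1e-8, atol = 1e-10, neg_tol = 1e-12,
    input = "pulse", infusion_rate = 1
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad) || is.null(names(ov)) || any(names(ov) == "")) {
      abort(paste0("unknown kinetic parameter(s): ",
                   paste(bad, collapse = ", ")))
    }
    p[names(ov)] <- ov
  }
  class(p) <- "kinetic_params"
  validate_kinetic_params(p)
  p
}

#' Validate kinetic parameters
#'
#' @param params A `"kinetic_params"` list (see [kinetic_defaults()]).
#' @return `params`, invisibly, if valid.
#' @export
validate_kinetic_params <- function(params) {
  pos <- c("k_up", "vmax_tph2", "km_tph2", "k_aadc", "vmax_vmat", "km_vmat",
           "k_rel", "vmax_sert", "km_sert", "vmax_maoa", "km_maoa", "k_hiaa",
           "t_end", "dt_sample", "rtol", "atol")
  for (nm in pos) {
    v <- params[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      abort(paste0("kinetic parameter ", nm, " must be a positive number"))
    }
  }
  for (nm in c("trp_ext0", "k_eloss", "infusion_rate", "neg_tol")) {
    v <- params[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      abort(paste0("kinetic parameter ", nm, " must be >= 0"))
    }
  }
  if (params$t_end / params$dt_sample < 10) {
    abort("t_end/dt_sample must be at least 10 (grid too coarse)")
  }
  if (!params$input %in% c("pulse", "infusion")) {
    abort("input must be 'pulse' or 'infusion'")
  }
  invisible(params)
}

check_coeffs <- function(c_tph2, c_sert, c_maoa) {
  for (v in list(c_tph2, c_sert, c_maoa)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      abort("activity coefficients must be positive finite numbers")
    }
  }
  invisible(NULL)
}

#' Instantaneous rates of change of the presynapse model
#'
#' Evaluates the right-hand side of the eight-state system at a given state.
#' States (all uM): `trp_ext` (extracellular dietary tryptophan), `trp_in`
#' (intracellular tryptophan), `htp` (5-HTP), `fc5ht` (free cytosolic 5-HT),
#' `v5ht` (vesicular 5-HT), `e5ht` (extracellular 5-HT), `hiaa` (5-HIAA) and
#' `cleared` (cumulative material removed through non-SERT clearance and
#' 5-HIAA removal; closes the mass balance).
#'
#' Fluxes: tryptophan uptake `k_up*trp_ext`; TPH2 synthesis
#' `c_tph2*vmax_tph2*trp_in/(km_tph2+trp_in)`; AADC `k_aadc*htp`; vesicular
#' packaging `vmax_vmat*fc5ht/(km_vmat+fc5ht)`; release `k_rel*v5ht`; SERT
#' reuptake `c_sert*vmax_sert*e5ht/(km_sert+e5ht)`; non-SERT loss
#' `k_eloss*e5ht`; MAOA degradation `c_maoa*vmax_maoa*fc5ht/(km_maoa+fc5ht)`;
#' 5-HIAA removal `k_hiaa*hiaa`. Under `input = "infusion"` a constant
#' `infusion_rate` feeds `trp_in` directly instead of the pulse.
#'
#' @param state Named numeric vector over the eight state variables.
#' @param t Time (min); the system is autonomous, `t` is accepted for solver
#'   compatibility.
#' @param params Kinetic parameters ([kinetic_defaults()]).
#' @param c_tph2,c_sert,c_maoa Positive activity coefficients.
#' @return Named numeric vector of rates (uM/min) in state order.
#' @export
#' @examples
#' s <- setNames(numeric(8), c("trp_ext", "trp_in", "htp", "fc5ht",
#'                             "v5ht", "e5ht", "hiaa", "cleared"))
#' s["trp_ext"] <- 100
#' presynapse_rates(s, params = kinetic_defaults())
presynapse_rates <- function(state, t = 0, params = kinetic_defaults(),
                             c_tph2 = 1, c_sert = 1, c_maoa = 1) {
  if (anyNA(state) || any(!is.finite(state))) {
    abort("non-finite state component")
  }
  check_coeffs(c_tph2, c_sert, c_maoa)
  s <- state[STATE_VARS]
  p <- params
  f_t <- c_tph2 * p$vmax_tph2 * s[["trp_in"]] / (p$km_tph2 + s[["trp_in"]])
  f_v <- p$vmax_vmat * s[["fc5ht"]] / (p$km_vmat + s[["fc5ht"]])
  f_s <- c_sert * p$vmax_sert * s[["e5ht"]] / (p$km_sert + s[["e5ht"]])
  f_m <- c_maoa * p$vmax_maoa * s[["fc5ht"]] / (p$km_maoa + s[["fc5ht"]])
  influx <- if (p$input == "infusion") p$infusion_rate else 0
  d <- c(
    trp_ext = -p$k_up * s[["trp_ext"]],
    trp_in  = p$k_up * s[["trp_ext"]] + influx - f_t,
    htp     = f_t - p$k_aadc * s[["htp"]],
    fc5ht   = p$k_aadc * s[["htp"]] + f_s - f_v - f_m,
    v5ht    = f_v - p$k_rel * s[["v5ht"]],
    e5ht    = p$k_rel * s[["v5ht"]] - f_s - p$k_eloss * s[["e5ht"]],
    hiaa    = f_m - p$k_hiaa * s[["hiaa"]],
    cleared = p$k_eloss * s[["e5ht"]] + p$k_hiaa * s[["hiaa"]]
  )
  d
}

#' Simulate one individual's presynaptic 5-HT dynamics
#'
#' Integrates the kinetic model for one activity-coefficient triple with
#' `deSolve::lsoda` (adaptive, stiff-capable) at the configured tolerances,
#' sampled on the uniform grid `0, dt_sample, ..., t_end`. Tiny negative
#' solver noise (magnitude at most `neg_tol`) is clipped to zero; the number
#' of clipped values is recorded in the `"n_clipped"` attribute. Larger
#' negative excursions are an error.
#'
#' @inheritParams presynapse_rates
#' @return A tibble of class `"presynapse_trajectory"`: `time_min` plus the
#'   eight state columns (uM). Attributes: `"coeffs"` (the triple),
#'   `"params"`, `"n_clipped"`.
#' @export
#' @examples
#' traj <- simulate_trajectory(params = kinetic_defaults(t_end = 60))
#' head(traj)
simulate_trajectory <- function(c_tph2 = 1, c_sert = 1, c_maoa = 1,
                                params = kinetic_defaults()) {
  validate_kinetic_params(params)
  check_coeffs(c_tph2, c_sert, c_maoa)
  y0 <- setNames(numeric(length(STATE_VARS)), STATE_VARS)
  if (params$input == "pulse") y0[["trp_ext"]] <- params$trp_ext0
  times <- seq(0, params$t_end, by = params$dt_sample)
  rhs <- function(t, y, parms) {
    list(unname(presynapse_rates(y, t, params, c_tph2, c_sert, c_maoa)))
  }
  sol <- deSolve::lsoda(y0, times, rhs, parms = NULL,
                        rtol = params$rtol, atol = params$atol)
  diagn <- attr(sol, "istate")
  if (!is.null(diagn) && diagn[1] < 0) {
    abort(paste0("ODE solver failed (istate = ", diagn[1], ")"))
  }
  m <- as.matrix(sol[, STATE_VARS, drop = FALSE])
  neg <- m < 0
  if (any(m < -params$neg_tol)) {
    abort(paste0("negative concentration beyond solver noise: min = ",
                 format(min(m)), " uM"))
  }
  n_clipped <- sum(neg)
  m[neg] <- 0
  out <- as_tibble(cbind(time_min = sol[, "time"], m))
  class(out) <- c("presynapse_trajectory", class(out))
  attr(out, "coeffs") <- c(c_tph2 = c_tph2, c_sert = c_sert, c_maoa = c_maoa)
  attr(out, "params") <- params
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Mass-balance audit of a simulated trajectory
#'
#' All reactions in the model are 1:1 molar transformations, so the sum of
#' the eight state variables (including the cumulative `cleared` pool) is
#' conserved under pulse input. Returns the maximum relative drift of the
#' total over the sampling grid, `max |total(t) - total(0)| / total(0)`.
#'
#' @param trajectory A `"presynapse_trajectory"` from [simulate_trajectory()]
#'   run with pulse input.
#' @return Dimensionless relative residual (a single number).
#' @export
#' @examples
#' traj <- simulate_trajectory(params = kinetic_defaults(t_end = 60))
#' mass_balance(traj)
mass_balance <- function(trajectory) {
  missing_cols <- setdiff(STATE_VARS, names(trajectory))
  if (length(missing_cols)) {
    abort(paste0("trajectory lacks full state column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  p <- attr(trajectory, "params")
  if (!is.null(p) && p$input == "infusion") {
    abort("mass_balance is defined for pulse input (closed system)")
  }
  total <- rowSums(trajectory[, STATE_VARS])
  if (total[1] == 0) {
    abort("total initial mass is zero; relative residual undefined")
  }
  max(abs(total - total[1])) / total[1]
}

#' Steady state of the constant-infusion model
#'
#' Analytic/root-finding solution of the flux-balance equations for the
#' constant-infusion variant (`input = "infusion"`, supply rate `R =
#' infusion_rate`). At steady state every concentration state is constant
#' (the cumulative `cleared` pool necessarily grows at rate `R` and is
#' returned as 0). Requires `R < c_tph2 * vmax_tph2`; with `k_eloss = 0`
#' additionally `R < c_maoa * vmax_maoa`, and then `hiaa = R / k_hiaa`
#' exactly. Used as an independent algebraic oracle for the ODE integration.
#'
#' @inheritParams presynapse_rates
#' @return Named numeric vector over the eight state variables (uM).
#' @export
#' @examples
#' p <- kinetic_defaults(input = "infusion", infusion_rate = 0.3)
#' steady_state(params = p)
steady_state <- function(c_tph2 = 1, c_sert = 1, c_maoa = 1,
                         params = kinetic_defaults(input = "infusion")) {
  validate_kinetic_params(params)
  check_coeffs(c_tph2, c_sert, c_maoa)
  if (params$input != "infusion") {
    abort("steady_state requires input = 'infusion' (the pulse model decays to zero)")
  }
  p <- params
  R <- p$infusion_rate
  out <- setNames(numeric(length(STATE_VARS)), STATE_VARS)
  if (R == 0) {
    class(out) <- NULL
    return(out)
  }
  vt <- c_tph2 * p$vmax_tph2
  if (R >= vt) {
    abort("no steady state: infusion rate exceeds maximal TPH2 capacity")
  }
  out[["trp_in"]] <- p$km_tph2 * R / (vt - R)
  out[["htp"]] <- R / p$k_aadc
  vm <- c_maoa * p$vmax_maoa
  f_v_of <- function(fc) p$vmax_vmat * fc / (p$km_vmat + fc)
  f_m_of <- function(fc) vm * fc / (p$km_maoa + fc)
  f_s_of <- function(e) c_sert * p$vmax_sert * e / (p$km_sert + e)
  if (p$k_eloss == 0) {
    # all throughput exits via MAOA: F_M = R
    if (R >= vm) {
      abort("no steady state: k_eloss = 0 and infusion exceeds MAOA capacity")
    }
    fc <- p$km_maoa * R / (vm - R)
    fv <- f_v_of(fc)
    vs <- c_sert * p$vmax_sert
    if (fv >= vs) {
      abort("no steady state: vesicular flux exceeds SERT capacity with k_eloss = 0")
    }
    e <- p$km_sert * fv / (vs - fv)
  } else {
    # e(fc) from the summed balance k_eloss*e = R - F_M(fc); the remaining
    # e-pool balance h(fc) = F_V - F_S - k_eloss*e is strictly increasing.
    fc_max <- if (R < vm) p$km_maoa * R / (vm - R) else Inf
    e_of <- function(fc) (R - f_m_of(fc)) / p$k_eloss
    h <- function(fc) {
      e <- e_of(fc)
      f_v_of(fc) - f_s_of(e) - p$k_eloss * e
    }
    upper <- if (is.finite(fc_max)) fc_max else {
      u <- 1
      while (h(u) < 0) u <- u * 2
      u
    }
    root <- stats::uniroot(h, lower = 0, upper = upper, tol = 1e-14)
    fc <- root$root
    e <- e_of(fc)
  }
  out[["fc5ht"]] <- fc
  out[["v5ht"]] <- f_v_of(fc) / p$k_rel
  out[["e5ht"]] <- e
  out[["hiaa"]] <- f_m_of(fc) / p$k_hiaa
  rates <- presynapse_rates(out, 0, p, c_tph2, c_sert, c_maoa)
  if (max(abs(rates[setdiff(STATE_VARS, "cleared")])) > 1e-9) {
    abort("steady-state residual exceeds 1e-9 uM/min")
  }
  out
}

#' Convert a trajectory to tidy long format
#'
#' @param trajectory A `"presynapse_trajectory"` tibble.
#' @param sample_id Optional sample identifier column to add.
#' @param species Which species to keep (default: the five reported ones).
#' @return Tibble with columns `sample_id` (if given), `time_min`, `species`,
#'   `concentration_uM`.
#' @export
tidy_trajectory <- function(trajectory, sample_id = NULL, species = SPECIES) {
  out <- tidyr::pivot_longer(
    as_tibble(trajectory)[, c("time_min", intersect(species, names(trajectory)))],
    -"time_min", names_to = "species", values_to = "concentration_uM")
  out$species <- factor(out$species, levels = species)
  out <- out[order(out$species, out$time_min), ]
  if (!is.null(sample_id)) out <- dplyr::bind_cols(
    tibble(sample_id = sample_id), out)
  out
}
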