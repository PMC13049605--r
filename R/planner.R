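#' Optimization objective specification
#'
#' Composite objective: a quadratic target term driving the worst-scenario
#' target dose to the prescription, plus mean-dose penalties for organs of
#' interest evaluated on the nominal scenario.
#'
#' @param target_mask logical array (planning target, ITV).
#' @param prescription prescription dose in Gy(RBE).
#' @param ooi_masks named list of logical arrays used as mean-dose terms.
#' @param target_weight,ooi_weight relative term weights (defaults 10 / 1;
#'   clinical priorities put coverage first).
#' @return An `objective_spec`.
#' @export
objective_spec <- function(target_mask, prescription, ooi_masks = list(),
                           target_weight = 10, ooi_weight = 1) {
  if (prescription <= 0) stop("prescription must be positive")
  if (target_weight < 0 || any(ooi_weight < 0)) stop("weights must be >= 0")
  ow <- if (length(ooi_weight) == 1) {
    rep(ooi_weight, length(ooi_masks))
  } else ooi_weight
  structure(list(target_mask = target_mask, prescription = prescription,
                 ooi_masks = ooi_masks, target_weight = target_weight,
                 ooi_weights = ow), class = "objective_spec")
}

# Subsample a voxel index set deterministically (fixed stride) to bound the
# optimizer's linear algebra; final evaluation always uses the full masks.
subsample_idx <- function(idx, cap) {
  n <- length(idx)
  if (n <= cap) return(idx)
  idx[round(seq(1, n, length.out = cap))]
}

# Influence of all beams on a voxel subset for each scenario in a set.
scenario_influences <- function(plan, anatomy, scenario_list, voxel_idx) {
  cache <- new.env(parent = emptyenv())
  lapply(scenario_list, function(s) {
    dose_influence_matrix(plan, anatomy, s, voxel_idx = voxel_idx,
                          sparse = FALSE, wepl_cache = cache)
  })
}

d98_from_doses <- function(d) {
  k <- max(1L, ceiling(length(d) * 0.98))
  sort(d, decreasing = TRUE)[k]
}

# Shared projected-gradient driver with Armijo backtracking.  fg(w) must
# return list(value, grad, worst); the composite objective is continuous
# (a max over convex per-scenario penalties), so backtracking always finds
# a non-increasing step away from a stationary point.  The trace is the
# composite objective and is non-increasing by construction.
projected_gradient <- function(w0, fg, max_iter = 500, tol = 1e-6) {
  w <- w0
  cur <- fg(w)
  trace <- cur$value
  worst <- cur$worst
  gmax <- max(abs(cur$grad))
  if (!is.finite(cur$value) || gmax == 0) {
    return(list(weights = w, objective_trace = trace, worst_trace = worst,
                iterations = 0L))
  }
  step <- 1 / gmax
  stall <- 0L
  w_prev <- NULL
  g_prev <- NULL
  for (it in seq_len(max_iter)) {
    # Barzilai-Borwein initial step, safeguarded by the backtracking below
    if (!is.null(w_prev)) {
      dw <- w - w_prev
      dg <- cur$grad - g_prev
      bb <- sum(dw * dg) / max(sum(dg * dg), 1e-300)
      if (is.finite(bb) && bb > 0) step <- min(max(bb, step / 16), step * 16)
    }
    accepted <- FALSE
    nxt <- cur
    for (bt in 1:50) {
      w_new <- pmax(0, w - step * cur$grad)
      nxt <- fg(w_new)
      dec <- sum(cur$grad * (w - w_new)) - (0.5 / step) * sum((w - w_new)^2)
      if (is.finite(nxt$value) &&
          nxt$value <= cur$value - 1e-4 * max(dec, 0)) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) break
    rel <- (cur$value - nxt$value) / max(cur$value, 1e-300)
    w_prev <- w
    g_prev <- cur$grad
    w <- w_new
    cur <- nxt
    trace <- c(trace, cur$value)
    worst <- c(worst, cur$worst)
    step <- step * 2
    # require a few consecutive near-flat iterations before declaring
    # convergence: the active worst scenario can change between iterates
    stall <- if (rel < tol) stall + 1L else 0L
    if (stall >= 3L) break
  }
  list(weights = w, objective_trace = trace, worst_trace = worst,
       iterations = length(trace) - 1L)
}

# Per-scenario target penalty: one-sided quadratic under the prescription
# (coverage) plus a milder one-sided quadratic above 105 % of it (hot
# spots), normalized by the prescription.  Convex in the weights.
target_penalty <- function(d, rx, over_weight = 0.25, hot_frac = 1.05) {
  under <- pmin(d - rx, 0)
  over <- pmax(d - hot_frac * rx, 0)
  list(value = (mean(under^2) + over_weight * mean(over^2)) / rx^2,
       resid = (2 * under + 2 * over_weight * over) / rx^2)
}

#' Minimax robust spot-weight optimization
#'
#' Minimizes a composite objective in which the target term is evaluated on
#' the worst scenario — the one with the lowest coverage of the
#' prescription, i.e. the largest one-sided under-dose penalty (plus a mild
#' hot-spot penalty), re-selected every iteration with ties broken by
#' scenario order — while organ-of-interest mean-dose penalties are
#' evaluated on the nominal scenario.  The per-scenario penalties are
#' convex, so the worst-case composite is a continuous convex function
#' solved by projected (sub)gradient descent with Armijo backtracking under
#' non-negativity.
#'
#' @param plan_template a [proton_plan()] (weights are overwritten).
#' @param anatomy planning anatomy.
#' @param objective an [objective_spec()].
#' @param scenario_set an optimization [scenario_set] (21 scenarios; a set
#'   collapsed to the nominal scenario yields standard non-robust
#'   optimization).
#' @param opts list: `max_iter` (500), `tol` (1e-6), `target_cap` /
#'   `ooi_cap` voxel subsampling caps for the optimizer's internal linear
#'   algebra (2000 / 600 per organ).
#' @return list with `plan` (weights filled in), `weights`,
#'   `objective_trace` (non-increasing), `worst_scenario_index`,
#'   `worst_trace`, `iterations`.
#' @export
robust_optimize <- function(plan_template, anatomy, objective, scenario_set,
                            opts = list()) {
  if (!identical(scenario_set$kind, "optimization")) {
    stop("scenario_set must be of optimization kind")
  }
  o <- modifyList(list(max_iter = 500, tol = 1e-6, target_cap = 2000,
                       ooi_cap = 600, minimax_p = 12, over_weight = 0.1,
                       hot_frac = 1.1, ooi_scale = 0.002), opts)
  t_idx <- which(objective$target_mask)
  if (!length(t_idx)) stop("empty target mask")
  t_sub <- subsample_idx(t_idx, o$target_cap)
  A <- scenario_influences(plan_template, anatomy, scenario_set$scenarios,
                           t_sub)
  if (max(vapply(A, max, 1)) <= 0) {
    stop("plan template has zero influence on the target")
  }
  ns_scen <- length(A)
  Abig <- do.call(rbind, A)    # scenario blocks stacked row-wise
  rm(A)
  rx <- objective$prescription
  nt <- length(t_sub)
  # nominal-scenario mean-dose row vectors for the OOI terms
  nominal <- scenario_spec()
  cache <- new.env(parent = emptyenv())
  m_ooi <- list()
  for (nm in names(objective$ooi_masks)) {
    oi <- which(objective$ooi_masks[[nm]])
    if (!length(oi)) next
    oi <- subsample_idx(oi, o$ooi_cap)
    Ao <- dose_influence_matrix(plan_template, anatomy, nominal,
                                voxel_idx = oi, sparse = FALSE,
                                wepl_cache = cache)
    m_ooi[[nm]] <- colMeans(Ao)
  }
  ow <- objective$ooi_weights
  tw <- objective$target_weight
  p <- o$minimax_p
  fg <- function(w) {
    Dm <- matrix(as.numeric(Abig %*% w), nrow = nt)   # voxels x scenarios
    under <- pmin(Dm - rx, 0)
    over <- pmax(Dm - o$hot_frac * rx, 0)
    vals <- (colSums(under^2) + o$over_weight * colSums(over^2)) /
      (nt * rx^2)
    worst <- which.max(vals)
    # smooth worst-case aggregation: a p-norm over the per-scenario convex
    # penalties upper-bounds the max and tends to it as p grows, keeping
    # the composite differentiable for the line search
    vm <- max(vals)
    if (vm > 0) {
      sp <- sum((vals / vm)^p)
      val <- tw * vm * sp^(1 / p)
      coefs <- (vals / vm)^(p - 1) * sp^(1 / p - 1)
    } else {
      val <- 0
      coefs <- numeric(length(vals))
    }
    resid <- (2 * under + 2 * o$over_weight * over) / (nt * rx^2)
    resid <- resid * rep(tw * coefs, each = nt)
    grad <- as.numeric(crossprod(Abig, as.numeric(resid)))
    for (i in seq_along(m_ooi)) {
      # ooi_scale normalizes a unit OOI weight to a soft preference that
      # shapes dose without competing with target coverage
      mo <- m_ooi[[i]]
      md <- sum(mo * w)
      val <- val + o$ooi_scale * ow[i] * (md / rx)^2
      grad <- grad + (2 * o$ooi_scale * ow[i] * md / rx^2) * mo
    }
    list(value = val, grad = grad, worst = worst)
  }
  # start from a uniform weight delivering the prescription on average
  ns <- ncol(Abig)
  mean_unit <- mean(as.numeric(Abig[seq_len(nt), ] %*% rep(1, ns)))
  w0 <- rep(rx / max(mean_unit, 1e-12), ns)
  sol <- projected_gradient(w0, fg, o$max_iter, o$tol)
  final <- fg(sol$weights)
  list(plan = set_plan_weights(plan_template, sol$weights),
       weights = sol$weights, objective_trace = sol$objective_trace,
       worst_scenario_index = final$worst, worst_trace = sol$worst_trace,
       iterations = sol$iterations)
}

#' Voxel-based dose-mimicking re-optimization at reduced setup uncertainty
#'
#' Regenerates a plan at a smaller setup uncertainty from a reference plan
#' by minimizing (i) a one-sided quadratic penalty for organ-of-interest
#' voxel doses exceeding the reference (nominal-scenario) dose, plus (ii) a
#' one-sided quadratic penalty for worst-scenario target voxel doses below
#' the prescription, preserving the reference plan's organ sparing while
#' enforcing coverage under the reduced scenarios.
#'
#' @param reference_dose nominal-scenario [dose_grid()] of the reference
#'   plan on the same anatomy.
#' @param plan_template template (typically from [make_plan_template()] at
#'   the reduced setup uncertainty).
#' @param anatomy planning anatomy.
#' @param reduced_scenarios optimization [scenario_set] at the reduced setup
#'   uncertainty; must be strictly smaller than `reference_su_mm`.
#' @param objective an [objective_spec()] (OOI weights of zero degenerate to
#'   coverage-only optimization).
#' @param reference_su_mm setup uncertainty of the reference plan (mm).
#' @param opts as in [robust_optimize()].
#' @return As [robust_optimize()].
#' @export
dose_mimic <- function(reference_dose, plan_template, anatomy,
                       reduced_scenarios, objective, reference_su_mm,
                       opts = list()) {
  if (reduced_scenarios$setup_uncertainty_mm >= reference_su_mm) {
    stop("reduced setup uncertainty must be smaller than the reference")
  }
  o <- modifyList(list(max_iter = 500, tol = 1e-6, target_cap = 2000,
                       ooi_cap = 600, minimax_p = 12, over_weight = 0.1,
                       hot_frac = 1.1), opts)
  t_idx <- which(objective$target_mask)
  if (!length(t_idx)) stop("empty target mask")
  t_sub <- subsample_idx(t_idx, o$target_cap)
  A <- scenario_influences(plan_template, anatomy,
                           reduced_scenarios$scenarios, t_sub)
  Abig <- do.call(rbind, A)
  rm(A)
  rx <- objective$prescription
  nt <- length(t_sub)
  nominal <- scenario_spec()
  cache <- new.env(parent = emptyenv())
  ooi_terms <- list()
  for (i in seq_along(objective$ooi_masks)) {
    if (objective$ooi_weights[i] == 0) next
    oi <- which(objective$ooi_masks[[i]])
    if (!length(oi)) next
    oi <- subsample_idx(oi, o$ooi_cap)
    Ao <- dose_influence_matrix(plan_template, anatomy, nominal,
                                voxel_idx = oi, sparse = FALSE,
                                wepl_cache = cache)
    ooi_terms[[length(ooi_terms) + 1L]] <-
      list(A = Ao, ref = reference_dose$data[oi],
           w = objective$ooi_weights[i], n = length(oi))
  }
  tw <- objective$target_weight
  p <- o$minimax_p
  fg <- function(w) {
    Dm <- matrix(as.numeric(Abig %*% w), nrow = nt)
    under <- pmin(Dm - rx, 0)
    # mild hot-spot control keeps the coverage-driven rescale bounded so
    # the mimicked plan reproduces, not exceeds, the reference dose level
    over <- pmax(Dm - o$hot_frac * rx, 0)
    vals <- (colSums(under^2) + o$over_weight * colSums(over^2)) /
      (nt * rx^2)
    worst <- which.max(vals)
    vm <- max(vals)
    if (vm > 0) {
      sp <- sum((vals / vm)^p)
      val <- tw * vm * sp^(1 / p)
      coefs <- (vals / vm)^(p - 1) * sp^(1 / p - 1)
    } else {
      val <- 0
      coefs <- numeric(length(vals))
    }
    resid <- (2 * under + 2 * o$over_weight * over) *
      rep(tw * coefs / (nt * rx^2), each = nt)
    grad <- as.numeric(crossprod(Abig, as.numeric(resid)))
    for (tm in ooi_terms) {
      over <- pmax(as.numeric(tm$A %*% w) - tm$ref, 0)
      val <- val + tm$w * mean(over^2) / rx^2
      grad <- grad + (2 * tm$w / (tm$n * rx^2)) *
        as.numeric(crossprod(tm$A, over))
    }
    list(value = val, grad = grad, worst = worst)
  }
  ns <- ncol(Abig)
  mean_unit <- mean(as.numeric(Abig[seq_len(nt), ] %*% rep(1, ns)))
  w0 <- rep(rx / max(mean_unit, 1e-12), ns)
  sol <- projected_gradient(w0, fg, o$max_iter, o$tol)
  final <- fg(sol$weights)
  list(plan = set_plan_weights(plan_template, sol$weights),
       weights = sol$weights, objective_trace = sol$objective_trace,
       worst_scenario_index = final$worst, worst_trace = sol$worst_trace,
       iterations = sol$iterations)
}
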