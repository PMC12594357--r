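#' Biological and transport parameters
#'
#' Parameter set for the microbial mineralization model on the pore graph.
#' Rates are per day; the time step `dt` is supplied in seconds and converted
#' internally (1 day = 86400 s). The diffusion coefficient `dc` is in voxel^2
#' per day (see [dc_voxel_day()] to convert a physical value). Masses are
#' micrograms of carbon, volumes voxel^3, so concentrations are ugC/voxel^3.
#'
#' Defaults are the Arthrobacter sp. 9R parameter set commonly used for soil
#' DOM degradation: maximum growth rate 9.6/d, half-saturation constant
#' 0.001, respiration rate 0.2/d, mortality rate 0.5/d, fraction of dead
#' biomass returned to DOM 0.55, SOM mineralization rate 0.001/d; FOM
#' hydrolysis is off by default (scenarios here track DOM and SOM only).
#'
#' @param rho respiration rate, 1/day.
#' @param mu mortality rate, 1/day.
#' @param v_dom maximum growth rate on DOM, 1/day.
#' @param k_dom half-saturation constant of DOM, ugC/voxel^3.
#' @param beta fraction of dead biomass returning to DOM (rest goes to SOM).
#' @param v_som SOM mineralization (hydrolysis) rate, 1/day.
#' @param v_fom FOM hydrolysis rate, 1/day.
#' @param dc DOM diffusion coefficient, voxel^2/day.
#' @param alpha diffusive overall conductance, dimensionless in (0, 1].
#' @param dt time step, seconds.
#' @return object of class `bio_params`.
#' @export
bio_params <- function(rho = 0.2, mu = 0.5, v_dom = 9.6, k_dom = 0.001,
                       beta = 0.55, v_som = 0.001, v_fom = 0,
                       dc = 1e5, alpha = 0.35, dt = 30) {
  p <- list(rho = rho, mu = mu, v_dom = v_dom, k_dom = k_dom, beta = beta,
            v_som = v_som, v_fom = v_fom, dc = dc, alpha = alpha, dt = dt)
  rates <- c(rho, mu, v_dom, v_som, v_fom)
  if (any(rates < 0)) stop_config("rates must be nonnegative")
  if (k_dom <= 0) stop_config("k_dom must be positive")
  if (beta < 0 || beta > 1) stop_config("beta must lie in [0, 1]")
  if (dc < 0) stop_config("dc must be nonnegative")
  if (alpha <= 0 || alpha > 1) stop_config("alpha must lie in (0, 1]")
  if (dt <= 0) stop_config("dt must be positive")
  structure(p, class = "bio_params")
}

#' Convert a physical diffusion coefficient to voxel^2/day
#'
#' @param dc_cm2_s diffusion coefficient in cm^2/s (DOM in water is about
#'   6.73e-6 cm^2/s).
#' @param resolution_um voxel edge length in micrometres.
#' @return coefficient in voxel^2/day.
#' @export
dc_voxel_day <- function(dc_cm2_s, resolution_um) {
  dc_cm2_s * 1e8 / resolution_um^2 * 86400
}

#' Per-node biological state
#'
#' Carbon masses per graph node: microbial biomass (MB), dissolved organic
#' matter (DOM), soil organic matter (SOM), fresh organic matter (FOM) and
#' CO2, all in ugC, plus the node volumes (voxel^3) used to derive the DOM
#' concentration `DOM / volume`.
#'
#' @param graph a [pore_graph()] (node volumes are taken from it), or `NULL`
#'   if `volumes` is given.
#' @param mb,dom,som,fom,co2 initial masses per node (recycled).
#' @param volumes node volumes, overriding the graph's.
#' @return object of class `bio_state`: list with matrix `b` (columns MB,
#'   DOM, SOM, FOM, CO2) and vector `v`.
#' @export
bio_state <- function(graph = NULL, mb = 0, dom = 0, som = 0, fom = 0, co2 = 0,
                      volumes = NULL) {
  v <- if (!is.null(volumes)) as.numeric(volumes) else {
    if (is.null(graph)) stop_config("either graph or volumes is required")
    as.numeric(graph$nodes$volume)
  }
  if (any(v <= 0)) stop_config("node volumes must be positive")
  n <- length(v)
  b <- cbind(MB = rep_len(mb, n), DOM = rep_len(dom, n), SOM = rep_len(som, n),
             FOM = rep_len(fom, n), CO2 = rep_len(co2, n))
  if (any(b < 0)) stop_config("masses must be nonnegative")
  structure(list(b = b, v = v), class = "bio_state")
}

#' @export
print.bio_state <- function(x, ...) {
  cat(sprintf("bio_state: %d nodes; totals MB %.4g, DOM %.4g, SOM %.4g, FOM %.4g, CO2 %.4g ugC\n",
              length(x$v), sum(x$b[, 1]), sum(x$b[, 2]), sum(x$b[, 3]),
              sum(x$b[, 4]), sum(x$b[, 5])))
  invisible(x)
}

#' One transformation (reaction) step of the microbial decomposition model
#'
#' Forward-Euler update applied independently at every node: Monod growth
#' `v_dom * c/(k_dom + c) * MB * dt` moves mass from DOM to MB; mortality
#' `mu * MB * dt` splits into DOM (fraction `beta`) and SOM (`1 - beta`);
#' respiration `rho * MB * dt` moves MB to CO2; hydrolysis `v_som * SOM * dt`
#' and `v_fom * FOM * dt` feed DOM. The DOM concentration is evaluated at the
#' start of the step. Total carbon is conserved exactly (terms cancel
#' pairwise). If the step would drive any pool negative the function stops
#' and names the offending node and the admissible time-step bound rather
#' than clamping (clamping would destroy conservation).
#'
#' @param state a [bio_state()].
#' @param params a [bio_params()].
#' @return the updated `bio_state`.
#' @export
transform_step <- function(state, params) {
  dt <- params$dt / 86400
  if ((params$rho + params$mu) * dt >= 1)
    stop_numeric("time step too large for the reaction terms: need dt < ",
                 format(86400 / (params$rho + params$mu)), " s")
  b <- state$b
  c_dom <- b[, 2] / state$v
  growth <- params$v_dom * c_dom / (params$k_dom + c_dom) * b[, 1] * dt
  growth[b[, 1] == 0] <- 0
  mort <- params$mu * b[, 1] * dt
  resp <- params$rho * b[, 1] * dt
  hyd_som <- params$v_som * b[, 3] * dt
  hyd_fom <- params$v_fom * b[, 4] * dt

  b2 <- b
  b2[, 1] <- b[, 1] - resp - mort + growth
  b2[, 2] <- b[, 2] + params$beta * mort - growth + hyd_som + hyd_fom
  b2[, 3] <- b[, 3] + (1 - params$beta) * mort - hyd_som
  b2[, 4] <- b[, 4] - hyd_fom
  b2[, 5] <- b[, 5] + resp

  if (any(b2 < 0)) {
    bad <- which(rowSums(b2 < 0) > 0)[1]
    # the binding constraint is DOM depletion by growth (the rate guard
    # already bounds the MB terms); report a sufficient bound
    stop_numeric("transformation step drove a pool negative at node ", bad,
                 "; reduce dt (currently ", params$dt, " s)")
  }
  state$b <- b2
  state
}

#' Per-arc exchange volume for one diffusion step
#'
#' `Theta = alpha * Dc * s / d * dt`: the equivalent volume exchanged between
#' two adjacent pores in one time step, from Fick's law across a contact
#' surface of `s` faces at centre distance `d`, scaled by the diffusive
#' overall conductance `alpha`. Used identically by the implicit and explicit
#' schemes (the calibration of `alpha` applies to both).
#'
#' @param s contact surface, voxel faces (area in voxel^2).
#' @param d centre-to-centre distance, voxels (> 0).
#' @param params a [bio_params()] (`dc` voxel^2/day, `dt` seconds).
#' @return exchange volume(s), voxel^3.
#' @export
theta <- function(s, d, params) {
  if (any(d <= 0)) stop_config("nonpositive arc distance")
  params$alpha * params$dc * s * (params$dt / 86400) / d
}

arc_thetas <- function(graph, params) {
  if (nrow(graph$arcs) == 0L) return(numeric(0))
  theta(graph$arcs$faces, graph$arcs$distance, params)
}

# sparse symmetric Theta matrix and its row sums
diffusion_operator <- function(graph, params) {
  n <- nrow(graph$nodes)
  th <- arc_thetas(graph, params)
  W <- Matrix::sparseMatrix(i = c(graph$arcs$r, graph$arcs$s),
                            j = c(graph$arcs$s, graph$arcs$r),
                            x = c(th, th), dims = c(n, n))
  list(W = W, rs = Matrix::rowSums(W), n = n)
}

# Jacobi-preconditioned conjugate gradient for SPD sparse systems
cg_solve <- function(A, b, x0 = NULL, tol = 1e-12, maxit = NULL) {
  n <- length(b)
  if (is.null(maxit)) maxit <- 10L * n
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) return(list(x = rep(0, n), iter = 0L, relres = 0))
  x <- if (is.null(x0)) rep(0, n) else x0
  Dinv <- 1 / Matrix::diag(A)
  r <- b - as.numeric(A %*% x)
  z <- Dinv * r
  p <- z
  rz <- sum(r * z)
  for (it in seq_len(maxit)) {
    relres <- sqrt(sum(r^2)) / bnorm
    if (relres <= tol) return(list(x = x, iter = it - 1L, relres = relres))
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    z <- Dinv * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  relres <- sqrt(sum(r^2)) / bnorm
  if (relres > tol)
    stop_numeric("conjugate gradient did not converge: relative residual ",
                 format(relres), " after ", maxit, " iterations")
  list(x = x, iter = maxit, relres = relres)
}

#' Implicit (backward Euler) DOM diffusion step on the graph
#'
#' Solves the symmetric positive-definite system
#' `(v_i + sum_j Theta_ij) c_i' - sum_j Theta_ij c_j' = v_i c_i`
#' for the new DOM concentrations with a Jacobi-preconditioned conjugate
#' gradient, then sets `DOM_i = v_i c_i'`. Unconditionally stable; conserves
#' total DOM up to the solver tolerance and obeys the maximum principle
#' (output concentrations stay within the input range).
#'
#' @param state a [bio_state()].
#' @param graph a [pore_graph()].
#' @param params a [bio_params()].
#' @param tol conjugate-gradient relative residual tolerance.
#' @param maxit maximum iterations (default `10 * nodes`).
#' @param op optional precomputed operator (internal, for [simulate_mineralization()]).
#' @return the updated `bio_state`.
#' @export
diffusion_step_implicit <- function(state, graph, params, tol = 1e-12,
                                    maxit = NULL, op = NULL) {
  if (is.null(op)) op <- diffusion_operator(graph, params)
  if (op$n == 0L) return(state)
  v <- state$v
  c0 <- state$b[, 2] / v
  A <- Matrix::Diagonal(op$n, v + op$rs) - op$W
  sol <- cg_solve(A, v * c0, x0 = c0, tol = tol, maxit = maxit)
  state$b[, 2] <- v * sol$x
  state
}

#' Explicit (forward Euler) DOM diffusion step on the graph
#'
#' `c_i' = (1 - sum_j Theta_ij / v_i) c_i + sum_j Theta_ij c_j / v_i`.
#' Requires the stability condition `sum_j Theta_ij <= v_i` at every node;
#' otherwise the step would produce negative concentrations and the function
#' stops, naming the largest admissible time step. Conserves total DOM to
#' machine precision.
#'
#' @inheritParams diffusion_step_implicit
#' @return the updated `bio_state`.
#' @export
diffusion_step_explicit <- function(state, graph, params, op = NULL) {
  if (is.null(op)) op <- diffusion_operator(graph, params)
  if (op$n == 0L) return(state)
  v <- state$v
  ratio <- max(op$rs / v)
  if (ratio > 1)
    stop_numeric("explicit diffusion unstable: sum(Theta)/v = ", format(ratio),
                 " > 1; need dt <= ", format(params$dt / ratio), " s")
  c0 <- state$b[, 2] / v
  c1 <- c0 + (as.numeric(op$W %*% c0) - op$rs * c0) / v
  state$b[, 2] <- v * c1
  state
}

#' Simulate microbial mineralization on the pore graph
#'
#' Operator-splitting time integration: each time step applies the
#' transformation (reaction) update [transform_step()] followed by one DOM
#' diffusion step (implicit by default; the explicit scheme serves to
#' validate the time step). Only DOM diffuses. Total carbon is conserved
#' through any schedule of steps (to machine precision for the explicit
#' scheme, to the solver tolerance for the implicit one).
#'
#' @param graph a [pore_graph()].
#' @param init a [bio_state()] on the graph's nodes.
#' @param params a [bio_params()].
#' @param duration_days total simulated time, days (truncated with a warning
#'   when not a multiple of `dt`).
#' @param scheme `"implicit"` or `"explicit"`.
#' @param snapshot_times times (days) at which per-node states are stored.
#' @param cg_tol conjugate-gradient tolerance for the implicit scheme.
#' @return object of class `sim_result`: `series` data.frame (`time_days`,
#'   pool totals in ugC and as percent of initial carbon) and `snapshots`.
#' @export
simulate_mineralization <- function(graph, init, params, duration_days,
                                    scheme = c("implicit", "explicit"),
                                    snapshot_times = NULL, cg_tol = 1e-12) {
  scheme <- match.arg(scheme)
  dt_d <- params$dt / 86400
  nsteps <- floor(duration_days / dt_d + 1e-9)
  if (abs(nsteps * dt_d - duration_days) > 1e-9 * max(1, duration_days))
    warning("duration is not a multiple of dt; truncating to ",
            nsteps * dt_d, " days")
  op <- diffusion_operator(graph, params)
  state <- init
  total0 <- sum(state$b)
  nrec <- nsteps + 1L
  series <- matrix(NA_real_, nrec, 6L,
                   dimnames = list(NULL, c("time_days", "MB", "DOM", "SOM", "FOM", "CO2")))
  series[1L, ] <- c(0, colSums(state$b))
  snaps <- list()
  snap_steps <- if (is.null(snapshot_times)) integer(0) else
    unique(pmin(nsteps, pmax(0L, round(snapshot_times / dt_d))))
  if (0L %in% snap_steps) snaps[["0"]] <- state
  for (step in seq_len(nsteps)) {
    state <- transform_step(state, params)
    state <- if (scheme == "implicit")
      diffusion_step_implicit(state, graph, params, tol = cg_tol, op = op)
    else
      diffusion_step_explicit(state, graph, params, op = op)
    series[step + 1L, ] <- c(step * dt_d, colSums(state$b))
    if (step %in% snap_steps) snaps[[as.character(step)]] <- state
  }
  out <- as.data.frame(series)
  for (pool in c("MB", "DOM", "SOM", "FOM", "CO2"))
    out[[paste0(pool, "_pct")]] <- 100 * out[[pool]] / total0
  structure(list(series = out, snapshots = snaps, total_initial = total0,
                 scheme = scheme, params = params, final_state = state),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  last <- tail(x$series, 1L)
  cat(sprintf("sim_result (%s): %d records over %.4g days; final MB %.4g, DOM %.4g, CO2 %.4g ugC\n",
              x$scheme, nrow(x$series), last$time_days, last$MB, last$DOM, last$CO2))
  invisible(x)
}

#' Non-spatialized (0D) baseline model
#'
#' Iterates the transformation update on the aggregate masses with the total
#' pore volume as the single node volume: the classical well-mixed ODE-style
#' baseline against which the spatialized (3D graph) simulation is compared.
#'
#' @param totals named or positional vector of initial `c(MB, DOM, SOM, FOM)`
#'   masses, ugC.
#' @param params a [bio_params()].
#' @param duration_days total simulated time, days.
#' @param total_volume total pore volume, voxel^3.
#' @return a `sim_result`.
#' @export
ode0d <- function(totals, params, duration_days, total_volume) {
  state <- bio_state(volumes = total_volume, mb = totals[[1]], dom = totals[[2]],
                     som = if (length(totals) > 2) totals[[3]] else 0,
                     fom = if (length(totals) > 3) totals[[4]] else 0)
  empty <- pore_graph(data.frame(id = 1L, volume = total_volume,
                                 cx = 0, cy = 0, cz = 0),
                      data.frame(r = integer(0), s = integer(0)))
  simulate_mineralization(empty, state, params, duration_days,
                          scheme = "explicit")
}

#' Place initial microbial biomass and DOM on the graph
#'
#' Biomass placement modes: `"spots"` samples `n_spots` distinct nodes with
#' probability proportional to node volume and gives each spot an equal mass
#' share (or `weights`); `"random"` samples each spot's node uniformly (with
#' replacement); `"uniform"` spreads the biomass over all nodes
#' proportionally to volume. DOM is always distributed homogeneously: every
#' node receives the same concentration `total_dom / total volume`.
#'
#' @param graph a [pore_graph()].
#' @param total_mb total microbial biomass, ugC.
#' @param n_spots number of colonization spots (ignored for `"uniform"`).
#' @param mode placement mode.
#' @param seed RNG seed for reproducible placement (restores the caller's
#'   RNG state afterwards).
#' @param total_dom total DOM mass, ugC.
#' @param weights optional per-spot mass weights (length `n_spots`).
#' @return a [bio_state()].
#' @export
place_initial_biomass <- function(graph, total_mb, n_spots = 1000L,
                                  mode = c("spots", "random", "uniform"),
                                  seed = NULL, total_dom = 0, weights = NULL) {
  mode <- match.arg(mode)
  v <- as.numeric(graph$nodes$volume)
  n <- length(v)
  mb <- numeric(n)
  if (mode == "uniform") {
    mb <- total_mb * v / sum(v)
  } else {
    if (mode == "spots" && n_spots > n)
      stop_config("n_spots (", n_spots, ") exceeds node count (", n, ")")
    w <- if (is.null(weights)) rep(1, n_spots) else {
      if (length(weights) != n_spots) stop_config("weights must have length n_spots")
      weights
    }
    nodes <- with_seed(seed, {
      if (mode == "spots") sample.int(n, n_spots, replace = FALSE, prob = v)
      else sample.int(n, n_spots, replace = TRUE)
    })
    share <- total_mb * w / sum(w)
    for (t in seq_len(n_spots)) mb[nodes[t]] <- mb[nodes[t]] + share[t]
  }
  dom <- total_dom * v / sum(v)
  bio_state(graph, mb = mb, dom = dom)
}

#' Write a simulation time series to CSV
#' @param result a `sim_result`.
#' @param path output path.
#' @export
write_series_csv <- function(result, path) {
  write.csv(result$series, path, row.names = FALSE)
  invisible(path)
}
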