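# Canonical microcircuit neural mass model: one cortical column holds four
# populations (spiny stellate ss, superficial pyramidal sp, inhibitory
# interneuron ii, deep pyramidal dp), each with second-order synaptic
# dynamics
#     dv/dt = i
#     di/dt = (u - 2 i) / T - v / T^2
# where u is the summed presynaptic drive (mV/s): signed connection
# strengths times the centred sigmoid firing rates of presynaptic
# populations, plus exogenous input into ss. Networks couple columns with
# laminar-specific forward/backward extrinsic connections and transmission
# delays.

#' Microcircuit parameters (log-scalings) for one cortical column
#'
#' All parameters are dimensionless log-scalings of the prior means stored in
#' [cmc_constants()]: effective value = prior mean * exp(scaling), so 0 means
#' "at the prior mean" and magnitudes stay strictly positive.
#'
#' @param G named numeric, log-scalings of the 10 intrinsic connections
#'   (missing entries default to 0). Names follow `from_to`, e.g. `"sp_sp"`
#'   is superficial-pyramidal self-inhibition (synaptic gain).
#' @param T named numeric over populations `ss, sp, ii, dp`: time-constant
#'   log-scalings.
#' @param S scalar sigmoid-slope log-scaling.
#' @param J named numeric over populations: lead-field contribution
#'   log-scalings (the prior-mean weights carry the signs).
#' @return An object of class `cmc_params`.
#' @export
cmc_params <- function(G = numeric(), T = numeric(), S = 0, J = numeric()) {
  k <- .cmc
  g <- setNames(numeric(nrow(k$G)), k$G$name)
  g[names(G)] <- G
  tt <- setNames(numeric(4), k$pops); tt[names(T)] <- T
  jj <- setNames(numeric(4), k$pops); jj[names(J)] <- J
  stopifnot(all(is.finite(c(g, tt, S, jj))))
  structure(list(G = g, T = tt, S = S, J = jj), class = "cmc_params")
}

#' Multi-area network of canonical microcircuits
#'
#' @param areas character vector of area names (each holds one microcircuit).
#' @param forward,backward two-column matrices (or data.frames) of area names
#'   `from, to` defining extrinsic edges. Forward connections originate in
#'   superficial pyramidal cells and target spiny stellate and deep pyramidal
#'   cells; backward connections originate in deep pyramidal cells and target
#'   superficial pyramidal and inhibitory interneuron cells. No self-loops.
#' @param drive_areas areas receiving the exogenous (e.g. thalamic) input.
#' @param lead_field channels x areas mixing matrix (default identity).
#' @param params optional named list of [cmc_params()] per area.
#' @return An object of class `cmc_network`.
#' @export
cmc_network <- function(areas = "src", forward = NULL, backward = NULL,
                        drive_areas = areas[[1]], lead_field = NULL,
                        params = NULL) {
  edge_names <- function(e) {
    if (is.null(e) || NROW(e) == 0) return(character())
    e <- as.matrix(e)
    stopifnot(all(e %in% areas))
    if (any(e[, 1] == e[, 2]))
      stop("extrinsic self-loops are not allowed (self-coupling lives in G)")
    paste0(e[, 1], "->", e[, 2])
  }
  fwd <- edge_names(forward); bwd <- edge_names(backward)
  if (length(intersect(fwd, bwd)))
    stop("an edge cannot be both forward and backward: ",
         paste(intersect(fwd, bwd), collapse = ", "))
  stopifnot(all(drive_areas %in% areas))
  if (is.null(lead_field)) {
    lead_field <- diag(length(areas))
    rownames(lead_field) <- colnames(lead_field) <- areas
  }
  stopifnot(ncol(lead_field) == length(areas))
  if (is.null(params)) params <- setNames(
    lapply(areas, function(a) cmc_params()), areas)
  structure(list(
    areas = areas, params = params,
    A_fwd = setNames(numeric(length(fwd)), fwd),
    A_bwd = setNames(numeric(length(bwd)), bwd),
    C = setNames(numeric(length(drive_areas)), drive_areas),
    D = c(intrinsic = 0, extrinsic = 0),
    B = list(), lead_field = lead_field), class = "cmc_network")
}

#' Single-column network (used for the resting-EEG studies)
#' @export
single_column_network <- function() cmc_network("ctx")

#' Three-area auditory hierarchy A1 -> STG -> IFG with reciprocal backward
#' connections (the mismatch-negativity network; exogenous drive enters A1)
#' @export
mmn_network <- function() {
  cmc_network(c("A1", "STG", "IFG"),
              forward  = cbind(c("A1", "STG"), c("STG", "IFG")),
              backward = cbind(c("STG", "IFG"), c("A1", "STG")),
              drive_areas = "A1")
}

#' Bilateral primary auditory cortex with shared subcortical drive (the
#' 40-Hz auditory steady-state network)
#' @export
assr_network <- function() {
  cmc_network(c("L_A1", "R_A1"), drive_areas = c("L_A1", "R_A1"))
}

#' Parameter-path deltas of the ASSR empirical operating point
#'
#' The empirical priors of the steady-state paradigm (faster sp/ii kernels,
#' steeper activation function, larger spiny-stellate lead-field
#' contribution) expressed as path deltas on [assr_network()]; this is the
#' "prior-mean ASSR model" of the induced-response analyses.
#'
#' @param net the network the deltas address (default [assr_network()])
#' @export
assr_operating_deltas <- function(net = assr_network()) {
  emp <- .cmc$assr_empirical
  out <- c()
  for (nm in names(emp)) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    out <- c(out, setNames(rep(emp[[nm]], length(net$areas)),
                           paste0(net$areas, ":", nm)))
  }
  out
}

# ---------------------------------------------------------------------------
# Flat parameter paths: every log-scaling in the network is addressable by a
# string path, e.g. "IFG:G:sp_sp", "A1:T:ii", "A:fwd:A1->STG", "C:A1",
# "D:intrinsic". Condition modulations use the prefix "B:<condition>:<path>".
# ---------------------------------------------------------------------------

#' Flatten a network's log-scaling parameters to a named vector
#' @param net a [cmc_network()]
#' @return named numeric vector of all log-scalings (B deltas not included)
#' @export
network_vec <- function(net) {
  out <- c()
  for (a in net$areas) {
    p <- net$params[[a]]
    out <- c(out,
             setNames(p$G, paste0(a, ":G:", names(p$G))),
             setNames(p$T, paste0(a, ":T:", names(p$T))),
             setNames(p$S, paste0(a, ":S")),
             setNames(p$J, paste0(a, ":J:", names(p$J))))
  }
  c(out,
    setNames(net$A_fwd, if (length(net$A_fwd)) paste0("A:fwd:", names(net$A_fwd)) else character()),
    setNames(net$A_bwd, if (length(net$A_bwd)) paste0("A:bwd:", names(net$A_bwd)) else character()),
    setNames(net$C, if (length(net$C)) paste0("C:", names(net$C)) else character()),
    setNames(net$D, paste0("D:", names(net$D))))
}

.set_path <- function(net, path, value, add = FALSE) {
  parts <- strsplit(path, ":", fixed = TRUE)[[1]]
  if (parts[[1]] == "B") {
    cond <- parts[[2]]; rest <- paste(parts[-(1:2)], collapse = ":")
    cur <- net$B[[cond]]
    if (is.null(cur)) cur <- numeric()
    cur[rest] <- value + if (add && !is.na(cur[rest])) cur[rest] else 0
    cur[is.na(cur)] <- value
    net$B[[cond]] <- cur
    return(net)
  }
  get0 <- function() {
    switch(parts[[1]],
      A = net[[paste0("A_", parts[[2]])]][[parts[[3]]]],
      C = net$C[[parts[[2]]]],
      D = net$D[[parts[[2]]]],
      { a <- parts[[1]]
        if (parts[[2]] == "S") net$params[[a]]$S
        else net$params[[a]][[parts[[2]]]][[parts[[3]]]] })
  }
  v <- if (add) get0() + value else value
  if (parts[[1]] == "A") net[[paste0("A_", parts[[2]])]][[parts[[3]]]] <- v
  else if (parts[[1]] == "C") net$C[[parts[[2]]]] <- v
  else if (parts[[1]] == "D") net$D[[parts[[2]]]] <- v
  else {
    a <- parts[[1]]
    if (!a %in% net$areas) stop("unknown area in path: ", path)
    if (parts[[2]] == "S") net$params[[a]]$S <- v
    else net$params[[a]][[parts[[2]]]][[parts[[3]]]] <- v
  }
  net
}

#' Add log-scaling deltas to a network by parameter path
#'
#' @param net a [cmc_network()]
#' @param deltas named numeric; names are parameter paths (see
#'   [network_vec()]), optionally with a `B:<condition>:` prefix for
#'   condition modulations.
#' @param validate check every path against the network (skipped on the
#'   package's own hot paths where the prior map fixes the path set)
#' @return the modified network
#' @export
apply_deltas <- function(net, deltas, validate = TRUE) {
  if (!length(deltas)) return(net)
  if (validate) {
    known <- names(network_vec(net))
    bad <- setdiff(sub("^B:[^:]+:", "", names(deltas)), known)
    if (length(bad)) stop("unknown parameter path: ", bad[[1]])
  }
  for (i in seq_along(deltas))
    net <- .set_path(net, names(deltas)[[i]], deltas[[i]], add = TRUE)
  net
}

.apply_condition <- function(net, condition) {
  if (is.null(condition)) return(net)
  if (!length(net$B) && is.null(net$B[[condition]])) return(net)
  b <- net$B[[condition]]
  if (is.null(b)) return(net)
  for (i in seq_along(b)) net <- .set_path(net, names(b)[[i]], b[[i]], add = TRUE)
  net
}

# ---------------------------------------------------------------------------
# Effective system matrices
# ---------------------------------------------------------------------------

# Returns, for a network with a condition applied, the quantities the
# numerical engine needs (all in seconds / mV / mV s^-1):
#   W0  undelayed couplings (self-inhibition loops)
#   Wi  intra-column couplings, delayed by taui
#   We  extrinsic couplings, delayed by taue
#   Tpop, rho, Cdrive, Jobs (channels x populations), taui, taue
build_matrices <- function(net, condition = NULL) {
  net <- .apply_condition(net, condition)
  k <- .cmc
  N <- length(net$areas)
  np <- 4L * N
  idx <- function(a, pop) (match(a, net$areas) - 1L) * 4L + match(pop, k$pops)
  W0 <- matrix(0, np, np); Wi <- matrix(0, np, np); We <- matrix(0, np, np)
  Tpop <- numeric(np); rho <- numeric(np); Cdrive <- numeric(np)
  Jv <- numeric(np)
  isself <- k$G_is_self
  for (ai in seq_len(N)) {
    a <- net$areas[[ai]]
    p <- net$params[[a]]
    off <- (ai - 1L) * 4L
    w <- k$G_signed_mean * exp(p$G)
    W0[cbind(off + k$G_to[isself], off + k$G_from[isself])] <- w[isself]
    Wi[cbind(off + k$G_to[!isself], off + k$G_from[!isself])] <- w[!isself]
    Tpop[off + 1:4] <- k$T_mean_ms * 1e-3 * exp(p$T)
    rho[off + 1:4] <- k$rho0 * exp(p$S)
    Jv[off + 1:4] <- k$J_mean * exp(p$J)
  }
  add_ext <- function(scal, origin, targets) {
    for (nm in names(scal)) {
      ft <- strsplit(nm, "->", fixed = TRUE)[[1]]
      for (tg in names(targets))
        We[idx(ft[[2]], tg), idx(ft[[1]], origin)] <<-
          targets[[tg]] * exp(scal[[nm]])
    }
  }
  add_ext(net$A_fwd, "sp", k$E_fwd)
  add_ext(net$A_bwd, "dp", k$E_bwd)
  for (a in names(net$C)) Cdrive[idx(a, "ss")] <- k$C_mean * exp(net$C[[a]])
  L <- net$lead_field
  Jobs <- matrix(0, nrow(L), np)
  for (j in seq_len(N))
    Jobs[, (j - 1L) * 4L + 1:4] <- outer(L[, j], Jv[(j - 1L) * 4L + 1:4])
  list(W0 = W0, Wi = Wi, We = We, Tpop = Tpop, rho = rho, Cdrive = Cdrive,
       Jobs = Jobs,
       taui = k$delay_mean_ms[["intrinsic"]] * 1e-3 * exp(net$D[["intrinsic"]]),
       taue = k$delay_mean_ms[["extrinsic"]] * 1e-3 * exp(net$D[["extrinsic"]]))
}

#' Sigmoid firing-rate function
#'
#' Logistic activation centred at 0 mV with unit maximum; the slope at the
#' inflection is `rho0 * exp(slope_scaling) / 4`.
#'
#' @param voltage membrane potential (mV)
#' @param slope_scaling log-scaling of the baseline slope
#' @return firing rate in \[0, 1\]
#' @export
sigmoid_rate <- function(voltage, slope_scaling = 0) {
  plogis(.cmc$rho0 * exp(slope_scaling) * voltage)
}

.sigc <- function(v, rho) 1 / (1 + exp(-rho * v)) - 0.5
.sigc_prime <- function(v, rho) {
  s <- 1 / (1 + exp(-rho * v)); rho * s * (1 - s)
}

#' Instantaneous flow of the network (delay-free vector field)
#'
#' The state holds, per area and population, membrane potential v (mV) and a
#' current-like state i (mV/ms-scale, internally mV/s): 8 states per area,
#' ordered all voltages first, then all currents. Delays do not move
#' equilibria; this delay-free field is what the fixed-point solver and the
#' sign/scaling invariants operate on (the integrator applies the delays).
#'
#' @param state numeric vector of length 8 x areas (voltages then currents)
#' @param net a [cmc_network()]
#' @param drive scalar exogenous input (mV/s), entering spiny stellate cells
#'   of the driven areas via C
#' @param condition optional condition label resolved through `net$B`
#' @return d(state)/dt
#' @export
cmc_flow <- function(state, net, drive = 0, condition = NULL) {
  m <- build_matrices(net, condition)
  np <- length(m$Tpop)
  if (length(state) != 2 * np)
    stop("state dimension ", length(state), " does not match network (", 2 * np, ")")
  v <- state[1:np]; cur <- state[np + 1:np]
  u <- (m$W0 + m$Wi + m$We) %*% .sigc(v, m$rho) + m$Cdrive * drive
  c(cur, (u - 2 * cur) / m$Tpop - v / m$Tpop^2)
}

#' Resting fixed point of a network
#'
#' Solves for the state with vanishing flow under a constant drive, by damped
#' Newton iteration on the voltage equations (currents are zero at any
#' equilibrium), falling back to long-horizon integration if Newton fails.
#'
#' @inheritParams cmc_flow
#' @param tol convergence tolerance on the flow residual (mV/s)
#' @param max_iter iteration budget
#' @return the equilibrium state vector (voltages then currents)
#' @export
fixed_point <- function(net, drive = 0, condition = NULL, tol = 1e-10,
                        max_iter = 200) {
  m <- build_matrices(net, condition)
  np <- length(m$Tpop)
  W <- m$W0 + m$Wi + m$We
  Fv <- function(v) m$Tpop * (W %*% .sigc(v, m$rho) + m$Cdrive * drive) - v
  v <- numeric(np)
  ok <- FALSE
  for (it in seq_len(max_iter)) {
    f <- Fv(v)
    if (max(abs(f)) < tol * max(m$Tpop)) { ok <- TRUE; break }
    Jm <- m$Tpop * (W %*% diag(.sigc_prime(drop(v), m$rho), np)) - diag(np)
    step <- tryCatch(-solve(Jm, f), error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    repeat {
      v_new <- v + lam * step
      if (max(abs(Fv(v_new))) < max(abs(f)) || lam < 1e-4) break
      lam <- lam / 2
    }
    v <- drop(v + lam * step)
  }
  if (!ok && max(abs(Fv(v))) >= tol * max(m$Tpop)) {
    # fallback: relax along the flow for a long horizon
    drv <- rep(drive, 20001)
    r <- cpp_integrate_cmc(m$W0, m$Wi, m$We, m$taui, m$taue, m$Tpop, m$rho,
                           m$Cdrive, diag(np), drv, 1e-4, 20000L,
                           v, numeric(np), 20000L)
    if (!isTRUE(r$ok)) stop("fixed_point: integration fallback diverged")
    v <- drop(r$v)
    res <- max(abs(Fv(v)))
    if (res >= tol * max(m$Tpop) * 100)
      stop("fixed_point did not converge; last residual ", signif(res, 3))
  }
  st <- c(v, numeric(np))
  nm <- as.vector(outer(.cmc$pops, net$areas, function(p, a) paste0(a, ".", p)))
  names(st) <- c(paste0("v.", nm), paste0("i.", nm))
  st
}

# Linearization at the fixed point: state-space matrices split by delay
# group, plus input and observation matrices.
linearize <- function(net, condition = NULL, drive0 = 0) {
  m <- build_matrices(net, condition)
  np <- length(m$Tpop)
  st <- fixed_point(net, drive = drive0, condition = condition)
  v <- st[1:np]
  sp <- .sigc_prime(v, m$rho)
  K <- 1 / m$Tpop
  blk <- function(W) rbind(cbind(matrix(0, np, np), matrix(0, np, np)),
                           cbind(K * (W %*% diag(sp, np)), matrix(0, np, np)))
  A0 <- rbind(cbind(matrix(0, np, np), diag(np)),
              cbind(K * (m$W0 %*% diag(sp, np)) - diag(1 / m$Tpop^2, np),
                    diag(-2 * K, np)))
  Ai <- blk(m$Wi); Ae <- blk(m$We)
  B <- rbind(matrix(0, np, 1), matrix(K * m$Cdrive, np, 1))
  Cobs <- cbind(m$Jobs, matrix(0, nrow(m$Jobs), np))
  list(A0 = A0, Ai = Ai, Ae = Ae, B = B, C = Cobs,
       taui = m$taui, taue = m$taue, x0 = st, mats = m)
}
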