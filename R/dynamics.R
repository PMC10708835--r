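#' Parameters of a planar serial link chain
#'
#' Describes the swing-limb surrogate used to generate dynamically consistent
#' joint torques: a planar open chain (default three links: thigh, shank,
#' foot) hanging from a fixed hip, with gravity acting downwards. Joint angles
#' are relative, measured from the parent link's axis, with the zero
#' configuration pointing straight down and flexion positive.
#'
#' @param masses Per-link mass in kg (> 0).
#' @param lengths Per-link length in m (> 0).
#' @param com Distance of each link's centre of mass from its proximal joint,
#'   in m (0 < com <= length).
#' @param inertia Moment of inertia of each link about its own centre of mass,
#'   in kg m^2 (>= 0).
#' @param gravity Gravitational acceleration magnitude in m/s^2.
#' @return An object of class `link_chain_params`.
#' @export
link_chain_params <- function(masses, lengths, com, inertia, gravity = 9.81) {
  n <- length(masses)
  if (n < 1L) stop("at least one link is required", call. = FALSE)
  if (length(lengths) != n || length(com) != n || length(inertia) != n) {
    stop("masses, lengths, com and inertia must have equal length", call. = FALSE)
  }
  if (any(masses <= 0) || any(lengths <= 0)) {
    stop("masses and lengths must be positive", call. = FALSE)
  }
  if (any(inertia < 0)) stop("inertias must be nonnegative", call. = FALSE)
  if (any(com <= 0) || any(com > lengths)) {
    stop("com distances must lie in (0, length]", call. = FALSE)
  }
  if (gravity < 0) stop("gravity must be nonnegative", call. = FALSE)
  structure(
    list(masses = as.numeric(masses), lengths = as.numeric(lengths),
         com = as.numeric(com), inertia = as.numeric(inertia),
         gravity = gravity, n_links = n),
    class = "link_chain_params"
  )
}

#' Anthropometric default: thigh, shank, foot
#'
#' Segment masses, lengths and inertias of a typical adult leg, used as the
#' default chain for the synthetic gait generator.
#'
#' @param gravity Gravitational acceleration (m/s^2).
#' @return A `link_chain_params` with three links.
#' @export
default_leg_params <- function(gravity = 9.81) {
  link_chain_params(
    masses  = c(7.0, 3.5, 1.0),
    lengths = c(0.42, 0.40, 0.20),
    com     = c(0.18, 0.17, 0.10),
    inertia = c(0.11, 0.05, 0.005),
    gravity = gravity
  )
}

#' @export
print.link_chain_params <- function(x, ...) {
  cat("Planar link chain:", x$n_links, "links\n")
  print(data.frame(mass_kg = x$masses, length_m = x$lengths,
                   com_m = x$com, inertia_kgm2 = x$inertia))
  cat("gravity:", x$gravity, "m/s^2\n")
  invisible(x)
}

# Per-link COM positions and their first/second partials w.r.t. the joint
# angles, for relative angles q with absolute link angles theta_i = cumsum(q).
# Link direction e(theta) = (sin, -cos): theta = 0 hangs straight down.
chain_geometry <- function(q, params) {
  n <- params$n_links
  theta <- cumsum(q)
  s <- sin(theta); cc <- cos(theta)
  e  <- rbind(s, -cc)      # 2 x n, link direction
  de <- rbind(cc, s)       # d e / d theta
  # p[[l]]: COM of link l; J[[l]]: 2 x n first partials; H[[l]][[k]][[m]]:
  # second partials, stored as a 2 x n x n array.
  p <- vector("list", n); J <- vector("list", n); H <- vector("list", n)
  for (l in seq_len(n)) {
    pl <- c(0, 0)
    if (l > 1L) for (j in seq_len(l - 1L)) pl <- pl + params$lengths[j] * e[, j]
    pl <- pl + params$com[l] * e[, l]
    Jl <- matrix(0, 2, n)
    Hl <- array(0, c(2, n, n))
    for (k in seq_len(l)) {
      v <- c(0, 0)
      if (l > k) for (j in k:(l - 1L)) v <- v + params$lengths[j] * de[, j]
      v <- v + params$com[l] * de[, l]
      Jl[, k] <- v
      for (m in seq_len(l)) {
        a <- max(k, m)
        w <- c(0, 0)
        if (l > a) for (j in a:(l - 1L)) w <- w - params$lengths[j] * e[, j]
        w <- w - params$com[l] * e[, l]
        Hl[, k, m] <- w
      }
    }
    p[[l]] <- pl; J[[l]] <- Jl; H[[l]] <- Hl
  }
  list(p = p, J = J, H = H)
}

#' Mass matrix of the planar chain
#'
#' @param q Joint angle vector (rad).
#' @param params A [link_chain_params()].
#' @return The symmetric positive-definite joint-space inertia matrix (n x n).
#' @export
mass_matrix <- function(q, params) {
  check_chain_state(q, params)
  geo <- chain_geometry(q, params)
  n <- params$n_links
  M <- matrix(0, n, n)
  for (l in seq_len(n)) {
    Jl <- geo$J[[l]]
    M <- M + params$masses[l] * crossprod(Jl)
    w <- matrix(0, n, 1); w[seq_len(l), 1] <- 1   # angular Jacobian of link l
    M <- M + params$inertia[l] * tcrossprod(w)
  }
  (M + t(M)) / 2
}

# dM/dq_k for all k, as an n x n x n array (third index = k).
mass_matrix_grad <- function(q, params) {
  geo <- chain_geometry(q, params)
  n <- params$n_links
  dM <- array(0, c(n, n, n))
  for (l in seq_len(n)) {
    Jl <- geo$J[[l]]; Hl <- geo$H[[l]]; ml <- params$masses[l]
    for (k in seq_len(n)) {
      Hk <- Hl[, , k]                       # 2 x n: d2 p_l / dq dq_k
      dM[, , k] <- dM[, , k] + ml * (crossprod(Hk, Jl) + crossprod(Jl, Hk))
    }
  }
  dM
}

#' Coriolis/centrifugal torque vector
#'
#' Velocity-dependent generalized torques from the Christoffel symbols of the
#' mass matrix.
#'
#' @param q,qd Joint angles (rad) and velocities (rad/s).
#' @inheritParams mass_matrix
#' @return Numeric vector of length n (N m).
#' @export
coriolis_vector <- function(q, qd, params) {
  check_chain_state(q, params)
  stopifnot(length(qd) == params$n_links)
  n <- params$n_links
  dM <- mass_matrix_grad(q, params)
  cvec <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) for (k in seq_len(n)) {
      cijk <- 0.5 * (dM[i, j, k] + dM[i, k, j] - dM[j, k, i])
      cvec[i] <- cvec[i] + cijk * qd[j] * qd[k]
    }
  }
  cvec
}

#' Gravitational torque vector
#'
#' @inheritParams coriolis_vector
#' @return Numeric vector of length n (N m).
#' @export
gravity_vector <- function(q, params) {
  check_chain_state(q, params)
  geo <- chain_geometry(q, params)
  n <- params$n_links
  g <- numeric(n)
  for (l in seq_len(n)) {
    g <- g + params$masses[l] * params$gravity * geo$J[[l]][2, ]
  }
  g
}

#' Kinetic energy of the chain
#'
#' @inheritParams coriolis_vector
#' @return Scalar kinetic energy (J).
#' @export
kinetic_energy <- function(q, qd, params) {
  0.5 * drop(crossprod(qd, mass_matrix(q, params) %*% qd))
}

check_chain_state <- function(q, params) {
  if (!inherits(params, "link_chain_params")) {
    stop("params must be a link_chain_params", call. = FALSE)
  }
  if (length(q) != params$n_links) {
    stop("state dimension (", length(q), ") does not match link count (",
         params$n_links, ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' Inverse dynamics of the planar chain
#'
#' Computes the generalized joint torques tau = M(q) qdd + C(q, qd) + G(q)
#' along a trajectory. This is the equation of motion of the planar serial
#' chain solved for the torques, given angles, angular velocities and angular
#' accelerations.
#'
#' @param states A list with matrices `q`, `qd`, `qdd` (rows = time samples,
#'   columns = joints) and optionally `time`.
#' @inheritParams mass_matrix
#' @return Matrix of torques (rows = time samples, columns = joints, N m).
#' @export
inverse_dynamics <- function(states, params) {
  q <- as.matrix(states$q); qd <- as.matrix(states$qd)
  qdd <- as.matrix(states$qdd)
  if (!all(dim(q) == dim(qd)) || !all(dim(q) == dim(qdd))) {
    stop("q, qd and qdd must have identical dimensions", call. = FALSE)
  }
  check_chain_state(q[1, ], params)
  tau <- matrix(0, nrow(q), ncol(q))
  for (t in seq_len(nrow(q))) {
    M <- mass_matrix(q[t, ], params)
    tau[t, ] <- M %*% qdd[t, ] + coriolis_vector(q[t, ], qd[t, ], params) +
      gravity_vector(q[t, ], params)
  }
  colnames(tau) <- colnames(q)
  tau
}

#' Forward dynamics: accelerations from torques
#'
#' Solves qdd = M(q)^-1 (tau - C(q, qd) - G(q)); the right inverse of
#' [inverse_dynamics()]. Used to verify that integrating the computed torques
#' reproduces the source trajectory.
#'
#' @param q,qd Current joint angles and velocities.
#' @param tau Applied joint torques (N m).
#' @inheritParams mass_matrix
#' @return Joint accelerations (rad/s^2).
#' @export
forward_dynamics <- function(q, qd, tau, params) {
  check_chain_state(q, params)
  M <- mass_matrix(q, params)
  drop(solve(M, tau - coriolis_vector(q, qd, params) - gravity_vector(q, params)))
}
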