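#' Registration configuration
#'
#' Weights, kernel widths and optimizer controls for F-shape registration
#' and atlas estimation. Coordinates are assumed commensurate (mm via
#' [fshape_to_mm()]); the signal kernel width is in micrometres of
#' thickness.
#'
#' @param gamma_f Weight of the template-signal L2 penalty.
#' @param gamma_zeta Weight of the per-subject signal-increment penalty.
#' @param gamma_w Weight of the varifold data-attachment term.
#' @param sigma_V Deformation kernel width (mm).
#' @param sigma_W Varifold position kernel width (mm).
#' @param sigma_sig Varifold signal kernel width (um).
#' @param shoot_steps Explicit Euler steps for geodesic shooting (>= 1).
#' @param tol Stopping threshold on the objective decrease between accepted
#'   iterations (absolute by default).
#' @param relative_tol Interpret `tol` relative to the current objective.
#' @param max_iter Iteration cap for per-subject registration and for atlas
#'   outer iterations.
#' @param step_init Global multiplier on the initial block step sizes (each
#'   parameter block adapts its own step from there).
#' @param step_zeta,step_p,step_f,step_x Natural initial step scales of the
#'   four parameter blocks: signal increments (um), momenta, template
#'   signal (um), template geometry (mm). Updates move along the
#'   normalized negative gradient by the current step, so steps live in
#'   parameter units.
#' @param step_shrink,step_grow Backtracking shrink factor on rejection and
#'   growth factor after acceptance.
#' @param max_backtrack Maximum step halvings per block update.
#' @param p_every Update the momentum block on every `p_every`-th
#'   iteration (1 = every iteration). The momentum update is the costly
#'   block; spacing it out speeds registration with little quality loss
#'   when deformations are mild.
#' @param update_geometry Update the template geometry during atlas
#'   estimation (with a step `geom_step_frac` times the signal step) or
#'   freeze it at the hypertemplate.
#' @param geom_step_frac Geometry step as a fraction of the signal step.
#' @param seed Seed recorded with the run (optimization itself is
#'   deterministic; the seed governs any randomized inputs).
#' @return An object of class `registration_config`.
#' @export
registration_config <- function(gamma_f = 1e-4, gamma_zeta = 1e-2, gamma_w = 1,
                                sigma_V = 1.5, sigma_W = 0.5, sigma_sig = 15,
                                shoot_steps = 10L, tol = 1e-4,
                                relative_tol = FALSE, max_iter = 300L,
                                step_init = 1,
                                step_zeta = 20, step_p = 0.01,
                                step_f = 20, step_x = 0.02,
                                step_shrink = 0.5,
                                step_grow = 1.5, max_backtrack = 40L,
                                p_every = 1L,
                                update_geometry = TRUE, geom_step_frac = 0.1,
                                seed = 1L) {
  vals <- c(gamma_f = gamma_f, gamma_zeta = gamma_zeta, gamma_w = gamma_w,
            sigma_V = sigma_V, sigma_W = sigma_W, sigma_sig = sigma_sig,
            tol = tol)
  if (any(vals <= 0)) {
    stop("weights, kernel widths and tol must all be positive", call. = FALSE)
  }
  stopifnot(shoot_steps >= 1L, max_iter >= 1L,
            step_shrink > 0, step_shrink < 1, step_grow >= 1)
  structure(
    list(gamma_f = gamma_f, gamma_zeta = gamma_zeta, gamma_w = gamma_w,
         sigma_V = sigma_V, sigma_W = sigma_W, sigma_sig = sigma_sig,
         shoot_steps = as.integer(shoot_steps), tol = tol,
         relative_tol = relative_tol, max_iter = as.integer(max_iter),
         step_init = step_init, step_zeta = step_zeta, step_p = step_p,
         step_f = step_f, step_x = step_x, step_shrink = step_shrink,
         step_grow = step_grow, max_backtrack = as.integer(max_backtrack),
         p_every = as.integer(p_every),
         update_geometry = update_geometry, geom_step_frac = geom_step_frac,
         seed = as.integer(seed)),
    class = "registration_config"
  )
}

#' Geodesic shooting of a point set
#'
#' Flows points by `shoot_steps` explicit Euler steps of the Hamiltonian
#' point system with Gaussian kernel: velocities `v = K(x) p`, momenta
#' co-evolved by the Hamiltonian gradient, step `1/shoot_steps`.
#'
#' @param x0 n x 3 matrix of initial points.
#' @param p n x 3 matrix of initial momenta.
#' @param cfg A [registration_config()] (uses `sigma_V`, `shoot_steps`).
#' @param keep_trajectory Keep the per-step states (needed by the adjoint
#'   pullback).
#' @return List with `x` (final points), `p` (final momenta), and
#'   optionally `traj`, the pre-step states as a list of two n x 3 x steps
#'   arrays `tx`, `tp`.
#' @export
shoot_forward <- function(x0, p, cfg, keep_trajectory = FALSE) {
  out <- cpp_shoot(as.matrix(x0), as.matrix(p), cfg$sigma_V^2,
                   cfg$shoot_steps)
  if (any(!is.finite(out$x)) || any(!is.finite(out$p))) {
    stop("geodesic shooting diverged (non-finite state); reduce the step",
         call. = FALSE)
  }
  list(x = out$x, p = out$p,
       traj = if (keep_trajectory) list(tx = out$tx, tp = out$tp) else NULL)
}

# constant trajectory at x0 with zero momenta (exact when p = 0);
# trajectories are stored transposed (3 x n x steps), matching cpp_shoot
frozen_traj <- function(x0, steps) {
  n <- nrow(x0)
  list(tx = array(rep(t(x0), steps), dim = c(3L, n, steps)),
       tp = array(0, dim = c(3L, n, steps)))
}

#' Deform a mesh by geodesic shooting of its vertices
#'
#' Connectivity is unchanged; zero momenta return the identical mesh.
#'
#' @param template_mesh A [tri_mesh()].
#' @param p n x 3 momenta (one row per vertex).
#' @param cfg A [registration_config()].
#' @return The deformed [tri_mesh()].
#' @export
deform <- function(template_mesh, p, cfg) {
  stopifnot(inherits(template_mesh, "tri_mesh"))
  p <- as.matrix(p)
  if (nrow(p) != nrow(template_mesh$vertices) || ncol(p) != 3L) {
    stop("momenta must be an n x 3 matrix matching the vertex count",
         call. = FALSE)
  }
  if (all(p == 0)) return(template_mesh)
  out <- shoot_forward(template_mesh$vertices, p, cfg)
  m <- template_mesh
  m$vertices <- out$x
  m
}

#' Geodesic energy of a deformation
#'
#' The initial-momentum RKHS norm `p' K(X) p`; zero iff the deformation is
#' the identity, and quadratic in the momenta.
#'
#' @inheritParams deform
#' @param template_mesh A [tri_mesh()].
#' @return Non-negative scalar.
#' @export
geodesic_energy <- function(template_mesh, p, cfg) {
  p <- as.matrix(p)
  K <- gaussian_gram(template_mesh$vertices, cfg$sigma_V)
  sum(p * (K %*% p))
}

# Adjoint (reverse-mode) pullback through the Euler shooting scheme.
# Given the gradient `gx_final` of a functional of the endpoint positions,
# returns its gradient with respect to the initial momenta p0 and initial
# positions x0. `traj` must come from shoot_forward(..., keep_trajectory).
shoot_pullback <- function(traj, gx_final, cfg) {
  cpp_shoot_pullback(traj$tx, traj$tp, as.matrix(gx_final), cfg$sigma_V^2)
}

# gradient of p'K(x)p with respect to p and x
energy_grad <- function(x, p, sigma) {
  K <- gaussian_gram(x, sigma)
  cc <- 2 / sigma^2
  M <- K * tcrossprod(p)
  list(gp = 2 * (K %*% p),
       gx = -2 * cc * (rowSums(M) * x - M %*% x),
       value = sum(p * (K %*% p)))
}
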