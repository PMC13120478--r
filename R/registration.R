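#' Per-subject registration parameters
#'
#' Geometric momenta (one 3-vector per template vertex) and functional
#' signal increments (one scalar per template vertex).
#'
#' @param p n x 3 numeric matrix of momenta.
#' @param zeta Length-n numeric vector of signal increments (um).
#' @return An object of class `registration_params`.
#' @export
registration_params <- function(p, zeta) {
  p <- as.matrix(p)
  zeta <- as.numeric(zeta)
  if (nrow(p) != length(zeta) || ncol(p) != 3L) {
    stop("p must be n x 3 and zeta length n", call. = FALSE)
  }
  if (any(!is.finite(p)) || any(!is.finite(zeta))) {
    stop("registration parameters must be finite", call. = FALSE)
  }
  structure(list(p = p, zeta = zeta), class = "registration_params")
}

zero_params <- function(n) registration_params(matrix(0, n, 3L), numeric(n))

# Apply (p, zeta) to the template: deformed geometry + incremented signal.
# Signals are pointwise thicknesses, transported without Jacobian rescaling.
apply_params <- function(template, params, cfg) {
  mesh <- deform(template$mesh, params$p, cfg)
  fshape(mesh, template$signal + params$zeta)
}

# Cache a subject's face geometry plus its self inner product.
subject_geometry <- function(subject, cfg) {
  g <- face_geometry(subject)
  g$self_inner <- fvarifold_inner_self(g, cfg)
  g
}

# ---------------------------------------------------------------------------
# Reference (single-pass) evaluation of the single-subject objective terms
#   E_i = p'K(X_m)p + gamma_zeta * sum(zeta^2 w) + gamma_w * A(reg_i, subj_i)
# with exact gradients via the shooting adjoint. The optimization loops use
# the cached evaluators below; this function is the plain reference path
# (used by evaluate_objective and the geometry update) and the two must
# agree exactly.
subject_term <- function(template, subject_geom, params, cfg, w, K0 = NULL,
                         grad = FALSE) {
  x0 <- template$mesh$vertices
  if (is.null(K0)) K0 <- gaussian_gram(x0, cfg$sigma_V)
  p <- params$p; zeta <- params$zeta
  energy <- sum(p * (K0 %*% p))
  pen <- cfg$gamma_zeta * sum(zeta^2 * w)
  shoot <- NULL
  if (!grad && all(p == 0)) {
    xS <- x0
  } else if (!grad) {
    xS <- shoot_forward(x0, p, cfg)$x
  } else {
    shoot <- cpp_shoot_cache(x0, p, cfg$sigma_V^2, cfg$shoot_steps)
    xS <- shoot$x
  }
  mesh <- template$mesh; mesh$vertices <- xS
  reg <- fshape(mesh, template$signal + zeta)
  greg <- face_geometry(reg)
  attach_val <- fvarifold_inner_self(greg, cfg) -
    2 * fvarifold_inner(greg, subject_geom, cfg) + subject_geom$self_inner
  value <- energy + pen + cfg$gamma_w * attach_val
  if (!grad) {
    return(list(value = value, registered = reg))
  }
  gaa <- varifold_inner_grad_self(greg, cfg)
  gab <- varifold_inner_grad(greg, subject_geom, cfg)
  gV <- 2 * gaa$gV - 2 * gab$gV
  gs <- 2 * gaa$gs - 2 * gab$gs
  pb <- cpp_shoot_reverse(shoot$tx, shoot$tp, shoot$Ks,
                          cfg$gamma_w * gV, cfg$sigma_V^2)
  eg <- energy_grad(x0, p, cfg$sigma_V)
  list(value = value,
       registered = reg,
       grad_p = eg$gp + pb$gp,
       grad_zeta = 2 * cfg$gamma_zeta * zeta * w + cfg$gamma_w * gs,
       grad_x0 = eg$gx + pb$gx,       # template-geometry contribution
       grad_fm = cfg$gamma_w * gs)    # template-signal contribution
}

# ---------------------------------------------------------------------------
# Cached evaluation state for the optimization loops. Holds the deformed
# geometry, the geometry-only kernel blocks (GKaa against itself, GKab
# against the subject), the signal kernel blocks (Saa, Sab), and the term
# value, so that signal-only trials recompute just the signal kernels and
# geometry-only trials just the geometry kernels.
subject_state <- function(template, sgeom, params, cfg, w, K0) {
  x0 <- template$mesh$vertices
  energy <- sum(params$p * (K0 %*% params$p))
  pen <- cfg$gamma_zeta * sum(params$zeta^2 * w)
  xS <- if (all(params$p == 0)) x0 else shoot_forward(x0, params$p, cfg)$x
  mesh <- template$mesh; mesh$vertices <- xS
  reg <- fshape(mesh, template$signal + params$zeta)
  ga <- face_geometry(reg)
  gaa <- geom_block_self(ga, cfg)
  gab <- geom_block(ga, sgeom, cfg)
  fa <- ga$fb[gaa$ia]
  Saa <- sig_block(fa, fa, cfg)
  Sab <- sig_block(ga$fb[gab$ia], sgeom$fb[gab$ib], cfg)
  attach <- sum(gaa$GK * Saa) - 2 * sum(gab$GK * Sab) + sgeom$self_inner
  list(value = energy + pen + cfg$gamma_w * attach,
       energy = energy, pen = pen, attach = attach,
       reg = reg, ga = ga, gaa = gaa, gab = gab, Saa = Saa, Sab = Sab)
}

# value under a trial zeta (geometry unchanged): recompute signal kernels
state_value_zeta <- function(st, template, sgeom, zeta, cfg, w) {
  fa_full <- face_means(template$mesh$faces, template$signal + zeta)
  ssig2 <- cfg$sigma_sig^2
  attach <- cpp_sum_gk_sig_sym(st$gaa$GK, fa_full[st$gaa$ia], ssig2) -
    2 * cpp_sum_gk_sig(st$gab$GK, fa_full[st$gab$ia],
                       sgeom$fb[st$gab$ib], ssig2) + sgeom$self_inner
  st$energy + cfg$gamma_zeta * sum(zeta^2 * w) + cfg$gamma_w * attach
}

# value under trial momenta (signal unchanged): reshoot + geometry kernels
state_value_p <- function(st, template, sgeom, p, cfg, K0) {
  x0 <- template$mesh$vertices
  energy <- sum(p * (K0 %*% p))
  xS <- if (all(p == 0)) x0 else shoot_forward(x0, p, cfg)$x
  mesh <- template$mesh; mesh$vertices <- xS
  ga <- face_geometry(fshape(mesh, st$reg$signal))
  if (!all(ga$ok == st$ga$ok)) return(Inf)  # degeneracy changed; reject
  a <- face_sub(ga); b <- face_sub(sgeom)
  sW2 <- cfg$sigma_W^2
  attach <- cpp_sum_geom_sig_sym(a$C, a$N, a$nl, st$Saa, sW2) -
    2 * cpp_sum_geom_sig(a$C, a$N, a$nl, b$C, b$N, b$nl, st$Sab, sW2) +
    sgeom$self_inner
  energy + st$pen + cfg$gamma_w * attach
}

# in-place state update after an accepted zeta move (geometry untouched)
state_apply_zeta <- function(st, template, sgeom, zeta, cfg, w) {
  st$reg$signal <- template$signal + zeta
  st$ga$fb <- face_means(template$mesh$faces, st$reg$signal)
  fa <- st$ga$fb[st$gaa$ia]
  st$Saa <- sig_block(fa, fa, cfg)
  st$Sab <- sig_block(st$ga$fb[st$gab$ia], sgeom$fb[st$gab$ib], cfg)
  st$attach <- sum(st$gaa$GK * st$Saa) - 2 * sum(st$gab$GK * st$Sab) +
    sgeom$self_inner
  st$pen <- cfg$gamma_zeta * sum(zeta^2 * w)
  st$value <- st$energy + st$pen + cfg$gamma_w * st$attach
  st
}

# in-place state update after an accepted momentum move (signal untouched)
state_apply_p <- function(st, template, sgeom, p, cfg, K0) {
  x0 <- template$mesh$vertices
  st$energy <- sum(p * (K0 %*% p))
  xS <- if (all(p == 0)) x0 else shoot_forward(x0, p, cfg)$x
  st$reg$mesh$vertices <- xS
  st$ga <- face_geometry(st$reg)
  st$gaa <- geom_block_self(st$ga, cfg)
  st$gab <- geom_block(st$ga, sgeom, cfg)
  st$attach <- sum(st$gaa$GK * st$Saa) - 2 * sum(st$gab$GK * st$Sab) +
    sgeom$self_inner
  st$value <- st$energy + st$pen + cfg$gamma_w * st$attach
  st
}

# exact gradients at the cached state; the momentum/geometry gradients
# (which need the shooting adjoint) are computed only when requested
state_grad <- function(st, template, sgeom, params, cfg, w, K0,
                       want_p = TRUE) {
  ssig2 <- cfg$sigma_sig^2
  if (want_p) {
    gaa <- varifold_inner_grad_self(st$ga, cfg)
    gab <- varifold_inner_grad(st$ga, sgeom, cfg)
    gV <- 2 * gaa$gV - 2 * gab$gV
    gs <- 2 * gaa$gs - 2 * gab$gs
  } else {
    # signal-only gradient from the cached geometry kernels
    fa_aa <- st$ga$fb[st$gaa$ia]
    gfb <- numeric(nrow(st$ga$faces))
    gfb[st$gaa$ia] <- 2 * cpp_sig_grad_sym(st$gaa$GK, fa_aa, ssig2)
    gfb[st$gab$ia] <- gfb[st$gab$ia] -
      2 * cpp_sig_grad(st$gab$GK, st$ga$fb[st$gab$ia],
                       sgeom$fb[st$gab$ib], ssig2)
    gs <- numeric(st$ga$nv)
    for (c in 1:3) {
      add <- rowsum(gfb / 3, st$ga$faces[, c])
      idx <- as.integer(rownames(add))
      gs[idx] <- gs[idx] + add
    }
  }
  out <- list(
    grad_zeta = 2 * cfg$gamma_zeta * params$zeta * w + cfg$gamma_w * gs,
    grad_fm = cfg$gamma_w * gs)
  if (want_p) {
    x0 <- template$mesh$vertices
    sh <- cpp_shoot_cache(x0, params$p, cfg$sigma_V^2, cfg$shoot_steps)
    pb <- cpp_shoot_reverse(sh$tx, sh$tp, sh$Ks, cfg$gamma_w * gV,
                            cfg$sigma_V^2)
    eg <- energy_grad(x0, params$p, cfg$sigma_V)
    out$grad_p <- eg$gp + pb$gp
    out$grad_x0 <- eg$gx + pb$gx
  }
  out
}

#' Evaluate the atlas objective
#'
#' The full objective
#' `J = gamma_f * sum_v f_m(v)^2 w(v) + sum_i [ p_i' K(X_m) p_i +
#' gamma_zeta * sum_v zeta_i(v)^2 w(v) + gamma_w * A(reg_i, subject_i) ]`
#' where `w(v)` is the vertex's share of template mesh area and `reg_i` is
#' the template deformed by `p_i` carrying signal `f_m + zeta_i`.
#'
#' @param template Template [fshape()].
#' @param subjects List of subject [fshape()]s.
#' @param params List of [registration_params()], aligned with `subjects`.
#' @param cfg A [registration_config()].
#' @return List with `value`, `template_signal_term`, and a `terms` tibble
#'   (energy, zeta penalty, attachment per subject).
#' @export
evaluate_objective <- function(template, subjects, params, cfg) {
  if (length(subjects) != length(params)) {
    stop("params must align with subjects", call. = FALSE)
  }
  w <- vertex_area_weights(template$mesh)
  K0 <- gaussian_gram(template$mesh$vertices, cfg$sigma_V)
  f_term <- cfg$gamma_f * sum(template$signal^2 * w)
  rows <- purrr::map2(subjects, params, function(s, prm) {
    sg <- subject_geometry(s, cfg)
    st <- subject_term(template, sg, prm, cfg, w, K0)
    en <- sum(prm$p * (K0 %*% prm$p))
    pen <- cfg$gamma_zeta * sum(prm$zeta^2 * w)
    tibble::tibble(energy = en, zeta_penalty = pen,
                   attachment = (st$value - en - pen) / cfg$gamma_w)
  })
  terms <- dplyr::bind_rows(rows)
  value <- f_term + sum(terms$energy) + sum(terms$zeta_penalty) +
    cfg$gamma_w * sum(terms$attachment)
  list(value = value, template_signal_term = f_term, terms = terms)
}

# One monotone block update: a safeguarded Barzilai-Borwein step along the
# raw negative gradient with backtracking. `blk` carries the block's
# memory (last accepted step length, previous state and gradient); the
# first step moves by the block's natural scale. Only candidates that
# decrease the objective are accepted, so the outer traces stay
# non-increasing regardless of the proposed step.
new_block <- function(scale) list(alpha = NULL, scale = scale,
                                  prev_state = NULL, prev_grad = NULL)

# Normalized-direction multiplicative update, used for the signal blocks
# (zeta and the template signal): moves along grad/max|grad| by the
# block's remembered step (parameter units), shrinking on rejection and
# growing after a first-try acceptance. More exploratory than the secant
# step, which suits the wide, shallow signal landscape.
norm_step <- function(state, grad, blk, eval_fn, f0, cfg) {
  gmax <- max(abs(grad))
  if (!is.finite(gmax) || gmax == 0) {
    return(list(state = state, value = f0, blk = blk, accepted = FALSE))
  }
  if (is.null(blk$alpha)) blk$alpha <- blk$scale
  dir <- grad / gmax
  step <- blk$alpha
  first <- TRUE
  for (k in seq_len(cfg$max_backtrack)) {
    cand <- state - step * dir
    f1 <- tryCatch(eval_fn(cand), error = function(e) Inf)
    if (is.finite(f1) && f1 < f0) {
      blk$alpha <- if (first) step * cfg$step_grow else step
      return(list(state = cand, value = f1, blk = blk, accepted = TRUE))
    }
    step <- step * cfg$step_shrink
    first <- FALSE
  }
  blk$alpha <- step
  list(state = state, value = f0, blk = blk, accepted = FALSE)
}

bb_step <- function(state, grad, blk, eval_fn, f0, cfg) {
  gmax <- max(abs(grad))
  if (!is.finite(gmax) || gmax == 0) {
    return(list(state = state, value = f0, blk = blk, accepted = FALSE))
  }
  if (is.null(blk$alpha)) {
    alpha <- blk$scale / gmax
  } else if (!is.null(blk$prev_grad)) {
    sdiff <- state - blk$prev_state
    y <- grad - blk$prev_grad
    sy <- sum(sdiff * y); yy <- sum(y * y)
    alpha <- if (is.finite(sy) && sy > 0 && yy > 0) sy / yy
             else blk$alpha * cfg$step_grow
    # other blocks move the landscape between this block's updates, which
    # can make the secant estimate arbitrary; keep it within a
    # multiplicative trust range of the last accepted step
    alpha <- min(max(alpha, blk$alpha / 10), blk$alpha * 10)
  } else {
    alpha <- blk$alpha * cfg$step_grow
  }
  for (k in seq_len(cfg$max_backtrack)) {
    cand <- state - alpha * grad
    f1 <- tryCatch(eval_fn(cand), error = function(e) Inf)
    if (is.finite(f1) && f1 < f0) {
      blk$alpha <- alpha
      blk$prev_state <- state
      blk$prev_grad <- grad
      return(list(state = cand, value = f1, blk = blk, accepted = TRUE))
    }
    alpha <- alpha * cfg$step_shrink
  }
  blk$alpha <- alpha
  blk$prev_state <- state
  blk$prev_grad <- grad
  list(state = state, value = f0, blk = blk, accepted = FALSE)
}

#' Register one F-shape to a fixed template
#'
#' Adaptive gradient descent on the single-subject objective terms from
#' zero parameters: alternating backtracking updates of the signal
#' increments and the momenta along their normalized gradients, each block
#' keeping its own adapted step size. An update is accepted only if it
#' decreases the objective, so the returned trace is non-increasing; the
#' loop stops when the decrease between accepted iterations falls below
#' `cfg$tol` or `cfg$max_iter` is reached.
#'
#' @param template Template [fshape()] (held fixed).
#' @param subject Subject [fshape()] (coordinates commensurate with the
#'   template, see [fshape_to_mm()]).
#' @param cfg A [registration_config()].
#' @return List with `params` ([registration_params()]), `registered`
#'   ([fshape()] on template connectivity), and `trace` (accepted objective
#'   values, starting at the initial objective).
#' @export
register_subject <- function(template, subject, cfg) {
  stopifnot(inherits(template, "fshape"), inherits(subject, "fshape"))
  n <- nrow(template$mesh$vertices)
  w <- vertex_area_weights(template$mesh)
  K0 <- gaussian_gram(template$mesh$vertices, cfg$sigma_V)
  sg <- subject_geometry(subject, cfg)
  prm <- zero_params(n)
  st <- subject_state(template, sg, prm, cfg, w, K0)
  f <- st$value
  trace <- f
  blk_z <- new_block(cfg$step_init * cfg$step_zeta)
  blk_p <- new_block(cfg$step_init * cfg$step_p)
  for (it in seq_len(cfg$max_iter)) {
    do_p <- (it - 1L) %% cfg$p_every == 0L
    g <- state_grad(st, template, sg, prm, cfg, w, K0, want_p = do_p)
    if ((do_p && any(!is.finite(g$grad_p))) ||
          any(!is.finite(g$grad_zeta))) {
      stop("non-finite gradient at iteration ", it, call. = FALSE)
    }
    f_before <- f
    bz <- norm_step(
      prm$zeta, g$grad_zeta, blk_z,
      function(z) state_value_zeta(st, template, sg, z, cfg, w),
      f, cfg)
    blk_z <- bz$blk
    if (bz$accepted) {
      prm$zeta <- bz$state; f <- bz$value
      st <- state_apply_zeta(st, template, sg, prm$zeta, cfg, w)
    }
    if (do_p) {
      bp <- bb_step(
        prm$p, g$grad_p, blk_p,
        function(pm) state_value_p(st, template, sg, pm, cfg, K0),
        f, cfg)
      blk_p <- bp$blk
      if (bp$accepted) {
        prm$p <- bp$state; f <- bp$value
        st <- state_apply_p(st, template, sg, prm$p, cfg, K0)
      }
    }
    trace <- c(trace, f)
    dec <- f_before - f
    thresh <- if (cfg$relative_tol) cfg$tol * max(abs(f), 1) else cfg$tol
    if (dec < thresh) break
  }
  list(params = registration_params(prm$p, prm$zeta),
       registered = st$reg,
       trace = trace)
}
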