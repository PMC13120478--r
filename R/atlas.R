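# mean of a per-vertex field over each face's corners
face_means <- function(faces, v) {
  (v[faces[, 1]] + v[faces[, 2]] + v[faces[, 3]]) / 3
}

#' Estimate a mean-template atlas from a set of F-shapes
#'
#' Joint minimization of the atlas objective (see [evaluate_objective()])
#' over the template signal, optionally the template geometry, and all
#' per-subject momenta and signal increments, by block-coordinate adaptive
#' gradient descent with backtracking. Every block update is accepted only
#' if the full objective decreases, so the returned objective trace is
#' non-increasing; iteration stops when the decrease between consecutive
#' outer iterations falls below `cfg$tol` (as in the per-subject
#' registration) or after `max_outer` outer iterations. The procedure is
#' deterministic given its inputs and configuration.
#'
#' @param subjects List of >= 2 subject [fshape()]s (commensurate
#'   coordinates).
#' @param hypertemplate Initial template [fshape()], typically the zero
#'   signal mesh built at the template density.
#' @param cfg A [registration_config()].
#' @param max_outer Cap on outer iterations (defaults to `cfg$max_iter`).
#' @return An object of class `fshape_atlas`: `template` (final mean
#'   template), `registered` (list of registered F-shapes on template
#'   connectivity), `params` (list of [registration_params()]),
#'   `objective_trace`, and `config`.
#' @export
estimate_atlas <- function(subjects, hypertemplate, cfg,
                           max_outer = cfg$max_iter) {
  if (length(subjects) < 2L) stop("need at least 2 subjects", call. = FALSE)
  stopifnot(inherits(hypertemplate, "fshape"))
  n <- nrow(hypertemplate$mesh$vertices)
  template <- hypertemplate
  w <- vertex_area_weights(template$mesh)
  K0 <- gaussian_gram(template$mesh$vertices, cfg$sigma_V)
  sgeoms <- purrr::map(subjects, subject_geometry, cfg = cfg)
  N <- length(subjects)
  params <- purrr::map(seq_len(N), ~zero_params(n))
  states <- purrr::map(seq_len(N), function(i) {
    subject_state(template, sgeoms[[i]], params[[i]], cfg, w, K0)
  })
  blk_z <- purrr::map(seq_len(N), ~new_block(cfg$step_init * cfg$step_zeta))
  blk_p <- purrr::map(seq_len(N), ~new_block(cfg$step_init * cfg$step_p))
  blk_f <- new_block(cfg$step_init * cfg$step_f)
  blk_g <- new_block(cfg$step_init * cfg$step_x)

  f_term <- cfg$gamma_f * sum(template$signal^2 * w)
  term_vals <- purrr::map_dbl(states, "value")
  J <- f_term + sum(term_vals)
  trace <- J

  for (outer in seq_len(max_outer)) {
    J_before <- J
    gs_sum <- numeric(n)
    gx_sum <- matrix(0, n, 3L)
    # --- per-subject block updates -------------------------------------
    do_p <- (outer - 1L) %% cfg$p_every == 0L
    want_p <- do_p || cfg$update_geometry
    for (i in seq_len(N)) {
      g <- state_grad(states[[i]], template, sgeoms[[i]], params[[i]],
                      cfg, w, K0, want_p = want_p)
      if ((want_p && any(!is.finite(g$grad_p))) ||
            any(!is.finite(g$grad_zeta))) {
        stop("non-finite gradient in subject term ", i, call. = FALSE)
      }
      gs_sum <- gs_sum + g$grad_fm
      if (want_p) gx_sum <- gx_sum + g$grad_x0
      bz <- norm_step(
        params[[i]]$zeta, g$grad_zeta, blk_z[[i]],
        function(z) state_value_zeta(states[[i]], template, sgeoms[[i]],
                                     z, cfg, w),
        term_vals[i], cfg)
      blk_z[[i]] <- bz$blk
      if (bz$accepted) {
        params[[i]]$zeta <- bz$state; term_vals[i] <- bz$value
        states[[i]] <- state_apply_zeta(states[[i]], template, sgeoms[[i]],
                                        bz$state, cfg, w)
      }
      if (do_p) {
        bp <- bb_step(
          params[[i]]$p, g$grad_p, blk_p[[i]],
          function(pm) state_value_p(states[[i]], template, sgeoms[[i]],
                                     pm, cfg, K0),
          term_vals[i], cfg)
        blk_p[[i]] <- bp$blk
        if (bp$accepted) {
          params[[i]]$p <- bp$state; term_vals[i] <- bp$value
          states[[i]] <- state_apply_p(states[[i]], template, sgeoms[[i]],
                                       bp$state, cfg, K0)
        }
      }
    }
    J <- f_term + sum(term_vals)

    # --- template signal update (geometry frozen -> cached kernels) ----
    faces <- template$mesh$faces
    eval_fm <- function(fm) {
      at <- purrr::map_dbl(seq_len(N), function(i) {
        st <- states[[i]]
        fa_full <- face_means(faces, fm + params[[i]]$zeta)
        fa <- fa_full[st$gaa$ia]
        Saa <- sig_block(fa, fa, cfg)
        Sab <- sig_block(fa_full[st$gab$ia],
                         sgeoms[[i]]$fb[st$gab$ib], cfg)
        st$energy + st$pen + cfg$gamma_w *
          (sum(st$gaa$GK * Saa) - 2 * sum(st$gab$GK * Sab) +
             sgeoms[[i]]$self_inner)
      })
      cfg$gamma_f * sum(fm^2 * w) + sum(at)
    }
    grad_fm <- 2 * cfg$gamma_f * template$signal * w + gs_sum
    bf <- norm_step(template$signal, grad_fm, blk_f, eval_fm, J, cfg)
    blk_f <- bf$blk
    if (bf$accepted) {
      template$signal <- bf$state
      f_term <- cfg$gamma_f * sum(template$signal^2 * w)
      states <- purrr::map(seq_len(N), function(i) {
        state_apply_zeta(states[[i]], template, sgeoms[[i]],
                         params[[i]]$zeta, cfg, w)
      })
      term_vals <- purrr::map_dbl(states, "value")
      J <- f_term + sum(term_vals)
    }

    # --- template geometry update (optional) ---------------------------
    if (cfg$update_geometry) {
      grad_x <- gx_sum  # area weights treated as frozen during this step
      eval_geom <- function(xv) {
        tm <- template; tm$mesh$vertices <- xv
        Kx <- gaussian_gram(xv, cfg$sigma_V)
        wx <- vertex_area_weights(tm$mesh)
        tv <- purrr::map_dbl(seq_len(N), function(i) {
          subject_term(tm, sgeoms[[i]], params[[i]], cfg, wx, Kx)$value
        })
        cfg$gamma_f * sum(tm$signal^2 * wx) + sum(tv)
      }
      bg <- bb_step(template$mesh$vertices, grad_x, blk_g, eval_geom, J, cfg)
      blk_g <- bg$blk
      if (bg$accepted) {
        template$mesh$vertices <- bg$state
        J <- bg$value
        w <- vertex_area_weights(template$mesh)
        K0 <- gaussian_gram(template$mesh$vertices, cfg$sigma_V)
        f_term <- cfg$gamma_f * sum(template$signal^2 * w)
        states <- purrr::map(seq_len(N), function(i) {
          subject_state(template, sgeoms[[i]], params[[i]], cfg, w, K0)
        })
        term_vals <- purrr::map_dbl(states, "value")
        J <- f_term + sum(term_vals)
      }
    }

    trace <- c(trace, J)
    if (J > J_before + 1e-9 * max(1, abs(J_before))) {
      stop("atlas objective increased; offending outer iteration ", outer,
           call. = FALSE)
    }
    dec <- J_before - J
    thresh <- if (cfg$relative_tol) cfg$tol * max(abs(J), 1) else cfg$tol
    if (dec < thresh) break
  }

  registered <- purrr::map(seq_len(N), function(i) {
    apply_params(template, params[[i]], cfg)
  })
  structure(
    list(template = template, registered = registered, params = params,
         objective_trace = trace, config = cfg),
    class = "fshape_atlas"
  )
}

#' @export
print.fshape_atlas <- function(x, ...) {
  cat(sprintf(
    "<fshape_atlas> %d subjects, %d template vertices; J %.4g -> %.4g in %d iterations\n",
    length(x$registered), nrow(x$template$mesh$vertices),
    x$objective_trace[1], utils::tail(x$objective_trace, 1),
    length(x$objective_trace) - 1L
  ))
  invisible(x)
}

#' Residual thickness features from an atlas
#'
#' Row i holds `f_m(v) - f_i~(v)` over the template vertices v: the offset
#' between the mean-template signal and subject i's registered signal. This
#' matrix (with labels) is the classification feature set.
#'
#' @param atlas An `fshape_atlas` from [estimate_atlas()], or a list with
#'   `template` and `registered` in the same layout.
#' @param labels Optional per-subject labels to attach.
#' @return An object of class `residual_set`: `matrix` (N x M), `labels`,
#'   `vertex_map` (template lattice indices).
#' @export
compute_residuals <- function(atlas, labels = NULL) {
  template <- atlas$template
  M <- nrow(template$mesh$vertices)
  rows <- purrr::map(atlas$registered, function(r) {
    if (length(r$signal) != M ||
          !identical(dim(r$mesh$faces), dim(template$mesh$faces)) ||
          !all(r$mesh$faces == template$mesh$faces)) {
      stop("registered F-shape does not share template connectivity",
           call. = FALSE)
    }
    template$signal - r$signal
  })
  mat <- do.call(rbind, rows)
  structure(
    list(matrix = mat, labels = labels, vertex_map = template$mesh$lattice),
    class = "residual_set"
  )
}

#' @export
print.residual_set <- function(x, ...) {
  cat(sprintf("<residual_set> %d subjects x %d vertices\n",
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the objective trace of an atlas
#'
#' @param x An `fshape_atlas`.
#' @param ... Unused.
#' @return Tibble with `iteration` and `objective`.
#' @method tidy fshape_atlas
#' @export
tidy.fshape_atlas <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$objective_trace) - 1L,
                 objective = x$objective_trace)
}

#' One-row summary of an atlas fit
#'
#' @param x An `fshape_atlas`.
#' @param ... Unused.
#' @return One-row tibble.
#' @method glance fshape_atlas
#' @export
glance.fshape_atlas <- function(x, ...) {
  tr <- x$objective_trace
  tibble::tibble(
    n_subjects = length(x$registered),
    n_vertices = nrow(x$template$mesh$vertices),
    iterations = length(tr) - 1L,
    objective_initial = tr[1],
    objective_final = tr[length(tr)]
  )
}

#' Objective-trace plot for an atlas
#' @param object An `fshape_atlas`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fshape_atlas
#' @export
autoplot.fshape_atlas <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$iteration, .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "outer iteration", y = "objective J")
}
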