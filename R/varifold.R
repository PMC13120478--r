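# Face-level geometry of an fshape: centroids, (unnormalized) normals,
# their lengths, areas, and the mean vertex signal per face. Zero-area
# faces are flagged; varifold sums skip them.
face_geometry <- function(fs) {
  V <- fs$mesh$vertices; F <- fs$mesh$faces
  V1 <- V[F[, 1], , drop = FALSE]
  V2 <- V[F[, 2], , drop = FALSE]
  V3 <- V[F[, 3], , drop = FALSE]
  C <- (V1 + V2 + V3) / 3
  e1 <- V2 - V1; e2 <- V3 - V1
  N <- cross3(e1, e2)
  nl <- sqrt(rowSums(N * N))
  fb <- (fs$signal[F[, 1]] + fs$signal[F[, 2]] + fs$signal[F[, 3]]) / 3
  ok <- nl > 0
  if (!all(ok)) {
    warning(sprintf("skipping %d zero-area face(s) in varifold computation",
                    sum(!ok)), call. = FALSE)
  }
  list(C = C, N = N, nl = nl, area = nl / 2, fb = fb, ok = ok,
       e1 = e1, e2 = e2, faces = F, nv = nrow(V))
}

# filtered (non-degenerate) views of the face arrays
face_sub <- function(g) {
  ia <- which(g$ok)
  list(C = g$C[ia, , drop = FALSE], N = g$N[ia, , drop = FALSE],
       nl = g$nl[ia], fb = g$fb[ia], ia = ia)
}

# geometry-only kernel block (position kernel x squared-cosine x areas)
geom_block <- function(ga, gb, cfg) {
  a <- face_sub(ga); b <- face_sub(gb)
  list(GK = cpp_geom_block(a$C, a$N, a$nl, b$C, b$N, b$nl, cfg$sigma_W^2),
       ia = a$ia, ib = b$ia)
}

# signal kernel between two mean-signal vectors
sig_block <- function(fa, fb, cfg) {
  cpp_sig_block(fa, fb, cfg$sigma_sig^2)
}

fvarifold_inner <- function(ga, gb, cfg) {
  a <- face_sub(ga); b <- face_sub(gb)
  cpp_inner_value(a$C, a$N, a$nl, a$fb, b$C, b$N, b$nl, b$fb,
                  cfg$sigma_W^2, cfg$sigma_sig^2)
}

# <a, a> via pair symmetry (identical to fvarifold_inner(ga, ga, cfg))
fvarifold_inner_self <- function(ga, cfg) {
  a <- face_sub(ga)
  cpp_inner_value_sym(a$C, a$N, a$nl, a$fb, cfg$sigma_W^2, cfg$sigma_sig^2)
}

# symmetric self geometry kernel
geom_block_self <- function(ga, cfg) {
  a <- face_sub(ga)
  list(GK = cpp_geom_block_sym(a$C, a$N, a$nl, cfg$sigma_W^2),
       ia = a$ia, ib = a$ia)
}

#' Functional-varifold dissimilarity between two F-shapes
#'
#' The squared kernel-norm distance `A(a, b) = <a,a> - 2<a,b> + <b,b>` where
#' the inner product sums, over all face pairs, a Gaussian kernel on face
#' centroids (width `sigma_W`), the squared cosine of the angle between face
#' normals, a Gaussian kernel on mean face signals (width `sigma_sig`), and
#' the product of the two face areas. Correspondence-free: the two meshes
#' need not share connectivity. Non-negative, symmetric, and zero on
#' identical F-shapes. Zero-area faces are skipped with a warning.
#'
#' @param a,b [fshape()] objects with commensurate coordinates.
#' @param cfg A [registration_config()].
#' @return Non-negative scalar.
#' @export
fvarifold_dissimilarity <- function(a, b, cfg) {
  ga <- face_geometry(a); gb <- face_geometry(b)
  val <- fvarifold_inner_self(ga, cfg) - 2 * fvarifold_inner(ga, gb, cfg) +
    fvarifold_inner_self(gb, cfg)
  max(val, 0)
}

# chain face-level gradients (centroid, normal, mean-signal) of a's faces
# back to a's vertices and per-vertex signal
chain_face_grads <- function(ga, ia, gC, gN, gfb) {
  nf <- nrow(ga$faces)
  gC_full <- matrix(0, nf, 3L); gC_full[ia, ] <- gC
  gN_full <- matrix(0, nf, 3L); gN_full[ia, ] <- gN
  gfb_full <- numeric(nf); gfb_full[ia] <- gfb
  F <- ga$faces
  gV <- matrix(0, ga$nv, 3L)
  gs <- numeric(ga$nv)
  for (c in 1:3) {
    add <- rowsum(gC_full / 3, F[, c])
    idx <- as.integer(rownames(add))
    gV[idx, ] <- gV[idx, ] + add
    adds <- rowsum(gfb_full / 3, F[, c])
    gs[idx] <- gs[idx] + adds
  }
  # normal N = e1 x e2 with e1 = V2-V1, e2 = V3-V1:
  # dL/dV2 = e2 x gN, dL/dV3 = gN x e1, dL/dV1 = -(dL/dV2 + dL/dV3)
  d2 <- cross3(ga$e2, gN_full)
  d3 <- cross3(gN_full, ga$e1)
  d1 <- -(d2 + d3)
  for (c in 1:3) {
    dd <- switch(c, d1, d2, d3)
    add <- rowsum(dd, F[, c])
    idx <- as.integer(rownames(add))
    gV[idx, ] <- gV[idx, ] + add
  }
  list(gV = gV, gs = gs)
}

# value and gradient of <a, b> with respect to a's vertices and signal
# (first slot only; for d<a,a>/da use twice this by symmetry)
varifold_inner_grad <- function(ga, gb, cfg) {
  a <- face_sub(ga); b <- face_sub(gb)
  bg <- cpp_block_grad(a$C, a$N, a$nl, a$fb, b$C, b$N, b$nl, b$fb,
                       cfg$sigma_W^2, cfg$sigma_sig^2)
  out <- chain_face_grads(ga, a$ia, bg$gC, bg$gN, bg$gfb)
  out$value <- bg$value
  out
}

# first-slot gradient of <a, a> via pair symmetry
varifold_inner_grad_self <- function(ga, cfg) {
  a <- face_sub(ga)
  bg <- cpp_block_grad_sym(a$C, a$N, a$nl, a$fb,
                           cfg$sigma_W^2, cfg$sigma_sig^2)
  out <- chain_face_grads(ga, a$ia, bg$gC, bg$gN, bg$gfb)
  out$value <- bg$value
  out
}

# Gradient (and value) of A(a, b) with respect to a's vertices and signal
# (b fixed).
fvarifold_grad <- function(a, b, cfg) {
  ga <- face_geometry(a); gb <- face_geometry(b)
  gaa <- varifold_inner_grad_self(ga, cfg)
  gab <- varifold_inner_grad(ga, gb, cfg)
  list(gV = 2 * gaa$gV - 2 * gab$gV,
       gs = 2 * gaa$gs - 2 * gab$gs,
       value = gaa$value - 2 * gab$value + fvarifold_inner_self(gb, cfg))
}

# Per-vertex share of total mesh area (one third of each incident face),
# used as the L2 quadrature weight on the template.
vertex_area_weights <- function(mesh) {
  fsg <- fshape(mesh, numeric(nrow(mesh$vertices)))
  g <- face_geometry(fsg)
  w <- numeric(nrow(mesh$vertices))
  for (c in 1:3) {
    add <- rowsum(g$area / 3, mesh$faces[, c])
    w[as.integer(rownames(add))] <- w[as.integer(rownames(add))] + add
  }
  w
}
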