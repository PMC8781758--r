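# Plane-stress finite-element verification of the graded-beam model.
#
# Structured 4-node bilinear quadrilateral mesh over the beam side face,
# isotropic plane stress with the through-thickness graded modulus sampled
# at element centroids, simply supported at the outer contacts, point loads
# F/2 at the inner contacts. The neutral layer is never prescribed: it
# emerges from the solve and is located as the zero crossing of the
# longitudinal strain at mid-span.

#' Structured quadrilateral beam mesh
#'
#' Rectangular grid of `nx` by `ny` bilinear quadrilaterals over the outer
#' span (length b + 2a) times the beam height. `ny` must be even so a node
#' row lies at mid-depth, and the four contact x-positions (0, a, a + b,
#' b + 2a) must land exactly on node columns.
#'
#' @param geom A [specimen_geometry()].
#' @param nx,ny Element counts along the span and through the height.
#' @return A list of class `beam_mesh`: node `coords` ((nx+1)(ny+1) x 2),
#'   `conn` (element-node connectivity, counter-clockwise), `nx`, `ny`,
#'   `dx`, `dy`, `length_L`, contact node indices.
#' @export
build_mesh <- function(geom, nx, ny) {
  stopifnot(inherits(geom, "specimen_geometry"))
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 2L || ny < 2L) stop("build_mesh: need nx, ny >= 2")
  if (ny %% 2L != 0L) stop("build_mesh: 'ny' must be even (mid-depth node row)")
  L <- geom$loading_span_b + 2 * geom$lever_arm_a
  h <- geom$height_h
  dx <- L / nx; dy <- h / ny
  xc <- c(0, geom$lever_arm_a, geom$lever_arm_a + geom$loading_span_b, L)
  k <- xc / dx
  if (any(abs(k - round(k)) > 1e-9))
    stop(sprintf(paste0(
      "build_mesh: contact x-positions (%s mm) do not fall on node columns ",
      "with nx = %d; choose nx so that nx*a/(b+2a) and nx*(a+b)/(b+2a) are ",
      "integers (e.g. a multiple of %d for the default geometry)"),
      paste(xc, collapse = ", "), nx, 21L))
  nnx <- nx + 1L; nny <- ny + 1L
  xs <- seq(0, L, length.out = nnx)
  ys <- seq(0, h, length.out = nny)
  coords <- cbind(x = rep(xs, times = nny), y = rep(ys, each = nnx))
  nid <- function(i, j) (j - 1L) * nnx + i
  e <- 0L
  conn <- matrix(0L, nx * ny, 4L)
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    e <- e + 1L
    conn[e, ] <- c(nid(i, j), nid(i + 1L, j), nid(i + 1L, j + 1L), nid(i, j + 1L))
  }
  structure(list(
    coords = coords, conn = conn, nx = nx, ny = ny, dx = dx, dy = dy,
    length_L = L, geom = geom,
    support_nodes = c(nid(1L, 1L), nid(nnx, 1L)),
    load_nodes = c(nid(as.integer(round(k[2])) + 1L, nny),
                   nid(as.integer(round(k[3])) + 1L, nny))),
    class = "beam_mesh")
}

# 8x8 stiffness of a dx-by-dy rectangular bilinear quad, unit modulus,
# plane stress, 2x2 Gauss quadrature. Scales linearly with E.
.ke_quad_unit <- function(dx, dy, nu, thickness) {
  D <- 1 / (1 - nu^2) * matrix(c(1, nu, 0, nu, 1, 0, 0, 0, (1 - nu) / 2), 3, 3)
  gp <- c(-1, 1) / sqrt(3)
  K <- matrix(0, 8, 8)
  for (xi in gp) for (eta in gp) {
    dNdx <- c(-(1 - eta), (1 - eta), (1 + eta), -(1 + eta)) / 4 * 2 / dx
    dNdy <- c(-(1 - xi), -(1 + xi), (1 + xi), (1 - xi)) / 4 * 2 / dy
    B <- matrix(0, 3, 8)
    B[1, seq(1, 8, 2)] <- dNdx
    B[2, seq(2, 8, 2)] <- dNdy
    B[3, seq(1, 8, 2)] <- dNdy
    B[3, seq(2, 8, 2)] <- dNdx
    K <- K + t(B) %*% D %*% B * (dx * dy / 4) * thickness
  }
  K
}

#' Low-level linear elastic solve on a beam mesh
#'
#' Assembles the global plane-stress stiffness from per-element moduli and
#' solves `K u = f` under homogeneous Dirichlet constraints. Exposed so that
#' element-level verification (patch tests, constant-strain states) can use
#' the same assembly path as the beam analysis.
#'
#' @param mesh A [build_mesh()] mesh.
#' @param E_elem Per-element modulus vector (MPa), element order as in
#'   `mesh$conn`.
#' @param nu Poisson's ratio.
#' @param thickness Out-of-plane thickness (mm).
#' @param fixed_dofs Integer dof indices held at zero (dofs are
#'   `2*node - 1` for x, `2*node` for y).
#' @param forces Global nodal force vector (N), length `2 * n_nodes`.
#' @return A list: `u` (displacements, mm), `reactions` (at the fixed dofs).
#' @export
fem_solve <- function(mesh, E_elem, nu, thickness, fixed_dofs, forces) {
  stopifnot(inherits(mesh, "beam_mesh"))
  nelem <- nrow(mesh$conn)
  if (length(E_elem) != nelem) stop("fem_solve: 'E_elem' length mismatch")
  if (any(E_elem <= 0)) stop("fem_solve: non-positive element modulus")
  ndof <- 2L * nrow(mesh$coords)
  if (length(forces) != ndof) stop("fem_solve: 'forces' length mismatch")
  Ke <- .ke_quad_unit(mesh$dx, mesh$dy, nu, thickness)
  conn <- mesh$conn
  edof <- cbind(2L * conn[, 1] - 1L, 2L * conn[, 1],
                2L * conn[, 2] - 1L, 2L * conn[, 2],
                2L * conn[, 3] - 1L, 2L * conn[, 3],
                2L * conn[, 4] - 1L, 2L * conn[, 4])
  ii <- edof[, rep(1:8, times = 8)]
  jj <- edof[, rep(1:8, each = 8)]
  xx <- E_elem %o% as.vector(Ke)
  K <- Matrix::sparseMatrix(i = as.vector(ii), j = as.vector(jj),
                            x = as.vector(xx), dims = c(ndof, ndof))
  free <- setdiff(seq_len(ndof), fixed_dofs)
  u <- numeric(ndof)
  sol <- tryCatch(Matrix::solve(K[free, free], forces[free]),
                  error = function(e)
                    stop("fem_solve: singular system; check boundary conditions"))
  u[free] <- as.vector(sol)
  reactions <- as.vector(K[fixed_dofs, , drop = FALSE] %*% u) - forces[fixed_dofs]
  list(u = u, reactions = reactions)
}

# longitudinal strain at node-row heights on the vertical line x = x_station;
# bilinear elements have eps_xx independent of xi, so edge values are exact
# element fields. Interior rows average the two adjacent element rows.
.strain_profile <- function(mesh, u, x_station) {
  nnx <- mesh$nx + 1L
  ic <- min(max(ceiling(x_station / mesh$dx - 1e-12), 1L), mesh$nx)
  nid <- function(i, j) (j - 1L) * nnx + i
  bot <- top <- numeric(mesh$ny)
  for (j in seq_len(mesh$ny)) {
    nds <- c(nid(ic, j), nid(ic + 1L, j), nid(ic + 1L, j + 1L), nid(ic, j + 1L))
    ux <- u[2L * nds - 1L]
    bot[j] <- (ux[2] - ux[1]) / mesh$dx
    top[j] <- (ux[3] - ux[4]) / mesh$dx
  }
  data.frame(y_mm = seq(0, mesh$geom$height_h, length.out = mesh$ny + 1L),
             eps_xx = c(bot[1], (bot[-1] + top[-mesh$ny]) / 2, top[mesh$ny]))
}

#' Solve the four-point-bent graded beam
#'
#' Per-element isotropic plane-stress stiffness with the modulus evaluated by
#' [modulus_profile()] at the element centroid height relative to the
#' analytically determined neutral axis; vertical supports at the outer
#' contacts (plus one horizontal restraint), downward loads F/2 at the inner
#' contacts. The zero-strain line is not prescribed anywhere — it emerges
#' from the solve.
#'
#' @param mesh A [build_mesh()] mesh.
#' @param model A [gradient_modulus_model()] (use zero gradients for a
#'   homogeneous beam).
#' @param axis A neutral-axis state giving the height `h_T` of the axis above
#'   the bottom face used to position the modulus profile.
#' @param load_F Total machine load F (N); see [four_point_load()].
#' @param nu Poisson's ratio (default 0.3).
#' @return A list of class `fem_result`: `u`, `profile` (mid-span
#'   longitudinal strain vs height), `eps_top`, `eps_bottom` (surface
#'   strains at mid-span), `neutral_axis_y` (mm from the bottom face),
#'   `reactions`, `reaction_balance` (|sum R_y + F| / F), `mesh`.
#' @export
assemble_and_solve <- function(mesh, model, axis, load_F, nu = 0.3) {
  stopifnot(inherits(mesh, "beam_mesh"),
            inherits(model, "gradient_modulus_model"))
  if (load_F <= 0) stop("assemble_and_solve: 'load_F' must be positive")
  # element centroid heights -> modulus, measured from the analytical axis
  jrow <- rep(seq_len(mesh$ny), each = mesh$nx)
  yc <- (jrow - 0.5) * mesh$dy - axis$h_T
  E_elem <- modulus_profile(model, yc)
  ndof <- 2L * nrow(mesh$coords)
  forces <- numeric(ndof)
  forces[2L * mesh$load_nodes] <- -load_F / 2
  fixed <- c(2L * mesh$support_nodes,          # vertical at both outer contacts
             2L * mesh$support_nodes[1] - 1L)  # horizontal at one
  sol <- fem_solve(mesh, E_elem, nu, mesh$geom$width_w, fixed, forces)
  prof <- .strain_profile(mesh, sol$u, mesh$length_L / 2)
  vert <- sol$reactions[seq_len(2)]
  structure(list(
    u = sol$u, profile = prof,
    eps_top = prof$eps_xx[nrow(prof)], eps_bottom = prof$eps_xx[1],
    neutral_axis_y = extract_neutral_axis(prof),
    reactions = sol$reactions,
    reaction_balance = abs(sum(vert) - load_F) / load_F,
    E_elem = E_elem, mesh = mesh), class = "fem_result")
}

#' Locate the neutral axis in a longitudinal strain profile
#'
#' Height (mm from the bottom face) of the sign change of the longitudinal
#' strain, by linear interpolation between adjacent sampling rows. Errors if
#' the section is fully tensile or fully compressive.
#'
#' @param profile Either a `fem_result` or a data frame with columns `y_mm`
#'   and `eps_xx`.
#' @return Neutral-axis height (mm).
#' @export
extract_neutral_axis <- function(profile) {
  if (inherits(profile, "fem_result")) profile <- profile$profile
  y <- profile$y_mm; e <- profile$eps_xx
  i <- which(e[-length(e)] * e[-1] <= 0 & (e[-length(e)] != 0 | e[-1] != 0))
  if (!length(i)) {
    if (all(e == 0)) stop("extract_neutral_axis: zero strain field")
    stop("extract_neutral_axis: no sign change (fully tensile or compressive section)")
  }
  i <- i[1]
  y[i] + (y[i + 1] - y[i]) * e[i] / (e[i] - e[i + 1])
}

#' Compare FEM and analytical neutral-axis positions along a trajectory
#'
#' For every solved record of a trajectory result, rebuilds the graded
#' section in the finite-element model, solves the four-point bend at the
#' measurement load, and compares the emergent zero-strain height with the
#' analytical h_T. Deviations are in percent of the beam height.
#'
#' @param traj_result An [analyze_trajectory()] result.
#' @param nx,ny Mesh resolution (reference: 126 x 24).
#' @param nu Poisson's ratio.
#' @return A data frame: `t`, `h_T_analytical_mm`, `h_T_fem_mm`,
#'   `deviation_pct`, plus mid-span surface strains from both methods
#'   (microstrain).
#' @export
compare_fem_analytical <- function(traj_result, nx = 126L, ny = 24L, nu = 0.3) {
  stopifnot(inherits(traj_result, "trajectory_result"))
  geom <- attr(traj_result, "geom")
  E0 <- attr(traj_result, "E0")
  h_ref <- attr(traj_result, "h_ref")
  moment_M <- attr(traj_result, "moment_M")
  load_F <- 2 * moment_M / geom$lever_arm_a
  mesh <- build_mesh(geom, nx, ny)
  rows <- lapply(which(traj_result$solved), function(i) {
    model <- gradient_modulus_model(E0, traj_result$alpha_C[i],
                                    traj_result$alpha_T[i], h_ref)
    axis <- structure(list(h_C = traj_result$h_C_mm[i],
                           h_T = traj_result$h_T_mm[i],
                           rho = traj_result$rho_mm[i]),
                      class = "neutral_axis_state")
    fem <- assemble_and_solve(mesh, model, axis, load_F, nu)
    data.frame(
      t = traj_result$t[i],
      h_T_analytical_mm = axis$h_T,
      h_T_fem_mm = fem$neutral_axis_y,
      deviation_pct = 100 * (fem$neutral_axis_y - axis$h_T) / geom$height_h,
      eps_T_fem_ue = fem$eps_bottom * 1e6,
      eps_C_fem_ue = -fem$eps_top * 1e6,
      eps_T_analytical_ue = traj_result$eps_T_ue[i],
      eps_C_analytical_ue = traj_result$eps_C_ue[i])
  })
  do.call(rbind, rows)
}
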