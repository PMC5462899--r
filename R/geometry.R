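#' Synapse geometry for the cleft simulation
#'
#' The presynaptic bouton is a box (default 1 x 1 x 0.5 um) whose underside
#' sits one cleft width above the postsynaptic membrane, which is modelled
#' as a large plane (default 64 x 64 um) carrying the receptor cluster (a
#' centred square, default 200 nm side). Molecules diffusing beyond the
#' escape radius are removed from the simulation.
#'
#' @param bouton_width,bouton_depth,bouton_height bouton box dimensions, um.
#' @param cleft_width synaptic cleft width in nm (default 20).
#' @param plane_side side length of the postsynaptic plane, um.
#' @param cluster_side side of the receptor cluster square in nm
#'   (default 200).
#' @param escape_radius removal radius in um, measured from the cluster
#'   centre (default 5).
#' @return An object of class `synapse_geometry`; all lengths stored in um.
#' @export
synapse_geometry <- function(bouton_width = 1, bouton_depth = 1,
                             bouton_height = 0.5, cleft_width = 20,
                             plane_side = 64, cluster_side = 200,
                             escape_radius = 5) {
  cleft <- cleft_width / 1000
  cluster <- cluster_side / 1000
  if (cleft <= 0) stop("cleft_width must be > 0")
  if (cluster > plane_side)
    stop("cluster_side must not exceed the postsynaptic plane side")
  half_diag <- sqrt(bouton_width^2 + bouton_depth^2) / 2
  if (escape_radius <= half_diag)
    stop("escape_radius must exceed the bouton footprint half-diagonal (",
         signif(half_diag, 3), " um)")
  structure(list(bouton = c(width = unname(bouton_width),
                            depth = unname(bouton_depth),
                            height = unname(bouton_height)),
                 cleft = cleft, plane_side = plane_side,
                 cluster = cluster, escape_radius = escape_radius),
            class = "synapse_geometry")
}

#' @exportS3Method base::print
print.synapse_geometry <- function(x, ...) {
  cat("Synapse geometry: bouton ", x$bouton["width"], "x", x$bouton["depth"],
      "x", x$bouton["height"], " um, cleft ", x$cleft * 1000,
      " nm, cluster ", x$cluster * 1000, " nm, escape radius ",
      x$escape_radius, " um\n", sep = "")
  invisible(x)
}

#' Place receptors on the postsynaptic plane
#'
#' Receptors are placed within the centred cluster square, either on a
#' regular grid (default; guarantees non-overlapping capture disks) or
#' uniformly at random.
#'
#' @param geometry a [synapse_geometry()].
#' @param n number of receptors (>= 0).
#' @param arrangement `"grid"` or `"uniform_random"`.
#' @param seed integer seed (required for `"uniform_random"`).
#' @param capture_radius receptor capture radius in nm (used for the grid
#'   packing check; default 5).
#' @return n x 2 matrix of x/y coordinates in um (cluster centred on the
#'   origin), with attributes `arrangement`, `spacing` and `grid_m`.
#' @export
place_receptors <- function(geometry, n,
                            arrangement = c("grid", "uniform_random"),
                            seed = NULL, capture_radius = 5) {
  arrangement <- match.arg(arrangement)
  if (n < 0) stop("n must be >= 0")
  side <- geometry$cluster
  if (n == 0) {
    out <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y")))
    attr(out, "arrangement") <- arrangement
    return(out)
  }
  if (arrangement == "grid") {
    m <- ceiling(sqrt(n))
    spacing <- side / m
    if (spacing < 2 * capture_radius / 1000)
      stop("grid packing failure: ", n, " receptors with capture radius ",
           capture_radius, " nm do not fit a ", side * 1000,
           " nm cluster without overlap")
    g <- (seq_len(m) - 0.5) / m * side - side / 2
    out <- as.matrix(expand.grid(x = g, y = g))[seq_len(n), , drop = FALSE]
    attr(out, "spacing") <- spacing
    attr(out, "grid_m") <- m
  } else {
    if (is.null(seed)) stop("seed required for uniform_random arrangement")
    u <- local_runif(2 * n, seed)
    out <- cbind(x = (u[seq_len(n)] - 0.5) * side,
                 y = (u[n + seq_len(n)] - 0.5) * side)
  }
  rownames(out) <- NULL
  attr(out, "arrangement") <- arrangement
  out
}

# deterministic uniforms independent of R's global RNG state
local_runif <- function(n, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  stats::runif(n)
}

# molecules per um^3 at 1 mM
AVOGADRO_UM3_MM <- 6.02214076e5

#' Calibrate the per-encounter binding probability
#'
#' Bridges the macroscopic binding rate constant to the microscopic
#' per-crossing acceptance probability of the particle simulator. A
#' molecule whose diffusion step carries it through the receptor plane
#' within the capture radius of a free site binds with probability
#'
#' \deqn{p = \frac{k_{on}}{\nu r^2} \sqrt{\frac{dt}{\pi D}}}
#'
#' where \eqn{\nu} is the number density of a 1 mM solution
#' (6.022e5 um^-3). The formula follows from equating the mass-action flux
#' `k_on * C` per receptor with the product of the Brownian plane-crossing
#' flux per unit area per step (`n sqrt(D dt / pi)`, for number density n)
#' and the capture disk area; a well-mixed simulation then reproduces
#' `k_on * C * N_receptors` independently of dt (p scales with sqrt(dt),
#' crossings per unit time with 1/sqrt(dt)).
#'
#' @param k_on macroscopic binding rate constant, 1/mM/ms.
#' @param D diffusion coefficient, um^2/ms.
#' @param dt diffusion step, ms.
#' @param capture_radius receptor capture radius in nm.
#' @return Probability in `[0, 1]`; errors if the combination requires a
#'   probability above 1 (use a smaller dt).
#' @export
calibrate_binding_probability <- function(k_on, D, dt, capture_radius = 5) {
  if (any(c(D, dt, capture_radius) <= 0))
    stop("D, dt and capture_radius must be > 0")
  if (k_on < 0) stop("k_on must be >= 0")
  r <- capture_radius / 1000
  p <- k_on / AVOGADRO_UM3_MM * sqrt(dt / (pi * D)) / r^2
  if (p > 1)
    stop("calibrated binding probability ", signif(p, 4),
         " exceeds 1; decrease dt (p scales with sqrt(dt))")
  p
}

#' Validate the binding calibration against mass action
#'
#' Simulates a closed reflecting box with uniformly distributed molecules
#' and a grid of receptor disks on its floor, counting plane crossings
#' accepted with the calibrated probability (binding is non-consuming, so
#' the concentration stays fixed). Returns the observed binding rate next
#' to the well-mixed mass-action prediction `k_on * C * N_receptors`.
#'
#' @inheritParams calibrate_binding_probability
#' @param n_molecules molecules in the box.
#' @param n_receptors_side receptors per side of the floor grid.
#' @param box_side,box_height box dimensions in um.
#' @param t_total simulated time in ms.
#' @param seed integer seed.
#' @return List with `observed_rate` and `expected_rate` (bindings/ms),
#'   `ratio`, `concentration_mM` and `n_bindings`.
#' @export
validate_binding_calibration <- function(k_on, D, dt,
                                         capture_radius = 5,
                                         n_molecules = 20000,
                                         n_receptors_side = 10,
                                         box_side = 0.5,
                                         box_height = 0.5,
                                         t_total = 0.05, seed = 1) {
  p <- calibrate_binding_probability(k_on, D, dt, capture_radius)
  g <- (seq_len(n_receptors_side) - 0.5) / n_receptors_side * box_side
  rec <- as.matrix(expand.grid(x = g, y = g))
  n_steps <- max(1L, as.integer(round(t_total / dt)))
  res <- cpp_binding_flux(box_side, box_height, as.integer(n_molecules),
                          rec[, 1], rec[, 2], capture_radius / 1000, p,
                          D, dt, n_steps, as.double(seed))
  conc <- n_molecules / (box_side^2 * box_height) / AVOGADRO_UM3_MM
  obs <- res$bindings / res$time_ms
  exp_rate <- k_on * conc * nrow(rec)
  list(observed_rate = obs, expected_rate = exp_rate,
       ratio = obs / exp_rate, concentration_mM = conc,
       n_bindings = res$bindings)
}
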