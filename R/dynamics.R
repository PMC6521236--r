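# Replicator dynamics with variable population size: fitness, right-hand
# side, trajectory integration, and steady-state solvers.
#
# Composition dynamics:  dx_i/dt = N^(c-1) * (f_i x_i^c - x_i * sum_j f_j x_j^c)
# Population size:       dN/dt   = N^c * sum_j f_j x_j^c - d N
# with fitness f = A x + h. Note the N^(c-1) prefactor only rescales time for
# the composition equations, which is why the predicted composition is
# insensitive to N0 and d.

#' @include AllClasses.R
NULL

#' Fitness vector of a community state
#'
#' \code{f = A x + h}: each species' driving force is the interaction benefit
#' it draws from the current composition plus its environmental offset.
#'
#' @param model an \code{\link{FCPModel}}.
#' @param x composition vector on the simplex.
#' @return numeric fitness vector, one entry per species.
#' @export
communityFitness <- function(model, x) {
  if (length(x) != nrow(model@A))
    stop("composition length does not match the model: ", length(x),
         " vs ", nrow(model@A))
  as.vector(model@A %*% x) + model@h
}

#' Time derivatives of composition and population size
#'
#' Evaluates the replicator right-hand side at a state. For \code{c = 1} the
#' composition equation reduces to the classical replicator equation
#' \code{dx_i = x_i (f_i - fbar)}. Powers \code{x^c} are taken after clipping
#' negative round-off to zero (the continuous extension \code{0^c = 0}).
#'
#' @param model an \code{\link{FCPModel}}.
#' @param x composition vector on the simplex.
#' @param N total population size (> 0).
#' @return list with elements \code{dx} (vector) and \code{dN} (scalar).
#' @export
fcpDerivatives <- function(model, x, N) {
  if (N <= 0) stop("population size must be positive")
  f <- communityFitness(model, x)
  xs <- pmax(x, 0)
  xc <- xs^model@c
  phi <- sum(f * xc)
  list(dx = N^(model@c - 1) * (f * xc - xs * phi),
       dN = N^model@c * phi - model@d * N)
}

.rhs_desolve <- function(t, y, parms) {
  num <- nrow(parms$A)
  x <- pmax(y[seq_len(num)], 0)
  N <- max(y[num + 1L], .Machine$double.xmin)
  f <- as.vector(parms$A %*% x) + parms$h
  xc <- x^parms$c
  phi <- sum(f * xc)
  list(c(N^(parms$c - 1) * (f * xc - x * phi), N^parms$c * phi - parms$d * N))
}

#' Integrate the community dynamics to (compositional) steady state
#'
#' Adaptive, stiff-capable integration (\code{deSolve::lsoda}) in reporting
#' chunks. The run is declared converged when the largest compositional
#' derivative stays below \code{tol} across one whole reporting interval;
#' the total population size N need not equilibrate, since predictions use
#' the composition only. The final composition is renormalised onto the
#' simplex at machine precision.
#'
#' @param model an \code{\link{FCPModel}}.
#' @param x0 initial composition on the simplex.
#' @param N0 initial population size (default 1000; the composition is
#'   insensitive to it).
#' @param tMax integration horizon (default 500).
#' @param tol steady-state tolerance on \code{max |dx_i|} (default 1e-8).
#' @param chunk length of one reporting interval (default 25).
#' @return a \code{\link{Trajectory}}.
#' @export
integrateFCP <- function(model, x0, N0 = 1000, tMax = 500, tol = 1e-8,
                         chunk = 25) {
  num <- nrow(model@A)
  if (length(x0) != num) stop("x0 length does not match the model")
  if (abs(sum(x0) - 1) > 1e-6) stop("x0 must lie on the simplex")
  if (N0 <= 0) stop("N0 must be positive")
  parms <- list(A = model@A, h = model@h, c = model@c, d = model@d)
  y <- c(x0 / sum(x0), N0)
  times <- 0
  xs <- matrix(y[seq_len(num)], 1)
  Ns <- N0
  t0 <- 0
  converged <- FALSE
  tConv <- NA_real_
  while (t0 < tMax) {
    t1 <- min(t0 + chunk, tMax)
    ts <- seq(t0, t1, length.out = 6L)
    out <- deSolve::ode(y, ts, .rhs_desolve, parms, method = "lsoda",
                        rtol = 1e-10, atol = 1e-12)
    if (attr(out, "istate")[1L] < 0)
      stop("integration failed near t = ", t0,
           "; last composition: ", paste(signif(y[seq_len(num)], 6), collapse = ", "))
    seg <- out[-1L, , drop = FALSE]
    segx <- pmax(seg[, 1L + seq_len(num), drop = FALSE], 0)
    segx <- segx / rowSums(segx)
    times <- c(times, seg[, 1L])
    xs <- rbind(xs, segx)
    Ns <- c(Ns, seg[, num + 2L])
    y <- seg[nrow(seg), -1L]
    y[seq_len(num)] <- pmax(y[seq_len(num)], 0)
    y[seq_len(num)] <- y[seq_len(num)] / sum(y[seq_len(num)])
    # sustained convergence: |dx| below tol at every report point in the chunk
    dmax <- apply(seg, 1L, function(r) {
      d <- .rhs_desolve(r[1L], r[-1L], parms)[[1L]]
      max(abs(d[seq_len(num)]))
    })
    t0 <- t1
    if (all(dmax < tol)) {
      converged <- TRUE
      tConv <- t1
      break
    }
  }
  new("Trajectory", times = times, x = xs, N = Ns,
      converged = converged, tConverged = tConv)
}

# Fast internal steady-state solvers operating on raw (A, h, c); the S4
# wrapper validates. Damped fixed-point iteration on the equilibrium
# condition x_i proportional to max(f_i, 0)^(1/(1-c)), which is the ODE's
# compositional rest point; falls back to integration when it fails.

.steady_fp <- function(A, h, c, x0, tol = 1e-13, maxIter = 20000L, damp = 0.5) {
  x <- x0 / sum(x0)
  p <- 1 / (1 - c)
  for (i in seq_len(maxIter)) {
    f <- as.vector(A %*% x) + h
    g <- pmax(f, 0)^p
    s <- sum(g)
    if (!is.finite(s) || s <= 0) return(NULL)
    xn <- (1 - damp) * x + damp * (g / s)
    if (max(abs(xn - x)) < tol) {
      xn <- pmax(xn, 0)
      return(xn / sum(xn))
    }
    x <- xn
  }
  NULL
}

.steady_ode <- function(A, h, c, d, x0, N0 = 1000, tMax = 2000, tol = 1e-9) {
  parms <- list(A = A, h = h, c = c, d = d)
  num <- length(h)
  y <- c(x0 / sum(x0), N0)
  t0 <- 0
  repeat {
    ts <- seq(t0, min(t0 + 100, tMax), length.out = 5L)
    out <- tryCatch(
      suppressWarnings(deSolve::ode(y, ts, .rhs_desolve, parms,
                                    method = "lsoda",
                                    rtol = 1e-10, atol = 1e-12)),
      error = function(e) NULL)
    if (is.null(out) || anyNA(out[nrow(out), ]) ||
        any(!is.finite(out[nrow(out), ]))) break  # keep last valid state
    y <- out[nrow(out), -1L]
    y[seq_len(num)] <- pmax(y[seq_len(num)], 0)
    y[num + 1L] <- min(max(y[num + 1L], 1e-6), 1e12)
    d0 <- .rhs_desolve(0, y, parms)[[1L]]
    t0 <- ts[length(ts)]
    if (anyNA(d0) || max(abs(d0[seq_len(num)])) < tol || t0 >= tMax) break
  }
  x <- pmax(y[seq_len(num)], 0)
  if (sum(x) <= 0 || anyNA(x)) x <- rep(1, num)
  x / sum(x)
}

.steady <- function(A, h, c, d = 0.1, x0, method = "fixedpoint") {
  if (method == "fixedpoint" && c < 1) {
    x <- .steady_fp(A, h, c, x0)
    if (!is.null(x)) return(x)
  }
  .steady_ode(A, h, c, d, x0)
}

#' Steady-state composition of a community model
#'
#' Solves for the compositional rest point reached from \code{x0}. The
#' default method iterates the equilibrium condition
#' \code{x_i = f_i^(1/(1-c)) / sum_j f_j^(1/(1-c))} (species with
#' non-positive fitness go extinct) with damping, which is orders of
#' magnitude faster than time integration and agrees with it to solver
#' tolerance; integration (\code{method = "ode"}) is used automatically as a
#' fallback and is the only route at \code{c = 1}.
#'
#' @param model an \code{\link{FCPModel}}.
#' @param x0 initial composition on the simplex.
#' @param method \code{"fixedpoint"} (default) or \code{"ode"}.
#' @return steady-state composition vector (named by species).
#' @export
steadyState <- function(model, x0, method = c("fixedpoint", "ode")) {
  method <- match.arg(method)
  if (length(x0) != nrow(model@A)) stop("x0 length does not match the model")
  if (abs(sum(x0) - 1) > 1e-6) stop("x0 must lie on the simplex")
  x <- .steady(model@A, model@h, model@c, model@d, x0, method)
  names(x) <- speciesIds(model)
  x
}
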