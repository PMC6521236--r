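# Fitting the community model to observed compositions: per-sample
# multi-start optimisation of (h, c), the Lasso environment map, prediction
# of held-out samples and scoring.

#' @include AllClasses.R dynamics.R
NULL

#' Bray-Curtis similarity between two compositions
#'
#' For vectors on the simplex this is \code{1 - 0.5 * sum(|x - y|)}: 1 for
#' identical compositions, 0 for disjoint ones.
#'
#' @param x,y compositions on the simplex, same species order.
#' @return similarity in [0, 1].
#' @export
brayCurtis <- function(x, y) {
  if (length(x) != length(y))
    stop("compositions differ in length: ", length(x), " vs ", length(y))
  1 - sum(abs(x - y)) / sum(x + y)
}

#' Canonical environmental offsets reproducing a composition exactly
#'
#' A composition only pins the fitness vector down to a positive scale: any
#' \code{f} with \code{x_i = f_i^(1/(1-c)) / sum_j f_j^(1/(1-c))} is
#' consistent with it. The canonical gauge fixes the scale by
#' \code{sum_i f_i^(1/(1-c)) = 1}, under which the exact-fit fitness is
#' simply \code{f_i = x_i^(1-c)} and the offsets follow in closed form as
#' \code{h = x^(1-c) - A x}. Used as the deterministic smart start of
#' \code{\link{fitSample}} and to re-express fitted offsets in a common gauge.
#'
#' @param x observed composition on the simplex.
#' @param c growth index in (0, 1).
#' @param A interaction matrix.
#' @return canonical offset vector h.
#' @export
canonicalOffsets <- function(x, c, A) {
  as.vector(x^(1 - c)) - as.vector(A %*% x)
}

# re-express (h, c) in the canonical gauge at its own fitted composition
.canonicalise <- function(A, h, c, xhat) {
  f <- as.vector(A %*% xhat) + h
  p <- 1 / (1 - c)
  s <- sum(pmax(f, 0)^p)
  if (s <= 0) return(h)
  f / s^(1 - c) - as.vector(A %*% xhat)
}

#' Fit environmental offsets and growth index to one observed composition
#'
#' Multi-start constrained minimisation of the squared error between the
#' model's steady-state composition and the observed one,
#' \code{sum_i (x_pred_i(h, c) - x_obs_i)^2}, over \code{|h_i| <= hBound} and
#' \code{c} in \code{cBounds} (box-constrained quasi-Newton). In addition to
#' \code{nStarts} random initial values, one deterministic start at the
#' closed-form canonical solution is included. Results are returned sorted
#' by objective, with offsets re-expressed in the canonical gauge so fits are
#' comparable across starts and samples.
#'
#' @param A interaction matrix.
#' @param xObs observed composition on the simplex.
#' @param x0 initial composition for the dynamics (default: uniform).
#' @param nStarts number of random starts (default 100).
#' @param cBounds bounds for the growth index (default c(0.05, 0.95)).
#' @param hBound box bound on each offset (default 10).
#' @param sampleId label stored in the result.
#' @param seed RNG seed for the random starts.
#' @return a \code{\link{SampleFitSet}} sorted by objective.
#' @export
fitSample <- function(A, xObs, x0 = NULL, nStarts = 100L,
                      cBounds = c(0.05, 0.95), hBound = 10,
                      sampleId = "sample", seed = 1L) {
  num <- nrow(A)
  if (length(xObs) != num) stop("xObs length does not match A")
  if (is.null(x0)) x0 <- rep(1 / num, num)
  xObs <- xObs / sum(xObs)

  obj <- function(par) {
    h <- par[seq_len(num)]
    cc <- par[num + 1L]
    x <- .steady_fp(A, h, cc, x0)
    if (is.null(x)) return(1e3)
    sum((x - xObs)^2)
  }

  set.seed(seed)
  starts <- lapply(seq_len(nStarts), function(i)
    c(stats::runif(num, -2, 2), stats::runif(1, cBounds[1] + 0.05, cBounds[2] - 0.05)))
  # deterministic smart start: closed-form canonical fit at mid-range c
  starts <- c(list(c(canonicalOffsets(xObs, 0.5, A), 0.5)), starts)

  lower <- c(rep(-hBound, num), cBounds[1])
  upper <- c(rep(hBound, num), cBounds[2])
  fits <- lapply(starts, function(p0) {
    res <- tryCatch(
      stats::optim(p0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 200, factr = 1e4)),
      error = function(e) NULL)
    if (is.null(res)) return(NULL)
    res
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("no start converged for sample ", sampleId)
  fits <- fits[ok]

  H <- matrix(NA_real_, length(fits), num)
  comps <- matrix(NA_real_, length(fits), num)
  cs <- numeric(length(fits))
  objs <- numeric(length(fits))
  bcs <- numeric(length(fits))
  for (i in seq_along(fits)) {
    par <- fits[[i]]$par
    h <- par[seq_len(num)]
    cc <- par[num + 1L]
    x <- .steady_fp(A, h, cc, x0)
    if (is.null(x)) x <- .steady_ode(A, h, cc, 0.1, x0)
    H[i, ] <- .canonicalise(A, h, cc, x)
    comps[i, ] <- x
    cs[i] <- cc
    objs[i] <- fits[[i]]$value
    bcs[i] <- max(0, min(1, brayCurtis(x, xObs)))
  }
  ord <- order(objs)
  colnames(H) <- rownames(A)
  colnames(comps) <- rownames(A)
  new("SampleFitSet", sampleId = sampleId, h = H[ord, , drop = FALSE],
      c = cs[ord], objective = objs[ord], bc = bcs[ord],
      composition = comps[ord, , drop = FALSE],
      nStarts = as.integer(nStarts), seed = as.integer(seed))
}

# standardise environment rows with given constants; NA -> training mean (0)
.standardise_env <- function(E, mu, sds) {
  Z <- sweep(E, 2, mu, "-")
  Z <- sweep(Z, 2, ifelse(sds > 0, sds, 1), "/")
  Z[is.na(Z)] <- 0
  Z
}

# multi-response (group-sparse) Lasso: one factor is selected or dropped
# jointly for all species. penalty: numeric lambda (0 => per-species OLS)
# or "cv". Returns B (species x factors), intercept, lambda.
.envmap_regression_multi <- function(Z, Y, penalty, seed) {
  num <- ncol(Y)
  nfac <- ncol(Z)
  if (identical(penalty, "cv")) {
    set.seed(seed)
    nf <- max(3L, min(5L, nrow(Z)))
    foldid <- sample(rep_len(seq_len(nf), nrow(Z)))
    fit <- suppressWarnings(
      glmnet::cv.glmnet(Z, Y, family = "mgaussian", foldid = foldid,
                        standardize = FALSE, grouped = FALSE))
    cf <- stats::coef(fit, s = "lambda.min")
    lam <- rep(fit$lambda.min, num)
  } else if (penalty > 0) {
    fit <- glmnet::glmnet(Z, Y, family = "mgaussian",
                          lambda = penalty * c(32, 8, 2, 1),
                          standardize = FALSE, thresh = 1e-12)
    cf <- stats::coef(fit, s = penalty)
    lam <- rep(penalty, num)
  } else {
    co <- stats::lm.fit(cbind(1, Z), Y)$coefficients
    co[is.na(co)] <- 0
    return(list(B = t(co[-1, , drop = FALSE]), intercept = co[1, ],
                lambda = rep(0, num)))
  }
  co <- vapply(cf, as.vector, numeric(nfac + 1))
  list(B = t(co[-1, , drop = FALSE]), intercept = co[1, ], lambda = lam)
}

# one round of per-species weighted regression given per-sample scales.
# penalty: numeric lambda (0 => exact weighted OLS) or "cv".
.envmap_regression <- function(Z, Y, W, penalty, seed) {
  nfac <- ncol(Z)
  num <- ncol(Y)
  B <- matrix(0, num, nfac, dimnames = list(colnames(Y), colnames(Z)))
  a <- numeric(num)
  lam <- numeric(num)
  for (i in seq_len(num)) {
    w <- W[, i]
    if (sum(w > 0) < 3) { a[i] <- stats::weighted.mean(Y[, i], pmax(w, 1e-9)); next }
    if (identical(penalty, "cv")) {
      set.seed(seed + i)
      nf <- max(3L, min(5L, sum(w > 0)))
      foldid <- rep_len(seq_len(nf), sum(w > 0))
      fid <- integer(length(w)); fid[w > 0] <- sample(foldid)
      fit <- glmnet::cv.glmnet(Z[w > 0, , drop = FALSE], Y[w > 0, i],
                               foldid = fid[w > 0], standardize = FALSE)
      lam[i] <- fit$lambda.min
      cf <- as.vector(stats::coef(fit, s = "lambda.min"))
    } else if (penalty > 0) {
      fit <- glmnet::glmnet(Z[w > 0, , drop = FALSE], Y[w > 0, i],
                            lambda = penalty * c(32, 8, 2, 1),
                            standardize = FALSE, thresh = 1e-12)
      lam[i] <- penalty
      cf <- as.vector(stats::coef(fit, s = penalty, exact = FALSE))
    } else {
      cf <- tryCatch(stats::lm.wfit(cbind(1, Z), Y[, i], w)$coefficients,
                     error = function(e) rep(NA_real_, nfac + 1))
      cf[is.na(cf)] <- 0
      lam[i] <- 0
    }
    a[i] <- cf[1]
    B[i, ] <- cf[-1]
  }
  list(B = B, intercept = a, lambda = lam)
}

# profiling residual at a trial growth index, used to select the consensus c:
# alternate ridge-stabilised weighted OLS for (B, a) with per-sample scalar
# fitness scales; extinct species are masked (their canonical fitness is 0
# but their true fitness is only bounded above).
.envmap_profile_resid <- function(cg, X, AX, Z, ridge = 1e-4) {
  W <- (X > 1e-8) * 1
  Fhat <- X^(1 - cg)
  Dz <- cbind(1, Z)
  pp <- ncol(Dz)
  Rm <- diag(pp) * ridge
  Rm[1, 1] <- 0
  psi <- rep(1, nrow(X))
  B <- matrix(0, pp, ncol(X))
  for (it in 1:60) {
    Y <- Fhat / psi - AX
    B <- vapply(seq_len(ncol(X)), function(i) {
      Xi <- Dz * W[, i]
      as.vector(solve(crossprod(Xi, Dz) + Rm, crossprod(Xi, Y[, i])))
    }, numeric(pp))
    Fmod <- AX + Dz %*% B
    psiNew <- pmax(rowSums(W * Fhat * Fmod) / pmax(rowSums(W * Fmod^2), 1e-12), 1e-6)
    if (max(abs(psiNew - psi)) < 1e-10) { psi <- psiNew; break }
    psi <- psiNew
  }
  sse <- sum(W * (Fhat - psi * (AX + Dz %*% B))^2)
  # relative to the response's own spread: the scale of x^(1-c) shrinks as
  # c -> 1, so raw SSEs are not comparable across the grid
  ctr <- colSums(W * Fhat) / pmax(colSums(W), 1)
  tss <- sum(W * sweep(Fhat, 2, ctr, "-")^2)
  list(resid = sse / max(tss, 1e-12), psi = psi)
}

#' Learn the environment-to-fitness map by Lasso
#'
#' Regresses the per-sample fitted offsets on the standardised environmental
#' factors with an L1 penalty (\code{h = B z(e) + intercept}). The default
#' fit addresses three features of the problem (see the methods vignette):
#' \itemize{
#'   \item the per-sample fitness scale is not identifiable from a
#'     composition, so a positive scalar scale per training sample is
#'     profiled out of the regression (alternating updates);
#'   \item which factors matter is a property of the shared environment, so
#'     the penalised fit is a multi-response group Lasso that selects each
#'     factor jointly for all species;
#'   \item a species absent from a sample only bounds its fitness above by
#'     zero, so absent entries are treated as censored (EM-style) rather
#'     than regressed towards an arbitrary value.
#' }
#' The consensus growth index is chosen by minimising the cross-sample
#' profiling residual over a grid (\code{growthIndex = "profile"});
#' \code{"median"} uses the median of the per-sample fitted values instead,
#' and a numeric value is used as given. With \code{profileScales = FALSE}
#' the fit reduces to independent per-species regressions of the canonical
#' offsets on the factors, with absent species' rows excluded.
#'
#' @param fits list of \code{\link{SampleFitSet}} objects, one per training
#'   sample, named by sample id (at least 3).
#' @param env an \code{\link{EnvironmentTable}} covering the fit sample ids.
#' @param A interaction matrix (needed to express fitness in a common gauge).
#' @param penalty L1 penalty: a number (0 = ordinary least squares) or
#'   \code{"cv"} for per-species k-fold cross-validation
#'   (k = min(5, n_train)).
#' @param growthIndex \code{"profile"} (default), \code{"median"}, or a
#'   numeric value in (0, 1).
#' @param profileScales profile per-sample fitness scales out of the
#'   regression (default TRUE; FALSE gives the plain per-species Lasso of
#'   canonical offsets on factors).
#' @param seed seed for cross-validation fold assignment.
#' @return an \code{\link{EnvMap}}.
#' @export
fitEnvMap <- function(fits, env, A, penalty = "cv",
                      growthIndex = "profile", profileScales = TRUE,
                      seed = 1L) {
  if (length(fits) < 3) stop("need at least 3 training samples")
  ids <- names(fits)
  if (is.null(ids) || any(!nzchar(ids)))
    ids <- vapply(fits, function(f) f@sampleId, character(1))
  E <- envValues(env)
  if (!all(ids %in% rownames(E)))
    stop("environment table is missing samples: ",
         paste(setdiff(ids, rownames(E)), collapse = ", "))
  E <- E[ids, , drop = FALSE]
  mu <- colMeans(E, na.rm = TRUE)
  sds <- apply(E, 2, stats::sd, na.rm = TRUE)
  sds[is.na(sds) | sds == 0] <- 1
  Z <- .standardise_env(E, mu, sds)

  # best-fit compositions per sample (these are the data the map must explain)
  X <- do.call(rbind, lapply(fits, function(f) f@composition[1L, ]))
  rownames(X) <- ids
  AX <- X %*% t(A)   # row s is A %*% x_s

  if (is.character(growthIndex) && growthIndex == "profile") {
    grid <- seq(0.15, 0.90, by = 0.05)
    rr <- vapply(grid, function(g) .envmap_profile_resid(g, X, AX, Z)$resid,
                 numeric(1))
    cc <- grid[which.min(rr)]
  } else if (is.character(growthIndex) && growthIndex == "median") {
    cc <- stats::median(vapply(fits, function(f) f@c[1L], numeric(1)))
  } else {
    cc <- as.numeric(growthIndex)
    if (is.na(cc) || cc <= 0 || cc >= 1) stop("growthIndex must lie in (0, 1)")
  }

  Fhat <- X^(1 - cc)                      # canonical fitness at consensus c
  if (profileScales) {
    # alternating fit: regression <-> per-sample fitness scales, with
    # censored responses for absent species (absence only bounds their
    # fitness above by zero)
    ext <- X <= 1e-8
    psi <- rep(1, nrow(X))
    Fwork <- Fhat
    D <- cbind(1, Z)
    reg <- NULL
    for (it in 1:30) {
      Y <- Fwork / psi - AX
      reg <- .envmap_regression_multi(Z, Y, penalty, seed)
      Fmod <- AX + D %*% rbind(reg$intercept, t(reg$B))
      psiNew <- pmax(rowSums(Fwork * Fmod) / pmax(rowSums(Fmod^2), 1e-12), 1e-6)
      Fnew <- Fhat
      Fnew[ext] <- pmin((psiNew * Fmod)[ext], 0)
      delta <- max(abs(psiNew - psi), abs(Fnew - Fwork))
      psi <- psiNew
      Fwork <- Fnew
      if (delta < 1e-9) break
    }
  } else {
    W <- (X > 1e-8) * 1
    psi <- rep(1, nrow(X))
    reg <- .envmap_regression(Z, Fhat - AX, W, penalty, seed)
  }
  dimnames(reg$B) <- list(colnames(X), colnames(Z))

  new("EnvMap", B = reg$B, intercept = stats::setNames(reg$intercept, colnames(X)),
      factorMeans = mu, factorSds = sds, lambda = reg$lambda,
      c = cc, scales = stats::setNames(psi, ids))
}

#' Predict a community composition from environmental measurements
#'
#' Applies the environment map (\code{h = B z(e) + intercept}, z using the
#' training-set standardisation constants; missing factors are imputed at the
#' training mean) and solves the dynamics to steady state from \code{x0}
#' at the map's consensus growth index.
#'
#' @param A interaction matrix.
#' @param envMap a trained \code{\link{EnvMap}}.
#' @param e named environment vector (or one row of an environment matrix);
#'   must cover the trained factor names.
#' @param x0 initial composition (default: uniform).
#' @return predicted composition vector.
#' @export
predictComposition <- function(A, envMap, e, x0 = NULL) {
  fac <- colnames(envMap@B)
  if (is.null(names(e))) {
    if (length(e) != length(fac)) stop("environment vector length mismatch")
    names(e) <- fac
  }
  unknown <- setdiff(fac, names(e))
  if (length(unknown)) stop("missing factors: ", paste(unknown, collapse = ", "))
  z <- .standardise_env(matrix(e[fac], 1, dimnames = list(NULL, fac)),
                        envMap@factorMeans, envMap@factorSds)
  h <- as.vector(envMap@B %*% z[1, ]) + envMap@intercept
  num <- nrow(A)
  if (is.null(x0)) x0 <- rep(1 / num, num)
  x <- .steady(A, h, envMap@c, 0.1, x0)
  names(x) <- rownames(A)
  x
}

#' Cross-validate composition predictions
#'
#' Splits the samples, fits the per-sample offsets on the training part
#' (\code{\link{fitSample}}), learns the environment map
#' (\code{\link{fitEnvMap}}), predicts every held-out sample from its
#' environment alone, and reports per-sample Bray-Curtis similarities plus
#' the pooled predicted-vs-observed linear regression over all
#' species-sample pairs.
#'
#' @param profiles a \code{\link{FunctionalProfiles}} object (the interaction
#'   matrix is built from it).
#' @param abundance an \code{\link{AbundanceTable}}.
#' @param env an \code{\link{EnvironmentTable}}.
#' @param folds number of cross-validation folds, or a list of character
#'   vectors of held-out sample ids (one per fold).
#' @param nStarts random starts per training sample (default 20).
#' @param penalty Lasso penalty, as in \code{\link{fitEnvMap}}.
#' @param growthIndex consensus growth-index rule, as in
#'   \code{\link{fitEnvMap}}.
#' @param seed master seed; per-sample fitting seeds are derived from it.
#' @return a \code{\link{PredictionReport}}.
#' @export
crossValidate <- function(profiles, abundance, env, folds = 5L,
                          nStarts = 20L, penalty = "cv",
                          growthIndex = "profile", seed = 1L) {
  A <- interactionMatrix(profiles)
  Xobs <- abundances(abundance)
  ids <- rownames(Xobs)
  if (!all(ids %in% sampleIds(env)))
    stop("sample ids of abundance and environment tables do not match")
  if (!setequal(colnames(Xobs), rownames(A)))
    stop("species ids of abundance and profile tables do not match")
  Xobs <- Xobs[, rownames(A), drop = FALSE]

  if (is.numeric(folds)) {
    k <- as.integer(folds)
    set.seed(seed)
    assign <- sample(rep_len(seq_len(k), length(ids)))
    folds <- split(ids, assign)
  }
  for (f in folds)
    if (length(ids) - length(f) < 3)
      stop("a fold leaves fewer than 3 training samples")

  pred <- matrix(NA_real_, length(ids), ncol(Xobs),
                 dimnames = dimnames(Xobs))
  for (f in folds) {
    train <- setdiff(ids, f)
    fits <- lapply(train, function(s)
      fitSample(A, Xobs[s, ], nStarts = nStarts, sampleId = s,
                seed = seed + match(s, ids)))
    names(fits) <- train
    em <- fitEnvMap(fits, env, A, penalty = penalty,
                    growthIndex = growthIndex, seed = seed)
    x0 <- colMeans(Xobs[train, , drop = FALSE])
    x0 <- x0 / sum(x0)
    for (s in f)
      pred[s, ] <- predictComposition(A, em, envValues(env)[s, ], x0 = x0)
  }

  held <- intersect(ids, unlist(folds))
  pred <- pred[held, , drop = FALSE]
  Xobs <- Xobs[held, , drop = FALSE]
  bc <- vapply(held, function(s) brayCurtis(pred[s, ], Xobs[s, ]), numeric(1))
  fit <- stats::lm(as.vector(pred) ~ as.vector(Xobs))
  new("PredictionReport", observed = Xobs, predicted = pred,
      bc = pmin(pmax(bc, 0), 1),
      r2 = summary(fit)$r.squared,
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]))
}

#' Relative influence of environmental factors
#'
#' Aggregates the environment map into one influence score per factor:
#' the sum over species of absolute standardised coefficients,
#' normalised to percentages (summing to 100).
#'
#' @param envMap a trained \code{\link{EnvMap}}.
#' @return named numeric vector of percentages, in the map's factor order.
#' @export
envInfluence <- function(envMap) {
  raw <- colSums(abs(envMap@B))
  if (sum(raw) == 0) {
    warning("all coefficients are zero; influence is uniform")
    raw <- rep(1, length(raw))
    names(raw) <- colnames(envMap@B)
  }
  100 * raw / sum(raw)
}

#' Serialise an environment map and interaction matrix to JSON
#'
#' Writes the full prediction state (A, B, intercept, standardisation
#' constants, consensus c) with provenance (seed, package version) so that
#' predictions can be reproduced from the file alone.
#'
#' @param envMap a trained \code{\link{EnvMap}}.
#' @param A the interaction matrix used in training.
#' @param path output JSON path.
#' @param seed the master seed used in training (stored as provenance).
#' @return invisibly, the path.
#' @export
writeModelJSON <- function(envMap, A, path, seed = NA_integer_) {
  obj <- list(
    package = "fcpcomm",
    version = as.character(utils::packageVersion("fcpcomm")),
    seed = seed,
    speciesIds = rownames(A),
    factorNames = colnames(envMap@B),
    A = unname(A),
    B = unname(envMap@B),
    intercept = unname(envMap@intercept),
    factorMeans = unname(envMap@factorMeans),
    factorSds = unname(envMap@factorSds),
    lambda = unname(envMap@lambda),
    c = envMap@c,
    scales = unname(envMap@scales))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a model serialised by \code{\link{writeModelJSON}}
#'
#' @param path JSON path.
#' @return list with elements \code{A} (matrix) and \code{envMap}
#'   (\code{\link{EnvMap}}).
#' @export
readModelJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  A <- as.matrix(obj$A)
  dimnames(A) <- list(obj$speciesIds, obj$speciesIds)
  B <- as.matrix(obj$B)
  dimnames(B) <- list(obj$speciesIds, obj$factorNames)
  em <- new("EnvMap", B = B, intercept = as.numeric(obj$intercept),
            factorMeans = stats::setNames(as.numeric(obj$factorMeans), obj$factorNames),
            factorSds = stats::setNames(as.numeric(obj$factorSds), obj$factorNames),
            lambda = as.numeric(obj$lambda), c = as.numeric(obj$c),
            scales = as.numeric(obj$scales))
  list(A = A, envMap = em, seed = obj$seed)
}
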