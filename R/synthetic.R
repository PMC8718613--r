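# Synthetic cohort generation with prescribed correlation structure.

#' Nearest positive-semidefinite correlation matrix by eigenvalue clipping
#'
#' Clips eigenvalues at a small positive floor and rescales to unit diagonal.
#' A matrix that already satisfies the floor is returned unchanged. This is a
#' one-shot spectral repair (not the iterative Higham projection): adequate
#' for simulation-grade targets, and documented as approximate - the
#' repaired matrix is PSD but not the nearest PSD matrix in Frobenius norm.
#'
#' @param m Symmetric matrix, unit diagonal, entries in [-1, 1].
#' @param eigFloor Smallest admissible eigenvalue (default 1e-8).
#' @return A PSD correlation matrix with the same dimnames.
#' @examples
#' m <- matrix(c(1, .9, .9, .9, 1, -.9, .9, -.9, 1), 3)  # indefinite
#' min(eigen(nearestPDCorrelation(m))$values) >= 0
#' @export
nearestPDCorrelation <- function(m, eigFloor = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop("'m' must be a square matrix", call. = FALSE)
  }
  if (any(abs(m - t(m)) > 1e-8)) {
    stop("'m' must be symmetric", call. = FALSE)
  }
  if (any(abs(diag(m) - 1) > 1e-8)) {
    stop("'m' must have a unit diagonal", call. = FALSE)
  }
  if (any(abs(m) > 1 + 1e-8)) {
    stop("correlation entries must lie in [-1, 1]", call. = FALSE)
  }
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= eigFloor) return(m)
  v <- pmax(e$values, eigFloor)
  r <- e$vectors %*% (v * t(e$vectors))
  d <- 1 / sqrt(diag(r))
  r <- r * outer(d, d)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  dimnames(r) <- dimnames(m)
  r
}

#' Construct a synthetic cohort specification
#'
#' Defaults emulate a cerebellar amino acid panel: concentrations of a few
#' micromol/g with moderate dispersion, a mildly positive background
#' correlation among the amino acids (metabolic networks of unstressed
#' animals are dominated by positive interdependence), lognormal margins
#' (concentrations are positive), and the group sizes of the six-group
#' design (8-17 animals).
#'
#' @param mean,sd Numeric vectors over the panel (length 17 or scalars,
#'   recycled).
#' @param targetCorr Target correlation matrix (default: 0.4 background
#'   between all pairs).
#' @param nAnimals Number of animals (default 12).
#' @param seed RNG seed (default 1).
#' @param family \code{"lognormal"} (default) or \code{"normal"}.
#' @param stressor,state Group label (defaults \code{control}, \code{NP}).
#' @return A \linkS4class{SyntheticSpec}.
#' @export
syntheticSpec <- function(mean = 2, sd = 0.5, targetCorr = NULL,
                          nAnimals = 12L, seed = 1L,
                          family = c("lognormal", "normal"),
                          stressor = "control", state = "NP") {
  family <- match.arg(family)
  A <- length(.PANEL)
  mean <- rep_len(mean, A)
  sd <- rep_len(sd, A)
  if (is.null(targetCorr)) {
    targetCorr <- matrix(0.4, A, A, dimnames = list(.PANEL, .PANEL))
    diag(targetCorr) <- 1
  }
  if (is.null(dimnames(targetCorr))) {
    dimnames(targetCorr) <- list(.PANEL, .PANEL)
  }
  new("SyntheticSpec", analytes = .PANEL, mean = mean, sd = sd,
      targetCorr = targetCorr, nAnimals = as.integer(nAnimals),
      seed = as.integer(seed), family = family,
      stressor = .matchToken(stressor, .STRESSORS, "stressor"),
      state = .matchToken(state, .STATES, "state"))
}

setMethod("show", "SyntheticSpec", function(object) {
  cat("SyntheticSpec:", object@nAnimals, "animals,",
      object@family, "family, group",
      groupId(object@stressor, object@state),
      "(seed", paste0(object@seed, ")"), "\n")
})

#' Generate a cohort from a specification
#'
#' Draws \code{nAnimals} correlated vectors by Cholesky factorization of the
#' PSD-repaired target correlation matrix. The normal family rescales the
#' draws to the requested means and SDs directly; the lognormal family
#' applies the correlation on the log scale and chooses log-scale parameters
#' so that the requested arithmetic means and SDs are matched
#' (\code{sigma^2 = log(1 + cv^2)}, \code{mu = log(mean) - sigma^2/2}), which
#' guarantees positive concentrations. Identical seeds give bit-identical
#' cohorts; the caller's RNG state is untouched.
#'
#' @param spec A \linkS4class{SyntheticSpec}.
#' @return A \linkS4class{CohortExperiment}.
#' @examples
#' co <- generateCohort(syntheticSpec(nAnimals = 8, seed = 42))
#' nAnimals(co)
#' @export
generateCohort <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  A <- length(spec@analytes)
  n <- spec@nAnimals
  R <- nearestPDCorrelation(spec@targetCorr)
  L <- tryCatch(chol(R), error = function(e) chol(R + diag(1e-8, A)))
  vals <- .withSeed(spec@seed, {
    z <- matrix(stats::rnorm(n * A), n, A)
    zc <- z %*% L
    if (spec@family == "normal") {
      sweep(sweep(zc, 2L, spec@sd, "*"), 2L, spec@mean, "+")
    } else {
      cv <- spec@sd / spec@mean
      sig <- sqrt(log1p(cv^2))
      mu <- log(spec@mean) - sig^2 / 2
      exp(sweep(sweep(zc, 2L, sig, "*"), 2L, mu, "+"))
    }
  })
  colnames(vals) <- spec@analytes
  rownames(vals) <- sprintf("sim_%03d", seq_len(n))
  cohortExperiment(vals, spec@stressor, spec@state)
}

#' Build a specification around published hub correlation vectors
#'
#' Constructs a target correlation matrix whose hub rows/columns carry the
#' given signed coefficient vectors, emulating the correlation regimes in
#' which a stressor turns the correlations of OGDHC or tryptophan with the
#' amino acids negative. The remaining pairs are filled either with a
#' constant \code{backgroundR}, or (\code{background = "factor"}, single hub
#' only) with the single-factor-consistent completion
#' \code{r_ij = v_i * v_j} of the hub vector \code{v}, which is always PSD
#' and therefore carries the hub vector into the generated cohort without
#' repair distortion. A constant background that contradicts a strong hub
#' vector is indefinite, and the PSD repair then shrinks the realized hub
#' correlations toward zero.
#'
#' @param hubVectors Named list mapping hub analyte name(s) to a named
#'   16-vector of signed correlations with the other panel analytes.
#' @param backgroundR Constant background correlation (|r| < 1, default 0).
#' @param background \code{"constant"} (default) or \code{"factor"}.
#' @param mean,sd,n,seed,family,stressor,state Passed to
#'   \code{\link{syntheticSpec}}.
#' @return A \linkS4class{SyntheticSpec}. When two hub vectors disagree on
#'   their shared cell an error is raised.
#' @export
specFromHubProfiles <- function(hubVectors, backgroundR = 0,
                                background = c("constant", "factor"),
                                mean = 2, sd = 0.5, n = 12L, seed = 1L,
                                family = c("lognormal", "normal"),
                                stressor = "control", state = "NP") {
  background <- match.arg(background)
  family <- match.arg(family)
  if (!length(hubVectors) || is.null(names(hubVectors))) {
    stop("'hubVectors' must be a named list", call. = FALSE)
  }
  if (abs(backgroundR) >= 1) {
    stop("|backgroundR| must be < 1", call. = FALSE)
  }
  hubs <- .normalizeAnalytes(names(hubVectors))
  A <- length(.PANEL)
  if (background == "factor") {
    if (length(hubs) != 1L) {
      stop("'factor' background requires exactly one hub vector",
           call. = FALSE)
    }
    v <- hubVectors[[1L]]
    partners <- .normalizeAnalytes(names(v))
    loading <- stats::setNames(rep(0, A), .PANEL)
    loading[partners] <- v
    M <- outer(loading, loading)
    M[hubs, ] <- loading
    M[, hubs] <- loading
    diag(M) <- 1
  } else {
    M <- matrix(backgroundR, A, A, dimnames = list(.PANEL, .PANEL))
    diag(M) <- 1
    set <- matrix(FALSE, A, A, dimnames = list(.PANEL, .PANEL))
    for (i in seq_along(hubs)) {
      v <- hubVectors[[i]]
      partners <- .normalizeAnalytes(names(v))
      if (length(v) != A - 1L || !setequal(partners,
                                           setdiff(.PANEL, hubs[i]))) {
        stop("hub vector for ", hubs[i],
             " must cover the 16 other panel analytes", call. = FALSE)
      }
      conflict <- set[hubs[i], partners] &
        abs(M[hubs[i], partners] - v) > 1e-12
      if (any(conflict)) {
        stop("conflicting values for the ", hubs[i], "-",
             paste(partners[conflict], collapse = "/"), " cell(s)",
             call. = FALSE)
      }
      M[hubs[i], partners] <- v
      M[partners, hubs[i]] <- v
      set[hubs[i], partners] <- TRUE
      set[partners, hubs[i]] <- TRUE
    }
  }
  syntheticSpec(mean = mean, sd = sd, targetCorr = M, nAnimals = n,
                seed = seed, family = family, stressor = stressor,
                state = state)
}

#' Serialize and restore synthetic specifications
#'
#' YAML round trip of a \linkS4class{SyntheticSpec} (means, sds, correlation
#' block, size, seed, family, group label).
#'
#' @param spec A \linkS4class{SyntheticSpec}.
#' @param path File path.
#' @return \code{writeSyntheticSpec} returns \code{path} invisibly;
#'   \code{readSyntheticSpec} returns the restored spec.
#' @export
writeSyntheticSpec <- function(spec, path) {
  stopifnot(is(spec, "SyntheticSpec"))
  obj <- list(analytes = spec@analytes, mean = spec@mean, sd = spec@sd,
              target_corr = apply(spec@targetCorr, 1L, as.numeric,
                                  simplify = FALSE),
              n_animals = spec@nAnimals, seed = spec@seed,
              family = spec@family, stressor = spec@stressor,
              state = spec@state)
  yaml::write_yaml(obj, path, precision = 17L)
  invisible(path)
}

#' @rdname writeSyntheticSpec
#' @export
readSyntheticSpec <- function(path) {
  obj <- yaml::read_yaml(path)
  tc <- do.call(rbind, lapply(obj$target_corr, as.numeric))
  dimnames(tc) <- list(obj$analytes, obj$analytes)
  syntheticSpec(mean = as.numeric(obj$mean), sd = as.numeric(obj$sd),
                targetCorr = tc, nAnimals = obj$n_animals, seed = obj$seed,
                family = obj$family, stressor = obj$stressor,
                state = obj$state)
}
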