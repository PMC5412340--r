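#' Cardinality-constrained elastic-net solve
#'
#' Solves `argmin ||b - A beta||^2 + lambda2 ||beta||^2` subject to an l1
#' penalty chosen so that the active set holds at most `m` variables. The
#' solver runs the LARS elastic-net path (LARS with the lasso modification on
#' the ridge-augmented design, handled implicitly through the Gram matrix
#' `A'A + lambda2 I`) and stops when the active set reaches `min(m, ncol(A))`
#' variables, at the point where the next variable would enter. When all
#' variables become active the solution jumps to the exact ridge closed form
#' (the l1 penalty has reached 0). The mechanism used is recorded in the
#' `"mechanism"` attribute (`"lars-en"` or `"ridge-limit"`).
#'
#' Ties in the entry criterion are broken by column order, so a duplicated
#' column pair admits exactly one active member, deterministically.
#'
#' @param A numeric design matrix (n x p)
#' @param b numeric response, length n
#' @param lambda2 non-negative ridge penalty
#' @param m cardinality bound (>= 1)
#' @param maxSteps safety cap on path steps
#' @return numeric coefficient vector of length p (named if A has column
#'   names), with attributes `mechanism` and `steps`
#' @export
cardinalityEnSolve <- function(A, b, lambda2 = 1e-3, m = ncol(A),
                               maxSteps = 50L + 8L * ncol(A)) {
  stopifnot(is.matrix(A), length(b) == nrow(A))
  if (!all(is.finite(A)) || !all(is.finite(b)))
    stop("non-finite values in the elastic-net inputs")
  if (m < 1) stop("cardinality m must be >= 1")
  p <- ncol(A)
  mTarget <- min(as.integer(m), p)
  eps <- 1e-10

  beta <- numeric(p)
  mu <- numeric(nrow(A))
  active <- integer(0)
  signs <- numeric(0)
  ignores <- integer(0)
  lastDropped <- 0L
  mech <- "lars-en"
  steps <- 0L

  ridgeFull <- function() {
    G <- crossprod(A)
    diag(G) <- diag(G) + lambda2
    drop(solve(G, crossprod(A, b)))
  }

  repeat {
    steps <- steps + 1L
    if (steps > maxSteps) break
    cvec <- drop(crossprod(A, b - mu)) - lambda2 * beta
    avail <- setdiff(seq_len(p), c(active, ignores))
    if (!length(avail) && length(active) == p) {
      beta <- ridgeFull()
      mech <- "ridge-limit"
      break
    }
    Cmax <- if (length(active)) max(abs(cvec[active])) else
      if (length(avail)) max(abs(cvec[avail])) else 0
    if (Cmax < eps) break

    # entry event: admit the strongest inactive variable (ties -> lowest
    # column index via which.max); skipped right after a lasso drop
    if (lastDropped == 0L && length(active) < mTarget && length(avail)) {
      cin <- abs(cvec[avail])
      if (max(cin) >= Cmax - eps * max(1, Cmax)) {
        j <- avail[which.max(cin)]
        active <- c(active, j)
        signs <- c(signs, sign(cvec[j]))
      }
    }
    lastDropped <- 0L
    if (!length(active)) break

    Aact <- A[, active, drop = FALSE]
    Ga <- crossprod(Aact)
    diag(Ga) <- diag(Ga) + lambda2
    w <- tryCatch(drop(solve(Ga, signs)), error = function(e) NULL)
    if (is.null(w)) {
      # singular addition (e.g. exact duplicate of an active column):
      # permanently exclude the newest entrant and retry
      ignores <- c(ignores, active[length(active)])
      active <- active[-length(active)]
      signs <- signs[-length(signs)]
      next
    }
    AA <- 1 / sqrt(sum(signs * w))
    w <- AA * w
    u <- drop(Aact %*% w)
    C <- max(abs(cvec[active]))
    gammaMax <- C / AA  # end of path for this active set

    inact <- setdiff(seq_len(p), c(active, ignores))
    gEntry <- Inf
    if (length(inact)) {
      a_all <- drop(crossprod(A, u))
      a <- a_all[inact]
      g1 <- (C - cvec[inact]) / (AA - a)
      g2 <- (C + cvec[inact]) / (AA + a)
      cand <- c(g1[g1 > eps], g2[g2 > eps])
      if (length(cand)) gEntry <- min(cand)
    }

    dg <- -beta[active] / w
    gDrop <- Inf
    kDrop <- 0L
    pos <- which(dg > eps)
    if (length(pos)) {
      kDrop <- pos[which.min(dg[pos])]
      gDrop <- dg[kDrop]
    }

    atCap <- length(active) == mTarget
    gammaStop <- min(gEntry, gammaMax)
    if (atCap && gDrop >= gammaStop) {
      # final segment: step to where the next variable would enter
      beta[active] <- beta[active] + gammaStop * w
      break
    }
    gamma <- min(gEntry, gDrop, gammaMax)
    beta[active] <- beta[active] + gamma * w
    mu <- mu + gamma * u
    if (gamma == gDrop) {
      lastDropped <- active[kDrop]
      beta[active[kDrop]] <- 0
      active <- active[-kDrop]
      signs <- signs[-kDrop]
    } else if (gamma == gammaMax && gEntry > gammaMax) {
      break  # path exhausted before reaching the cardinality target
    }
  }

  beta[abs(beta) < eps] <- 0
  if (!is.null(colnames(A))) names(beta) <- colnames(A)
  attr(beta, "mechanism") <- mech
  attr(beta, "steps") <- steps
  beta
}

#' Fit a sparse discriminant model by penalized optimal scoring
#'
#' Sparse linear discriminant analysis with the ordinal severity grade as a
#' multi-group class label. LDA is recast as optimal scoring: class
#' indicators are assigned real scores theta and regressed on the features
#' with an elastic-net penalty whose l1 part is driven by the cardinality
#' bound `m` (see [cardinalityEnSolve()]). Directions are extracted
#' sequentially; each score vector is kept D-orthonormal (D = diagonal class
#' frequencies) to the previous ones and to the trivial constant score.
#'
#' For each direction j the alternation is: (i) `beta_j <- argmin
#' ||Y theta_j - X beta||^2 + lambda2 ||beta||^2` with at most `m` active
#' coefficients; (ii) `theta_j <- normalize((I - Q Q' D) D^{-1} Y' X beta_j)`
#' under `theta' D theta = 1`, until the relative change in beta falls below
#' `tol` or `maxIter` is reached. In the dense limit (`m >= ncol(X)`,
#' vanishing penalties) the fitted directions span the classical LDA
#' discriminant subspace.
#'
#' @param X standardized samples x genes matrix (column names = gene ids)
#' @param labels severity grades, one per row of X (>= 2 distinct values)
#' @param m per-direction cardinality bound
#' @param lambda2 ridge penalty (default 1e-3)
#' @param q number of directions, at most K - 1 (default K - 1)
#' @param maxIter,tol alternation control
#' @return an [SldaModel-class]
#' @export
fitSlda <- function(X, labels, m, lambda2 = 1e-3, q = NULL,
                    maxIter = 30L, tol = 1e-4) {
  stopifnot(is.matrix(X), nrow(X) == length(labels))
  levels <- sort(unique(labels))
  K <- length(levels)
  if (K < 2L)
    stop("degenerate labels: fewer than 2 classes present")
  n <- nrow(X); p <- ncol(X)
  if (is.null(q)) q <- K - 1L
  q <- min(as.integer(q), K - 1L)
  Y <- matrix(0, n, K)
  Y[cbind(seq_len(n), match(labels, levels))] <- 1
  dpi <- colSums(Y) / n

  Qmat <- matrix(1, K, 1)  # trivial constant score, D-norm 1 by construction
  B <- matrix(0, p, q, dimnames = list(colnames(X), NULL))
  Theta <- matrix(0, K, q)
  iters <- integer(q)
  conv <- logical(q)

  orthInit <- function(j) {
    # deterministic init: ordinal scores for the first direction, indicator
    # contrasts afterwards, D-orthogonalized against earlier scores
    basis <- cbind(as.numeric(levels), diag(K))
    for (cand in j:ncol(basis)) {
      th <- basis[, cand]
      th <- th - Qmat %*% crossprod(Qmat, dpi * th)
      nrm <- sqrt(sum(dpi * th^2))
      if (nrm > 1e-8) return(drop(th) / nrm)
    }
    stop("could not initialize a score vector orthogonal to earlier ones")
  }

  for (j in seq_len(q)) {
    th <- orthInit(j)
    beta_old <- numeric(p)
    beta <- numeric(p)
    for (it in seq_len(maxIter)) {
      iters[j] <- it
      beta <- cardinalityEnSolve(X, drop(Y %*% th), lambda2, m)
      if (all(beta == 0)) break
      tnew <- drop(crossprod(Y, X %*% beta)) / n / dpi
      tnew <- tnew - drop(Qmat %*% crossprod(Qmat, dpi * tnew))
      nrm <- sqrt(sum(dpi * tnew^2))
      if (nrm < 1e-12) break
      th <- tnew / nrm
      delta <- max(abs(beta - beta_old)) / max(1, max(abs(beta)))
      beta_old <- beta
      if (delta < tol) { conv[j] <- TRUE; break }
    }
    if (any(beta != 0)) {
      i0 <- which.max(abs(beta))
      if (beta[i0] < 0) { beta <- -beta; th <- -th }  # sign convention
      # scale the direction by its canonical correlation with the class
      # scores: raw optimal-scoring coefficients have arbitrary relative
      # scale across directions, and unscaled noise directions would
      # contaminate the cross-direction max-|loading| ranking
      r <- suppressWarnings(stats::cor(drop(X %*% beta), drop(Y %*% th)))
      beta <- beta * abs(if (is.na(r)) 0 else r)
    }
    B[, j] <- beta
    Theta[, j] <- th
    Qmat <- cbind(Qmat, th)
  }

  new("SldaModel", directions = B, scores = Theta,
      classLevels = as.integer(levels), classFreq = dpi,
      lambda2 = lambda2, m = as.integer(m),
      iterations = iters, converged = conv)
}

#' Extract ranked markers from a fitted sparse discriminant model
#'
#' Genes are scored by their maximum absolute loading across the discriminant
#' directions; the top `m` genes with non-zero score are returned (fewer if
#' the model has fewer non-zero loadings). Ties are broken by gene id.
#'
#' @param model an [SldaModel-class]
#' @param m requested set size
#' @param symptom symptom tag for the resulting set
#' @return a [MarkerSet-class] with `method = "slda"`
#' @export
selectMarkersSlda <- function(model, m, symptom = "unspecified") {
  stopifnot(is(model, "SldaModel"))
  B <- model@directions
  sc <- apply(abs(B), 1L, max)
  nz <- which(sc > 0)
  ord <- nz[order(-sc[nz], rownames(B)[nz])]
  sel <- utils::head(ord, m)
  new("MarkerSet", symptom = symptom, method = "slda",
      genes = rownames(B)[sel], scores = unname(sc[sel]),
      pvalues = numeric(0), m = as.integer(m))
}
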