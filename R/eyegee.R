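#' Logistic regression by generalized estimating equations for paired eyes
#'
#' Fits a marginal logistic model to clustered binary outcomes (typically
#' the two eyes of a subject) by generalized estimating equations with an
#' exchangeable working correlation. The scale parameter and the working
#' correlation are re-estimated from Pearson residuals at every iteration
#' (moment estimators); inference uses the robust (sandwich) covariance
#' exclusively.
#'
#' @param formula Model formula with a binary (0/1) outcome.
#' @param id Cluster identifier: a column name in `data` (bare or quoted)
#'   or a vector of length `nrow(data)`. All records sharing an id form one
#'   cluster.
#' @param data Data frame of eye-level records.
#' @param corstr Working correlation: `"exchangeable"` (default) or
#'   `"independence"` (fixes the working correlation at zero).
#' @param tol Convergence tolerance on the maximum absolute coefficient
#'   change.
#' @param maxit Maximum number of Fisher-scoring iterations.
#' @return An object of class `"eyegee"`: coefficients, robust covariance
#'   (`vcov`), working correlation `alpha`, scale `phi`, cluster counts,
#'   `converged` flag, fitted values and the model frame. Standard methods
#'   (`print`, `summary`, `coef`, `vcov`, `predict`, `residuals`,
#'   `fitted`) apply; [odds_ratios()] tabulates exponentiated effects.
#' @details With singleton clusters (or `corstr = "independence"` and no
#'   correlation to absorb) the estimating equations reduce to the ordinary
#'   logistic-regression score equations, so estimates coincide with
#'   `glm(..., family = binomial)`. Non-convergence returns the last
#'   iterate with `converged = FALSE` and a warning rather than an error,
#'   so bootstrap loops can count and discard such replicates.
#' @examples
#' d <- data.frame(y = rbinom(40, 1, 0.4), x = rnorm(40),
#'                 subj = rep(1:20, each = 2))
#' fit <- eyegee(y ~ x, id = subj, data = d)
#' summary(fit)
#' @export
eyegee <- function(formula, id, data, corstr = c("exchangeable",
                                                 "independence"),
                   tol = 1e-8, maxit = 100) {
  corstr <- match.arg(corstr)
  cl <- match.call()
  id <- eval(substitute(id), data, parent.frame())
  if (is.character(id) && length(id) == 1L && id %in% names(data)) {
    id <- data[[id]]
  }
  if (length(id) != nrow(data)) {
    stop("id must identify a column of data or have one entry per record",
         call. = FALSE)
  }
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  keep <- stats::complete.cases(X) & !is.na(y)
  X <- X[keep, , drop = FALSE]
  y <- as.numeric(y[keep])
  id <- as.character(id)[keep]
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1",
                                 call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  if (length(unique(id)) < 2L) stop("need at least 2 clusters",
                                    call. = FALSE)

  fit <- gee_irls(X, y, id, corstr, tol, maxit)
  if (!fit$converged) {
    warning("GEE did not converge in ", maxit,
            " iterations; returning last iterate")
  }
  if (any(abs(fit$beta) > 15)) {
    warning("very large coefficient(s); possible separation")
  }
  structure(list(
    coefficients = stats::setNames(fit$beta, colnames(X)),
    vcov = structure(fit$vcov, dimnames = list(colnames(X), colnames(X))),
    alpha = fit$alpha, phi = fit$phi,
    n_clusters = fit$n_clusters, n_records = length(y),
    converged = fit$converged, iterations = fit$iterations,
    fitted.values = fit$mu, y = y, X = X, id = id,
    formula = formula, corstr = corstr, call = cl
  ), class = "eyegee")
}

# Fisher-scoring loop. Clusters of size 1 and 2 are handled by closed-form
# vectorized algebra (the paired-eye case); larger clusters fall back to a
# per-cluster solve with R = (1-alpha) I + alpha J.
gee_irls <- function(X, y, id, corstr, tol, maxit) {
  p <- ncol(X)
  n <- length(y)
  ord <- order(id)
  X <- X[ord, , drop = FALSE]
  y <- y[ord]
  id <- id[ord]
  runs <- rle(id)
  sizes <- runs$lengths
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  i1 <- starts[sizes == 1L]
  s2 <- starts[sizes == 2L]
  big <- which(sizes > 2L)
  max_size <- max(sizes)
  npairs <- sum(sizes * (sizes - 1)) / 2

  beta <- as.numeric(stats::glm.fit(X, y,
                                    family = stats::binomial())$coefficients)
  alpha <- 0
  phi <- 1
  converged <- FALSE
  iter <- 0L
  while (iter < maxit) {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    a <- pmax(mu * (1 - mu), 1e-10)
    r <- (y - mu) / sqrt(a)
    phi <- sum(r^2) / (n - p)
    if (corstr == "exchangeable" && npairs > 0) {
      cs <- function(v) {
        cum <- cumsum(v)
        tot <- cum[ends] - c(0, cum[ends[-length(ends)]])
        tot
      }
      pair_sum <- sum((cs(r)^2 - cs(r^2)) / 2)
      denom <- (npairs - p) * phi
      alpha <- if (denom > 0) pair_sum / denom else 0
      lo <- -1 / (max_size - 1) + 1e-6
      alpha <- min(max(alpha, lo), 1 - 1e-6)
    } else {
      alpha <- 0
    }
    eng <- gee_engine(X, y, mu, a, alpha, phi, i1, s2, big, starts, sizes)
    delta <- solve(eng$bread, eng$score)
    beta <- beta + delta
    if (max(abs(delta)) < tol) {
      converged <- TRUE
      break
    }
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  a <- pmax(mu * (1 - mu), 1e-10)
  eng <- gee_engine(X, y, mu, a, alpha, phi, i1, s2, big, starts, sizes)
  bread_inv <- solve(eng$bread)
  vcov <- bread_inv %*% crossprod(eng$G) %*% bread_inv
  vcov <- (vcov + t(vcov)) / 2
  mu_out <- numeric(n)
  mu_out[ord] <- mu
  list(beta = beta, vcov = vcov, alpha = alpha, phi = phi,
       n_clusters = length(sizes), converged = converged,
       iterations = iter, mu = mu_out)
}

# Cluster-wise quantities for one scoring step: bread = sum_i D_i' V_i^-1
# D_i, score = sum_i D_i' V_i^-1 (y_i - mu_i), and G with one row per
# cluster holding D_i' V_i^-1 (y_i - mu_i) (the sandwich meat is G'G).
gee_engine <- function(X, y, mu, a, alpha, phi, i1, s2, big, starts, sizes) {
  p <- ncol(X)
  s <- y - mu
  bread <- matrix(0, p, p)
  score <- numeric(p)
  G <- matrix(0, length(sizes), p)
  clus_row <- 0L

  if (length(i1)) {
    X1 <- X[i1, , drop = FALSE]
    bread <- bread + crossprod(X1, X1 * (a[i1] / phi))
    G1 <- X1 * (s[i1] / phi)
    G[seq_along(i1), ] <- G1
    score <- score + colSums(G1)
    clus_row <- length(i1)
  }
  if (length(s2)) {
    ia <- s2
    ib <- s2 + 1L
    Xa <- X[ia, , drop = FALSE]
    Xb <- X[ib, , drop = FALSE]
    a1 <- a[ia]; a2 <- a[ib]
    s1 <- s[ia]; s2v <- s[ib]
    cc <- 1 / (phi * (1 - alpha^2))
    w12 <- -cc * alpha * sqrt(a1 * a2)
    bread <- bread + crossprod(Xa, Xa * (cc * a1) + Xb * w12) +
      crossprod(Xb, Xb * (cc * a2) + Xa * w12)
    u1 <- cc * (s1 - alpha * sqrt(a1 / a2) * s2v)
    u2 <- cc * (s2v - alpha * sqrt(a2 / a1) * s1)
    G2 <- Xa * u1 + Xb * u2
    G[clus_row + seq_along(ia), ] <- G2
    score <- score + colSums(G2)
    clus_row <- clus_row + length(ia)
  }
  for (k in big) {
    idx <- starts[k] + seq_len(sizes[k]) - 1L
    Xi <- X[idx, , drop = FALSE]
    ai <- a[idx]
    Ri <- matrix(alpha, sizes[k], sizes[k])
    diag(Ri) <- 1
    Vi <- phi * (sqrt(ai) %o% sqrt(ai)) * Ri
    DtVinv <- t(Xi * ai) %*% solve(Vi)
    bread <- bread + DtVinv %*% (Xi * ai)
    gi <- drop(DtVinv %*% s[idx])
    clus_row <- clus_row + 1L
    G[clus_row, ] <- gi
    score <- score + gi
  }
  list(bread = bread, score = score, G = G)
}

#' @export
print.eyegee <- function(x, ...) {
  cat("Logistic GEE (", x$corstr, " working correlation)\n", sep = "")
  cat("Call: ", deparse(x$call), "\n")
  cat(sprintf("%d records in %d clusters; alpha = %.4f; %s\n",
              x$n_records, x$n_clusters, x$alpha,
              if (x$converged) sprintf("converged in %d iterations",
                                       x$iterations) else "NOT converged"))
  cat("\nCoefficients:\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
summary.eyegee <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  z <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients, `Robust SE` = se,
               z = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(call = object$call, coefficients = tab,
                 alpha = object$alpha, phi = object$phi,
                 n_clusters = object$n_clusters,
                 n_records = object$n_records,
                 converged = object$converged, corstr = object$corstr),
            class = "summary.eyegee")
}

#' @export
print.summary.eyegee <- function(x, ...) {
  cat("Logistic GEE (", x$corstr, " working correlation)\n", sep = "")
  cat("Call: ", deparse(x$call), "\n\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("\nScale phi = %.4f; working correlation alpha = %.4f\n",
              x$phi, x$alpha))
  cat(sprintf("%d records in %d clusters\n", x$n_records, x$n_clusters))
  invisible(x)
}

#' @export
coef.eyegee <- function(object, ...) object$coefficients

#' @export
vcov.eyegee <- function(object, ...) object$vcov

#' @export
fitted.eyegee <- function(object, ...) object$fitted.values

#' @export
predict.eyegee <- function(object, newdata = NULL,
                           type = c("link", "response"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- drop(object$X %*% object$coefficients)
  } else {
    X <- stats::model.matrix(stats::delete.response(
      stats::terms(object$formula)), newdata)
    eta <- drop(X %*% object$coefficients[colnames(X)])
  }
  if (type == "response") stats::plogis(eta) else eta
}

#' @export
residuals.eyegee <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  r <- object$y - object$fitted.values
  if (type == "pearson") {
    r <- r / sqrt(object$fitted.values * (1 - object$fitted.values))
  }
  r
}

#' Odds ratios with robust confidence intervals from a GEE fit
#'
#' @param fit An [eyegee()] fit.
#' @param level Confidence level.
#' @return Data frame: `term`, `or`, `lower`, `upper`, `p` (Wald test on
#'   the log-odds scale with robust standard errors).
#' @export
odds_ratios <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "eyegee"))
  se <- sqrt(diag(fit$vcov))
  z <- stats::qnorm(1 - (1 - level) / 2)
  b <- fit$coefficients
  data.frame(term = names(b), or = exp(b), lower = exp(b - z * se),
             upper = exp(b + z * se),
             p = 2 * stats::pnorm(-abs(b / se)),
             row.names = NULL, stringsAsFactors = FALSE)
}
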