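# Confirmatory factor analysis with a simple structure (each feature loads
# on exactly one factor, factors freely correlated, factor variances fixed
# at 1), maximum-likelihood discrepancy, CFI/RMSEA fit indices, single-pass
# loading pruning, and Bartlett factor scores.

#' The default 10-factor measurement structure
#'
#' Maps the features to the ten construct-by-modality factors: `Pros_a`,
#' `Pause_a`, `IMC_e`, `Amp_e`, `Amp_a`, `Rhy_e`, `Rhy_a`, `Comp_e`,
#' `Comp_a`, `Reg_e`. Regularity of the acoustic signal has no factor (its
#' single feature is screened out in the reference analysis).
#'
#' @param features restrict the mapping to these feature names (e.g. the
#'   screened subset); factors left without features are dropped
#' @return named list: factor name -> character vector of feature names
#' @export
default_factor_spec <- function(features = NULL) {
  man <- feature_manifest(as_table = TRUE)
  key <- paste(man$construct, man$modality)
  fmap <- c("prosody acoustic" = "Pros_a", "pause acoustic" = "Pause_a",
            "connectivity sEMG" = "IMC_e", "amplitude sEMG" = "Amp_e",
            "amplitude acoustic" = "Amp_a", "rhythm sEMG" = "Rhy_e",
            "rhythm acoustic" = "Rhy_a", "complexity sEMG" = "Comp_e",
            "complexity acoustic" = "Comp_a", "regularity sEMG" = "Reg_e")
  spec <- lapply(names(fmap), function(k) man$name[key == k])
  names(spec) <- unname(fmap)
  if (!is.null(features)) {
    spec <- lapply(spec, intersect, y = features)
    spec <- spec[vapply(spec, length, integer(1)) > 0]
  }
  spec
}

# build Sigma(theta) for the simple-structure model
cfa_sigma <- function(lambda, psi, Phi, assign_idx) {
  L <- matrix(0, length(lambda), nrow(Phi))
  L[cbind(seq_along(lambda), assign_idx)] <- lambda
  S <- L %*% Phi %*% t(L)
  diag(S) <- diag(S) + psi
  list(Sigma = S, L = L)
}

# unpack parameter vector; single-indicator factors have lambda, psi fixed
cfa_unpack <- function(theta, state) {
  lambda <- state$lambda_fix
  psi <- state$psi_fix
  lambda[state$free_feat] <- theta[seq_len(state$nf_free)]
  psi[state$free_feat] <- exp(theta[state$nf_free + seq_len(state$nf_free)])
  nfac <- state$nfac
  Lchol <- diag(nfac)
  if (nfac > 1) {
    z <- theta[2 * state$nf_free + seq_len(nfac * (nfac - 1) / 2)]
    Lchol[upper.tri(Lchol)] <- 0
    Lchol[lower.tri(Lchol)] <- z
    Lchol <- Lchol / sqrt(rowSums(Lchol^2))
  }
  Phi <- Lchol %*% t(Lchol)
  list(lambda = lambda, psi = psi, Phi = Phi)
}

cfa_objective <- function(theta, state) {
  par <- cfa_unpack(theta, state)
  Sg <- cfa_sigma(par$lambda, par$psi, par$Phi, state$assign_idx)$Sigma
  ch <- tryCatch(chol(Sg), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  logdet <- 2 * sum(log(diag(ch)))
  Sinv_S <- chol2inv(ch) %*% state$S
  val <- logdet + sum(diag(Sinv_S)) - state$logdetS - nrow(state$S)
  if (!is.finite(val)) 1e10 else val
}

fit_cfa_once <- function(S, n, spec) {
  feats <- unlist(spec, use.names = FALSE)
  nfac <- length(spec)
  p <- length(feats)
  assign_idx <- rep(seq_along(spec), vapply(spec, length, integer(1)))
  sizes <- vapply(spec, length, integer(1))
  single <- sizes[assign_idx] == 1
  # single-indicator factors: loading and uniqueness fixed (factor = item)
  lambda_fix <- ifelse(single, sqrt(1 - 1e-3), NA_real_)
  psi_fix <- ifelse(single, 1e-3, NA_real_)
  free_feat <- which(!single)
  state <- list(S = S, logdetS = determinant(S)$modulus[1],
                assign_idx = assign_idx, nfac = nfac,
                lambda_fix = lambda_fix, psi_fix = psi_fix,
                free_feat = free_feat, nf_free = length(free_feat))
  # conservative start: on the unidentified ridge of a null structure the
  # optimizer stays near zero loadings instead of hallucinating structure
  theta0 <- c(rep(0.3, state$nf_free), rep(log(0.7), state$nf_free),
              rep(0, nfac * (nfac - 1) / 2))
  opt <- stats::nlminb(theta0, cfa_objective, state = state,
                       control = list(iter.max = 500, eval.max = 2000))
  par <- cfa_unpack(opt$par, state)
  # sign convention: majority-positive loadings per factor
  for (f in seq_len(nfac)) {
    idx <- which(assign_idx == f)
    if (sum(par$lambda[idx]) < 0) {
      par$lambda[idx] <- -par$lambda[idx]
      par$Phi[f, -f] <- -par$Phi[f, -f]
      par$Phi[-f, f] <- -par$Phi[-f, f]
    }
  }
  # fit indices: chi-square vs the independence baseline
  Fmin <- opt$objective
  Tstat <- (n - 1) * Fmin
  npar <- 2 * state$nf_free + nfac * (nfac - 1) / 2
  df <- p * (p + 1) / 2 - npar
  Fb <- -state$logdetS  # baseline: diagonal Sigma on a correlation matrix
  Tb <- (n - 1) * Fb
  dfb <- p * (p - 1) / 2
  cfi <- 1 - max(Tstat - df, 0) / max(Tb - dfb, Tstat - df, .Machine$double.eps)
  rmsea <- sqrt(max(Tstat - df, 0) / (df * (n - 1)))
  list(lambda = stats::setNames(par$lambda, feats), psi = par$psi,
       Phi = par$Phi, assign_idx = assign_idx, spec = spec,
       Fmin = Fmin, chisq = Tstat, df = df, CFI = cfi, RMSEA = rmsea,
       convergence = opt$convergence, message = opt$message)
}

#' Fit the confirmatory factor model
#'
#' Maximum-likelihood estimation of the simple-structure model on z-scored
#' features: each feature loads only on its assigned factor, factor
#' variances are fixed at 1 and factor correlations are free. Features whose
#' standardized loading falls below `loading_cutoff` are pruned and the
#' model refit once (single pass). Model fit is summarized by CFI and RMSEA
#' against the independence baseline, and per-sample factor scores are
#' computed with the Bartlett (weighted least squares) method.
#'
#' @param table data.frame/matrix of features (columns); z-scored internally
#' @param spec named list factor -> feature names, see
#'   [default_factor_spec()]
#' @param loading_cutoff pruning threshold on the standardized loading
#' @param prune prune-and-refit below-cutoff features?
#' @return object of class `mmb_cfa`: loadings, uniquenesses, factor
#'   correlations `Phi`, `CFI`, `RMSEA`, Bartlett `scores`, `pruned`
#'   feature names
#' @export
fit_cfa <- function(table, spec = default_factor_spec(colnames(table)),
                    loading_cutoff = 0.5, prune = TRUE) {
  tab <- as.data.frame(table)[, unlist(spec), drop = FALSE]
  Z <- scale(as.matrix(tab[stats::complete.cases(tab), , drop = FALSE]))
  n <- nrow(Z)
  p <- ncol(Z)
  if (n < 5 * p)
    warning("fewer than 5 complete rows per feature; estimates may be unstable")
  sds <- attr(Z, "scaled:scale")
  if (any(sds < 1e-12)) stop("constant feature(s): ",
                             paste(colnames(Z)[sds < 1e-12], collapse = ", "))
  S <- stats::cov(Z)
  fit <- fit_cfa_once(S, n, spec)
  if (fit$convergence != 0)
    warning("CFA optimizer did not report clean convergence: ", fit$message)
  pruned <- character(0)
  if (prune) {
    low <- names(fit$lambda)[abs(fit$lambda) < loading_cutoff]
    if (length(low) > 0) {
      pruned <- low
      spec2 <- lapply(fit$spec, setdiff, y = low)
      spec2 <- spec2[vapply(spec2, length, integer(1)) > 0]
      Z <- Z[, unlist(spec2), drop = FALSE]
      S <- stats::cov(Z)
      fit <- fit_cfa_once(S, n, spec2)
    }
  }
  if (any(fit$psi < 1e-3 + 1e-9 & is.na(match(names(fit$lambda), pruned))
          & vapply(fit$spec, length, integer(1))[fit$assign_idx] > 1))
    warning("Heywood case: near-zero uniqueness estimated")
  scores <- bartlett_scores(Z, fit)
  structure(c(fit, list(scores = scores, pruned = pruned, n = n)),
            class = "mmb_cfa")
}

#' Bartlett factor scores
#'
#' Weighted-least-squares scores
#' `(L' Psi^-1 L)^-1 L' Psi^-1 z` per row of the z-scored feature matrix;
#' conditionally unbiased for the generating factors under the model.
#'
#' @param Z z-scored feature matrix (columns ordered as in the fit)
#' @param fit a fitted model from [fit_cfa()] (or its internal list)
#' @return matrix rows x factors
#' @export
bartlett_scores <- function(Z, fit) {
  L <- matrix(0, length(fit$lambda), length(fit$spec))
  L[cbind(seq_along(fit$lambda), fit$assign_idx)] <- fit$lambda
  W <- t(L) %*% diag(1 / fit$psi, nrow(L))
  B <- solve(W %*% L, W)
  sc <- as.matrix(Z[, names(fit$lambda), drop = FALSE]) %*% t(B)
  colnames(sc) <- names(fit$spec)
  sc
}

#' @export
print.mmb_cfa <- function(x, ...) {
  cat(sprintf(
    "<mmb_cfa> %d factors, %d features (%d pruned), n = %d\n",
    length(x$spec), length(x$lambda), length(x$pruned), x$n))
  cat(sprintf("  chisq(%d) = %.2f, CFI = %.3f, RMSEA = %.3f\n",
              x$df, x$chisq, x$CFI, x$RMSEA))
  invisible(x)
}

#' @export
summary.mmb_cfa <- function(object, ...) {
  cat("Standardized loadings by factor:\n")
  for (f in names(object$spec)) {
    cat(" ", f, "\n")
    for (ft in object$spec[[f]])
      cat(sprintf("    %-40s %6.3f\n", ft, object$lambda[ft]))
  }
  print(object)
  invisible(object)
}

#' @export
coef.mmb_cfa <- function(object, ...) object$lambda

#' @export
predict.mmb_cfa <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$scores)
  tab <- as.data.frame(newdata)[, names(object$lambda), drop = FALSE]
  Z <- scale(as.matrix(tab))
  bartlett_scores(Z, object)
}
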