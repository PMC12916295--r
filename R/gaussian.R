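# Named Gaussian densities: the common currency of priors, posteriors and
# second-level effects.

#' Named multivariate Gaussian density
#'
#' @param mean named numeric vector
#' @param cov covariance matrix (symmetric, positive semi-definite;
#'   dimension names are taken from `mean`)
#' @return object of class `gaussian_density` with elements `mean`, `cov`
#' @export
gaussian_density <- function(mean, cov) {
  if (is.null(names(mean)) || anyDuplicated(names(mean)))
    stop("gaussian_density: mean must have unique names", call. = FALSE)
  cov <- as.matrix(cov)
  if (!all(dim(cov) == length(mean)))
    stop("gaussian_density: cov dimension mismatch", call. = FALSE)
  if (max(abs(cov - t(cov))) > 1e-8 * max(1, max(abs(cov))))
    stop("gaussian_density: cov must be symmetric", call. = FALSE)
  cov <- (cov + t(cov)) / 2
  dimnames(cov) <- list(names(mean), names(mean))
  structure(list(mean = mean, cov = cov), class = "gaussian_density")
}

#' @export
print.gaussian_density <- function(x, ...) {
  cat("gaussian_density over", length(x$mean), "parameters\n")
  print(data.frame(mean = x$mean, sd = sqrt(pmax(diag(x$cov), 0))))
  invisible(x)
}

#' Marginal of a named Gaussian over a subset of parameters
#' @param d a `gaussian_density`
#' @param fields character vector of parameter names to keep
#' @export
marginal_density <- function(d, fields) {
  miss <- setdiff(fields, names(d$mean))
  if (length(miss))
    stop("fields not in density: ", paste(miss, collapse = ", "), call. = FALSE)
  gaussian_density(d$mean[fields], d$cov[fields, fields, drop = FALSE])
}

# log determinant via Cholesky with a symmetric eigen fallback
logdet <- function(M) {
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (!is.null(ch)) return(2 * sum(log(diag(ch))))
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("logdet: matrix not positive definite", call. = FALSE)
  sum(log(ev))
}

# KL(q || p) between two Gaussians with matching layout
kl_gaussian <- function(q, p) {
  n <- length(q$mean)
  Pp <- solve(p$cov)
  dm <- q$mean - p$mean
  0.5 * (sum(diag(Pp %*% q$cov)) + drop(t(dm) %*% Pp %*% dm) - n +
           logdet(p$cov) - logdet(q$cov))
}
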