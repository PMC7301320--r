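#' Assemble the PCA case matrix for one drug x condition cell
#'
#' Stacks the averaged ERPs of one drug x condition tag into the temporal
#' PCA input: rows are cases (subject x block x channel), columns are the
#' 218 half-sampled time points, values in microvolts. With 26 subjects,
#' 2 blocks and 19 channels this is the 988 x 218 matrix with a
#' case-to-variable ratio of 4.53.
#'
#' @param averages an `average_erp_set` (see [build_average_set()]).
#' @param drug,condition tag of the cell to extract.
#' @return a numeric matrix with attributes `keys` (data.frame with
#'   `subject`, `block`, `channel` per row), `times_ms` and `tag`.
#' @export
build_case_matrix <- function(averages, drug, condition) {
  dn <- dimnames(averages$data)
  if (!(drug %in% dn$drug) || !(condition %in% dn$condition)) {
    stop_input("no averages for tag %s/%s", drug, condition)
  }
  miss <- is.na(averages$counts[, , drug, condition])
  if (any(miss)) {
    idx <- which(miss, arr.ind = TRUE)
    stop_input("missing cells for %s/%s: %s", drug, condition,
               paste(sprintf("subject %s block %s", idx[, 1], idx[, 2]),
                     collapse = "; "))
  }
  subjects <- dn$subject
  blocks <- dn$block
  channels <- dn$channel
  keys <- expand.grid(channel = channels, block = blocks, subject = subjects,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  keys <- keys[, c("subject", "block", "channel")]
  x <- matrix(NA_real_, nrow(keys), length(averages$times_ms))
  r <- 1L
  for (s in subjects) for (b in blocks) for (ch in channels) {
    x[r, ] <- averages$data[s, b, drug, condition, ch, ]
    r <- r + 1L
  }
  attr(x, "keys") <- keys
  attr(x, "times_ms") <- averages$times_ms
  attr(x, "tag") <- c(drug = drug, condition = condition)
  x
}

#' Varimax rotation with Kaiser normalization
#'
#' Orthogonal Varimax rotation of a loading matrix. Rows are normalized by
#' their communalities before rotation (Kaiser normalization) and restored
#' afterwards. The Varimax simplicity criterion is tracked across
#' iterations and is non-decreasing; if the iteration limit is reached the
#' best iterate is returned with a warning flag.
#'
#' @param loadings variables x factors loading matrix.
#' @param kaiser apply Kaiser row normalization (default TRUE).
#' @param eps relative convergence tolerance (default 1e-7).
#' @param maxit maximum iterations (default 1000).
#' @return list with `loadings` (rotated), `rotmat` (orthonormal rotation
#'   matrix), `criterion` (per-iteration trace), `converged`.
#' @export
varimax_kaiser <- function(loadings, kaiser = TRUE, eps = 1e-7,
                           maxit = 1000) {
  L <- as.matrix(loadings)
  p <- nrow(L)
  nc <- ncol(L)
  if (nc < 2) {
    return(list(loadings = L, rotmat = diag(nc),
                criterion = varimax_criterion(L), converged = TRUE))
  }
  sc <- if (kaiser) sqrt(rowSums(L^2)) else rep(1, p)
  sc[sc == 0] <- 1
  x <- L / sc
  # two deterministic starts: identity, and a fixed rotation that breaks
  # the saddle symmetry of exactly balanced mixings
  starts <- list(diag(nc), fixed_rotation_start(nc))
  runs <- lapply(starts, function(T0) {
    varimax_iterate(x, T0, eps, maxit)
  })
  best_run <- runs[[which.max(vapply(runs, function(r) r$crit, 0))]]
  if (!best_run$converged) {
    warning("varimax did not converge; returning best iterate")
  }
  list(loadings = (x %*% best_run$TT) * sc, rotmat = best_run$TT,
       criterion = best_run$trace, converged = best_run$converged)
}

# core SVD-based ascent iteration for the Varimax criterion
varimax_iterate <- function(x, TT, eps, maxit) {
  p <- nrow(x)
  d <- 0
  crit <- numeric(0)
  best <- list(TT = TT, crit = varimax_criterion(x %*% TT))
  converged <- FALSE
  for (i in seq_len(maxit)) {
    z <- x %*% TT
    crit[i] <- varimax_criterion(z)
    if (crit[i] >= best$crit) best <- list(TT = TT, crit = crit[i])
    B <- crossprod(x, z^3 - z %*% diag(drop(rep(1, p) %*% z^2)) / p)
    sB <- La.svd(B)
    TT <- sB$u %*% sB$vt
    dpast <- d
    d <- sum(sB$d)
    if (d < dpast * (1 + eps)) {
      converged <- TRUE
      break
    }
  }
  cf <- varimax_criterion(x %*% TT)
  if (cf >= best$crit) best <- list(TT = TT, crit = cf)
  crit <- c(crit, cf)
  list(TT = best$TT, crit = best$crit, trace = crit, converged = converged)
}

# deterministic orthonormal start (QR of a fixed pseudo-random matrix)
fixed_rotation_start <- function(nc) {
  m <- matrix(sin(seq_len(nc * nc) * 12.9898) * 43758.5453 %% 1, nc, nc)
  qr.Q(qr(m + diag(nc)))
}

#' Varimax simplicity criterion
#'
#' Sum over factors of the variance of the squared loadings.
#'
#' @param L loading matrix.
#' @return numeric scalar.
#' @export
varimax_criterion <- function(L) {
  z2 <- L^2
  p <- nrow(L)
  sum(colSums(z2^2) / p - (colSums(z2) / p)^2)
}

#' Temporal PCA of an ERP case matrix
#'
#' Fits the covariance-based temporal PCA: eigendecomposition of the
#' time x time covariance of the column-centered case matrix, unrotated
#' loadings scaled to microvolts (eigenvector x sqrt(eigenvalue)),
#' standardized factor scores, and (by default) unrestricted Varimax
#' rotation with Kaiser normalization of all factors with non-null
#' variance. Rotated factors are reordered by decreasing variance and
#' sign-flipped so each factor's peak loading is positive (polarity is
#' carried by the scores).
#'
#' @param x case matrix from [build_case_matrix()] (or any cases x time
#'   matrix; supply `times_ms` if it has no attribute).
#' @param rotate `"varimax"` (default) or `"none"`.
#' @param kaiser Kaiser-normalize loadings before rotation (default TRUE).
#' @param times_ms time axis override.
#' @param eps,maxit rotation convergence controls.
#' @return an object of class `erp_pca` with elements `loadings` (time x
#'   factor, microvolt-scaled), `scores` (case x factor, standardized),
#'   `eigenvalues`, `pct_variance`, `total_variance`, `center`, `rotmat`,
#'   `criterion`, `peak_latency_ms`, `keys`, `tag`, `times_ms`.
#' @export
erp_pca <- function(x, rotate = c("varimax", "none"), kaiser = TRUE,
                    times_ms = NULL, eps = 1e-7, maxit = 1000) {
  rotate <- match.arg(rotate)
  x <- as.matrix(x)
  if (nrow(x) < 2) stop_input("need at least 2 cases")
  times_ms <- times_ms %||% attr(x, "times_ms") %||% seq_len(ncol(x))
  keys <- attr(x, "keys")
  tag <- attr(x, "tag")
  center <- colMeans(x)
  xc <- sweep(x, 2, center)
  cv <- crossprod(xc) / (nrow(x) - 1)
  e <- eigen(cv, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  total <- sum(diag(cv))
  # epsilon guard: factors with (near-)zero variance are not rotated or scored
  tol <- max(lam) * 1e-10
  nf <- max(1L, sum(lam > tol))
  V <- e$vectors[, seq_len(nf), drop = FALSE]
  lam_f <- lam[seq_len(nf)]
  L <- V %*% diag(sqrt(lam_f), nf) # microvolt-scaled loadings
  S <- xc %*% V %*% diag(1 / sqrt(lam_f), nf) # standardized scores
  rot <- NULL
  if (rotate == "varimax" && nf > 1) {
    rot <- varimax_kaiser(L, kaiser = kaiser, eps = eps, maxit = maxit)
    L <- rot$loadings
    S <- S %*% rot$rotmat
  }
  pct <- colSums(L^2) / total * 100
  ord <- order(pct, decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  S <- S[, ord, drop = FALSE]
  pct <- pct[ord]
  peak_idx <- apply(abs(L), 2, which.max)
  flip <- ifelse(L[cbind(peak_idx, seq_len(nf))] < 0, -1, 1)
  L <- sweep(L, 2, flip, `*`)
  S <- sweep(S, 2, flip, `*`)
  colnames(L) <- colnames(S) <- paste0("F", seq_len(nf))
  structure(list(loadings = L, scores = S, eigenvalues = lam,
                 pct_variance = pct, total_variance = total,
                 center = center, rotmat = rot$rotmat %||% diag(nf),
                 criterion = rot$criterion %||% varimax_criterion(L),
                 converged = rot$converged %||% TRUE,
                 peak_latency_ms = times_ms[peak_idx],
                 n_cases = nrow(x), keys = keys, tag = tag,
                 times_ms = times_ms, rotation = rotate,
                 selected = NULL, labels = NULL,
                 call = match.call()),
            class = "erp_pca")
}

#' @export
print.erp_pca <- function(x, n = 8, ...) {
  tag <- if (!is.null(x$tag)) sprintf(" [%s/%s]", x$tag["drug"],
                                      x$tag["condition"]) else ""
  cat(sprintf("Temporal PCA%s: %d cases x %d time points, %d rotated factors (%s)\n",
              tag, x$n_cases, length(x$times_ms), ncol(x$loadings),
              x$rotation))
  k <- min(n, ncol(x$loadings))
  df <- data.frame(factor = colnames(x$loadings)[1:k],
                   pct_variance = round(x$pct_variance[1:k], 2),
                   peak_ms = round(x$peak_latency_ms[1:k], 1))
  if (!is.null(x$labels)) df$label <- x$labels[1:k]
  if (!is.null(x$selected)) df$selected <- x$selected[1:k]
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.erp_pca <- function(object, ...) {
  df <- data.frame(factor = colnames(object$loadings),
                   pct_variance = object$pct_variance,
                   peak_ms = object$peak_latency_ms,
                   label = object$labels %||% NA_character_,
                   selected = object$selected %||% NA)
  structure(list(table = df, tag = object$tag,
                 total_variance = object$total_variance,
                 converged = object$converged),
            class = "summary.erp_pca")
}

#' @export
print.summary.erp_pca <- function(x, ...) {
  cat(sprintf("Temporal PCA summary (total variance %.1f uV^2)\n",
              x$total_variance))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
coef.erp_pca <- function(object, ...) object$loadings

#' @export
fitted.erp_pca <- function(object, ...) {
  sweep(object$scores %*% t(object$loadings), 2, object$center, `+`)
}

#' @export
residuals.erp_pca <- function(object, x = NULL, ...) {
  if (is.null(x)) {
    stop_input("supply the original case matrix to compute residuals")
  }
  as.matrix(x) - fitted(object)
}

#' Scores for new cases
#'
#' @param object an `erp_pca`.
#' @param newdata cases x time matrix on the same time axis.
#' @param ... unused.
#' @return case x factor score matrix.
#' @export
predict.erp_pca <- function(object, newdata, ...) {
  xc <- sweep(as.matrix(newdata), 2, object$center)
  # loadings are V sqrt(lam) R: scores = Xc V R / sqrt(lam) = Xc L (L'L)^-1
  xc %*% object$loadings %*% solve(crossprod(object$loadings))
}

#' @export
plot.erp_pca <- function(x, which = NULL, ...) {
  which <- which %||% which(x$selected %||% rep(TRUE, ncol(x$loadings)))
  if (!length(which)) which <- seq_len(min(5, ncol(x$loadings)))
  graphics::matplot(x$times_ms, x$loadings[, which, drop = FALSE],
                    type = "l", lty = 1, xlab = "time (ms)",
                    ylab = "scaled loading (uV)", ...)
  lbl <- if (!is.null(x$labels)) x$labels[which] else colnames(x$loadings)[which]
  graphics::legend("topright", legend = lbl, col = seq_along(which),
                   lty = 1, cex = 0.8)
  invisible(x)
}

#' @export
screeplot.erp_pca <- function(x, npcs = 20, ...) {
  k <- min(npcs, length(x$eigenvalues))
  graphics::barplot(x$eigenvalues[1:k], names.arg = seq_len(k),
                    xlab = "factor", ylab = "eigenvalue", ...)
  invisible(x)
}
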