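#' SMOTE class balancing
#'
#' Balances a binary feature matrix by synthesizing minority-class rows:
#' each synthetic row lies on the segment between a randomly chosen
#' minority row and one of its `k_neighbors` nearest minority neighbors
#' (Euclidean distance, interpolation coefficient uniform in `[0, 1]`).
#' Original rows are returned unchanged, followed by the synthetic rows.
#' Balancing is only ever applied to training data; resampled rows must
#' never reach a test fold.
#'
#' @param X Numeric matrix or data frame of feature rows.
#' @param y Binary label vector.
#' @param k_neighbors Number of nearest minority neighbors (default 5);
#'   the minority class must have more than `k_neighbors` rows.
#' @param seed Optional integer seed for reproducible interpolation draws.
#' @return List with balanced `X`, `y` and a logical vector `synthetic`
#'   marking the generated rows.
#' @export
smote_balance <- function(X, y, k_neighbors = 5, seed = NULL) {
  X <- as.matrix(X)
  y <- as.character(y)
  tab <- table(y)
  if (length(tab) < 2L)
    bf_stop("SMOTE needs both classes present", "bf_balance_error")
  minority <- names(tab)[which.min(tab)]
  n_min <- min(tab); n_maj <- max(tab)
  if (n_min <= k_neighbors)
    bf_stop(sprintf("minority class has %d rows; need more than k_neighbors = %d",
                    n_min, k_neighbors), "bf_neighbor_error")
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  n_new <- n_maj - n_min
  if (n_new == 0L)
    return(list(X = X, y = y, synthetic = rep(FALSE, nrow(X))))
  Xm <- X[y == minority, , drop = FALSE]
  base <- sample.int(n_min, n_new, replace = TRUE)
  u <- stats::runif(n_new)
  synth <- matrix(NA_real_, n_new, ncol(X))
  sq <- rowSums(Xm^2)
  for (b in unique(base)) {
    # k nearest minority neighbors of row b (itself excluded)
    d2 <- sq - 2 * drop(Xm %*% Xm[b, ]) + sum(Xm[b, ]^2)
    d2[b] <- Inf
    nb <- order(d2)[seq_len(k_neighbors)]
    rows <- which(base == b)
    pick <- nb[sample.int(k_neighbors, length(rows), replace = TRUE)]
    synth[rows, ] <- Xm[rep(b, length(rows)), , drop = FALSE] +
      u[rows] * (Xm[pick, , drop = FALSE] -
                   Xm[rep(b, length(rows)), , drop = FALSE])
  }
  colnames(synth) <- colnames(X)
  list(X = rbind(X, synth), y = c(y, rep(minority, n_new)),
       synthetic = c(rep(FALSE, nrow(X)), rep(TRUE, n_new)))
}
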