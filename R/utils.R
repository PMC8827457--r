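# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a child seed from a master seed and a stream index; stays < 2^31.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 16807) %% 2147483629) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

# Separable Gaussian blur with reflective (half-sample symmetric) boundary.
# A normalized truncated kernel plus reflective padding preserves total mass.
gaussian_blur <- function(x, sigma) {
  if (length(sigma) == 1L) sigma <- c(sigma, sigma)
  if (any(sigma < 0)) stop("sigma must be non-negative", call. = FALSE)
  blur1 <- function(m, s) {
    if (s == 0) return(m)
    r <- max(1L, ceiling(3 * s))
    k <- exp(-(seq(-r, r))^2 / (2 * s^2))
    k <- k / sum(k)
    n <- nrow(m)
    idx <- c(rev(seq_len(min(r, n))), seq_len(n), rev(seq_len(n))[seq_len(min(r, n))])
    if (r > n) { # degenerate tiny inputs: clamp reflection
      idx <- c(rep(1L, r - n), idx, rep(n, r - n))
    }
    p <- m[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (t in seq_along(k)) {
      out <- out + k[t] * p[(t - 1L) + seq_len(n), , drop = FALSE]
    }
    out
  }
  x <- blur1(x, sigma[1])
  t(blur1(t(x), sigma[2]))
}

# 4-connected component labelling of a logical matrix (two-pass union-find).
label_components <- function(mask) {
  mask <- mask != 0
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nxt <- 0L
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (!mask[i, j]) next
    up <- if (i > 1L) lab[i - 1L, j] else 0L
    lf <- if (j > 1L) lab[i, j - 1L] else 0L
    if (up == 0L && lf == 0L) {
      nxt <- nxt + 1L; parent[nxt] <- nxt; lab[i, j] <- nxt
    } else if (up != 0L && lf != 0L) {
      ru <- find(up); rl <- find(lf)
      lab[i, j] <- min(ru, rl)
      parent[max(ru, rl)] <- min(ru, rl)
    } else {
      lab[i, j] <- max(up, lf)
    }
  }
  if (nxt == 0L) return(lab)
  roots <- vapply(seq_len(nxt), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  pos <- lab != 0L
  lab[pos] <- relab[lab[pos]]
  lab
}
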