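# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded package operations do
#' not perturb the caller's random number stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stopf("`%s` must be TRUE or FALSE", name)
  }
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stopf("`%s` must be an integer >= %d", name, min)
  }
}

assert_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min) {
    stopf("`%s` must be a single number >= %s", name, format(min))
  }
}

# Median of the observed values; NA when nothing is observed.
med_obs <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  median(x)
}

#' Additive two-way fixed-effects summarization
#'
#' Least-squares fit of `y ~ unit + peptide` on observed cells with
#' sum-to-zero peptide effects; returns the per-unit summary
#' (intercept + unit effect), which reduces to the per-unit mean on
#' balanced complete data. Units with no observation get NA. This is the
#' summarization model used for both spiked standard proteins (units =
#' runs) and endogenous proteins (units = subjects).
#'
#' @param y numeric vector of log2 intensities (NA allowed, dropped).
#' @param unit,peptide parallel label vectors.
#' @param all_units optional superset of unit labels for the output.
#' @return named numeric vector of per-unit summaries.
#' @noRd
additive_summary <- function(y, unit, peptide, all_units = NULL) {
  keep <- !is.na(y)
  y <- y[keep]; unit <- as.character(unit)[keep]; peptide <- as.character(peptide)[keep]
  units <- unique(unit)
  out_units <- all_units %||% units
  out <- setNames(rep(NA_real_, length(out_units)), out_units)
  if (!length(y)) return(out)
  peps <- unique(peptide)
  J <- length(peps)
  ui <- match(unit, units)
  pj <- match(peptide, peps)
  if (J == 1L) {
    s <- vapply(split(y, ui), mean, 0)
    out[units[as.integer(names(s))]] <- s
    return(out)
  }
  # Reduced normal equations for the peptide effects after absorbing the
  # unit effects; sum-to-zero constraint imposed by rank-one augmentation.
  I <- length(units)
  N <- matrix(0, I, J)
  Y <- matrix(0, I, J)
  N[cbind(ui, pj)] <- 1
  Y[cbind(ui, pj)] <- y
  m <- rowSums(N)
  ybar <- rowSums(Y) / m
  Mred <- crossprod(N / sqrt(m))          # J x J: sum_u n_uj n_uk / m_u
  A <- diag(colSums(N), J) - Mred
  b <- colSums(Y) - colSums(N * ybar)
  p_eff <- tryCatch(
    solve(A + matrix(1, J, J), b),
    error = function(e) rep(0, J)         # confounded design: fall back to means
  )
  s <- ybar - as.vector(N %*% p_eff) / m
  out[units] <- s
  out
}

# Pretty fraction formatting for messages.
pct <- function(x) sprintf("%.1f%%", 100 * x)
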