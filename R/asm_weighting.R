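# Per-pathway weights for the ASM and non-ASM gene subsets, derived from
# the proportions of informative genes through the harmonic-average rule.

#' Harmonic average of two positive proportions
#'
#' `H = 2 / (1/R_n + 1/R_m)`, always between `min(R_n, R_m)` and
#' `max(R_n, R_m)`; the harmonic mean damps the influence of an extreme
#' proportion.
#'
#' @param R_n,R_m strictly positive proportions.
#' @return harmonic average.
#' @export
harmonic_average <- function(R_n, R_m) {
  if (any(R_n <= 0) || any(R_m <= 0)) stop("proportions must be > 0", call. = FALSE)
  2 * R_n * R_m / (R_n + R_m)
}

#' Binned ASM weight for pathways without informative non-ASM genes
#'
#' Maps an informative-gene proportion to an integer weight 1..6 on the
#' cutoffs 0.1, 0.3, 0.5, 0.7, 0.9 with left-closed bins:
#' `[0,0.1) -> 1`, ..., `[0.9,1] -> 6`.
#'
#' @param prop proportion(s) in (0, 1].
#' @return integer weight(s) in 1..6.
#' @export
binned_weight <- function(prop) {
  if (any(prop <= 0 | prop > 1)) stop("prop must lie in (0, 1]", call. = FALSE)
  findInterval(prop, c(0.1, 0.3, 0.5, 0.7, 0.9)) + 1L
}

# fast numeric (w_asm, w_nonasm) used inside the permutation loop;
# branch logic identical to pathway_weights()
.weight_pair <- function(n, m, k_n, k_m) {
  if (n == 0L || m == 0L) return(c(1, 1))
  if (k_m == 0L && k_n > 0L) return(c(binned_weight(k_n / n), 1))
  if (k_n * m > k_m * n) {              # exact integer comparison of k_n/n > k_m/m
    R_n <- k_n / n; R_m <- k_m / m
    return(c((R_n + R_m) / (2 * R_m), (R_n + R_m) / (2 * R_n)))
  }
  c(1, 1)
}

#' ASM / non-ASM weights for one pathway
#'
#' Given the pathway's ASM subset size `n`, non-ASM subset size `m` and
#' the informative-gene counts `k_n`, `k_m`, applies the weighting rule:
#' \itemize{
#' \item `degenerate_equal`: the pathway is entirely ASM or entirely
#'   non-ASM (`n == 0` or `m == 0`); no contrast exists, weights (1, 1).
#' \item `binned`: no informative non-ASM genes but some informative ASM
#'   genes; `w_asm` = [binned_weight()] of `k_n/n`, `w_nonasm` = 1.
#' \item `harmonic`: the ASM proportion `R_n = k_n/n` strictly exceeds
#'   `R_m = k_m/m`; weights are `R_n/H` and `R_m/H` with `H` the
#'   [harmonic_average()], so `w_asm >= 1 >= w_nonasm`.
#' \item `equal`: otherwise (including `k_n = 0`), weights (1, 1).
#' }
#' The proportion comparison is done on exact integer cross-products, so
#' reduced fractions with equal value are treated as equal.
#'
#' @param n,m counts of ASM and non-ASM genes on the pathway's mapped list.
#' @param k_n,k_m counts of informative genes in each subset.
#' @param pathway_name optional label carried through to the output.
#' @return object of class `pathway_weights`: list with `pathway_name`,
#'   `n`, `m`, `k_n`, `k_m`, `R_n`, `R_m`, `H`, `w_asm`, `w_nonasm`,
#'   `rule_branch`.
#' @export
pathway_weights <- function(n, m, k_n, k_m, pathway_name = NA_character_) {
  n <- as.integer(n); m <- as.integer(m)
  k_n <- as.integer(k_n); k_m <- as.integer(k_m)
  stopifnot(n + m >= 1, k_n >= 0, k_m >= 0)
  if (k_n > n || k_m > m) stop("informative counts exceed subset sizes", call. = FALSE)
  R_n <- if (n > 0) k_n / n else NA_real_
  R_m <- if (m > 0) k_m / m else NA_real_
  if (n == 0L || m == 0L) {
    branch <- "degenerate_equal"; H <- NA_real_; w <- c(1, 1)
  } else if (k_m == 0L && k_n > 0L) {
    branch <- "binned_no_nonasm_informative"; H <- NA_real_
    w <- c(binned_weight(R_n), 1)
  } else if (k_n * m > k_m * n) {
    branch <- "harmonic"
    H <- harmonic_average(R_n, R_m)
    w <- c(R_n / H, R_m / H)
  } else {
    branch <- "equal"; H <- NA_real_; w <- c(1, 1)
  }
  structure(list(pathway_name = pathway_name, n = n, m = m, k_n = k_n,
                 k_m = k_m, R_n = R_n, R_m = R_m, H = H,
                 w_asm = w[1], w_nonasm = w[2], rule_branch = branch),
            class = "pathway_weights")
}

#' @export
print.pathway_weights <- function(x, ...) {
  cat(sprintf("pathway_weights [%s]: n=%d (k=%d), m=%d (k=%d) -> w_asm=%.4g, w_nonasm=%.4g (%s)\n",
              ifelse(is.na(x$pathway_name), "-", x$pathway_name),
              x$n, x$k_n, x$m, x$k_m, x$w_asm, x$w_nonasm, x$rule_branch))
  invisible(x)
}
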