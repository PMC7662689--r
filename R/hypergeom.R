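#' Upper-tail hypergeometric probability of shared miRNA regulators
#'
#' Computes `P(X >= x)` for `X` hypergeometric with a population of `n_total`
#' miRNAs, of which `n_lnc` regulate the lncRNA, when `n_mrna` regulate the
#' mRNA. This is the competition test at the core of ceRNA network
#' construction: a small tail probability means the lncRNA and the mRNA share
#' more miRNA regulators than expected by chance, i.e. they plausibly compete
#' for the same miRNA pool. The same statistic doubles as the
#' over-representation test in [gene_set_ora()].
#'
#' The tail is evaluated in survival-function form (`stats::phyper` with
#' `lower.tail = FALSE`), which is numerically stable far into the tail, and
#' clipped to `[0, 1]`.
#'
#' @param n_total Total number of miRNAs in the background universe (`N_T`).
#' @param n_lnc Number of miRNAs regulating the lncRNA (`N_lnc`).
#' @param n_mrna Number of miRNAs regulating the mRNA (`N_mRNA`).
#' @param x Observed number of shared miRNAs. Vectorised over all arguments.
#' @return Numeric vector of tail probabilities `P(X >= x)`.
#' @examples
#' hypergeom_tail(10, 4, 5, 0) # 1: the empty event is certain
#' hypergeom_tail(6, 3, 3, 3) # 1/20: all three regulators shared
#' @export
hypergeom_tail <- function(n_total, n_lnc, n_mrna, x) {
  args <- vctrs_recycle(n_total = n_total, n_lnc = n_lnc, n_mrna = n_mrna, x = x)
  with(args, {
    if (any(is.na(n_total) | is.na(n_lnc) | is.na(n_mrna) | is.na(x))) {
      abort("hypergeom_tail() arguments must not contain missing values.")
    }
    if (any(n_lnc < 0 | n_mrna < 0 | n_lnc > n_total | n_mrna > n_total)) {
      abort("Require 0 <= n_lnc, n_mrna <= n_total.")
    }
    if (any(x < 0 | x > pmin(n_lnc, n_mrna))) {
      abort("Require 0 <= x <= min(n_lnc, n_mrna).")
    }
    p <- phyper(x - 1, m = n_lnc, n = n_total - n_lnc, k = n_mrna,
                lower.tail = FALSE)
    pmin(pmax(p, 0), 1)
  })
}

# minimal common-length recycling without depending on vctrs
vctrs_recycle <- function(...) {
  args <- list(...)
  n <- max(lengths(args))
  bad <- lengths(args) != 1L & lengths(args) != n
  if (any(bad)) abort("Arguments must have length 1 or a common length.")
  lapply(args, rep_len, n)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement and
#' clipping at 1, returned in the input order. Thin wrapper over
#' [stats::p.adjust()] with a domain check on the inputs.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) abort("`p` must be numeric.")
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1] and contain no missing values.")
  }
  p.adjust(p, method = "BH")
}
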